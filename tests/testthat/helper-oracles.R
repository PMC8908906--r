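# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition with naive loops, so they share
# no code path with the package implementations they check.

# random genotype fixture
random_geno <- function(n, m, n_chrom = 1, miss = 0, maxpos = 1e6) {
  stopifnot(m %% n_chrom == 0)
  per <- m / n_chrom
  map <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    data.frame(snp_id = sprintf("c%ds%d", ch, seq_len(per)),
               chrom = as.character(ch),
               pos_bp = sort(sample.int(maxpos, per)),
               allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  }))
  p <- runif(m, 0.1, 0.9)
  D <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (miss > 0) D[runif(length(D)) < miss] <- NA
  dimnames(D) <- list(sprintf("an%03d", seq_len(n)), NULL)
  geno_matrix(D, map)
}

# heterosis / recombination loss from first principles (explicit breed loop)
oracle_heterosis <- function(sire, dam) {
  breeds <- union(names(sire), names(dam))
  tot <- 0
  for (b in breeds) {
    bs <- if (b %in% names(sire)) sire[[b]] else 0
    bd <- if (b %in% names(dam)) dam[[b]] else 0
    tot <- tot + bs * bd
  }
  1 - tot
}

oracle_rec_loss <- function(sire, dam) {
  breeds <- union(names(sire), names(dam))
  tot <- 0
  for (b in breeds) {
    bs <- if (b %in% names(sire)) sire[[b]] else 0
    bd <- if (b %in% names(dam)) dam[[b]] else 0
    tot <- tot + (bs^2 + bd^2) / 2
  }
  1 - tot
}

random_composition <- function(breeds) {
  x <- rexp(length(breeds))
  setNames(x / sum(x), breeds)
}

# recursive kinship (Malecot) oracle; ped sorted parents-first, NA founders
oracle_kinship <- function(ped) {
  ids <- ped$animal_id
  n <- length(ids)
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  phi <- matrix(NA_real_, n, n)
  kin <- function(i, j) {
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + (if (!is.na(si[i]) && !is.na(di[i])) kin(si[i], di[i]) else 0))
    } else {
      a <- max(i, j)  # sorted: the later animal's parents are earlier
      b <- min(i, j)
      if (is.na(si[a]) && is.na(di[a])) 0 else {
        0.5 * ((if (!is.na(si[a])) kin(si[a], b) else 0) +
                 (if (!is.na(di[a])) kin(di[a], b) else 0))
      }
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(n)) kin(i, j)
  phi
}

# gene-dropping estimate of 2 * kinship between two animals
oracle_gene_drop_A <- function(ped, n_drops = 1e5) {
  ids <- ped$animal_id
  n <- length(ids)
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  # drop a single biallelic locus; founders get unique allele labels
  al1 <- matrix(0L, n_drops, n)
  al2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      al1[, i] <- lab + 1L
      al2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick1 <- runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick1, al1[, si[i]], al2[, si[i]])
      pick2 <- runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick2, al1[, di[i]], al2[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ibd <- (al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
      (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])
    A[i, j] <- mean(ibd) / 2
  }
  A
}

# naive ROHet oracle: explicit window loops per the detector definition
naive_rohet <- function(d, pos, params) {
  m <- length(d)
  w <- params$window
  if (m < w) return(data.frame(start_bp = integer(), end_bp = integer(),
                               n_snps = integer()))
  nw <- m - w + 1
  win_ok <- logical(nw)
  for (s in seq_len(nw)) {
    window <- d[s:(s + w - 1)]
    n_na <- sum(is.na(window))
    n_hom <- sum(window != 1, na.rm = TRUE)
    win_ok[s] <- n_na <= params$max_missing_per_window &&
      n_hom <= params$max_hom_per_window
  }
  flagged <- logical(m)
  for (j in seq_len(m)) {
    covering <- intersect(seq_len(nw), (j - w + 1):j)
    flagged[j] <- mean(win_ok[covering]) > params$snp_in_run_threshold
  }
  # consecutive flagged SNPs -> candidate runs, endpoints trimmed to called
  runs <- list()
  i <- 1
  while (i <= m) {
    if (!flagged[i]) {
      i <- i + 1
      next
    }
    j <- i
    while (j < m && flagged[j + 1] && (pos[j + 1] - pos[j]) <= params$max_gap_bp) {
      j <- j + 1
    }
    s <- i
    e <- j
    while (s <= e && is.na(d[s])) s <- s + 1
    while (e >= s && is.na(d[e])) e <- e - 1
    if (s <= e) {
      len <- pos[e] - pos[s] + 1
      nsnp <- e - s + 1
      if (len >= params$min_length_bp && nsnp / len >= params$min_density) {
        runs[[length(runs) + 1]] <- data.frame(start_bp = pos[s],
                                               end_bp = pos[e],
                                               n_snps = nsnp)
      }
    }
    i <- j + 1
  }
  if (!length(runs)) {
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer()))
  }
  do.call(rbind, runs)
}

# dense direct-formula REML log-likelihood (Patterson-Thompson, profiled GLS)
oracle_reml_loglik <- function(y, X, K, sa2, se2) {
  n <- length(y)
  p <- ncol(X)
  V <- sa2 * K + diag(se2, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
                       determinant(XtViX)$modulus + t(r) %*% Vi %*% r))
}

# brute-force Method I GRM with explicit double loop
oracle_grm <- function(D, p) {
  n <- nrow(D)
  m <- ncol(D)
  Z <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    Z[i, j] <- if (is.na(D[i, j])) 0 else D[i, j] - 2 * p[j]
  }
  G <- matrix(0, n, n)
  denom <- 2 * sum(p * (1 - p))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    G[i, k] <- sum(Z[i, ] * Z[k, ]) / denom
  }
  G
}

# per-locus additive+dominance OLS through lm()
oracle_scan_locus <- function(e, d) {
  ok <- !is.na(d)
  e <- e[ok]
  d <- d[ok]
  a <- d
  h <- as.numeric(d == 1)
  classes <- length(unique(d))
  if (classes == 3) {
    fit <- summary(lm(e ~ a + h))$coefficients
    c(b1 = fit["a", 1], se1 = fit["a", 2], p_add = fit["a", 4],
      b2 = fit["h", 1], se2 = fit["h", 2], p_dom = fit["h", 4])
  } else if (classes == 2) {
    fit <- summary(lm(e ~ a))$coefficients
    c(b1 = fit["a", 1], se1 = fit["a", 2], p_add = fit["a", 4],
      b2 = NA, se2 = NA, p_dom = NA)
  } else {
    c(b1 = NA, se1 = NA, p_add = NA, b2 = NA, se2 = NA, p_dom = NA)
  }
}

# genotype fixture with controllable LD: partner columns copy an anchor
# column with a given disagreement rate
ld_geno <- function(n, pos, anchor_cols, copy_of = NULL, seed = 1) {
  set.seed(seed)
  m <- length(pos)
  D <- sapply(seq_len(m), function(j) rbinom(n, 2, 0.5))
  if (!is.null(copy_of)) {
    for (k in seq_along(copy_of$to)) {
      src <- D[, copy_of$from[k]]
      flip <- runif(n) < copy_of$err[k]
      D[, copy_of$to[k]] <- ifelse(flip, rbinom(n, 2, 0.5), src)
    }
  }
  dimnames(D) <- list(sprintf("an%03d", seq_len(n)), NULL)
  geno_matrix(matrix(as.integer(D), n, m, dimnames = dimnames(D)),
              data.frame(snp_id = paste0("s", seq_len(m)), chrom = "1",
                         pos_bp = pos, allele_a = "A", allele_b = "B"))
}
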