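#' Adjust phenotypes for fixed effects and the polygenic effect
#'
#' First stage of the two-stage genome-wide scan: fits the pre-adjustment
#' mixed model (contemporary group, birth herd type, dam parity and twin
#' status as fixed effects -- no heterozygosity covariate -- and a random
#' polygenic effect with covariance `G sigma_a2`) and returns the residuals
#' `e = y - X beta - u`, which carry neither the nuisance structure nor the
#' additive polygenic background.
#'
#' @param ph phenotype data.frame with `animal_id`, `trait_value`,
#'   `dam_parity`, `birth_herd`, `twin`, `contemporary_group`
#' @param grm a [build_grm_method1()] result covering all phenotyped animals
#' @return list of class `adjusted_phenotypes`: `residuals` (named by
#'   animal id) and `fit` (the [fit_lmm()] object)
#' @export
adjust_phenotypes <- function(ph, grm) {
  stopifnot(inherits(grm, "grm"))
  k <- match(ph$animal_id, rownames(grm$G))
  if (anyNA(k)) {
    stop("animal(s) missing from the GRM: ",
         paste(utils::head(ph$animal_id[is.na(k)], 5), collapse = ", "))
  }
  G <- grm$G[k, k, drop = FALSE]
  X <- build_design(ph, factors = c("dam_parity", "birth_herd", "twin",
                                    "contemporary_group"))
  fit <- fit_lmm(ph$trait_value, X, G)
  structure(list(residuals = stats::setNames(fit$residuals, ph$animal_id),
                 fit = fit),
            class = "adjusted_phenotypes")
}

# closed-form OLS of e on [1, additive code, dominance code] via genotype
# class sufficient statistics; returns one scan row per column of stats
.scan_from_class_stats <- function(n0, n1, n2, s0, s1, s2, ss) {
  n_used <- n0 + n1 + n2
  m_cls <- 3L - (n0 == 0) - (n1 == 0) - (n2 == 0)
  b1 <- se1 <- p_add <- b2 <- se2 <- p_dom <- rep(NA_real_, length(n0))
  # full model (all three classes observed): saturated in the class means
  full <- m_cls == 3L & n_used > 3L
  if (any(full)) {
    m0 <- s0[full] / n0[full]
    m1 <- s1[full] / n1[full]
    m2 <- s2[full] / n2[full]
    rss <- ss[full] - (s0[full]^2 / n0[full] + s1[full]^2 / n1[full] +
                         s2[full]^2 / n2[full])
    df <- n_used[full] - 3L
    s2e <- pmax(rss, 0) / df
    b1[full] <- (m2 - m0) / 2
    b2[full] <- m1 - (m0 + m2) / 2
    v1 <- s2e * (1 / n0[full] + 1 / n2[full]) / 4
    v2 <- s2e * (1 / n1[full] + (1 / n0[full] + 1 / n2[full]) / 4)
    se1[full] <- sqrt(v1)
    se2[full] <- sqrt(v2)
    p_add[full] <- 2 * stats::pt(-abs(b1[full] / se1[full]), df)
    p_dom[full] <- 2 * stats::pt(-abs(b2[full] / se2[full]), df)
  }
  # two observed classes: dominance not estimable; additive slope from the
  # simple regression of e on the additive code
  two <- m_cls == 2L & n_used > 2L
  if (any(two)) {
    cnt <- rbind(n0[two], n1[two], n2[two])
    sm <- rbind(s0[two], s1[two], s2[two])
    code <- c(0, 1, 2)
    sa <- colSums(cnt * code)
    saa <- colSums(cnt * code^2)
    sy <- colSums(sm)
    say <- colSums(sm * code)
    nn <- n_used[two]
    sxx <- saa - sa^2 / nn
    sxy <- say - sa * sy / nn
    slope <- sxy / sxx
    rss <- pmax(ss[two] - sy^2 / nn - slope * sxy, 0)
    df <- nn - 2L
    vs <- rss / df / sxx
    b1[two] <- slope
    se1[two] <- sqrt(vs)
    p_add[two] <- 2 * stats::pt(-abs(slope / sqrt(vs)), df)
  }
  data.frame(n_used = as.integer(n_used), het_freq = n1 / pmax(n_used, 1L),
             b1 = b1, se1 = se1, p_add = p_add,
             b2 = b2, se2 = se2, p_dom = p_dom)
}

#' Additive + dominance regression at a single locus
#'
#' OLS of the adjusted residuals on an intercept, the additive genotype
#' code (0/1/2 copies of allele b) and the dominance code (1 for the
#' heterozygote, 0 for either homozygote), restricted to animals with a
#' non-missing call. When fewer than three genotype classes are observed
#' the dominance effect is not estimable and `b2` is `NA`; monomorphic loci
#' return `NA` for both effects.
#'
#' @param e residual vector named by animal id (or an
#'   `adjusted_phenotypes` object)
#' @param g a [geno_matrix()]
#' @param snp a SNP id or column index
#' @return one-row data.frame: `snp_id`, `n_used`, `het_freq`, `b1`, `se1`,
#'   `p_add`, `b2`, `se2`, `p_dom`
#' @export
scan_locus <- function(e, g, snp) {
  res <- run_scan(e, g, snps = snp, fdr_threshold = NULL)
  res$table
}

#' Genome-wide additive + dominance scan with FDR control
#'
#' Runs [scan_locus()]'s regression at every SNP (vectorized over loci),
#' converts the additive and dominance p-value families separately into
#' Storey q-values, computes the genomic inflation factor of each family,
#' and reports the SNP sets significant at the FDR threshold.
#'
#' @param e residual vector named by animal id, or an
#'   [adjust_phenotypes()] result
#' @param g a [geno_matrix()] over the same animals
#' @param fdr_threshold q-value cut-off for significance (default 0.01);
#'   `NULL` skips the q-value/diagnostic stage (used for single-locus calls)
#' @param snps optional subset of SNPs to scan
#' @return list of class `scan_result`: `table` (one row per SNP with b1,
#'   se1, p_add, q_add, b2, se2, p_dom, q_dom, n_used, het_freq),
#'   `lambda_add`, `lambda_dom`, `sig_add`, `sig_dom` (SNP id vectors) and
#'   `fdr_threshold`
#' @export
run_scan <- function(e, g, fdr_threshold = 0.01, snps = NULL) {
  if (inherits(e, "adjusted_phenotypes")) e <- e$residuals
  stopifnot(inherits(g, "geno_matrix"), !is.null(names(e)))
  k <- match(names(e), rownames(g$dosage))
  if (anyNA(k)) stop("residual animal(s) missing from the genotype matrix")
  D <- g$dosage[k, , drop = FALSE]
  map <- g$map
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, map$snp_id) else as.integer(snps)
    if (anyNA(j)) stop("unknown SNP id(s)")
    D <- D[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  ev <- as.numeric(e)
  ind <- function(val) {
    M <- D == val
    M[is.na(M)] <- FALSE
    M
  }
  I0 <- ind(0L); I1 <- ind(1L); I2 <- ind(2L)
  n0 <- colSums(I0); n1 <- colSums(I1); n2 <- colSums(I2)
  s0 <- as.numeric(crossprod(I0, ev))
  s1 <- as.numeric(crossprod(I1, ev))
  s2 <- as.numeric(crossprod(I2, ev))
  called <- I0 | I1 | I2
  ss <- as.numeric(crossprod(called, ev^2))
  tab <- .scan_from_class_stats(n0, n1, n2, s0, s1, s2, ss)
  tab <- cbind(data.frame(snp_id = map$snp_id, chrom = map$chrom,
                          pos_bp = map$pos_bp, stringsAsFactors = FALSE),
               tab)
  if (is.null(fdr_threshold)) {
    return(structure(list(table = tab, lambda_add = NA_real_,
                          lambda_dom = NA_real_, sig_add = character(),
                          sig_dom = character(), fdr_threshold = NA_real_),
                     class = "scan_result"))
  }
  tab$q_add <- NA_real_
  tab$q_dom <- NA_real_
  ok_a <- !is.na(tab$p_add)
  ok_d <- !is.na(tab$p_dom)
  if (any(ok_a)) tab$q_add[ok_a] <- qvalues(tab$p_add[ok_a])
  if (any(ok_d)) tab$q_dom[ok_d] <- qvalues(tab$p_dom[ok_d])
  lambda_add <- if (sum(ok_a) >= 100) genomic_lambda(tab$p_add[ok_a]) else NA_real_
  lambda_dom <- if (sum(ok_d) >= 100) genomic_lambda(tab$p_dom[ok_d]) else NA_real_
  structure(list(table = tab, lambda_add = lambda_add,
                 lambda_dom = lambda_dom,
                 sig_add = tab$snp_id[ok_a & tab$q_add <= fdr_threshold],
                 sig_dom = tab$snp_id[ok_d & tab$q_dom <= fdr_threshold],
                 fdr_threshold = fdr_threshold),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d SNPs; lambda_add=%.3f lambda_dom=%.3f; %d additive and %d dominance SNPs at q<=%s\n",
              nrow(x$table), x$lambda_add, x$lambda_dom,
              length(x$sig_add), length(x$sig_dom),
              format(x$fdr_threshold)))
  invisible(x)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` where the chi-square statistics
#' are recovered from the p-values (`qchisq(1 - p, 1)`). Values near 1
#' indicate well-calibrated tests; inflation above ~1.1 suggests residual
#' stratification.
#'
#' @param p_values numeric vector of p-values (at least 100 recommended)
#' @return lambda (> 0)
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  stopifnot(length(p_values) >= 1, all(p_values >= 0 & p_values <= 1))
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` from the tail of the p-value
#' distribution on the lambda grid 0, 0.05, ..., 0.90 with a cubic
#' smoothing-spline extrapolation (Storey & Tibshirani's smoother), then
#' computes `q_i = min over t >= p_(i) of pi0 * m * t / #{p <= t}`. With
#' `pi0 = 1` the procedure reduces to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @param pi0 optional fixed null proportion (estimated when `NULL`)
#' @param lambda_grid grid for the pi0 smoother
#' @return q-values in the input order
#' @export
qvalues <- function(p, pi0 = NULL, lambda_grid = seq(0, 0.90, by = 0.05)) {
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1, na.rm = FALSE), !anyNA(p))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100 || min(p) == max(p)) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l),
                      numeric(1))
      sp <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda_grid))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  r <- rank(p, ties.method = "max")      # #{p <= p_i}
  q0 <- pi0 * m * p / r
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(cummin(q0[o]), 1)         # min over thresholds t >= p_i
  q
}
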