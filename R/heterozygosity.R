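#' Per-locus allele frequency and expected heterozygosity
#'
#' Expected heterozygosity at a biallelic locus is `1 - q^2 - (1 - q)^2 =
#' 2q(1-q)`, with `q` the allele-b frequency estimated from the non-missing
#' calls of the analyzed cohort (or supplied externally, e.g. from a larger
#' reference cohort).
#'
#' @param g a [geno_matrix()]
#' @param freqs optional external allele-b frequencies, one per SNP
#' @return data.frame with `snp_id`, `freq_b`, `exp_het`
#' @export
locus_stats <- function(g, freqs = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(freqs)) {
    n_called <- colSums(!is.na(g$dosage))
    if (any(n_called == 0)) {
      stop("SNP(s) with all calls missing: ",
           paste(utils::head(g$map$snp_id[n_called == 0], 5), collapse = ", "))
    }
    freqs <- colMeans(g$dosage, na.rm = TRUE) / 2
  }
  stopifnot(length(freqs) == ncol(g$dosage), all(freqs >= 0 & freqs <= 1))
  data.frame(snp_id = g$map$snp_id, freq_b = as.numeric(freqs),
             exp_het = 2 * freqs * (1 - freqs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed heterozygosity per animal
#'
#' Number of called heterozygous SNPs divided by the total number of called
#' SNPs; missing calls are excluded from both counts.
#'
#' @param g a [geno_matrix()]
#' @return named numeric vector, one value per animal
#' @export
observed_heterozygosity <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  called <- rowSums(!is.na(g$dosage))
  if (any(called == 0)) {
    stop("animal(s) with all calls missing: ",
         paste(utils::head(rownames(g$dosage)[called == 0], 5), collapse = ", "))
  }
  rowSums(g$dosage == 1L, na.rm = TRUE) / called
}

#' Homozygosity by locus (HL) per animal
#'
#' `sum(E_hom) / (sum(E_hom) + sum(E_het))`, where `E_hom` (`E_het`) are the
#' expected heterozygosities of the loci at which the animal is homozygous
#' (heterozygous). 0 means fully heterozygous, 1 fully homozygous; loci with
#' missing calls are excluded.
#'
#' @param g a [geno_matrix()]
#' @param stats output of [locus_stats()] (cohort frequencies used if absent)
#' @return named numeric vector, one value per animal
#' @export
homozygosity_by_locus <- function(g, stats = locus_stats(g)) {
  stopifnot(inherits(g, "geno_matrix"), nrow(stats) == ncol(g$dosage))
  E <- stats$exp_het
  het <- g$dosage == 1L
  het[is.na(het)] <- FALSE
  hom <- g$dosage != 1L
  hom[is.na(hom)] <- FALSE
  e_hom <- as.numeric(hom %*% E)
  e_het <- as.numeric(het %*% E)
  den <- e_hom + e_het
  if (any(den == 0)) {
    stop("HL undefined (all called loci monomorphic) for animal(s): ",
         paste(utils::head(rownames(g$dosage)[den == 0], 5), collapse = ", "))
  }
  stats::setNames(e_hom / den, rownames(g$dosage))
}

#' Default parameters of the run-of-heterozygosity detector
#'
#' A 50-SNP window slides one SNP at a time. A window is "heterozygous" when
#' it contains at most `max_missing_per_window` missing and at most
#' `max_hom_per_window` homozygous calls. A SNP is flagged when the fraction
#' of windows covering it that are heterozygous exceeds
#' `snp_in_run_threshold`. Maximal stretches of consecutive flagged SNPs
#' (inter-SNP gap at most `max_gap_bp`) become candidate runs, kept when the
#' spanned length is at least `min_length_bp` and the SNP density is at
#' least `min_density` (SNPs per bp).
#'
#' @param window window size in SNPs
#' @param max_missing_per_window,max_hom_per_window window tolerance counts
#' @param min_length_bp minimum run span (closed interval, bp)
#' @param min_density minimum SNPs per bp within a run (default one SNP per
#'   50 kb)
#' @param snp_in_run_threshold fraction of covering heterozygous windows
#'   needed to flag a SNP
#' @param max_gap_bp largest allowed gap between consecutive run SNPs
#' @param short_chrom how to treat a chromosome with fewer SNPs than the
#'   window: `"skip"` (with a warning) or `"shrink"` (use one window of the
#'   chromosome's full size)
#' @return a list of detector parameters
#' @export
rohet_params <- function(window = 50, max_missing_per_window = 2,
                         max_hom_per_window = 1, min_length_bp = 1000,
                         min_density = 1 / 50000, snp_in_run_threshold = 0.05,
                         max_gap_bp = 1e6, short_chrom = c("skip", "shrink")) {
  list(window = as.integer(window),
       max_missing_per_window = as.integer(max_missing_per_window),
       max_hom_per_window = as.integer(max_hom_per_window),
       min_length_bp = as.numeric(min_length_bp),
       min_density = as.numeric(min_density),
       snp_in_run_threshold = as.numeric(snp_in_run_threshold),
       max_gap_bp = as.numeric(max_gap_bp),
       short_chrom = match.arg(short_chrom))
}

#' Detect runs of heterozygosity (ROHet)
#'
#' Sliding-window detector over each animal and chromosome; see
#' [rohet_params()] for the rule. Run spans are closed intervals from the
#' first to the last flagged SNP position.
#'
#' @param g a [geno_matrix()]
#' @param params output of [rohet_params()]
#' @param animals optional subset of animal ids
#' @return data.frame with `animal_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`
#' @export
detect_rohet <- function(g, params = rohet_params(), animals = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(animals)) animals <- rownames(g$dosage)
  chroms <- unique(g$map$chrom)
  warned <- FALSE
  out <- vector("list", 0)
  for (ch in chroms) {
    idx <- which(g$map$chrom == ch)
    pos <- g$map$pos_bp[idx]
    w <- params$window
    if (length(idx) < w) {
      if (params$short_chrom == "skip") {
        if (!warned) {
          warning("detect_rohet: skipping chromosome(s) with fewer than ",
                  w, " SNPs (first: ", ch, ")")
          warned <- TRUE
        }
        next
      }
      w <- length(idx)
    }
    sub <- g$dosage[animals, idx, drop = FALSE]
    for (a in seq_along(animals)) {
      runs <- .rohet_one(sub[a, ], pos, w, params)
      if (nrow(runs)) {
        runs$animal_id <- animals[a]
        runs$chrom <- ch
        out[[length(out) + 1L]] <- runs
      }
    }
  }
  if (!length(out)) {
    return(data.frame(animal_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[, c("animal_id", "chrom", "start_bp", "end_bp", "n_snps", "length_bp")]
}

# core detector for one animal on one position-sorted chromosome
.rohet_one <- function(d, pos, w, params) {
  m <- length(d)
  is_missing <- is.na(d)
  is_hom <- !is_missing & d != 1L
  nw <- m - w + 1L
  cmiss <- c(0L, cumsum(is_missing))
  chom <- c(0L, cumsum(is_hom))
  starts <- seq_len(nw)
  win_ok <- (cmiss[starts + w] - cmiss[starts]) <= params$max_missing_per_window &
            (chom[starts + w] - chom[starts]) <= params$max_hom_per_window
  # per-SNP fraction of covering windows that pass
  cok <- c(0L, cumsum(win_ok))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  n_cov <- hi - lo + 1L
  n_ok <- cok[hi + 1L] - cok[lo]
  flagged <- n_ok / n_cov > params$snp_in_run_threshold
  .assemble_runs(flagged, pos, is_missing, params)
}

# group consecutive flagged SNPs into runs (trimming endpoints to called
# SNPs), then apply gap/length/density rules
.assemble_runs <- function(flagged, pos, is_missing, params) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer())
  idx <- which(flagged)
  if (!length(idx)) return(empty)
  gap_break <- c(TRUE, diff(idx) > 1L | diff(pos[idx]) > params$max_gap_bp)
  grp <- cumsum(gap_break)
  starts <- as.integer(tapply(idx, grp, min))
  ends <- as.integer(tapply(idx, grp, max))
  # run boundaries must be called SNPs; interior missing calls may remain
  for (k in seq_along(starts)) {
    while (starts[k] <= ends[k] && is_missing[starts[k]]) starts[k] <- starts[k] + 1L
    while (ends[k] >= starts[k] && is_missing[ends[k]]) ends[k] <- ends[k] - 1L
  }
  ok <- starts <= ends
  starts <- starts[ok]
  ends <- ends[ok]
  if (!length(starts)) return(empty)
  n_snps <- as.integer(ends - starts + 1L)
  start_bp <- pos[starts]
  end_bp <- pos[ends]
  len <- end_bp - start_bp + 1L
  keep <- len >= params$min_length_bp & n_snps / len >= params$min_density
  if (!any(keep)) return(empty)
  data.frame(start_bp = start_bp[keep], end_bp = end_bp[keep],
             n_snps = n_snps[keep], length_bp = as.integer(len[keep]),
             row.names = NULL)
}

#' Per-animal ROHet summaries with length classes
#'
#' @param runs output of [detect_rohet()]
#' @param animal_ids all animal ids (animals without runs get zero counts)
#' @param class_breaks_bp right-closed upper bounds of the short and
#'   intermediate length classes; default short <= 150 kb, intermediate
#'   (150, 300] kb, long > 300 kb
#' @return data.frame with `animal_id`, `rohet_count`, `rohet_total_bp`,
#'   `n_short`, `n_intermediate`, `n_long`
#' @export
rohet_summary <- function(runs, animal_ids,
                          class_breaks_bp = c(150000, 300000)) {
  stopifnot(length(class_breaks_bp) == 2, diff(class_breaks_bp) > 0)
  out <- data.frame(animal_id = animal_ids, rohet_count = 0L,
                    rohet_total_bp = 0, n_short = 0L, n_intermediate = 0L,
                    n_long = 0L, stringsAsFactors = FALSE)
  if (!nrow(runs)) return(out)
  len <- runs$length_bp
  cls <- cut(len, breaks = c(-Inf, class_breaks_bp, Inf),
             labels = c("n_short", "n_intermediate", "n_long"))
  for (col in c("n_short", "n_intermediate", "n_long")) {
    tab <- table(runs$animal_id[cls == col])
    i <- match(names(tab), out$animal_id)
    out[[col]][i] <- as.integer(tab)
  }
  tab <- table(runs$animal_id)
  i <- match(names(tab), out$animal_id)
  out$rohet_count[i] <- as.integer(tab)
  tot <- tapply(runs$length_bp, runs$animal_id, sum)
  out$rohet_total_bp[match(names(tot), out$animal_id)] <- as.numeric(tot)
  out
}

#' Heterozygosity profile: OH, HL and ROHet summaries per animal
#'
#' @param g a [geno_matrix()]
#' @param stats optional [locus_stats()]
#' @param params optional [rohet_params()]
#' @return data.frame with one row per animal: `animal_id`, `oh`, `hl`,
#'   `rohet_count`, `rohet_total_bp`, `n_short`, `n_intermediate`, `n_long`
#' @export
het_profile <- function(g, stats = locus_stats(g), params = rohet_params()) {
  runs <- detect_rohet(g, params)
  summ <- rohet_summary(runs, rownames(g$dosage))
  data.frame(animal_id = rownames(g$dosage),
             oh = as.numeric(observed_heterozygosity(g)),
             hl = as.numeric(homozygosity_by_locus(g, stats)),
             summ[, -1, drop = FALSE],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' OH and HL restricted to a SNP subset, with per-animal exclusions
#'
#' Recomputes observed heterozygosity and homozygosity by locus on a subset
#' of the panel (e.g. SNPs from chromosomes carrying dominance hits, for a
#' trait-specific measure), optionally removing a different SNP set per
#' animal (e.g. each animal's own ROHet SNPs).
#'
#' @param g a [geno_matrix()]
#' @param stats [locus_stats()] for the full panel (subset expected
#'   heterozygosities are taken from it, keeping weights comparable)
#' @param snp_subset SNP ids (or indices) defining the subset; default all
#' @param exclude optional named list: animal id -> SNP ids to drop for that
#'   animal only
#' @return data.frame with `animal_id`, `oh`, `hl`
#' @export
subset_measures <- function(g, stats = locus_stats(g), snp_subset = NULL,
                            exclude = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(snp_subset)) snp_subset <- g$map$snp_id
  if (!length(snp_subset)) stop("empty SNP subset")
  idx <- if (is.character(snp_subset)) match(snp_subset, g$map$snp_id) else as.integer(snp_subset)
  if (anyNA(idx)) stop("unknown SNP id(s) in subset")
  idx <- sort(unique(idx))
  D <- g$dosage[, idx, drop = FALSE]
  if (!is.null(exclude)) {
    for (an in names(exclude)) {
      drop_idx <- match(exclude[[an]], g$map$snp_id[idx])
      drop_idx <- drop_idx[!is.na(drop_idx)]
      if (length(drop_idx)) D[an, drop_idx] <- NA_integer_
    }
  }
  sub <- geno_matrix(D, g$map[idx, , drop = FALSE])
  st <- stats[idx, , drop = FALSE]
  data.frame(animal_id = rownames(g$dosage),
             oh = as.numeric(observed_heterozygosity(sub)),
             hl = as.numeric(homozygosity_by_locus(sub, st)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' SNP ids covered by an animal's runs of heterozygosity
#'
#' @param g a [geno_matrix()]
#' @param runs output of [detect_rohet()]
#' @return named list: animal id -> character vector of SNP ids inside that
#'   animal's runs
#' @export
rohet_snp_sets <- function(g, runs) {
  out <- list()
  if (!nrow(runs)) return(out)
  for (i in seq_len(nrow(runs))) {
    on_chr <- g$map$chrom == runs$chrom[i]
    inside <- on_chr & g$map$pos_bp >= runs$start_bp[i] &
      g$map$pos_bp <= runs$end_bp[i]
    an <- runs$animal_id[i]
    out[[an]] <- c(out[[an]], g$map$snp_id[inside])
  }
  lapply(out, unique)
}

#' Spearman rank correlation
#'
#' Average ranks are used for ties. Errors on constant input, where the
#' coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return rho in [-1, 1]
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}
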