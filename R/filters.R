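#' Per-SNP allele-b frequency and minor allele frequency
#'
#' Frequencies are computed from non-missing calls only.
#'
#' @param g a [geno_matrix()]
#' @return data.frame with columns `snp_id`, `freq_b` (allele-b frequency),
#'   `maf`, `n_called`. SNPs with no called genotype get `NA` frequencies.
#' @export
allele_freqs <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  n_called <- colSums(!is.na(g$dosage))
  freq_b <- ifelse(n_called > 0, colMeans(g$dosage, na.rm = TRUE) / 2, NA_real_)
  data.frame(snp_id = g$map$snp_id, freq_b = freq_b,
             maf = pmin(freq_b, 1 - freq_b), n_called = n_called,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove SNPs with low minor allele frequency
#'
#' Retains exactly the SNPs with MAF strictly greater than `threshold`
#' (SNPs with MAF equal to the threshold are removed, matching a
#' "MAF <= threshold removed" editing rule). MAF is computed from
#' non-missing calls; SNPs with all calls missing are dropped and reported.
#'
#' @param g a [geno_matrix()]
#' @param threshold real in [0, 0.5); default 0.05
#' @return a filtered `geno_matrix`, SNP order preserved
#' @export
apply_maf_filter <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "geno_matrix"), threshold >= 0, threshold < 0.5)
  fr <- allele_freqs(g)
  all_missing <- fr$n_called == 0
  if (any(all_missing)) {
    message("apply_maf_filter: dropping ", sum(all_missing),
            " SNP(s) with all calls missing: ",
            paste(utils::head(fr$snp_id[all_missing], 5), collapse = ", "))
  }
  keep <- !all_missing & fr$maf > threshold
  if (!any(keep)) stop("no SNPs survive the MAF filter")
  subset_geno(g, snps = which(keep))
}

#' Remove records from small contemporary groups
#'
#' @param ph data.frame of phenotype records with a `contemporary_group`
#'   column
#' @param min_size smallest group size retained (default 5: groups with
#'   fewer than five animals are removed)
#' @return the surviving records, original order preserved
#' @export
filter_small_groups <- function(ph, min_size = 5) {
  stopifnot(is.data.frame(ph), "contemporary_group" %in% names(ph),
            min_size >= 1)
  sizes <- table(ph$contemporary_group)
  keep_groups <- names(sizes)[sizes >= min_size]
  ph[ph$contemporary_group %in% keep_groups, , drop = FALSE]
}
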