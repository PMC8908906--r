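#' VanRaden Method I genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))` with `Z = M - 2p`, where `M` is the
#' allele-b dosage matrix and `p` the per-SNP allele-b frequency. Missing
#' dosages are mean-imputed as `2 p_i` before centering (they contribute 0
#' to Z). Invariant to allele relabeling at any SNP.
#'
#' @param g a [geno_matrix()]
#' @param freqs optional external allele-b frequencies (defaults to the
#'   sample frequencies, in which case every row of G sums to zero)
#' @return list of class `grm`: `G` (n x n, dimnames = animal ids),
#'   `freqs_used`, `n_snps_used`
#' @export
build_grm_method1 <- function(g, freqs = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  M <- g$dosage
  if (is.null(freqs)) {
    n_called <- colSums(!is.na(M))
    if (any(n_called == 0)) stop("SNP(s) with all calls missing")
    freqs <- colMeans(M, na.rm = TRUE) / 2
  }
  stopifnot(length(freqs) == ncol(M))
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all SNPs monomorphic: Method I denominator is zero")
  Z <- sweep(M, 2, 2 * freqs)
  Z[is.na(Z)] <- 0  # mean imputation: dosage 2p centers to zero
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(list(G = G, freqs_used = as.numeric(freqs),
                 n_snps_used = ncol(M)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d animals, %d SNPs, mean diagonal %.3f\n",
              nrow(x$G), x$n_snps_used, mean(diag(x$G))))
  invisible(x)
}

#' Write a GRM as a plain-text lower-triangle table
#'
#' GCTA-like layout: one row per (i, j <= i) pair with 1-based indices, the
#' number of SNPs used, and the relationship value.
#'
#' @param grm a [build_grm_method1()] result
#' @param path output file
#' @export
write_grm_text <- function(grm, path) {
  n <- nrow(grm$G)
  ij <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tab <- data.frame(i = ij[, 1], j = ij[, 2], n_snps = grm$n_snps_used,
                    value = grm$G[ij])
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}
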