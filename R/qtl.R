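#' Pairwise LD as squared dosage correlation
#'
#' Composite (genotypic, phase-free) linkage disequilibrium: the squared
#' Pearson correlation of the two dosage vectors over jointly called
#' animals. Symmetric in the pair and within [0, 1].
#'
#' @param g a [geno_matrix()]
#' @param snp_i,snp_j SNP ids or column indices
#' @return r-squared, or `NA` when fewer than 3 jointly called animals or
#'   either locus is monomorphic among them
#' @export
ld_r2 <- function(g, snp_i, snp_j) {
  stopifnot(inherits(g, "geno_matrix"))
  ix <- if (is.character(snp_i)) match(snp_i, g$map$snp_id) else as.integer(snp_i)
  jx <- if (is.character(snp_j)) match(snp_j, g$map$snp_id) else as.integer(snp_j)
  if (anyNA(c(ix, jx))) stop("unknown SNP id")
  x <- g$dosage[, ix]
  y <- g$dosage[, jx]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# r2 of one anchor column against a block of columns, joint-missing aware
.ld_r2_block <- function(D, anchor_col, cols) {
  x <- D[, anchor_col]
  out <- rep(NA_real_, length(cols))
  for (k in seq_along(cols)) {
    y <- D[, cols[k]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    xs <- x[ok]
    ys <- y[ok]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    out[k] <- stats::cor(xs, ys)^2
  }
  out
}

#' Collapse significant SNPs into QTL regions via local LD
#'
#' For each significant SNP, the candidate region consists of that SNP plus
#' every same-chromosome SNP within the distance window that is in LD
#' (`r2 >= r2_min`) with it; the candidate span is the closed interval from
#' the smallest to the largest member position. Overlapping candidate
#' regions on a chromosome are merged transitively into a single QTL
#' region. The lead SNP of a region is its significant member with the
#' smallest p-value (ties: smaller position, then lexicographic id).
#'
#' @param sig data.frame of significant SNPs with columns `snp_id` and `p`
#'   (positions are taken from `g`)
#' @param g a [geno_matrix()] containing all scanned SNPs
#' @param window_bp LD search window (bp). With
#'   `window_centered = TRUE` (default) this is the half-width of a window
#'   centered on each significant SNP; otherwise it is the total span.
#' @param r2_min LD threshold for region membership (default 0.5)
#' @param window_centered see `window_bp`
#' @return data.frame with one row per region: `chrom`, `start_bp`,
#'   `end_bp`, `n_snps` (member SNPs), `n_significant`, `lead_snp`,
#'   `lead_pos`, `lead_p`, `member_snps` (comma-joined ids)
#' @export
build_regions <- function(sig, g, window_bp = 500000, r2_min = 0.5,
                          window_centered = TRUE) {
  stopifnot(is.data.frame(sig), all(c("snp_id", "p") %in% names(sig)),
            inherits(g, "geno_matrix"))
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      n_significant = integer(), lead_snp = character(),
                      lead_pos = integer(), lead_p = numeric(),
                      member_snps = character(), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  si <- match(sig$snp_id, g$map$snp_id)
  if (anyNA(si)) stop("significant SNP(s) absent from the genotype matrix")
  half <- if (window_centered) window_bp else window_bp / 2
  # candidate interval + members per significant SNP
  cand <- vector("list", nrow(sig))
  for (k in seq_len(nrow(sig))) {
    i <- si[k]
    ch <- g$map$chrom[i]
    pos0 <- g$map$pos_bp[i]
    near <- which(g$map$chrom == ch & abs(g$map$pos_bp - pos0) <= half)
    near <- setdiff(near, i)
    partners <- integer(0)
    if (length(near)) {
      r2 <- .ld_r2_block(g$dosage, i, near)
      partners <- near[!is.na(r2) & r2 >= r2_min]
    }
    members <- sort(c(i, partners))
    cand[[k]] <- list(chrom = ch,
                      start = min(g$map$pos_bp[members]),
                      end = max(g$map$pos_bp[members]),
                      members = members, sig_idx = k)
  }
  # transitive merge of overlapping candidates per chromosome
  out <- list()
  for (ch in unique(vapply(cand, `[[`, character(1), "chrom"))) {
    cc <- Filter(function(x) x$chrom == ch, cand)
    ord <- order(vapply(cc, `[[`, numeric(1), "start"))
    cc <- cc[ord]
    cur <- cc[[1]]
    flush <- function(cur) {
      members <- sort(unique(cur$members))
      sk <- cur$sig_idx
      lead_rows <- sig[sk, , drop = FALSE]
      lead_pos <- g$map$pos_bp[si[sk]]
      o <- order(lead_rows$p, lead_pos, lead_rows$snp_id)[1]
      data.frame(chrom = ch, start_bp = cur$start, end_bp = cur$end,
                 n_snps = length(members), n_significant = length(unique(sk)),
                 lead_snp = lead_rows$snp_id[o], lead_pos = lead_pos[o],
                 lead_p = lead_rows$p[o],
                 member_snps = paste(g$map$snp_id[members], collapse = ","),
                 stringsAsFactors = FALSE)
    }
    if (length(cc) > 1) {
      for (x in cc[-1]) {
        if (x$start <= cur$end) {
          cur$end <- max(cur$end, x$end)
          cur$start <- min(cur$start, x$start)
          cur$members <- c(cur$members, x$members)
          cur$sig_idx <- c(cur$sig_idx, x$sig_idx)
        } else {
          out[[length(out) + 1L]] <- flush(cur)
          cur <- x
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cur)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(g$map$chrom)), res$start_bp), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write QTL regions as a BED table
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param regions a [build_regions()] result
#' @param path output file
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start_bp - 1L,
                    end = regions$end_bp, name = regions$lead_snp,
                    score = -log10(regions$lead_p))
  utils::write.table(bed, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}
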