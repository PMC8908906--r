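#' Genotype matrix container
#'
#' Bundles an animals x SNPs dosage matrix with its SNP map. Dosages count
#' copies of `allele_b` and take values 0, 1, 2 or `NA` (missing). SNPs are
#' stored sorted by (chromosome, position); chromosome order is the order of
#' first appearance in the supplied map.
#'
#' @param dosage integer matrix, animals in rows (rownames = sample ids),
#'   SNPs in columns. Entries must be 0, 1, 2 or NA.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`; one row per column of `dosage`. Positions are
#'   1-based inclusive base pairs.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   and `map`.
#' @export
geno_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(map),
            all(c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b") %in% names(map)),
            nrow(map) == ncol(dosage))
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("id", seq_len(nrow(dosage)))
  }
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  if (anyDuplicated(map[, c("chrom", "pos_bp")])) {
    stop("duplicate (chrom, pos_bp) in map")
  }
  if (any(map$pos_bp < 1L)) stop("pos_bp must be >= 1")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  storage.mode(dosage) <- "integer"
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d animals x %d SNPs on %d chromosome(s); %d missing call(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              sum(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by SNPs and/or animals
#'
#' @param g a [geno_matrix()]
#' @param snps SNP ids or column indices to keep (order of the panel is kept)
#' @param animals sample ids or row indices to keep
#' @return a `geno_matrix`
#' @export
subset_geno <- function(g, snps = NULL, animals = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  keep_snp <- seq_len(ncol(g$dosage))
  if (!is.null(snps)) {
    keep_snp <- if (is.character(snps)) match(snps, g$map$snp_id) else as.integer(snps)
    if (anyNA(keep_snp)) stop("unknown SNP id(s) in subset")
    keep_snp <- sort(unique(keep_snp))
  }
  keep_an <- seq_len(nrow(g$dosage))
  if (!is.null(animals)) {
    keep_an <- if (is.character(animals)) match(animals, rownames(g$dosage)) else as.integer(animals)
    if (anyNA(keep_an)) stop("unknown animal id(s) in subset")
  }
  geno_matrix(g$dosage[keep_an, keep_snp, drop = FALSE],
              g$map[keep_snp, , drop = FALSE])
}

# byte -> 4 two-bit PLINK genotype codes, sample order = low bits first
.plink_decode_table <- local({
  tab <- matrix(0L, nrow = 256, ncol = 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1L, k] <- v %% 4L
      v <- v %/% 4L
    }
  }
  tab
})

# PLINK 2-bit code -> dosage of A1 (allele_b): 00 hom A1 = 2, 01 missing,
# 10 het = 1, 11 hom A2 = 0
.plink_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)

#' Read a PLINK .bed/.bim/.fam triplet
#'
#' Reads a binary PLINK v1 fileset (SNP-major layout). The returned dosage
#' counts copies of the .bim A1 allele, which becomes `allele_b` of the map
#' (A2 becomes `allele_a`); this mapping is fixed so downstream effect signs
#' are interpretable, and is reported via `message()` once per call.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist
#' @param quiet suppress the allele-mapping message
#' @return a [geno_matrix()]
#' @export
read_plink <- function(prefix, quiet = FALSE) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("missing PLINK file: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp", "a1", "a2"))
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK v1 .bed file (bad magic number)")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed layout is supported")
  bpp <- ceiling(n / 4)                      # bytes per SNP
  payload <- raw[-(1:3)]
  if (length(payload) != bpp * m) {
    stop(sprintf("dimension error: .bed payload has %d bytes, expected %d for %d samples x %d SNPs",
                 length(payload), bpp * m, n, m))
  }
  codes <- .plink_decode_table[as.integer(payload) + 1L, , drop = FALSE]
  # codes: (bpp*m) x 4; reshape to per-SNP sample vectors
  codes <- matrix(t(codes), nrow = 4L * bpp)  # (4*bpp) x m, sample-within-SNP
  dosage <- matrix(.plink_code_to_dosage[codes[seq_len(n), , drop = FALSE] + 1L],
                   nrow = n, ncol = m)
  rownames(dosage) <- as.character(fam[[2]])
  map <- data.frame(snp_id = bim$snp_id, chrom = as.character(bim$chrom),
                    pos_bp = bim$pos_bp, allele_a = bim$a2, allele_b = bim$a1,
                    stringsAsFactors = FALSE)
  if (!quiet) message("read_plink: dosage counts the .bim A1 allele (stored as allele_b)")
  geno_matrix(dosage, map)
}

#' Write a genotype matrix as a PLINK .bed/.bim/.fam triplet
#'
#' Inverse of [read_plink()]: `allele_b` is written as A1 and `allele_a` as
#' A2, so a write/read round trip reproduces the dosage matrix exactly.
#'
#' @param g a [geno_matrix()]
#' @param prefix output path prefix
#' @return `prefix`, invisibly
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- nrow(g$dosage)
  m <- ncol(g$dosage)
  fam <- data.frame(fid = rownames(g$dosage), iid = rownames(g$dosage),
                    father = 0L, mother = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(chrom = g$map$chrom, snp_id = g$map$snp_id, cm = 0L,
                    pos_bp = g$map$pos_bp, a1 = g$map$allele_b, a2 = g$map$allele_a)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 1L] <- 2L
    out[!is.na(d) & d == 0L] <- 3L
    out
  }
  bpp <- ceiling(n / 4)
  pad <- 4L * bpp - n
  bytes <- raw(bpp * m)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    cd <- c(code_of(g$dosage[, j]), integer(pad))
    byte_vals <- colSums(matrix(cd * mult, nrow = 4))
    bytes[((j - 1L) * bpp + 1L):(j * bpp)] <- as.raw(byte_vals)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), con)
  invisible(prefix)
}
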