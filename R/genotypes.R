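#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs allele dosage matrix (counts of the
#' reference/A1 allele, values in \{0, 1, 2\}, `NA` allowed for missing
#' genotypes) with SNP metadata and reference-allele frequencies computed
#' from the non-missing calls.
#'
#' @param dosages numeric matrix, `n` individuals x `m` SNPs; entries in
#'   \{0, 1, 2, NA\}.
#' @param snp_ids character vector of SNP identifiers (length `m`).
#' @param chrom chromosome label per SNP (length `m`).
#' @param pos base-pair position per SNP (1-based, length `m`).
#' @param individual_ids identifiers for the rows (length `n`).
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `snp_ids`, `chrom`, `pos`, `f` (reference-allele frequency) and
#'   `individual_ids`.
#' @export
genotype_matrix <- function(dosages,
                            snp_ids = NULL,
                            chrom = NULL,
                            pos = NULL,
                            individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(individual_ids)) individual_ids <- paste0("id", seq_len(n))
  if (length(snp_ids) != m || length(chrom) != m || length(pos) != m) {
    stop("SNP metadata length does not match the number of columns")
  }
  if (length(individual_ids) != n) {
    stop("individual_ids length does not match the number of rows")
  }
  structure(
    list(
      dosages = dosages,
      snp_ids = as.character(snp_ids),
      chrom = as.character(chrom),
      pos = as.integer(pos),
      f = allele_frequencies(dosages),
      individual_ids = as.character(individual_ids)
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d SNPs (%d missing calls)\n",
    nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Reference-allele frequency per column over non-missing dosages.
allele_frequencies <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Decodes a variant-major (SNP-major) PLINK 1 binary fileset into a
#' [genotype_matrix()]. Dosages count the A1 allele of the .bim file; the
#' two-bit codes 00/10/11 map to dosages 2/1/0 and 01 to missing.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("missing PLINK file: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic number): ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major (variant-major) bed files are supported: ", bed_path)
  }
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) - 3L != bytes_per_snp * m) {
    stop(sprintf(
      "bed size inconsistent with bim/fam: expected %d data bytes, found %d",
      bytes_per_snp * m, length(raw) - 3L
    ))
  }
  body <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit genotype codes of each byte
  codes <- rbind(
    body %% 4L,
    (body %/% 4L) %% 4L,
    (body %/% 16L) %% 4L,
    body %/% 64L
  )
  codes <- matrix(as.vector(codes), nrow = bytes_per_snp * 4L, ncol = m)
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  lookup <- c(2, NA, 1, 0)
  dosages <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  genotype_matrix(
    dosages,
    snp_ids = bim[[2]],
    chrom = bim[[1]],
    pos = bim[[4]],
    individual_ids = fam[[2]]
  )
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Inverse of [read_plink()]: encodes the dosages as a SNP-major PLINK 1
#' binary fileset. A1/A2 are written as "A"/"B" placeholder allele labels.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages)
  m <- ncol(G$dosages)
  bim <- data.frame(G$chrom, G$snp_ids, 0, G$pos, "A", "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$individual_ids, G$individual_ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bytes_per_snp <- ceiling(n / 4)
  padded <- 4L * bytes_per_snp
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  out <- integer(bytes_per_snp * m)
  for (j in seq_len(m)) {
    cj <- code_of(G$dosages[, j])
    length(cj) <- padded          # pad with NA -> treat as code 0 below
    cj[is.na(cj)] <- 0L
    cm <- matrix(cj, nrow = 4L)
    out[((j - 1L) * bytes_per_snp + 1L):(j * bytes_per_snp)] <-
      cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
  }
  writeBin(as.raw(out), con)
  invisible(prefix)
}

#' Remove low minor-allele-count SNPs
#'
#' Drops SNPs whose minor-allele copy count (over non-missing genotypes) is
#' below `min_allele_count`, preserving SNP order.
#'
#' @param G a [genotype_matrix()].
#' @param min_allele_count non-negative integer threshold; SNPs with fewer
#'   minor-allele copies than this are removed.
#' @return A filtered [genotype_matrix()].
#' @export
filter_snps <- function(G, min_allele_count) {
  stopifnot(inherits(G, "genotype_matrix"), min_allele_count >= 0)
  ref_copies <- colSums(G$dosages, na.rm = TRUE)
  total <- 2 * colSums(!is.na(G$dosages))
  minor_copies <- pmin(ref_copies, total - ref_copies)
  keep <- minor_copies >= min_allele_count
  if (!any(keep)) stop("all SNPs removed by the minor-allele-count filter")
  genotype_matrix(
    G$dosages[, keep, drop = FALSE],
    snp_ids = G$snp_ids[keep],
    chrom = G$chrom[keep],
    pos = G$pos[keep],
    individual_ids = G$individual_ids
  )
}

#' Standardize genotypes into a design matrix
#'
#' Column `j` of the result is `(dosage - 2 f_j) / sqrt(2 f_j (1 - f_j))`.
#' Missing dosages are mean-imputed to `2 f_j`, i.e. they become exactly 0
#' after centering. By default `f` is the sample allele frequency of `G`
#' itself; pass `f` explicitly (e.g. reference-panel frequencies) to
#' standardize a validation panel on the reference scale.
#'
#' @param G a [genotype_matrix()].
#' @param f optional vector of reference-allele frequencies to use instead
#'   of the sample frequencies.
#' @return Numeric matrix `n x m` of standardized dosages.
#' @export
standardize_genotypes <- function(G, f = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(f)) f <- G$f
  if (length(f) != ncol(G$dosages)) stop("f length does not match SNP count")
  if (any(f <= 0 | f >= 1)) {
    stop("monomorphic SNPs present (f of 0 or 1); filter them first")
  }
  W <- sweep(G$dosages, 2, 2 * f, "-")
  W[is.na(W)] <- 0
  sweep(W, 2, sqrt(2 * f * (1 - f)), "/")
}
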