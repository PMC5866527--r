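# Small fixtures built in code, shared across test files.

toy_genotypes <- function() {
  # 5 individuals x 3 SNPs, one missing call in SNP 3
  d <- matrix(c(
    0, 1, 2,
    1, 1, 0,
    2, 0, 1,
    0, 2, NA,
    1, 1, 2
  ), nrow = 5, byrow = TRUE)
  genotype_matrix(d, snp_ids = c("s1", "s2", "s3"),
                  chrom = c("1", "1", "2"), pos = c(100, 200, 50),
                  individual_ids = paste0("ind", 1:5))
}

random_correlation <- function(t) {
  # random PSD correlation matrix via a random Gram matrix
  X <- matrix(rnorm(t * (t + 2)), t + 2, t)
  stats::cov2cor(crossprod(X))
}

# n individuals x m SNPs of independent Hardy-Weinberg genotypes
hwe_panel <- function(n, m, f = NULL) {
  if (is.null(f)) f <- runif(m, 0.1, 0.9)
  d <- vapply(f, function(fj) rbinom(n, 2L, fj), integer(n))
  genotype_matrix(d)
}
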