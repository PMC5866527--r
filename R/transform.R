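#' Error structure of a multi-trait analysis
#'
#' Container for the between-trait error correlation matrix `K`, the
#' diagonal matrix of error standard deviations `T` and, optionally, the
#' genetic covariance matrix `G` (for reporting linear-combination genetic
#' parameters). These are accepted as inputs, typically estimated beforehand
#' from pedigree with a multivariate mixed model.
#'
#' @param K t x t error correlation matrix (symmetric, unit diagonal, PSD).
#' @param T_sd vector (or diagonal matrix) of t positive error standard
#'   deviations, in trait units.
#' @param G optional t x t genetic covariance matrix, in trait units squared.
#' @param trait_names optional trait labels.
#' @return An object of class `error_structure`.
#' @export
error_structure <- function(K, T_sd, G = NULL, trait_names = NULL) {
  K <- as.matrix(K)
  if (is.matrix(T_sd)) T_sd <- diag(as.matrix(T_sd))
  t <- nrow(K)
  if (ncol(K) != t) stop("K must be square")
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  if (max(abs(diag(K) - 1)) > 1e-8) stop("K must have unit diagonal")
  if (length(T_sd) != t || any(T_sd <= 0)) {
    stop("T_sd must hold one positive error SD per trait")
  }
  if (!is.null(G)) {
    G <- as.matrix(G)
    if (!all(dim(G) == t)) stop("G must be t x t")
  }
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(t))
  structure(list(K = K, T_sd = as.numeric(T_sd), G = G,
                 trait_names = trait_names),
            class = "error_structure")
}

#' Eigen-decompose the error correlation matrix
#'
#' Returns the orthonormal eigenvectors `B` and eigenvalues `Lambda` of `K`
#' with `K = B diag(Lambda) B'`. Eigenvalues are sorted in decreasing order
#' and each eigenvector's sign is fixed so that its largest-magnitude entry
#' is positive, making the decomposition deterministic.
#'
#' @param K t x t error correlation matrix, or an [error_structure()].
#' @return An object of class `transform_bundle` with fields `B` and
#'   `Lambda`.
#' @export
decompose_error_correlation <- function(K) {
  if (inherits(K, "error_structure")) K <- K$K
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("K is not positive semi-definite (eigenvalue ",
         format(min(e$values)), ")")
  }
  B <- e$vectors
  for (j in seq_len(ncol(B))) {
    k <- which.max(abs(B[, j]))
    if (B[k, j] < 0) B[, j] <- -B[, j]
  }
  structure(list(B = B, Lambda = pmax(e$values, 0)),
            class = "transform_bundle")
}

#' Build error-uncorrelated linear combinations of traits
#'
#' Transforms each individual's trait vector `y` into `LC = B' T^{-1} y`.
#' Because `K = B diag(Lambda) B'` is the error correlation and `T` carries
#' the error SDs, the LC traits have error covariance `diag(Lambda)`, i.e.
#' zero error covariance between LCs.
#'
#' @param Y a [phenotype_table()] with t traits.
#' @param es an [error_structure()] for the same t traits.
#' @param tb a `transform_bundle` from [decompose_error_correlation()];
#'   computed from `es$K` if omitted.
#' @return A [phenotype_table()] of LC traits named `LC1..LCt`; per-record
#'   weights are carried over unchanged (one weight per individual applied
#'   to all its LCs).
#' @export
make_linear_combinations <- function(Y, es, tb = NULL) {
  stopifnot(inherits(Y, "phenotype_table"), inherits(es, "error_structure"))
  if (is.null(tb)) tb <- decompose_error_correlation(es)
  t <- length(es$T_sd)
  if (ncol(Y$y) != t) stop("trait count mismatch between Y and es")
  lc <- Y$y %*% diag(1 / es$T_sd, t) %*% tb$B
  phenotype_table(lc, weights = Y$weights,
                  individual_ids = Y$individual_ids,
                  trait_names = paste0("LC", seq_len(t)))
}

#' Back-transform LC-scale values to the original trait scale
#'
#' Applies `T B` to LC-scale vectors: the inverse of the LC construction,
#' valid identically for GEBV and for SNP effects on the LC scale.
#'
#' @param values_LC a t-vector or an n x t matrix of LC-scale values.
#' @param es an [error_structure()].
#' @param tb a `transform_bundle`; computed from `es$K` if omitted.
#' @return Values on the original trait scale, same shape as the input.
#' @export
back_transform <- function(values_LC, es, tb = NULL) {
  stopifnot(inherits(es, "error_structure"))
  if (is.null(tb)) tb <- decompose_error_correlation(es)
  t <- length(es$T_sd)
  vec_in <- is.null(dim(values_LC))
  V <- if (vec_in) matrix(values_LC, 1) else as.matrix(values_LC)
  if (ncol(V) != t) stop("LC value dimension does not match trait count")
  out <- V %*% t(tb$B) %*% diag(es$T_sd, t)
  colnames(out) <- es$trait_names
  if (vec_in) drop(out) else out
}

#' Genetic parameters of the linear combinations
#'
#' Computes the LC-scale genetic covariance `B' T^{-1} G T^{-1} B` and the
#' per-LC heritability `g_jj / (g_jj + Lambda_j)`, where `Lambda_j` is the
#' LC error variance.
#'
#' @param es an [error_structure()] with `G` set.
#' @param tb a `transform_bundle`; computed from `es$K` if omitted.
#' @return List with `G_lc` (t x t) and `h2` (length t).
#' @export
lc_genetic_parameters <- function(es, tb = NULL) {
  stopifnot(inherits(es, "error_structure"))
  if (is.null(es$G)) stop("error_structure has no genetic covariance G")
  if (is.null(tb)) tb <- decompose_error_correlation(es)
  t <- length(es$T_sd)
  Tinv <- diag(1 / es$T_sd, t)
  G_lc <- t(tb$B) %*% Tinv %*% es$G %*% Tinv %*% tb$B
  g <- diag(G_lc)
  h2 <- ifelse(g + tb$Lambda > 0, g / (g + tb$Lambda), 0)
  list(G_lc = G_lc, h2 = h2)
}

#' Read a square matrix from TSV
#'
#' Utility for supplying K, T or G as tab-separated files with a header row
#' of trait names.
#'
#' @param path file path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab)
  rownames(m) <- colnames(m)
  m
}
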