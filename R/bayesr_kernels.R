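# Single-site Gibbs kernels for the mixture-of-normals whole-genome
# regression. These R implementations define the conditional distributions;
# the compiled chain in src/ implements the same math for full-length runs.

#' Sufficient statistics for one SNP's conditional update
#'
#' Given the working residual with SNP j's contribution removed, returns
#' `rhs = w_j' E^{-1} r / sigma2_e` and `lhs = w_j' E^{-1} w_j / sigma2_e`,
#' the two scalars on which the component and effect conditionals depend.
#'
#' @param w_j standardized genotype column.
#' @param residual working residual excluding SNP j's contribution.
#' @param weights per-record error weights (diagonal of E^{-1}).
#' @param sigma2_e residual variance.
#' @return List with `rhs` and `lhs`.
#' @export
snp_sufficient_stats <- function(w_j, residual, weights = 1, sigma2_e = 1) {
  ew <- weights * w_j
  list(rhs = sum(ew * residual) / sigma2_e,
       lhs = sum(ew * w_j) / sigma2_e)
}

# Log integrated likelihood (up to a shared constant) of component k for a
# SNP with sufficient stats (rhs, lhs): the effect is integrated out of its
# N(0, sigma2_k) prior. sigma2_k = 0 gives log L = 0 (the reference).
log_component_likelihood <- function(rhs, lhs, sigma2_k) {
  ifelse(sigma2_k == 0, 0,
         -0.5 * log1p(lhs * sigma2_k) +
           0.5 * rhs^2 * sigma2_k / (1 + lhs * sigma2_k))
}

#' Conditional posterior over the four mixture components of one SNP
#'
#' `P(comp = k)` is proportional to `q_k * L_k` where `L_1 = 1` and, for the
#' non-null classes, `L_k = (1 + lhs * sigma2_k)^(-1/2)
#' exp(rhs^2 sigma2_k / (2 (1 + lhs sigma2_k)))` — the marginal likelihood
#' with the SNP effect integrated out of its class prior.
#'
#' @param rhs,lhs sufficient statistics from [snp_sufficient_stats()].
#' @param q mixing proportions over the four classes (simplex).
#' @param prior a [mixture_prior()].
#' @return Normalized 4-vector of component probabilities.
#' @export
component_posterior <- function(rhs, lhs, q, prior) {
  if (!is.finite(rhs) || !is.finite(lhs)) stop("non-finite SNP statistics")
  logL <- log_component_likelihood(rhs, lhs, prior$sigma2_k)
  logp <- ifelse(q > 0, log(q) + logL, -Inf)
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Draw a SNP effect given its mixture component
#'
#' For the null class (`sigma2_k = 0`) returns exactly 0; otherwise draws
#' from `N(rhs / (lhs + 1/sigma2_k), 1 / (lhs + 1/sigma2_k))`.
#'
#' @param rhs,lhs sufficient statistics.
#' @param sigma2_k the component's prior variance.
#' @return One effect draw.
#' @export
sample_effect <- function(rhs, lhs, sigma2_k) {
  if (sigma2_k == 0) return(0)
  prec <- lhs + 1 / sigma2_k
  stats::rnorm(1, rhs / prec, sqrt(1 / prec))
}

#' Draw mixing proportions from their Dirichlet conditional
#'
#' With a flat Dirichlet(1,1,1,1) hyperprior, the conditional given the
#' per-class SNP counts is Dirichlet(counts + 1).
#'
#' @param counts per-class SNP counts (length 4, non-negative).
#' @return A draw from the 4-simplex.
#' @export
sample_mixing_proportions <- function(counts) {
  if (any(counts < 0)) stop("negative class counts")
  g <- stats::rgamma(length(counts), shape = counts + 1, rate = 1)
  g / sum(g)
}

#' Draw the residual variance from its scaled inverse chi-square conditional
#'
#' Uses degrees of freedom `n + nu0` and scale
#' `(r' E^{-1} r + nu0 * S0) / (n + nu0)`; the default `nu0 = -2, S0 = 0` is
#' the flat prior on `sigma2_e`. The draw is floored at 1e-12 to guard
#' degenerate all-zero residuals.
#'
#' @param residual residual vector.
#' @param weights error weights (diagonal of E^{-1}).
#' @param nu0,S0 prior degrees of freedom and scale.
#' @return One variance draw.
#' @export
sample_residual_variance <- function(residual, weights = 1, nu0 = -2,
                                     S0 = 0) {
  n <- length(residual)
  ssq <- sum(weights * residual^2) + nu0 * S0
  df <- n + nu0
  if (df <= 0) stop("non-positive degrees of freedom for sigma2_e")
  max(ssq / stats::rchisq(1, df), 1e-12)
}

#' Draw the polygenic effects from their multivariate normal conditional
#'
#' Joint draw of `a ~ N(C^{-1} E^{-1} y_adj / sigma2_e, C^{-1})` with
#' `C = E^{-1} / sigma2_e + A^{-1} / sigma2_a` (one polygenic value per
#' phenotyped individual, Z = I), via a dense Cholesky factorization.
#' `sigma2_a = 0` disables the term and returns zeros.
#'
#' @param y_adj phenotype adjusted for all other model terms.
#' @param A numerator relationship matrix.
#' @param sigma2_a polygenic variance.
#' @param sigma2_e residual variance.
#' @param weights error weights.
#' @return List with the draw `a`, its conditional mean `mean`, and the
#'   quadratic form `a' A^{-1} a` (used by the sigma2_a update).
#' @export
sample_polygenic <- function(y_adj, A, sigma2_a, sigma2_e, weights = 1) {
  n <- length(y_adj)
  if (sigma2_a == 0) {
    return(list(a = numeric(n), mean = numeric(n), quad = 0))
  }
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("relationship matrix is singular; bend A before sampling")
  })
  w <- rep_len(weights, n)
  C <- diag(w / sigma2_e, n) + Ainv / sigma2_a
  R <- chol(C)
  mu <- backsolve(R, forwardsolve(t(R), w * y_adj / sigma2_e))
  a <- mu + backsolve(R, stats::rnorm(n))
  list(a = a, mean = mu, quad = drop(crossprod(a, Ainv %*% a)))
}
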