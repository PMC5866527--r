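#' Fit the univariate mixture-of-normals regression (BayesR)
#'
#' Single-site Gibbs sampling of the model
#' `y = 1 mu + Z a + W v + e`, where each SNP effect `v_j` comes from a
#' four-class mixture of normals with variances fixed at
#' \{0, 1e-4, 1e-3, 1e-2\} times the pedigree additive variance
#' ([mixture_prior()]), the mixing proportions get a flat Dirichlet
#' hyperprior, and the residual variance a flat scaled-inverse-chi-square
#' prior. Posterior summaries are averaged over `config$n_chains` replicate
#' chains.
#'
#' @param y numeric phenotype vector (one trait).
#' @param W standardized genotype design matrix from
#'   [standardize_genotypes()].
#' @param config an [mcmc_config()].
#' @param prior a [mixture_prior()].
#' @param A optional numerator relationship matrix enabling the polygenic
#'   term (unit weights only); its eigen-decomposition is reused across
#'   chains.
#' @param weights per-record error weights (diagonal of E^-1).
#' @param update_q,update_sigma2e,update_sigma2a set `FALSE` to hold the
#'   mixing proportions / residual variance / polygenic variance fixed at
#'   their initial values.
#' @param fit_intercept fit an intercept (default `TRUE`).
#' @param snp_order `"fixed"` (ascending map order, default) or
#'   `"random"` (fresh permutation of the SNP update order each sweep;
#'   affects mixing only, not the stationary distribution).
#' @param q_init initial mixing proportions.
#' @param sigma2_e_init initial residual variance (default `var(y)/2`).
#' @param sigma2_a_init initial polygenic variance when `A` is given.
#' @return A `bayesr_fit` list: `pp` (m x 4 posterior component
#'   probabilities), `pp_nonzero` (posterior probability of a non-zero
#'   effect), `mean_effect`, `class_counts` (posterior mean SNPs per class,
#'   summing to m), `gebv` (`W %*% mean_effect`; polygenic term excluded),
#'   `q_mean`, `sigma2_e_mean`, `sigma2_a_mean`, `intercept_mean`,
#'   `polygenic_mean` and the per-chain summaries in `chains`.
#' @export
run_bayesr <- function(y, W, config = mcmc_config(), prior,
                       A = NULL, weights = 1,
                       update_q = TRUE, update_sigma2e = TRUE,
                       update_sigma2a = TRUE, fit_intercept = TRUE,
                       snp_order = c("fixed", "random"),
                       q_init = c(0.7, 0.2, 0.07, 0.03),
                       sigma2_e_init = NULL, sigma2_a_init = NULL) {
  snp_order <- match.arg(snp_order)
  stopifnot(inherits(config, "mcmc_config"), inherits(prior, "mixture_prior"))
  y <- as.numeric(y)
  W <- as.matrix(W)
  n <- nrow(W)
  if (length(y) != n) stop("y and W are not aligned")
  weights <- rep_len(weights, n)
  if (is.null(sigma2_e_init)) sigma2_e_init <- stats::var(y) / 2
  if (is.null(sigma2_a_init)) sigma2_a_init <- prior$sigma2_a_star / 2
  q_init <- q_init / sum(q_init)

  if (!is.null(A)) {
    eig <- eigen(as.matrix(A), symmetric = TRUE)
    A_U <- eig$vectors
    A_d <- eig$values
  } else {
    A_U <- matrix(0, 0, 0)
    A_d <- numeric(0)
  }

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- .bayesr_chain_cpp(
      W, y, weights, prior$sigma2_k,
      config$n_iter, config$burn_in, config$thin,
      sigma2_e_init, q_init, update_q, update_sigma2e, fit_intercept,
      A_U, A_d, sigma2_a_init, update_sigma2a, 100L,
      snp_order == "random"
    )
  }
  avg <- function(field) Reduce(`+`, lapply(chains, `[[`, field)) /
    length(chains)
  pp <- avg("pp")
  mean_effect <- drop(avg("mean_effect"))
  fit <- list(
    pp = pp,
    pp_nonzero = 1 - pp[, 1],
    mean_effect = mean_effect,
    class_counts = drop(avg("class_counts")),
    gebv = drop(W %*% mean_effect),
    q_mean = drop(avg("q_mean")),
    sigma2_e_mean = avg("sigma2_e_mean"),
    sigma2_a_mean = avg("sigma2_a_mean"),
    intercept_mean = avg("intercept_mean"),
    polygenic_mean = drop(avg("polygenic_mean")),
    joint_hist = if (length(chains[[1]]$joint_hist)) {
      drop(avg("joint_hist"))
    },
    prior = prior,
    config = config,
    chains = chains
  )
  class(fit) <- "bayesr_fit"
  fit
}

#' @export
print.bayesr_fit <- function(x, ...) {
  cat("BayesR fit:", length(x$mean_effect), "SNPs;",
      "posterior mean SNPs per class:",
      paste(round(x$class_counts, 1), collapse = " / "), "\n")
  invisible(x)
}

#' Predict genomic breeding values from a fit
#'
#' @param object a `bayesr_fit` or `bayesmv_fit`.
#' @param W_new standardized genotypes of the target individuals, built with
#'   the reference-panel allele frequencies
#'   (`standardize_genotypes(G_new, f = G_ref$f)`).
#' @param ... unused.
#' @return A GEBV vector (`bayesr_fit`) or matrix with one column per trait
#'   (`bayesmv_fit`).
#' @export
predict.bayesr_fit <- function(object, W_new, ...) {
  drop(as.matrix(W_new) %*% object$mean_effect)
}
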