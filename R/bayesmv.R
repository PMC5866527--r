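# Multivariate sampler: a shared per-SNP association indicator with prior
# probability p of being unassociated on every trait, and, conditional on
# association, independent per-trait four-class mixture components.

#' Joint prior probability of a component configuration
#'
#' For per-trait component labels `k = (k_1, ..., k_t)`, the prior is
#' `p + (1 - p) * prod_j q[j, k_j]` when every `k_j = 1` (the SNP may be
#' unassociated, or associated with all effects in the null class) and
#' `(1 - p) * prod_j q[j, k_j]` otherwise.
#'
#' @param p prior probability that a SNP is unassociated.
#' @param q matrix of per-trait mixing proportions, traits in rows (t x 4),
#'   or a single simplex vector for one trait.
#' @param k integer vector of per-trait component labels in 1..4.
#' @return The prior probability of the configuration.
#' @export
joint_prior_probability <- function(p, q, k) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (length(k) != nrow(q)) stop("one component label per trait required")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  prod_q <- prod(q[cbind(seq_len(nrow(q)), k)])
  if (all(k == 1)) p + (1 - p) * prod_q else (1 - p) * prod_q
}

#' Conditional posterior probability that a SNP is associated
#'
#' Because the linear combinations have independent errors, the likelihood
#' factorizes over traits, giving odds
#' `(1 - p) * prod_j sum_k q[j,k] L[j,k]` against `p * prod_j L[j,1]`,
#' where `L[j,k]` is the per-trait integrated component likelihood of
#' [component_posterior()] (and `L[j,1] = 1`).
#'
#' @param stats list with one element per trait, each holding `rhs` and
#'   `lhs` from [snp_sufficient_stats()] computed on that trait's residual.
#' @param p prior unassociated probability.
#' @param q t x 4 matrix of per-trait mixing proportions.
#' @param priors list of one [mixture_prior()] per trait.
#' @return `P(delta = 1 | data)`.
#' @export
association_posterior <- function(stats, p, q, priors) {
  t <- length(stats)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (p <= 0) return(1)
  if (p >= 1) return(0)
  log_odds <- log(1 - p) - log(p)
  for (j in seq_len(t)) {
    rhs <- stats[[j]]$rhs
    lhs <- stats[[j]]$lhs
    if (!is.finite(rhs) || !is.finite(lhs)) stop("non-finite SNP statistics")
    logL <- log_component_likelihood(rhs, lhs, priors[[j]]$sigma2_k)
    lw <- ifelse(q[j, ] > 0, log(q[j, ]) + logL, -Inf)
    mx <- max(lw)
    log_odds <- log_odds + mx + log(sum(exp(lw - mx)))
  }
  1 / (1 + exp(-log_odds))
}

#' Draw the unassociated proportion from its Beta conditional
#'
#' With a flat Beta(1, 1) hyperprior, the conditional given the count of
#' currently unassociated SNPs is
#' `Beta(n_unassociated + 1, m - n_unassociated + 1)`.
#'
#' @param n_unassociated number of SNPs with association indicator 0.
#' @param m total number of SNPs.
#' @return One draw of `p`.
#' @export
sample_p <- function(n_unassociated, m) {
  if (n_unassociated < 0 || n_unassociated > m) stop("invalid count")
  stats::rbeta(1, n_unassociated + 1, m - n_unassociated + 1)
}

#' Fit the multivariate shared-association model (BayesMV)
#'
#' Gibbs sampling of the multi-trait model in which every SNP is either
#' unassociated (no effect on any trait, prior probability `p`) or
#' associated, in which case its effect on each trait is drawn
#' independently from that trait's four-class mixture ([mixture_prior()]).
#' The traits are assumed to have independent errors and polygenic effects
#' — run it on the linear combinations from [make_linear_combinations()]
#' unless the error covariance is already diagonal. Per SNP and sweep, the
#' association indicator is drawn with the components marginalized out,
#' then components and effects are drawn per trait; `p` gets a flat Beta
#' hyperprior and each trait's mixing proportions a flat Dirichlet.
#'
#' @param Y a [phenotype_table()] (LC traits) or an n x t numeric matrix.
#' @param W standardized genotype design matrix.
#' @param config an [mcmc_config()].
#' @param priors a list of one [mixture_prior()] per trait (a single prior
#'   is recycled).
#' @param A optional numerator relationship matrix (unit weights only);
#'   enables an independent polygenic term per trait.
#' @param weights n x t error weights (defaults to the table's weights).
#' @param p_init initial unassociated probability.
#' @param update_p set `FALSE` to hold `p` fixed (with `p_init = 0` this is
#'   the BayesR limit: all SNPs associated).
#' @param update_q,update_sigma2e,update_sigma2a,fit_intercept as in
#'   [run_bayesr()].
#' @param snp_order `"fixed"` or `"random"` SNP update order per sweep, as
#'   in [run_bayesr()].
#' @param q_init initial per-trait mixing proportions.
#' @param sigma2_e_init initial residual variance per trait (default
#'   `var(y_j)/2`).
#' @param es,tb optional [error_structure()] and transform bundle; when
#'   given, back-transformed original-trait GEBV and SNP effects are
#'   included in the fit.
#' @return A `bayesmv_fit` list: `pp_assoc` (P(associated)), `pp_any`
#'   (P(non-zero effect on at least one trait), tallied directly from the
#'   sampled states), per-trait `pp` (m x 4 each), `mean_effect` (m x t, LC
#'   scale), `joint_class_counts` (posterior mean SNPs per joint
#'   configuration: unassociated, then each on/off pattern of traits with
#'   non-zero effects), `gebv` (n x t, LC scale), `p_mean`, `q_mean`,
#'   variance summaries, and `gebv_traits` / `mean_effect_traits` when
#'   `es` is supplied.
#' @export
run_bayesmv <- function(Y, W, config = mcmc_config(), priors,
                        A = NULL, weights = NULL,
                        p_init = 0.5, update_p = TRUE,
                        update_q = TRUE, update_sigma2e = TRUE,
                        update_sigma2a = TRUE, fit_intercept = TRUE,
                        snp_order = c("fixed", "random"),
                        q_init = c(0.7, 0.2, 0.07, 0.03),
                        sigma2_e_init = NULL, es = NULL, tb = NULL) {
  snp_order <- match.arg(snp_order)
  stopifnot(inherits(config, "mcmc_config"))
  if (inherits(Y, "phenotype_table")) {
    if (is.null(weights)) weights <- Y$weights
    trait_names <- Y$trait_names
    Y <- Y$y
  } else {
    Y <- as.matrix(Y)
    trait_names <- colnames(Y)
    if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(Y)))
  }
  W <- as.matrix(W)
  n <- nrow(W)
  t <- ncol(Y)
  if (nrow(Y) != n) stop("Y and W are not aligned")
  if (inherits(priors, "mixture_prior")) priors <- list(priors)
  if (length(priors) == 1) priors <- rep(priors, t)
  if (length(priors) != t) stop("one mixture_prior per trait required")
  if (is.null(weights)) weights <- 1
  weights <- matrix(weights, n, t)
  sigma2_k <- vapply(priors, `[[`, numeric(4), "sigma2_k")  # 4 x t
  q0 <- matrix(q_init / sum(q_init), 4, t)
  if (is.null(sigma2_e_init)) sigma2_e_init <- apply(Y, 2, stats::var) / 2
  sigma2_e_init <- rep_len(sigma2_e_init, t)
  sigma2_a_init <- vapply(priors, `[[`, numeric(1), "sigma2_a_star") / 2

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
    chains[[ch]] <- .bayesmv_chain_cpp(
      W, Y, weights, sigma2_k,
      config$n_iter, config$burn_in, config$thin,
      p_init, update_p, q0, update_q,
      sigma2_e_init, update_sigma2e, fit_intercept,
      A_U, A_d, sigma2_a_init, update_sigma2a, 100L,
      snp_order == "random"
    )
  }
  avg <- function(field) Reduce(`+`, lapply(chains, `[[`, field)) /
    length(chains)

  mean_effect <- avg("mean_effect")
  colnames(mean_effect) <- trait_names
  pp_comp <- avg("pp_comp")  # m x 4 x t array
  pp <- lapply(seq_len(t), function(tr) pp_comp[, , tr])
  names(pp) <- trait_names
  jc <- drop(avg("joint_class_counts"))
  names(jc) <- joint_class_labels(t)
  gebv <- W %*% mean_effect

  fit <- list(
    pp_assoc = drop(avg("pp_assoc")),
    pp_any = drop(avg("pp_any")),
    pp = pp,
    mean_effect = mean_effect,
    joint_class_counts = jc,
    gebv = gebv,
    p_mean = avg("p_mean"),
    q_mean = avg("q_mean"),
    sigma2_e_mean = drop(avg("sigma2_e_mean")),
    sigma2_a_mean = drop(avg("sigma2_a_mean")),
    joint_hist = if (length(chains[[1]]$joint_hist)) {
      drop(avg("joint_hist"))
    },
    trait_names = trait_names,
    priors = priors,
    config = config,
    chains = chains
  )
  if (!is.null(es)) {
    if (is.null(tb)) tb <- decompose_error_correlation(es)
    fit$gebv_traits <- back_transform(gebv, es, tb)
    fit$mean_effect_traits <- back_transform(mean_effect, es, tb)
  }
  class(fit) <- "bayesmv_fit"
  fit
}

#' @export
print.bayesmv_fit <- function(x, ...) {
  cat("BayesMV fit:", length(x$pp_assoc), "SNPs x",
      length(x$trait_names), "traits; posterior mean p =",
      round(x$p_mean, 4), "\n")
  print(round(x$joint_class_counts, 1))
  invisible(x)
}

#' @export
predict.bayesmv_fit <- function(object, W_new, ...) {
  as.matrix(W_new) %*% object$mean_effect
}

# "unassociated", then one label per on/off pattern of traits with
# non-zero effects ("zero_all" = associated but every component null)
joint_class_labels <- function(t) {
  pat <- vapply(0:(2^t - 1), function(b) {
    on <- which(bitwAnd(b, 2^(0:(t - 1))) > 0)
    if (!length(on)) "zero_all" else paste0("t", paste(on, collapse = "_t"))
  }, character(1))
  c("unassociated", pat)
}

#' Joint genetic-architecture table
#'
#' Posterior mean numbers of SNPs per joint configuration across traits.
#' For a `bayesmv_fit` the `direct` mode returns the per-iteration sampled
#' configuration tallies accumulated during the run. The `product` mode
#' (the univariate-style summary used for comparison tables) combines
#' per-trait marginal zero/non-zero posterior probabilities as independent
#' products per SNP and sums over SNPs; it accepts either fit type.
#'
#' @param fit a `bayesmv_fit`, or (product mode) a list of `bayesr_fit`
#'   objects, one per trait.
#' @param mode `"direct"` or `"product"`.
#' @return Named vector of posterior mean SNP counts per joint class.
#' @export
summarize_joint_architecture <- function(fit, mode = c("direct", "product")) {
  mode <- match.arg(mode)
  if (mode == "direct") {
    if (!inherits(fit, "bayesmv_fit")) {
      stop("direct mode requires a bayesmv_fit")
    }
    return(fit$joint_class_counts)
  }
  zero_pp <- if (inherits(fit, "bayesmv_fit")) {
    vapply(fit$pp, function(m4) m4[, 1], numeric(length(fit$pp_assoc)))
  } else {
    vapply(fit, function(f) f$pp[, 1], numeric(length(fit[[1]]$pp_nonzero)))
  }
  t <- ncol(zero_pp)
  labels <- joint_class_labels(t)[-1]  # no unassociated class in product mode
  counts <- stats::setNames(numeric(length(labels)), labels)
  for (b in 0:(2^t - 1)) {
    on <- bitwAnd(b, 2^(0:(t - 1))) > 0
    per_snp <- rep(1, nrow(zero_pp))
    for (j in seq_len(t)) {
      per_snp <- per_snp * if (on[j]) 1 - zero_pp[, j] else zero_pp[, j]
    }
    counts[b + 1] <- sum(per_snp)
  }
  counts
}
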