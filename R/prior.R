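#' Four-class mixture prior on SNP effects
#'
#' SNP effects are drawn from a mixture of four zero-mean normals whose
#' variances are fixed fractions \{0, 1e-4, 1e-3, 1e-2\} of the additive
#' genetic variance estimated from pedigree, `sigma2_a_star`. The class
#' variances are fixed throughout sampling; only the mixing proportions are
#' learned.
#'
#' @param sigma2_a_star pedigree additive genetic variance of the analyzed
#'   trait (trait units squared); must be positive.
#' @param fractions mixture-class variance fractions; the first must be 0
#'   (the null class) and the rest strictly increasing.
#' @return An object of class `mixture_prior` with `sigma2_a_star`,
#'   `fractions` and the derived class variances `sigma2_k`.
#' @export
mixture_prior <- function(sigma2_a_star,
                          fractions = c(0, 1e-4, 1e-3, 1e-2)) {
  if (!is.numeric(sigma2_a_star) || sigma2_a_star <= 0) {
    stop("sigma2_a_star must be a positive variance")
  }
  if (fractions[1] != 0 || any(diff(fractions) <= 0)) {
    stop("fractions must start at 0 and be strictly increasing")
  }
  structure(
    list(sigma2_a_star = sigma2_a_star,
         fractions = fractions,
         sigma2_k = fractions * sigma2_a_star),
    class = "mixture_prior"
  )
}

#' MCMC run configuration
#'
#' @param n_iter total Gibbs iterations per chain.
#' @param burn_in iterations discarded before averaging; must be < `n_iter`.
#' @param n_chains number of replicate chains whose posterior summaries are
#'   averaged.
#' @param thin keep every `thin`-th post-burn-in sample in the averages.
#' @param seed integer seed; chain `c` uses `seed + c - 1`, making runs
#'   bit-reproducible.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 30000, burn_in = 20000, n_chains = 5,
                        thin = 1, seed = 1) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (n_chains < 1 || thin < 1) stop("n_chains and thin must be >= 1")
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         n_chains = as.integer(n_chains), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "mcmc_config"
  )
}
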