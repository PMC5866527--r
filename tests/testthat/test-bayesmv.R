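# The shared-association multivariate sampler: prior arithmetic, the
# association conditional against exhaustive enumeration, full-chain
# equivalence with enumeration on a tiny instance, and its BayesR limit.

test_that("joint prior probabilities follow the shared-spike formula", {
  q <- rbind(c(0.5, 0.3, 0.15, 0.05), c(0.5, 0.2, 0.2, 0.1))
  expect_equal(joint_prior_probability(0.2, q, c(1, 1)),
               0.2 + 0.8 * 0.25)
  expect_equal(joint_prior_probability(0.2, q, c(2, 3)),
               0.8 * 0.3 * 0.2)
  # p = 0 reduces to the plain product of mixing proportions
  for (k1 in 1:4) for (k2 in 1:4) {
    expect_equal(joint_prior_probability(0, q, c(k1, k2)),
                 q[1, k1] * q[2, k2])
  }
})

test_that("joint prior normalizes over all configurations for any t", {
  set.seed(21)
  for (t in 2:4) {
    q <- matrix(rgamma(4 * t, 1), t, 4)
    q <- q / rowSums(q)
    p <- runif(1)
    ks <- as.matrix(expand.grid(rep(list(1:4), t)))
    total <- sum(apply(ks, 1, function(k) joint_prior_probability(p, q, k)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("association posterior equals exhaustive enumeration", {
  set.seed(22)
  n <- 20
  w <- scale(rbinom(n, 2, 0.4))[, 1]
  priors <- list(mixture_prior(1, c(0, 0.01, 0.1, 0.5)),
                 mixture_prior(2, c(0, 0.01, 0.1, 0.5)))
  q <- rbind(c(0.4, 0.3, 0.2, 0.1), c(0.25, 0.25, 0.25, 0.25))
  Y <- cbind(w * 0.6 + rnorm(n), rnorm(n))
  s2e <- c(1, 1.3)
  p <- 0.7

  stats <- lapply(1:2, function(j) {
    snp_sufficient_stats(w, Y[, j], 1, s2e[j])
  })

  # enumerate the 1 + 4^2 latent states of the single SNP
  log_mvn <- function(y, S) {
    ch <- chol(S)
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
  }
  lik_trait <- function(j, k) {
    S <- s2e[j] * diag(n) + priors[[j]]$sigma2_k[k] * tcrossprod(w)
    log_mvn(Y[, j], S)
  }
  null_ll <- lik_trait(1, 1) + lik_trait(2, 1)
  w_unassoc <- p * exp(0)                   # relative to the null likelihood
  w_assoc <- 0
  for (k1 in 1:4) for (k2 in 1:4) {
    w_assoc <- w_assoc + (1 - p) * q[1, k1] * q[2, k2] *
      exp(lik_trait(1, k1) + lik_trait(2, k2) - null_ll)
  }
  expect_equal(association_posterior(stats, p, q, priors),
               w_assoc / (w_assoc + w_unassoc), tolerance = 1e-8)

  expect_equal(association_posterior(stats, 0, q, priors), 1)
  # flat data, strong prior toward unassociated
  null_stats <- lapply(1:2, function(j) list(rhs = 0, lhs = 20))
  expect_lt(association_posterior(null_stats, 0.99, q, priors), 0.5)
  expect_error(
    association_posterior(list(list(rhs = NaN, lhs = 1),
                               list(rhs = 0, lhs = 1)), 0.5, q, priors),
    "non-finite")
})

test_that("p draws follow the Beta conditional", {
  set.seed(23)
  m <- 1000
  d_all <- vapply(1:1e5, function(i) sample_p(m, m), numeric(1))
  expect_equal(mean(d_all), (m + 1) / (m + 2), tolerance = 0.01)
  d_half <- vapply(1:2e4, function(i) sample_p(m / 2, m), numeric(1))
  expect_equal(mean(d_half), 0.5, tolerance = 0.01)
  expect_error(sample_p(-1, 10), "invalid")
})

test_that("chain posterior matches enumeration on 2 SNPs x 2 traits", {
  set.seed(24)
  n <- 20
  W <- cbind(scale(rbinom(n, 2, 0.5))[, 1], scale(rbinom(n, 2, 0.3))[, 1])
  priors <- list(mixture_prior(1, c(0, 0.01, 0.1, 0.5)),
                 mixture_prior(1, c(0, 0.01, 0.1, 0.5)))
  Y <- cbind(W[, 1] * 0.7 + rnorm(n), rnorm(n))
  q <- c(0.4, 0.3, 0.2, 0.1)
  s2e <- c(1, 1)
  p <- 0.4

  # exhaustive posterior over the 17^2 joint latent states
  log_mvn <- function(y, S) {
    ch <- chol(S)
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
  }
  # per-SNP state: 0 = unassociated, else 1 + (k1-1) + 4*(k2-1)
  state_prior <- function(st) {
    if (st == 0) return(p)
    k1 <- (st - 1) %% 4 + 1
    k2 <- (st - 1) %/% 4 + 1
    (1 - p) * q[k1] * q[k2]
  }
  state_k <- function(st, tr) {
    if (st == 0) return(1)
    if (tr == 1) (st - 1) %% 4 + 1 else (st - 1) %/% 4 + 1
  }
  enum <- matrix(0, 17, 17)
  for (s1 in 0:16) for (s2 in 0:16) {
    ll <- 0
    for (tr in 1:2) {
      S <- s2e[tr] * diag(n) +
        priors[[tr]]$sigma2_k[state_k(s1, tr)] * tcrossprod(W[, 1]) +
        priors[[tr]]$sigma2_k[state_k(s2, tr)] * tcrossprod(W[, 2])
      ll <- ll + log_mvn(Y[, tr], S)
    }
    enum[s1 + 1, s2 + 1] <- log(state_prior(s1)) + log(state_prior(s2)) + ll
  }
  enum <- exp(enum - max(enum))
  enum <- enum / sum(enum)

  fit <- run_bayesmv(
    Y, W, mcmc_config(200000, 20000, 1, seed = 7), priors,
    p_init = p, update_p = FALSE, update_q = FALSE,
    update_sigma2e = FALSE, fit_intercept = FALSE,
    q_init = q, sigma2_e_init = s2e
  )
  chain_joint <- matrix(fit$joint_hist, 17, 17)  # SNP 1 state varies fastest
  expect_lt(max(abs(chain_joint - enum)), 0.02)
  # marginal association probabilities against the enumerated marginals
  expect_equal(fit$pp_assoc[1], 1 - sum(enum[1, ]), tolerance = 0.02)
  expect_equal(fit$pp_assoc[2], 1 - sum(enum[, 1]), tolerance = 0.02)
})

test_that("with p fixed at 0 and one trait, BayesMV matches BayesR", {
  set.seed(25)
  G <- hwe_panel(150, 60)
  W <- standardize_genotypes(G)
  y <- W[, 10] * 0.4 + rnorm(150)
  cfg <- mcmc_config(4000, 1000, 2, seed = 5)
  prior <- mixture_prior(1)
  # q and sigma2_e held fixed so both chains mix fast and the posterior
  # component probabilities can be compared within tight MC error
  q0 <- c(0.6, 0.2, 0.15, 0.05)
  fr <- run_bayesr(y, W, cfg, prior, update_q = FALSE,
                   update_sigma2e = FALSE, q_init = q0, sigma2_e_init = 1)
  fm <- run_bayesmv(matrix(y, ncol = 1), W, cfg, list(prior),
                    p_init = 0, update_p = FALSE, update_q = FALSE,
                    update_sigma2e = FALSE, q_init = q0,
                    sigma2_e_init = 1)
  expect_lt(max(abs(fm$pp[[1]] - fr$pp)), 0.05)
  expect_lt(max(abs(fm$mean_effect[, 1] - fr$mean_effect)), 0.02)
  expect_equal(fm$pp_assoc, rep(1, 60))
})

test_that("forced mixture classes propagate through the chain", {
  # q pinned on class 4 with p = 0: every SNP is associated in class 4
  set.seed(26)
  G <- hwe_panel(50, 5)
  W <- standardize_genotypes(G)
  Y <- matrix(rnorm(100), 50, 2)
  fit <- run_bayesmv(Y, W, mcmc_config(300, 100, 1, seed = 1),
                     mixture_prior(1),
                     p_init = 0, update_p = FALSE,
                     q_init = c(0, 0, 0, 1), update_q = FALSE)
  expect_equal(unname(fit$joint_class_counts[["t1_t2"]]), 5)
  expect_true(all(fit$pp[[1]][, 4] == 1))
})

test_that("posterior invariants hold on a signal-bearing run", {
  set.seed(27)
  G <- hwe_panel(200, 100)
  W <- standardize_genotypes(G)
  Y <- cbind(W[, 7] * 0.5 + rnorm(200), W[, 7] * 0.4 + rnorm(200))
  fit <- run_bayesmv(Y, W, mcmc_config(2000, 500, 1, seed = 2),
                     mixture_prior(1))
  expect_true(all(fit$pp_any <= fit$pp_assoc + 1e-12))
  expect_equal(sum(fit$joint_class_counts), 100)
  expect_gt(fit$pp_any[7], 0.9)
  # same seed reproduces the fit exactly
  fit2 <- run_bayesmv(Y, W, mcmc_config(2000, 500, 1, seed = 2),
                      mixture_prior(1))
  expect_identical(fit$pp_assoc, fit2$pp_assoc)
  expect_identical(fit$joint_class_counts, fit2$joint_class_counts)
})

test_that("joint architecture product mode follows the product rule", {
  # two traits with marginal zero-probability 0.5 everywhere: a quarter of
  # the SNPs in each joint cell
  fake <- list(
    list(pp = matrix(c(0.5, 0.5, 0.3, 0.2, 0, 0, 0, 0), 2, 4),
         pp_nonzero = c(0.5, 0.5)),
    list(pp = matrix(c(0.5, 0.5, 0.2, 0.3, 0, 0, 0, 0), 2, 4),
         pp_nonzero = c(0.5, 0.5))
  )
  counts <- summarize_joint_architecture(fake, mode = "product")
  expect_equal(unname(counts[c("zero_all", "t1", "t2", "t1_t2")]),
               rep(0.5, 4))
})

test_that("QTL mapping concentrates near true pleiotropic QTL", {
  # Under the fully pleiotropic scenario, confidently associated SNPs
  # (pp_any > 0.9) should be the causatives or their close LD neighbours.
  runs <- scaled_runs(1)
  hits <- unlist(lapply(runs, function(r) {
    det <- which(r$pp_any_mv > 0.9)
    if (!length(det)) return(numeric(0))
    near <- vapply(det, function(i) {
      min(abs(i - unlist(r$qtl))) <= 10
    }, logical(1))
    near
  }))
  expect_gt(mean(hits), 0.8)
})
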