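# Scaled replicates of the two pleiotropy scenarios, shared across test
# files (computed once per test session, on first use). Each replicate
# fits BayesMV to both traits jointly and BayesR to each trait separately
# on the same data, then measures within-population validation accuracy
# against the true breeding values.

.run_cache <- new.env(parent = emptyenv())

scaled_replicate <- function(pqtl, seed, n_iter = 5000, burn_in = 2000) {
  sc <- sim_scenario(pqtl = pqtl, n_val_across = 0)
  st <- simulate_study(sc, seed = seed)
  W <- standardize_genotypes(st$ref$geno)
  Wv <- standardize_genotypes(st$val_within$geno, f = st$ref$geno$f)
  prior <- mixture_prior(sc$sigma2_P)   # class variances on the sigma2_P scale
  cfg <- mcmc_config(n_iter, burn_in, n_chains = 1, seed = seed)

  fmv <- run_bayesmv(st$ref$phenotypes, W, cfg, prior)
  fbr <- lapply(seq_len(sc$n_traits), function(j) {
    run_bayesr(st$ref$phenotypes$y[, j], W, cfg, prior)
  })

  tbv <- st$val_within$truth$tbv
  acc_mv <- vapply(seq_len(sc$n_traits), function(j) {
    prediction_accuracy(tbv[, j], predict(fmv, Wv)[, j])
  }, numeric(1))
  acc_br <- vapply(seq_len(sc$n_traits), function(j) {
    prediction_accuracy(tbv[, j], predict(fbr[[j]], Wv))
  }, numeric(1))

  list(
    qtl = st$ref$truth$qtl_indices,
    acc_mv = acc_mv,
    acc_br = acc_br,
    pp_any_mv = fmv$pp_any,
    pp_any_br = pp_any_trait(
      vapply(fbr, function(f) f$pp[, 1], numeric(sc$m)), mode = "product"),
    joint_mv = fmv$joint_class_counts,
    joint_br_product = summarize_joint_architecture(fbr, mode = "product"),
    p_mean = fmv$p_mean,
    m = sc$m
  )
}

scaled_runs <- function(pqtl, n_rep = 10) {
  key <- paste0("pqtl", pqtl)
  if (is.null(.run_cache[[key]])) {
    seeds <- if (pqtl == 1) 100 + seq_len(n_rep) else 200 + seq_len(n_rep)
    .run_cache[[key]] <- lapply(seeds, function(s) scaled_replicate(pqtl, s))
  }
  .run_cache[[key]]
}
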