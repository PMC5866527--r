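# LD-structured genotype and multi-trait phenotype simulator. Two traits
# receive 10 additive QTL each, every QTL explaining 1% of the phenotypic
# variance (heritability 0.10), with either fully pleiotropic QTL shared by
# both traits (pqtl = 1) or disjoint QTL sets (pqtl = 0) and zero error
# covariance between traits.

#' Simulation scenario
#'
#' @param n_ref reference (training) individuals.
#' @param n_val_within validation individuals drawn from the same
#'   population as the reference.
#' @param n_val_across validation individuals from a diverged population
#'   (Balding-Nichols drift, see [derive_population()]).
#' @param m SNP count.
#' @param n_qtl_per_trait QTL per trait (default 10).
#' @param per_qtl_var_frac phenotypic-variance fraction explained by each
#'   QTL (default 0.01), so heritability is
#'   `n_qtl_per_trait * per_qtl_var_frac`.
#' @param pqtl 1 = all QTL pleiotropic (shared by both traits),
#'   0 = disjoint QTL sets per trait.
#' @param n_traits number of traits (default 2).
#' @param n_replicates replicate datasets (default 20).
#' @param fst divergence of the across-population validation panel.
#' @param sigma2_P phenotypic variance per trait (1 without loss of
#'   generality).
#' @param pool_size founder haplotypes in the mosaic pool.
#' @param ld_decay adjacent-marker latent correlation of the haplotype
#'   model, in [0, 1); 0 gives independent SNPs.
#' @param segment_mean mean mosaic segment length in SNPs.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_ref = 1000, n_val_within = 500,
                         n_val_across = 500, m = 2000,
                         n_qtl_per_trait = 10, per_qtl_var_frac = 0.01,
                         pqtl = 1, n_traits = 2, n_replicates = 20,
                         fst = 0.1, sigma2_P = 1,
                         pool_size = 100, ld_decay = 0.9,
                         segment_mean = 100) {
  if (!pqtl %in% c(0, 1)) stop("pqtl must be 0 or 1")
  h2 <- n_qtl_per_trait * per_qtl_var_frac
  if (h2 >= 1) stop("QTL variance fractions exceed the phenotypic variance")
  structure(
    list(n_ref = n_ref, n_val_within = n_val_within,
         n_val_across = n_val_across, m = m,
         n_qtl_per_trait = n_qtl_per_trait,
         per_qtl_var_frac = per_qtl_var_frac, pqtl = pqtl,
         n_traits = n_traits, n_replicates = n_replicates, fst = fst,
         sigma2_P = sigma2_P, h2 = h2, pool_size = pool_size,
         ld_decay = ld_decay, segment_mean = segment_mean),
    class = "sim_scenario"
  )
}

#' Founder haplotype pool with tunable LD
#'
#' Haplotypes are thresholded latent first-order autoregressive Gaussians:
#' site j's latent value is `ld_decay` times site j-1's plus independent
#' noise, and the allele is 1 when the latent value is below the quantile
#' of the site's target frequency. Adjacent-marker allelic correlation
#' therefore rises monotonically with `ld_decay` and decays geometrically
#' with distance.
#'
#' @param m SNPs per haplotype.
#' @param pool_size number of haplotypes.
#' @param ld_decay latent AR(1) coefficient in [0, 1).
#' @param freq_range range of target allele frequencies, drawn uniformly.
#' @return A `haplotype_pool`: binary `pool_size x m` matrix `H`, target
#'   frequencies `f_target` and `ld_decay`.
#' @export
make_haplotype_pool <- function(m, pool_size = 100, ld_decay = 0.9,
                                freq_range = c(0.05, 0.95)) {
  f <- stats::runif(m, freq_range[1], freq_range[2])
  z <- matrix(stats::rnorm(pool_size * m), pool_size, m)
  if (ld_decay > 0) {
    for (j in 2:m) {
      z[, j] <- ld_decay * z[, j - 1] +
        sqrt(1 - ld_decay^2) * z[, j]
    }
  }
  H <- sweep(z, 2, stats::qnorm(f), "<") * 1L
  structure(list(H = H, f_target = f, ld_decay = ld_decay),
            class = "haplotype_pool")
}

# one gamete: mosaic of pool haplotypes with geometric segment lengths
sample_gamete <- function(pool, segment_mean) {
  m <- ncol(pool$H)
  switches <- c(1L, stats::rbinom(m - 1L, 1L, 1 / segment_mean))
  seg <- cumsum(switches)
  hap_of_seg <- sample.int(nrow(pool$H), seg[m], replace = TRUE)
  pool$H[cbind(hap_of_seg[seg], seq_len(m))]
}

#' Sample a genotype panel from a haplotype pool
#'
#' Each individual is the sum of two independent mosaic gametes
#' ([make_haplotype_pool()]). Columns that come out monomorphic are
#' re-drawn from freshly resampled pool columns a limited number of times.
#'
#' @param pool a `haplotype_pool`.
#' @param n individuals.
#' @param segment_mean mean mosaic segment length in SNPs.
#' @param id_prefix prefix for individual identifiers.
#' @param max_retries retry limit for monomorphic columns.
#' @return A [genotype_matrix()].
#' @export
sample_panel <- function(pool, n, segment_mean = 100, id_prefix = "id",
                         max_retries = 20) {
  m <- ncol(pool$H)
  D <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    D[i, ] <- sample_gamete(pool, segment_mean) +
      sample_gamete(pool, segment_mean)
  }
  for (try in seq_len(max_retries)) {
    f <- colMeans(D) / 2
    mono <- which(f == 0 | f == 1)
    if (!length(mono)) break
    for (j in mono) {
      fj <- min(max(pool$f_target[j], 0.05), 0.95)
      D[, j] <- stats::rbinom(n, 1L, fj) + stats::rbinom(n, 1L, fj)
    }
  }
  f <- colMeans(D) / 2
  if (any(f == 0 | f == 1)) {
    stop("monomorphic SNPs remained after ", max_retries, " retries")
  }
  genotype_matrix(D, individual_ids = paste0(id_prefix, seq_len(n)))
}

#' Simulate an LD-structured genotype panel
#'
#' Convenience wrapper: builds a founder haplotype pool and samples `n`
#' individuals from it.
#'
#' @param n individuals.
#' @param m SNPs.
#' @param pool_size,ld_decay,segment_mean see [make_haplotype_pool()] and
#'   [sample_panel()].
#' @return List with `panel` (a [genotype_matrix()]) and `pool`.
#' @export
simulate_genotype_panel <- function(n, m, pool_size = 100, ld_decay = 0.9,
                                    segment_mean = 100) {
  pool <- make_haplotype_pool(m, pool_size, ld_decay)
  list(panel = sample_panel(pool, n, segment_mean), pool = pool)
}

#' Derive a diverged population's haplotype pool
#'
#' Perturbs the source pool's allele frequencies by the Balding-Nichols
#' construction — `f' ~ Beta(f (1 - fst)/fst, (1 - f)(1 - fst)/fst)`, so
#' `E[(f' - f)^2] = fst * f (1 - f)` — and regenerates the haplotype pool
#' at the new frequencies with the same LD structure.
#'
#' @param pool source `haplotype_pool`.
#' @param fst divergence parameter in [0, 1); 0 returns frequencies drawn
#'   at the source values.
#' @return A new `haplotype_pool`.
#' @export
derive_population <- function(pool, fst) {
  f <- pool$f_target
  if (fst > 0) {
    a <- f * (1 - fst) / fst
    b <- (1 - f) * (1 - fst) / fst
    f <- stats::rbeta(length(f), a, b)
    f <- pmin(pmax(f, 1e-3), 1 - 1e-3)
  }
  new_pool <- make_haplotype_pool(length(f), nrow(pool$H), pool$ld_decay)
  # re-threshold the new pool's latent field at the drifted frequencies
  new_pool$f_target <- f
  z <- matrix(stats::rnorm(length(pool$H)), nrow(pool$H), ncol(pool$H))
  if (pool$ld_decay > 0) {
    for (j in 2:ncol(z)) {
      z[, j] <- pool$ld_decay * z[, j - 1] +
        sqrt(1 - pool$ld_decay^2) * z[, j]
    }
  }
  new_pool$H <- sweep(z, 2, stats::qnorm(f), "<") * 1L
  new_pool
}

#' Select QTL positions for the pleiotropy scenarios
#'
#' With `pqtl = 1` a single set of `n_qtl_per_trait` SNPs is shared by all
#' traits; with `pqtl = 0` each trait gets its own disjoint set. Only SNPs
#' with minor allele frequency above `maf_min` are eligible.
#'
#' @param G reference [genotype_matrix()].
#' @param scenario a [sim_scenario()].
#' @param maf_min minor-allele-frequency floor for QTL eligibility.
#' @return List of integer index vectors, one per trait.
#' @export
select_qtl <- function(G, scenario, maf_min = 0.01) {
  maf <- pmin(G$f, 1 - G$f)
  eligible <- which(maf > maf_min)
  need <- if (scenario$pqtl == 1) scenario$n_qtl_per_trait else
    scenario$n_qtl_per_trait * scenario$n_traits
  if (length(eligible) < need) {
    stop("not enough SNPs with MAF > ", maf_min, " to place QTL")
  }
  picked <- sample(eligible, need)
  if (scenario$pqtl == 1) {
    rep(list(picked), scenario$n_traits)
  } else {
    split(picked, rep(seq_len(scenario$n_traits),
                      each = scenario$n_qtl_per_trait))
  }
}

#' QTL effect size for a fixed variance contribution
#'
#' `|effect| = sqrt(per_qtl_var_frac * sigma2_P / (2 f (1 - f)))` per allele
#' copy, so the QTL contributes exactly `per_qtl_var_frac * sigma2_P` of
#' variance under Hardy-Weinberg genotype frequencies at allele frequency
#' `f`.
#'
#' @param f allele frequency in (0, 1).
#' @param sigma2_P phenotypic variance.
#' @param per_qtl_var_frac variance fraction per QTL.
#' @return Positive effect size (trait units per allele copy).
#' @export
qtl_effect_size <- function(f, sigma2_P = 1, per_qtl_var_frac = 0.01) {
  if (any(f <= 0 | f >= 1)) stop("allele frequency must be in (0, 1)")
  sqrt(per_qtl_var_frac * sigma2_P / (2 * f * (1 - f)))
}

#' Simulate multi-trait phenotypes from placed QTL
#'
#' Assigns each QTL an effect of magnitude [qtl_effect_size()] with a
#' random sign (signs independent across traits at shared QTL unless
#' `equal_signs`), computes true breeding values as dosage-weighted sums
#' and adds independent Gaussian errors per trait with variance
#' `sigma2_P * (1 - h2)`, so total phenotypic variance is `sigma2_P` and
#' cross-trait error covariance is zero.
#'
#' @param G a [genotype_matrix()].
#' @param qtl_indices list of per-trait QTL index vectors from
#'   [select_qtl()].
#' @param scenario a [sim_scenario()].
#' @param equal_signs force shared QTL to have the same effect sign on
#'   every trait.
#' @return List with `phenotypes` (a [phenotype_table()]) and `truth`
#'   (class `sim_truth`: `qtl_indices`, `qtl_effects` on the dosage scale,
#'   `tbv` n x t, `sigma2_P`).
#' @export
simulate_phenotypes <- function(G, qtl_indices, scenario,
                                equal_signs = FALSE) {
  n <- nrow(G$dosages)
  t <- scenario$n_traits
  tbv <- matrix(0, n, t)
  effects <- vector("list", t)
  base_signs <- NULL
  for (j in seq_len(t)) {
    idx <- qtl_indices[[j]]
    if (length(idx)) {
      mag <- qtl_effect_size(G$f[idx], scenario$sigma2_P,
                             scenario$per_qtl_var_frac)
      signs <- sample(c(-1, 1), length(idx), replace = TRUE)
      if (equal_signs) {
        if (is.null(base_signs)) base_signs <- signs
        signs <- base_signs
      }
      effects[[j]] <- mag * signs
      tbv[, j] <- G$dosages[, idx, drop = FALSE] %*% effects[[j]]
    } else {
      effects[[j]] <- numeric(0)
    }
  }
  err_sd <- sqrt(scenario$sigma2_P * (1 - scenario$h2))
  y <- tbv + matrix(stats::rnorm(n * t, sd = err_sd), n, t)
  colnames(y) <- paste0("trait", seq_len(t))
  list(
    phenotypes = phenotype_table(y, individual_ids = G$individual_ids),
    truth = structure(
      list(qtl_indices = qtl_indices, qtl_effects = effects,
           tbv = tbv, sigma2_P = rep(scenario$sigma2_P, t)),
      class = "sim_truth"
    )
  )
}

#' Simulate one complete study replicate
#'
#' Builds a founder pool, samples the reference and within-population
#' validation panels from it and the across-population panel from a
#' diverged pool, places QTL (on the reference panel's frequencies) and
#' simulates phenotypes and true breeding values for every panel.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed making the replicate fully reproducible.
#' @return List with `ref` (list: `geno`, `phenotypes`, `truth`),
#'   `val_within` and `val_across` (each: `geno`, `truth`), `pool`, and the
#'   scenario.
#' @export
simulate_study <- function(scenario = sim_scenario(), seed = 1) {
  set.seed(seed)
  pool <- make_haplotype_pool(scenario$m, scenario$pool_size,
                              scenario$ld_decay)
  ref <- sample_panel(pool, scenario$n_ref, scenario$segment_mean, "ref")
  qtl <- select_qtl(ref, scenario)
  sim_ref <- simulate_phenotypes(ref, qtl, scenario)

  make_val <- function(panel, prefix) {
    t <- scenario$n_traits
    tbv <- matrix(0, nrow(panel$dosages), t)
    for (j in seq_len(t)) {
      idx <- qtl[[j]]
      if (length(idx)) {
        tbv[, j] <- panel$dosages[, idx, drop = FALSE] %*%
          sim_ref$truth$qtl_effects[[j]]
      }
    }
    list(geno = panel,
         truth = structure(
           list(qtl_indices = qtl, qtl_effects = sim_ref$truth$qtl_effects,
                tbv = tbv, sigma2_P = sim_ref$truth$sigma2_P),
           class = "sim_truth"
         ))
  }

  val_within <- NULL
  if (scenario$n_val_within > 0) {
    panel <- sample_panel(pool, scenario$n_val_within,
                          scenario$segment_mean, "valw")
    val_within <- make_val(panel, "valw")
  }
  val_across <- NULL
  if (scenario$n_val_across > 0) {
    pool2 <- derive_population(pool, scenario$fst)
    panel <- sample_panel(pool2, scenario$n_val_across,
                          scenario$segment_mean, "vala")
    val_across <- make_val(panel, "vala")
  }

  list(ref = list(geno = ref, phenotypes = sim_ref$phenotypes,
                  truth = sim_ref$truth),
       val_within = val_within, val_across = val_across,
       pool = pool, scenario = scenario)
}

#' Write a simulated study to disk
#'
#' Writes the reference panel as PLINK bed/bim/fam, phenotypes as TSV and
#' the truth table (SNP id, trait, effect, allele frequency) as TSV.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(study$ref$geno, file.path(dir, "ref"))
  write_phenotypes(study$ref$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- study$ref$truth
  rows <- do.call(rbind, lapply(seq_along(truth$qtl_indices), function(j) {
    idx <- truth$qtl_indices[[j]]
    data.frame(snp_id = study$ref$geno$snp_ids[idx], trait = j,
               effect = truth$qtl_effects[[j]], f = study$ref$geno$f[idx])
  }))
  utils::write.table(rows, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a simulation scenario from a config file
#'
#' Accepts a two-column `key<TAB>value` (or `key=value`) text file naming
#' any subset of the [sim_scenario()] fields; unnamed fields keep their
#' defaults.
#'
#' @param path config file path.
#' @return A [sim_scenario()].
#' @export
read_scenario <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[=\t]")
  keys <- vapply(parts, function(p) trimws(p[1]), character(1))
  vals <- vapply(parts, function(p) as.numeric(trimws(p[2])), numeric(1))
  known <- names(formals(sim_scenario))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown scenario fields: ", paste(bad, collapse = ", "))
  do.call(sim_scenario, as.list(stats::setNames(vals, keys)))
}
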