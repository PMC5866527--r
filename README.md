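# bayesmv

Multi-trait Bayesian mixture models for simultaneous QTL mapping, genetic
architecture estimation and genomic prediction.

## The problem

Genomic prediction and QTL mapping usually analyze one trait at a time,
ignoring that a single polymorphism often affects several traits
(pleiotropy). Methods that do model traits jointly typically assume QTL
effects follow one multivariate normal distribution with a common
correlation across all loci — an assumption contradicted by loci whose
effect signs differ between traits despite a positive overall genetic
correlation.

This package implements a multivariate whole-genome regression (**BayesMV**)
that shares information across traits only in the *selection* of SNPs: each
SNP carries one latent indicator, "unassociated with every trait" (prior
probability *p*) versus "associated", and an associated SNP's effects are
estimated independently per trait from a four-class mixture of normals

σ²_k ∈ {0, 10⁻⁴, 10⁻³, 10⁻²} · σ²_a\*,

where σ²_a\* is the trait's additive genetic variance. The univariate
counterpart (**BayesR**, the *p* = 0 limit) is included, as are:

* an error-decorrelating trait transform `LC = B′T⁻¹y` (eigenvectors of the
  error correlation matrix), with back-transformation `T·B·(·)` of GEBV and
  SNP effects, required because the multivariate model assumes independent
  residuals across traits;
* PLINK bed/bim/fam input/output, phenotype/pedigree tables, the pedigree
  numerator relationship matrix and an optional polygenic term;
* an LD-structured genotype/phenotype simulator with fully-pleiotropic and
  no-pleiotropy scenarios, within- and across-population validation splits;
* evaluation tools: prediction accuracy r(TBV, GEBV), bias b(y, ŷ),
  QTL-mapping power and FDR at a posterior-probability threshold, and a
  multi-trait single-SNP χ² association scan.

All samplers are single-site Gibbs with the per-SNP effect integrated out
of the component update, run in compiled (RcppArmadillo) code, seeded and
bit-reproducible. See the methods vignette
(`vignettes/bayesmv-methods.Rmd`) for the model, priors, numerical
conventions and known scale effects.

## Worked example

Simulate the fully pleiotropic scenario (2,000 SNPs, 1,000 reference
individuals, two traits with the same 10 QTL each explaining 1% of the
phenotypic variance, h² = 0.10), fit the multivariate model, and validate
in 500 individuals from the same population:

```r
library(bayesmv)

sc    <- sim_scenario(pqtl = 1, n_ref = 1000, n_val_within = 500,
                      n_val_across = 0, m = 2000)
study <- simulate_study(sc, seed = 2024)

W     <- standardize_genotypes(study$ref$geno)
prior <- mixture_prior(sc$sigma2_P)   # class variances on the sigma2_P scale
cfg   <- mcmc_config(n_iter = 5000, burn_in = 2000, n_chains = 1, seed = 1)
fit   <- run_bayesmv(study$ref$phenotypes, W, cfg, prior)
print(fit)
#> BayesMV fit: 2000 SNPs x 2 traits; posterior mean p = 0.9852
#> unassociated     zero_all           t1           t2        t1_t2
#>       1971.5          0.8          3.3          4.5         19.9

Wval <- standardize_genotypes(study$val_within$geno, f = study$ref$geno$f)
gebv <- predict(fit, Wval)
sapply(1:2, function(j)
  prediction_accuracy(study$val_within$truth$tbv[, j], gebv[, j]))
#> 0.785 0.762

qtl_power_fdr(fit$pp_any, study$ref$truth$qtl_indices[[1]], threshold = 0.9)[c("power", "fdr")]
#> $power 0.4   $fdr 0
```

Reading the output: the model classifies 1,971 of 2,000 SNPs as
unassociated (posterior mean *p* = 0.985; the truth is 1,990/2,000) and
places almost all of the associated mass in the both-traits class
(`t1_t2`), correctly recognizing the shared architecture; 4 of the 10 QTL
exceed posterior probability 0.9 with no false detections, and the GEBV
correlate ≈ 0.77 with the true breeding values. The matching univariate
fits (`run_bayesr()` per trait) reach ≈ 0.67 on the same replicates — the
multivariate advantage under pleiotropy.

Command-line wrappers for the three analysis stages live in `inst/cli/`
(`bayesr.R`, `bayesmv.R`, `evaluate.R`); each is a thin Rscript over the
functions above (`Rscript inst/cli/bayesmv.R --help`).

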