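---
title: "Multi-trait Bayesian mixture models for QTL mapping and genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait Bayesian mixture models for QTL mapping and genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmv)
```

## The model

Both samplers fit the whole-genome regression

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{a} + \mathbf{W}\mathbf{v} + \mathbf{e},$$

where $\mathbf{y}$ holds one trait's phenotypes, $\mathbf{b}$ fixed effects
(an intercept by default), $\mathbf{a} \sim N(0, \mathbf{A}\sigma^2_a)$ an
optional polygenic term scaled by the pedigree numerator relationship
matrix, $\mathbf{W}$ the standardized SNP genotypes
($w_{ij} = (x_{ij} - 2f_j)/\sqrt{2f_j(1-f_j)}$, missing dosages mean-imputed
to $2f_j$), and $\mathbf{e} \sim N(0, \mathbf{E}\sigma^2_e)$ with known
diagonal error weights $\mathbf{E}^{-1}$ for heteroscedastic records.

Each SNP effect is drawn from a four-component mixture of normals with
variances fixed at $\{0,\, 10^{-4},\, 10^{-3},\, 10^{-2}\} \times
\sigma^2_{a^*}$, where $\sigma^2_{a^*}$ is the additive genetic variance of
the analyzed trait supplied by the user (typically a pedigree-based
estimate). Only the mixing proportions $\mathbf{q}$ are learned, with a flat
Dirichlet(1,1,1,1) hyperprior. This is the univariate sampler, `run_bayesr()`.

The multivariate sampler, `run_bayesmv()`, adds one latent binary indicator
per SNP shared across all $t$ traits: with probability $p$ the SNP is
*unassociated* and has exactly zero effect on every trait; with probability
$1-p$ it is *associated* and its effect on each trait $j$ is drawn
independently from that trait's four-class mixture with proportions
$q_{j,k}$. The prior probability that a SNP occupies component combination
$(k_1, \dots, k_t)$ is therefore
$p + (1-p)\prod_j q_{j,1}$ when all $k_j = 1$ and
$(1-p)\prod_j q_{j,k_j}$ otherwise. The univariate model is the $p = 0$
limit. The deliberate asymmetry — association shared across traits, effect
sizes independent per trait — avoids assuming that QTL effects follow a
common multivariate normal correlation across traits, which is violated by
well-known loci whose effect signs differ between traits.

## Error-independent linear combinations

The multivariate model assumes residuals independent across traits. For
correlated traits, `make_linear_combinations()` builds
$\mathbf{LC} = \mathbf{B}'\mathbf{T}^{-1}\mathbf{y}$ from the eigenvectors
$\mathbf{B}$ of the error correlation matrix $\mathbf{K}$
($\mathbf{K} = \mathbf{B}\Lambda\mathbf{B}'$) and the diagonal error SDs
$\mathbf{T}$, giving LC traits with error covariance $\Lambda$ (diagonal by
construction). GEBV and SNP effects are mapped back to the original traits
with $\mathbf{T}\mathbf{B}(\cdot)$ (`back_transform()`), and
`lc_genetic_parameters()` reports the LC-scale genetic covariance
$\mathbf{B}'\mathbf{T}^{-1}\mathbf{G}\mathbf{T}^{-1}\mathbf{B}$ and
heritabilities $g_{jj}/(g_{jj} + \Lambda_j)$. The transform decorrelates the
*errors* only; the genetic correlations of the LCs are reported, not forced
to zero. Estimating $\mathbf{K}$, $\mathbf{T}$, $\mathbf{G}$ themselves
(e.g. by a pedigree-based multivariate mixed model) is out of scope — they
are inputs. Per-record error weights are carried through the transform
unchanged, one weight per individual applied to all its LCs; weights that
differ across traits within an individual have no exact single-weight
representation on the LC scale, so the first trait's weight is used.

Eigenvalues are sorted in decreasing order and each eigenvector's sign is
fixed by making its largest-magnitude entry positive: the decomposition is
deterministic, which matters for reproducible LC labels. When eigenvalues
tie (e.g. $\mathbf{K} = \mathbf{I}$) the basis within the tied block is
whatever LAPACK returns, and only span-level properties are guaranteed.

## Gibbs sampling scheme

Per sweep and SNP, the component (univariate) or the association indicator
plus per-trait components (multivariate) are drawn with the SNP's effect
integrated out of its conditional, then the effect is redrawn given the
component: for sufficient statistics $r = \mathbf{w}_j'\mathbf{E}^{-1}
\tilde{\mathbf{y}}/\sigma^2_e$ and $l = \mathbf{w}_j'\mathbf{E}^{-1}
\mathbf{w}_j/\sigma^2_e$ (residual $\tilde{\mathbf{y}}$ excluding SNP $j$),
the integrated likelihood of a class with variance $\sigma^2_k$ is
$(1 + l\sigma^2_k)^{-1/2}\exp\{r^2\sigma^2_k / (2(1 + l\sigma^2_k))\}$, and
the effect conditional is $N(r/(l + 1/\sigma^2_k),\, 1/(l + 1/\sigma^2_k))$.
In the multivariate model the association indicator is drawn first with all
components marginalized (the per-trait likelihoods factorize because the LC
errors are independent), which mixes far better than updating the indicator
conditional on the current components. Conjugate updates follow for
$\mathbf{q}$ (Dirichlet), $p$ (Beta(1,1) hyperprior), $\sigma^2_e$ (flat
scaled-inverse-$\chi^2$: $\nu_0 = -2$, $S_0 = 0$, draws floored at
$10^{-12}$), the intercept, and the polygenic vector (via the
eigen-decomposition of $\mathbf{A}$, one $O(n^2)$ transform per iteration;
the compiled polygenic path requires unit weights — the general weighted
conditional is available as `sample_polygenic()`). The working residual is
rebuilt from scratch every 100 sweeps to keep floating-point drift below
$10^{-8}$.

The chains run in compiled code with all draws taken from R's RNG, so a
seed makes a run bit-reproducible; `mcmc_config()` defaults to 30,000
iterations, 20,000 burn-in and 5 replicate chains whose posterior summaries
are averaged. "Associated but currently zero on every trait" is retained as
a distinct latent state, and the joint architecture table
(`summarize_joint_architecture()`) tallies sampled configurations directly
per iteration; a `product` mode reconstructs the univariate-style table
from products of per-trait marginal posterior probabilities for
comparison. `pp_any` — the probability of a non-zero effect on at least one
trait — is likewise tallied directly from the sampled states, never from
products of marginals.

On tiny problems ($\le$ 6 SNPs univariate; joint state space $\le$ 5,000
multivariate) the chains additionally record the full joint histogram over
latent configurations; the test suite holds $\mathbf{q}$, $p$ and
$\sigma^2_e$ fixed there and verifies the histogram against exhaustive
enumeration of all configurations with closed-form marginal likelihoods.

## The simulator

`simulate_study()` emulates a dense single-chromosome panel from a dairy
cattle breeding population:

* **Haplotype pool.** Founder haplotypes are thresholded latent AR(1)
  Gaussians: site $j$'s latent value is `ld_decay` times site $j-1$'s plus
  noise, thresholded at the quantile of a target frequency drawn uniformly
  on (0.05, 0.95). Individuals are sums of two mosaic gametes that switch
  source haplotypes with geometric segment lengths. Defaults — pool of 100
  haplotypes, `ld_decay = 0.9`, mean segment 100 SNPs — give
  adjacent-marker $r^2$ in the 0.4–0.6 range typical of high-density
  bovine chips, decaying geometrically with distance, plus the background
  relatedness of a finite founder pool.
* **Trait architecture.** Two traits, 10 QTL each, every QTL explaining 1%
  of the phenotypic variance ($\sigma^2_P = 1$ without loss of generality):
  the allele-substitution effect at frequency $a$ is
  $\sqrt{0.01\sigma^2_P / (2a(1-a))}$ with a random sign, QTL are sampled
  among SNPs with MAF > 0.01, and independent Gaussian errors top the
  variance up to $\sigma^2_P$, so $h^2 = 0.10$ per trait and the
  cross-trait error covariance is zero. `pqtl = 1` makes the 10 QTL fully
  shared between traits (signs drawn independently per trait unless
  `equal_signs`); `pqtl = 0` gives each trait its own disjoint set.
* **Validation splits.** A within-population validation panel is drawn from
  the same founder pool; an across-population panel comes from a pool whose
  frequencies drift by the Balding–Nichols construction with `fst = 0.1`
  (beta-distributed around the source frequencies with
  $E[(f'-f)^2] = F_{st} f(1-f)$).

What the simulator does *not* emulate: real site-frequency spectra,
mutation/recombination hotspots, pedigree structure within a panel
(individuals are exchangeable draws from the pool), selection, or
genotyping error. Passing tests therefore demonstrate correctness of the
samplers and the qualitative pleiotropy phenomena under a realistic LD
regime, not performance guarantees on any particular livestock dataset.

## Choice of the class-variance scale in simulations

For simulated traits the analyses in this package set
$\sigma^2_{a^*} = \sigma^2_P$, so the four classes explain
$\{0, 10^{-4}, 10^{-3}, 10^{-2}\}$ of the *phenotypic* variance and a
simulated QTL (1% of $\sigma^2_P$) sits exactly in the largest class. The
alternative — scaling by the trait's genetic variance
$h^2\sigma^2_P = 0.1$ — makes every class ten times smaller than the
effects actually segregating, over-shrinks the QTL and degrades both
mapping and prediction; with the phenotypic scale the sampler's class
occupancies and prediction accuracies reproduce the expected architecture
cleanly. For real data the natural input remains the pedigree genetic
variance of the analyzed (LC) trait.

## Problem sizes, runtime and known scale effects

The package's reference simulation sizes are desk-scale: $m = 2{,}000$
SNPs, $n_{\text{ref}} = 1{,}000$, 500 validation individuals, chains of
5,000 iterations with 2,000 burn-in, 10–20 replicates; one replicate
(multivariate fit plus two univariate fits) takes roughly 20 s on one CPU.

Two behaviors depend strongly on scale and are worth knowing:

* **Prediction accuracy.** With 10 QTL of 1% each and $h^2 = 0.10$, the
  information per QTL grows with $n$. At $n_{\text{ref}} = 3{,}000$ the
  multivariate sampler reaches within-population accuracy $\approx 0.97$
  versus $\approx 0.90$ univariate under full pleiotropy; at
  $n_{\text{ref}} = 1{,}000$ the same code yields $\approx 0.77$ versus
  $\approx 0.67$ — the *advantage* (and its direction) is stable, the
  absolute accuracy is information-limited.
* **Occupancy of the smallest non-zero class.** The $10^{-4}$-variance
  class is nearly likelihood-indistinguishable from the zero class
  whenever $n \sigma^2_2 / \sigma^2_e \ll 1$; under the flat Dirichlet
  hyperprior its occupancy is then prior-driven rather than data-driven,
  which inflates univariate "non-zero" SNP counts at small $n \times m$.
  The shared association indicator of the multivariate model concentrates
  this mass into the unassociated spike instead, which is one of its
  practical advantages for architecture estimation. At large $n$ (real
  datasets, or $n \approx 3{,}000$ with dense panels) both models separate
  the classes cleanly.

## Degenerate inputs and numerical conventions

Monomorphic SNPs must be filtered before standardization (the constructor
errors otherwise); missing dosages are mean-imputed, hence exactly zero
after centering and carrying no association signal. Variance draws are
floored at $10^{-12}$; component probabilities are computed in log space;
zero mixing proportions are allowed and excluded exactly. An empty
detection set defines FDR as 0. The power/FDR window option (off by
default) counts detections within a fixed number of panel positions of a
true QTL as causal, for LD-aware mapping summaries; printed power always
uses exact causatives. The multi-trait scan uses signed per-trait
t-statistics and the across-SNP correlation matrix of those statistics as
the working covariance, referred to $\chi^2_t$; it errors on a singular
correlation matrix rather than regularizing silently.

## Limitations

The polygenic term in the compiled chains requires unit error weights;
weighted analyses with a pedigree term must use the R-level conditional.
The mixture never adapts its class variances, by design — misspecifying
$\sigma^2_{a^*}$ rescales every class. GEBV exclude the polygenic term by
default (validation individuals are typically unpedigreed); per-chain
polygenic means are available for workflows that need them. The number of
mixture classes is fixed at four.
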