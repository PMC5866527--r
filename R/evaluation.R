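# Prediction accuracy/bias, QTL-mapping power and FDR, posterior
# probability aggregation across traits, and the multi-trait single-SNP
# association scan used as a mapping comparator.

#' Prediction accuracy
#'
#' Pearson correlation `r(TBV, GEBV)` (simulations) or `r(y, GEBV)` (real
#' phenotypes).
#'
#' @param truth_or_pheno true breeding values or observed phenotypes.
#' @param gebv predicted breeding values, aligned with the first argument.
#' @return Correlation in [-1, 1].
#' @export
prediction_accuracy <- function(truth_or_pheno, gebv) {
  if (length(truth_or_pheno) != length(gebv)) stop("vectors not aligned")
  if (length(gebv) < 3) stop("need at least 3 validation records")
  if (stats::sd(truth_or_pheno) == 0 || stats::sd(gebv) == 0) {
    stop("accuracy undefined: zero variance")
  }
  stats::cor(truth_or_pheno, gebv)
}

#' Prediction bias
#'
#' Slope of the ordinary least-squares regression of the observed values on
#' the predictions, `b(y, gebv)`; an unbiased prediction has slope 1.
#'
#' @param y observed values (phenotypes or TBV).
#' @param gebv predictions.
#' @return Regression slope.
#' @export
prediction_bias <- function(y, gebv) {
  if (length(y) != length(gebv)) stop("vectors not aligned")
  if (stats::sd(gebv) == 0) stop("bias undefined: zero GEBV variance")
  stats::cov(y, gebv) / stats::var(gebv)
}

#' Average validation results over subgroups
#'
#' Unweighted mean of subgroup accuracies and biases (e.g. bulls and cows
#' of one breed).
#'
#' @param results list of lists/data.frames each holding `accuracy` and
#'   `bias`.
#' @return List with mean `accuracy` and `bias` and the subgroup count `n`.
#' @export
group_average <- function(results) {
  acc <- vapply(results, function(r) r$accuracy, numeric(1))
  bias <- vapply(results, function(r) r$bias, numeric(1))
  list(accuracy = mean(acc), bias = mean(bias), n = length(results))
}

#' Posterior probability of a non-zero effect on any trait
#'
#' `product` mode combines per-trait zero-class posterior probabilities as
#' `1 - prod_j P(zero on trait j)` — the univariate-style summary.
#' `direct` mode passes through a directly sampled any-trait posterior
#' probability (as accumulated by [run_bayesmv()]).
#'
#' @param per_trait_zero_pp m x t matrix of per-trait zero-class
#'   probabilities (`product` mode) or the m-vector of sampled any-trait
#'   probabilities (`direct` mode).
#' @param mode `"product"` or `"direct"`.
#' @return m-vector of probabilities.
#' @export
pp_any_trait <- function(per_trait_zero_pp, mode = c("product", "direct")) {
  mode <- match.arg(mode)
  x <- as.matrix(per_trait_zero_pp)
  if (any(x < -1e-12 | x > 1 + 1e-12)) stop("probabilities outside [0, 1]")
  x <- pmin(pmax(x, 0), 1)
  if (mode == "direct") return(drop(x))
  1 - apply(x, 1, prod)
}

#' QTL-mapping power and false discovery rate
#'
#' A SNP is detected when its posterior probability of a non-zero effect
#' exceeds `threshold`. Power is the fraction of causative SNPs detected;
#' FDR is the fraction of detected SNPs that are not causative (0 when
#' nothing is detected). `window > 0` relaxes "causative" to any SNP within
#' that many positions of a true QTL.
#'
#' @param pp_any m-vector of posterior probabilities.
#' @param causal integer indices of the true QTL.
#' @param threshold detection cutoff (default 0.9).
#' @param window index distance within which a detection counts as causal
#'   (default 0 = exact).
#' @return List with `threshold`, `power`, `fdr` and the `detected` index
#'   set.
#' @export
qtl_power_fdr <- function(pp_any, causal, threshold = 0.9, window = 0) {
  if (!length(causal)) stop("empty causal set")
  m <- length(pp_any)
  if (any(causal < 1 | causal > m)) stop("causal indices out of range")
  detected <- which(pp_any > threshold)
  causal_like <- if (window > 0) {
    unique(unlist(lapply(causal, function(i) {
      max(1, i - window):min(m, i + window)
    })))
  } else {
    causal
  }
  power <- length(intersect(detected, causal)) / length(causal)
  fdr <- if (length(detected)) {
    length(setdiff(detected, causal_like)) / length(detected)
  } else {
    0
  }
  list(threshold = threshold, power = power, fdr = fdr, detected = detected)
}

#' Multi-trait single-SNP association scan
#'
#' For each SNP, signed t-statistics are computed per trait from simple
#' single-SNP regressions; the multi-trait statistic is
#' `chi2 = t' V^{-1} t` with `V` the across-SNP correlation matrix of the
#' t-statistics, referred to a chi-square with one degree of freedom per
#' trait.
#'
#' @param Y a [phenotype_table()] or n x t matrix with at least 2 traits
#'   (a single trait degenerates to the squared t).
#' @param G a [genotype_matrix()] or a pre-standardized design matrix.
#' @return data.frame with per-trait `t_*` columns, `chi2`, `p` and
#'   `neglog10p`.
#' @export
multitrait_gwas <- function(Y, G) {
  if (inherits(Y, "phenotype_table")) Y <- Y$y
  Y <- as.matrix(Y)
  W <- if (inherits(G, "genotype_matrix")) standardize_genotypes(G) else
    as.matrix(G)
  n <- nrow(W)
  t <- ncol(Y)
  if (n != nrow(Y)) stop("Y and G are not aligned")
  if (n <= t + 2) stop("too few individuals for the association scan")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Wc <- scale(W, center = TRUE, scale = FALSE)
  ss_w <- colSums(Wc^2)
  beta <- crossprod(Wc, Yc) / ss_w                     # m x t
  tstat <- matrix(0, ncol(W), t)
  for (j in seq_len(t)) {
    rss <- sum(Yc[, j]^2) - beta[, j]^2 * ss_w
    se <- sqrt(rss / (n - 2) / ss_w)
    tstat[, j] <- beta[, j] / se
  }
  V <- if (t == 1) matrix(1, 1, 1) else stats::cor(tstat)
  cond <- kappa(V)
  if (!is.finite(cond) || cond > 1e10) {
    stop("t-statistic correlation matrix is singular (condition number ",
         format(cond), ")")
  }
  chi2 <- rowSums((tstat %*% solve(V)) * tstat)
  p <- stats::pchisq(chi2, df = t, lower.tail = FALSE)
  out <- as.data.frame(tstat)
  names(out) <- paste0("t_", seq_len(t))
  out$chi2 <- chi2
  out$p <- p
  out$neglog10p <- -log10(pmax(p, .Machine$double.xmin))
  out
}
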