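#' Likelihood-ratio comparison of nested mixed models
#'
#' Compares a full model to a null model missing one or more fixed-effect
#' terms (the mixed-model ANOVA used throughout the association scans).
#' Both fits must be maximum-likelihood fits on identical rows: REML
#' likelihoods are not comparable across fixed-effect structures.
#'
#' @param full,null `lmm_fit` objects fitted with `method = "ML"` on the
#'   same rows; `null`'s fixed terms must be a strict subset of `full`'s.
#' @return A list with the chi-squared `statistic` (floored at 0), `df`
#'   (difference in fixed-effect count) and `p` (upper chi-squared tail).
#' @export
lrt_compare <- function(full, null) {
  if (!inherits(full, "lmm_fit") || !inherits(null, "lmm_fit")) {
    hx_stop("lrt_compare expects two 'lmm_fit' objects")
  }
  if (full$method != "ML" || null$method != "ML") {
    hx_stop("both models must be fitted with ML; refit (REML likelihoods are not comparable across fixed structures)")
  }
  if (full$n != null$n || !isTRUE(all.equal(full$y, null$y, tolerance = 0))) {
    hx_stop("models were not fitted on identical rows; refit on a common complete-case set")
  }
  if (!all(colnames(null$X) %in% colnames(full$X)) ||
      ncol(full$X) <= ncol(null$X)) {
    hx_stop("null model is not nested in the full model")
  }
  df <- full$p - null$p
  statistic <- max(0, 2 * (full$logLik - null$logLik))
  list(statistic = statistic, df = df,
       p = stats::pchisq(statistic, df = df, lower.tail = FALSE))
}

#' Marginal and conditional R-squared from variance components
#'
#' The variance-explained decomposition for mixed models: marginal
#' \eqn{R^2 = \sigma^2_f / (\sigma^2_f + \sigma^2_\alpha +
#' \sigma^2_\epsilon)} uses the fixed effects only; conditional
#' \eqn{R^2 = (\sigma^2_f + \sigma^2_\alpha) / (\sigma^2_f +
#' \sigma^2_\alpha + \sigma^2_\epsilon)} adds the random intercept.
#' \eqn{\sigma^2_f} is the variance of the fixed-effect linear predictor.
#'
#' @param var_fixed,var_random,var_residual non-negative variance
#'   components (vectorized).
#' @return A data.frame with columns `marginal` and `conditional`, both in
#'   `[0, 1]` with `conditional >= marginal`.
#' @export
r2_components <- function(var_fixed, var_random, var_residual) {
  if (any(var_fixed < 0 | var_random < 0 | var_residual < 0, na.rm = TRUE)) {
    hx_stop("variance components must be non-negative")
  }
  total <- var_fixed + var_random + var_residual
  if (any(total <= 0)) {
    hx_stop("total variance is zero; R-squared is undefined (degenerate model)")
  }
  data.frame(marginal = var_fixed / total,
             conditional = (var_fixed + var_random) / total)
}

#' Marginal/conditional R-squared of a fitted mixed model
#'
#' @param fit a converged `lmm_fit`. The fixed-effect variance is the
#'   sample variance of the fixed-effect linear predictor over the
#'   analysis rows.
#' @return One-row data.frame with `marginal` and `conditional`.
#' @export
nakagawa_r2 <- function(fit) {
  if (!inherits(fit, "lmm_fit")) hx_stop("nakagawa_r2 expects an 'lmm_fit'")
  if (!isTRUE(fit$converged)) hx_stop_fit("fit did not converge; R-squared undefined")
  var_f <- stats::var(fit$fitted_fixed)
  r2_components(var_f, fit$sigma2_alpha, fit$sigma2_eps)
}

#' Simulation-based scaled residuals and uniformity diagnostics
#'
#' Simulates `n_sim` response vectors from the fitted marginal model (new
#' random intercepts and residuals each time -- the unconditional scheme)
#' and scores each observation by the proportion of simulated values below
#' the observed one, ties broken uniformly at random from the current
#' (seedable) RNG stream. For a correctly specified model the scaled
#' residuals are approximately Uniform(0, 1); departures are assessed by a
#' one-sample Kolmogorov-Smirnov test and by a Spearman trend of residuals
#' against rank-transformed fixed-effect predictions.
#'
#' Residuals of observations sharing a group are positively correlated
#' under this unconditional scheme, so the KS p-value is approximate; see
#' the methods vignette for the regime where the approximation is good.
#'
#' @param fit a converged `lmm_fit`.
#' @param n_sim number of simulated response vectors (>= 100; 1000 is the
#'   conventional default).
#' @param seed optional integer seed for reproducible diagnostics.
#' @return An object of class `"lmm_residuals"`: `residuals` in `[0, 1]`,
#'   `ks_statistic`, `ks_p`, `trend_rho`, `trend_p`, `n_sim`.
#' @export
simulated_residuals <- function(fit, n_sim = 1000L, seed = NULL) {
  if (!inherits(fit, "lmm_fit")) hx_stop("simulated_residuals expects an 'lmm_fit'")
  if (n_sim < 100L) hx_stop("n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  n <- fit$n
  k <- fit$n_groups
  gidx <- as.integer(fit$group)
  tau <- sqrt(fit$sigma2_alpha)
  sig <- sqrt(fit$sigma2_eps)
  U <- matrix(stats::rnorm(k * n_sim, sd = tau), k, n_sim)
  ysim <- fit$fitted_fixed +
    U[gidx, , drop = FALSE] +
    matrix(stats::rnorm(n * n_sim, sd = sig), n, n_sim)
  n_less <- rowSums(ysim < fit$y)
  n_eq <- rowSums(ysim == fit$y)
  res <- (n_less + stats::runif(n) * n_eq) / n_sim
  ks <- suppressWarnings(stats::ks.test(res, "punif"))
  tr <- suppressWarnings(
    stats::cor.test(res, rank(fit$fitted_fixed), method = "spearman"))
  structure(list(residuals = res,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                 trend_rho = unname(tr$estimate), trend_p = tr$p.value,
                 n_sim = as.integer(n_sim)),
            class = "lmm_residuals")
}

#' @export
print.lmm_residuals <- function(x, ...) {
  cat(sprintf("Simulation-based scaled residuals (%d simulations)\n", x$n_sim))
  cat(sprintf("  KS uniformity: D = %.4f, p = %.4g\n", x$ks_statistic, x$ks_p))
  cat(sprintf("  residual~rank(prediction) trend: rho = %.4f, p = %.4g\n",
              x$trend_rho, x$trend_p))
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up FDR adjustment,
#' preserving input order. NA entries are not allowed.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || !is.numeric(p) || any(p < 0 | p > 1)) {
    hx_stop("p-values must be numeric in [0, 1] with no NA")
  }
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, m * p))
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  adj[o] <- pmin(1, cummin(m / (m:1) * p[o]))
  adj
}
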