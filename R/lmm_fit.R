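#' Fit a Gaussian linear mixed model with one random intercept
#'
#' Fits \eqn{y = X\beta + u_{g} + \epsilon} with \eqn{u_g \sim N(0,
#' \sigma^2_\alpha)} per level of a grouping factor (cancer type in the
#' intended application) and \eqn{\epsilon \sim N(0, \sigma^2_\epsilon)},
#' by deterministic profiled (restricted) maximum likelihood over the
#' variance ratio \eqn{\lambda = \sigma^2_\alpha / \sigma^2_\epsilon}.
#'
#' For fixed \eqn{\lambda} the marginal covariance is
#' \eqn{\sigma^2_\epsilon (I + \lambda Z Z')}, block diagonal over groups,
#' so \eqn{\beta} and \eqn{\sigma^2_\epsilon} profile out in closed form via
#' the Woodbury identity; only a one-dimensional search over
#' \eqn{\log\lambda} remains. The search is a fixed coarse grid followed by
#' golden-section refinement and an explicit comparison against the
#' boundary \eqn{\lambda = 0} (which reduces to ordinary least squares).
#' The fit is therefore fully deterministic given the data.
#'
#' @param data data.frame containing all model columns.
#' @param response name of the numeric response column.
#' @param terms character vector of fixed-effect term labels (column names;
#'   interactions as `"a:b"`). May be empty for an intercept-only model.
#' @param grouping name of the grouping column (>= 2 levels required).
#' @param method `"ML"` (default; required for likelihood-ratio comparison
#'   of fixed effects) or `"REML"` for variance reporting. REML
#'   log-likelihood follows the lme4 convention (includes
#'   \eqn{\log|X'V_0^{-1}X|}).
#' @param log_lambda_interval search interval for \eqn{\log_e \lambda}.
#'
#' @return An object of class `"lmm_fit"`: coefficients, standard errors,
#'   `vcov`, variance components `sigma2_alpha` and `sigma2_eps`, the
#'   variance ratio `lambda`, `logLik`, the fixed-effect linear predictor
#'   `fitted_fixed`, group BLUPs `ranef`, and bookkeeping fields
#'   (`n`, `n_groups`, `p`, `boundary`, `method`, ...). Rows with missing
#'   values in any model column are dropped and counted in `n_dropped`.
#'
#' @examples
#' d <- data.frame(y = rnorm(60), x = rnorm(60),
#'                 g = rep(c("a", "b", "c"), each = 20))
#' fit <- fit_lmm(d, "y", "x", "g")
#' coef(fit)
#' @export
fit_lmm <- function(data, response, terms = character(), grouping,
                    method = c("ML", "REML"),
                    log_lambda_interval = c(-15, 15)) {
  method <- match.arg(method)
  if (!is.data.frame(data)) hx_stop("`data` must be a data.frame")
  used <- unique(c(response, all.vars(reformulate(c("1", terms))), grouping))
  stopifnot_columns(data, used, where = "model data")

  cc <- stats::complete.cases(data[used])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]

  g <- factor(data[[grouping]])
  g <- droplevels(g)
  if (nlevels(g) < 2L) {
    hx_stop(sprintf(
      "grouping factor '%s' has %d level(s) after dropping incomplete rows; >= 2 required (random-intercept variance is unidentifiable)",
      grouping, nlevels(g)))
  }
  y <- data[[response]]
  if (!is.numeric(y)) hx_stop(sprintf("response '%s' must be numeric", response))
  form <- reformulate(if (length(terms)) terms else "1", response = NULL)
  X <- stats::model.matrix(form, data = data)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) hx_stop("too few complete rows for the fixed-effect design")
  qx <- qr(X)
  if (qx$rank < p) {
    hx_stop(sprintf(
      "fixed-effect design is rank deficient (rank %d < %d columns); check for collinear or constant terms",
      qx$rank, p))
  }

  # sufficient statistics; per-lambda cost is O(k p^2)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  gi <- split(seq_len(n), g)
  ng <- lengths(gi)
  k <- length(gi)
  S <- t(vapply(gi, function(i) colSums(X[i, , drop = FALSE]), numeric(p)))
  dim(S) <- c(k, p)
  tg <- vapply(gi, function(i) sum(y[i]), numeric(1))

  solve_at <- function(lambda) {
    cg <- lambda / (1 + ng * lambda)
    A <- XtX - crossprod(S, S * cg)
    b <- Xty - crossprod(S, cg * tg)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
    rss_v <- max(yty - sum(cg * tg^2) - sum(b * beta), 1e-300)
    logdet_V0 <- sum(log1p(ng * lambda))
    logdet_A <- 2 * sum(log(diag(R)))
    list(beta = beta, rss_v = rss_v, logdet_V0 = logdet_V0,
         logdet_A = logdet_A, R = R, cg = cg)
  }

  prof_loglik <- function(lambda) {
    s <- solve_at(lambda)
    if (is.null(s)) return(-Inf)
    if (method == "ML") {
      sigma2 <- s$rss_v / n
      -0.5 * (n * (log(2 * pi * sigma2) + 1) + s$logdet_V0)
    } else {
      sigma2 <- s$rss_v / (n - p)
      # lme4 REMLcrit convention: includes log|X' V0^-1 X|
      -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + s$logdet_V0 + s$logdet_A)
    }
  }

  # deterministic search: coarse grid, then optimize() in the best bracket,
  # then explicit boundary comparison at lambda = 0
  grid <- seq(log_lambda_interval[1], log_lambda_interval[2], length.out = 41L)
  ll_grid <- vapply(grid, function(u) prof_loglik(exp(u)), numeric(1))
  i_best <- which.max(ll_grid)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(length(grid), i_best + 1L)]
  opt <- stats::optimize(function(u) prof_loglik(exp(u)),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  ll0 <- prof_loglik(0)
  boundary <- ll0 >= opt$objective - 1e-8
  lambda <- if (boundary) 0 else exp(opt$maximum)
  loglik <- if (boundary) ll0 else opt$objective
  if (!is.finite(loglik)) {
    hx_stop_fit("profiled likelihood is non-finite at the optimum; model could not be fitted")
  }

  s <- solve_at(lambda)
  sigma2_eps <- s$rss_v / (if (method == "ML") n else n - p)
  sigma2_alpha <- lambda * sigma2_eps
  Ainv <- chol2inv(s$R)
  vcov_beta <- sigma2_eps * Ainv
  se <- sqrt(diag(vcov_beta))
  beta <- drop(s$beta)
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  fitted_fixed <- drop(X %*% beta)
  # BLUPs: shrunken group means of marginal residuals
  resid_marg <- y - fitted_fixed
  shr <- ng * lambda / (1 + ng * lambda)
  ranef <- shr * vapply(gi, function(i) mean(resid_marg[i]), numeric(1))

  structure(list(
    coefficients = beta, se = se, vcov = vcov_beta,
    sigma2_alpha = sigma2_alpha, sigma2_eps = sigma2_eps,
    lambda = lambda, logLik = loglik, method = method,
    converged = TRUE, boundary = boundary,
    n = n, n_groups = k, p = p, n_dropped = n_dropped,
    fitted_fixed = fitted_fixed, ranef = ranef,
    y = y, group = g, X = X,
    response = response, terms = terms, grouping = grouping
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), random intercept on '%s'\n",
              x$method, x$grouping))
  cat(sprintf("  n = %d, groups = %d, logLik = %.4f%s\n", x$n, x$n_groups,
              x$logLik, if (x$boundary) " (boundary: sigma2_alpha = 0)" else ""))
  cat(sprintf("  sigma2_alpha = %.4g, sigma2_eps = %.4g\n",
              x$sigma2_alpha, x$sigma2_eps))
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$coefficients

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + 2L, class = "logLik")
}

#' @export
vcov.lmm_fit <- function(object, ...) object$vcov

#' Wald confidence intervals for fixed effects
#'
#' @param object an `lmm_fit`.
#' @param parm coefficient names (default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.lmm_fit <- function(object, parm = NULL, level = 0.95, ...) {
  parm <- parm %||% names(object$coefficients)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(lower = est - z * se, upper = est + z * se)
  rownames(out) <- parm
  out
}
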