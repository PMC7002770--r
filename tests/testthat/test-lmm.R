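test_that("fit_lmm agrees with lme4 on ML and REML fits", {
  skip_if_not_installed("lme4")
  d <- make_lmm_data(n_groups = 10, per_group = 30, tau = 1.2, seed = 42)
  for (reml in c(FALSE, TRUE)) {
    mine <- fit_lmm(d, "y", c("x", "purity"), "g",
                    method = if (reml) "REML" else "ML")
    ref <- lme4::lmer(y ~ x + purity + (1 | g), d, REML = reml)
    expect_equal(mine$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
    expect_equal(unname(mine$coefficients), unname(lme4::fixef(ref)),
                 tolerance = 1e-6)
    expect_equal(mine$sigma2_alpha, as.numeric(lme4::VarCorr(ref)$g),
                 tolerance = 1e-5)
    expect_equal(mine$sigma2_eps, stats::sigma(ref)^2, tolerance = 1e-5)
    expect_equal(unname(mine$se),
                 unname(summary(ref)$coefficients[, 2]), tolerance = 1e-5)
  }
})

test_that("boundary fits reduce to OLS and are flagged", {
  set.seed(1)
  n <- 200
  d <- data.frame(x = rnorm(n), g = factor(rep(1:8, each = 25)))
  d$y <- 2 + 0.7 * d$x + rnorm(n)
  # truly unstructured data often lands exactly on the boundary
  f <- fit_lmm(d, "y", "x", "g")
  X <- cbind(1, d$x)
  if (f$boundary) {
    expect_equal(unname(f$coefficients), oracle_ols(X, d$y), tolerance = 1e-9)
    expect_equal(f$sigma2_alpha, 0)
  } else {
    succeed("interior optimum; boundary exercised in acceptance suite")
  }
})

test_that("fit_lmm validates its preconditions", {
  d <- make_lmm_data(seed = 2)
  d1 <- d[d$g == "1", ]
  expect_error(fit_lmm(d1, "y", "x", "g"), class = "hx_error")
  d$x2 <- d$x
  expect_error(fit_lmm(d, "y", c("x", "x2"), "g"), "rank deficient",
               class = "hx_error")
  expect_error(fit_lmm(d, "y", "nope", "g"), class = "hx_error")
})

test_that("fixed-effect estimates are invariant to group relabeling", {
  d <- make_lmm_data(seed = 3)
  f1 <- fit_lmm(d, "y", c("x", "purity"), "g")
  d2 <- d
  d2$g <- factor(paste0("z", rev(as.integer(d2$g))))
  f2 <- fit_lmm(d2, "y", c("x", "purity"), "g")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("lrt_compare: nesting, ML requirement, identical rows, p at 0", {
  d <- make_lmm_data(seed = 4)
  full <- fit_lmm(d, "y", c("x", "purity"), "g")
  null <- fit_lmm(d, "y", "purity", "g")
  res <- lrt_compare(full, null)
  expect_equal(res$df, 1)
  expect_gte(res$statistic, 0)
  expect_true(res$p >= 0 && res$p <= 1)
  # statistic 0 at df 1 -> p = 1 (chi-squared survival at 0)
  fake_null <- full
  fake_null$p <- full$p - 1L
  fake_null$X <- full$X[, -2, drop = FALSE]
  expect_equal(lrt_compare(full, fake_null)$p, 1)

  reml <- fit_lmm(d, "y", c("x", "purity"), "g", method = "REML")
  expect_error(lrt_compare(reml, null), "ML", class = "hx_error")
  expect_error(lrt_compare(null, full), class = "hx_error")
  d2 <- d[-1, ]
  null2 <- fit_lmm(d2, "y", "purity", "g")
  expect_error(lrt_compare(full, null2), class = "hx_error")
})

test_that("strong planted effects give vanishing LRT p", {
  d <- make_lmm_data(n_groups = 10, per_group = 50, beta = 5, sigma = 1, seed = 5)
  full <- fit_lmm(d, "y", c("x", "purity"), "g")
  null <- fit_lmm(d, "y", "purity", "g")
  expect_lt(lrt_compare(full, null)$p, 1e-6)
})

test_that("r2 closed forms and identities", {
  r2 <- r2_components(2, 1, 1)
  expect_equal(r2$marginal, 0.5)
  expect_equal(r2$conditional, 0.75)
  expect_equal(r2_components(0, 1, 1)$marginal, 0)
  z <- r2_components(3, 0, 2)
  expect_equal(z$marginal, z$conditional)
  expect_error(r2_components(0, 0, 0), class = "hx_error")
  expect_error(r2_components(-1, 1, 1), class = "hx_error")
})

test_that("nakagawa_r2 uses the fixed-predictor variance", {
  d <- make_lmm_data(seed = 6)
  f <- fit_lmm(d, "y", c("x", "purity"), "g")
  r2 <- nakagawa_r2(f)
  vf <- var(f$fitted_fixed)
  expect_equal(r2$marginal, vf / (vf + f$sigma2_alpha + f$sigma2_eps))
  expect_gte(r2$conditional, r2$marginal)
  expect_true(r2$conditional <= 1 && r2$marginal >= 0)
})

test_that("scaled residuals live in [0,1], are permutation-equivariant, detect extremes", {
  d <- make_lmm_data(seed = 7)
  f <- fit_lmm(d, "y", c("x", "purity"), "g")
  r <- simulated_residuals(f, n_sim = 200, seed = 1)
  expect_true(all(r$residuals >= 0 & r$residuals <= 1))
  expect_length(r$residuals, f$n)

  # observation far below anything the model can simulate
  d2 <- d
  d2$y[1] <- min(d$y) - 50
  f2 <- fit_lmm(d2, "y", c("x", "purity"), "g")
  r2 <- simulated_residuals(f2, n_sim = 200, seed = 1)
  expect_lt(r2$residuals[1], 1 / 200)

  # permuting observations permutes residuals (same seed stream)
  perm <- sample(nrow(d))
  fp <- fit_lmm(d[perm, ], "y", c("x", "purity"), "g")
  rp <- simulated_residuals(fp, n_sim = 500, seed = 9)
  ro <- simulated_residuals(f, n_sim = 500, seed = 9)
  expect_equal(cor(rank(ro$residuals[perm]), rank(rp$residuals)),
               1, tolerance = 0.1)
  expect_error(simulated_residuals(f, n_sim = 50), class = "hx_error")
})

test_that("adjust_pvalues matches the definition and validates input", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(rep(0.3, 4), "bonferroni"), rep(1, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh_fdr"),
               rep(0.04, 4))
  set.seed(8)
  for (i in 1:50) {
    p <- round(runif(sample(1:6, 1)), 2)
    expect_equal(adjust_pvalues(p, "bh_fdr"), oracle_bh(p))
    expect_equal(adjust_pvalues(p, "bonferroni"), oracle_bonferroni(p))
    # cross-check against stats::p.adjust as a second, independent route
    expect_equal(adjust_pvalues(p, "bh_fdr"), p.adjust(p, "BH"))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "hx_error")
  expect_error(adjust_pvalues(c(0.5, NA)), class = "hx_error")
})
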