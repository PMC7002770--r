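make_analysis_table <- function(cfg) {
  b <- generate_cohort(cfg)
  sc <- compute_hypoxia_scores(b$expression, b$signatures[[1]],
                               names(b$signatures)[1])
  st <- if (nrow(b$driver_events)) {
    summarize_driver_status(b$driver_events, samples = b$covariates$sample)
  } else NULL
  tab <- quietly(assemble_feature_table(b$covariates, sc, density = b$features,
                                        status = st,
                                        subclonality = b$subclonality))
  cls <- quietly(dichotomize_scores(setNames(tab$hypoxia_score, tab$sample)))
  tab$hypoxia_class <- as.integer(cls == "hypoxic")
  list(tab = tab, bundle = b)
}

test_that("min-samples filter keeps exactly the groups at or above k", {
  d <- data.frame(cancer_type = rep(c("A", "B", "C"), c(14, 15, 40)), x = 1)
  f <- quietly(apply_min_samples_filter(d, "cancer_type", 15))
  expect_setequal(unique(f$cancer_type), c("B", "C"))
  expect_identical(nrow(f), 55L)
  expect_identical(quietly(apply_min_samples_filter(d, "cancer_type", 10)), d)
  expect_error(apply_min_samples_filter(d, "cancer_type", 100),
               class = "hx_error")
  # random sizes against a direct census
  set.seed(13)
  d2 <- data.frame(cancer_type = sample(LETTERS[1:8], 300, replace = TRUE))
  f2 <- quietly(apply_min_samples_filter(d2, "cancer_type", 35))
  census <- table(d2$cancer_type)
  expect_setequal(unique(f2$cancer_type), names(census)[census >= 35])
})

test_that("a planted feature dominates a null scan", {
  cfg <- sim_config(n_cancer_types = 8, samples_per_type = 40,
                    signatures = c(buffa = 25), n_background_genes = 10,
                    expression_effect = 2,
                    feature_slopes = c(total_deletions = 2), seed = 41)
  x <- make_analysis_table(cfg)
  feats <- names(cfg$feature_slopes)
  sc <- quietly(run_association_scan(x$tab, feats))
  expect_identical(attr(sc, "correction"), "bonferroni")  # 15 tests < 20
  expect_identical(sc$feature[1], "total_deletions")
  expect_lt(sc$p_adj[1], 0.05)
  expect_true(all(sc$p_adj >= sc$p, na.rm = TRUE))
  expect_true(all(sc$r2_conditional >= sc$r2_marginal, na.rm = TRUE))
  expect_gt(sc$direction[1], 0)
})

test_that("scan results are invariant to feature ordering", {
  cfg <- sim_config(n_cancer_types = 5, samples_per_type = 30,
                    signatures = c(buffa = 15), n_background_genes = 5,
                    seed = 42)
  x <- make_analysis_table(cfg)
  feats <- c("pga", "total_deletions", "snvs_per_mb", "wgd_score")
  s1 <- quietly(run_association_scan(x$tab, feats))
  s2 <- quietly(run_association_scan(x$tab, rev(feats)))
  expect_equal(as.data.frame(s1)[order(s1$feature), ],
               as.data.frame(s2)[order(s2$feature), ],
               ignore_attr = TRUE)
})

test_that("empty feature lists, sparse binaries and fit failures are handled", {
  cfg <- small_config(seed = 43)
  x <- make_analysis_table(cfg)
  expect_identical(nrow(quietly(run_association_scan(x$tab, character(0)))), 0L)
  # binary feature below the mutated-count floor is skipped
  x$tab$rare <- 0L
  x$tab$rare[1:2] <- 1L
  sc <- quietly(run_association_scan(x$tab, c("pga", "rare")))
  expect_true(sc$skipped[sc$feature == "rare"])
  expect_false(sc$skipped[sc$feature == "pga"])
  # constant feature cannot be fitted; scan continues with a flagged record
  x$tab$broken <- 1
  sc2 <- quietly(run_association_scan(x$tab, c("pga", "broken")))
  expect_true(sc2$failed[sc2$feature == "broken"])
  expect_false(sc2$failed[sc2$feature == "pga"])
})

test_that("correction switches to BH at 20 or more tests", {
  cfg <- small_config(seed = 44)
  x <- make_analysis_table(cfg)
  set.seed(1)
  for (i in 1:20) x$tab[[paste0("noise", i)]] <- rnorm(nrow(x$tab))
  feats <- c(paste0("noise", 1:20))
  sc <- quietly(run_association_scan(x$tab, feats))
  expect_identical(attr(sc, "correction"), "bh_fdr")
  sc2 <- quietly(run_association_scan(x$tab, feats[1:19]))
  expect_identical(attr(sc2, "correction"), "bonferroni")
})

test_that("independence test: collinearity errors, planted signal detected", {
  cfg <- sim_config(n_cancer_types = 6, samples_per_type = 40,
                    signatures = c(buffa = 25), n_background_genes = 5,
                    expression_effect = 2,
                    feature_slopes = c(total_deletions = 1.5,
                                       snvs_per_mb = 1.5), seed = 45)
  x <- make_analysis_table(cfg)
  expect_error(run_independence_test(x$tab, "pga", "pga"), class = "hx_error")
  # duplicated column: perfectly collinear -> rank error
  x$tab$pga_copy <- x$tab$pga
  expect_error(run_independence_test(x$tab, "pga_copy", "pga"),
               class = "hx_error")
  # feature with its own planted signal stays significant given the adjuster
  res <- run_independence_test(x$tab, "snvs_per_mb", "total_deletions")
  expect_lt(res$p, 0.01)
  expect_identical(res$df, 1L)
})

test_that("interaction test validates factors and degenerate responses", {
  cfg <- small_config(seed = 46)
  x <- make_analysis_table(cfg)
  expect_true(all(c("hypoxia_class", "driver_PTEN", "polyclonal") %in%
                    names(x$tab)))
  res <- run_interaction_test(x$tab, "hypoxia_class", "driver_PTEN")
  expect_identical(res$df, 1L)
  expect_true(res$p >= 0 && res$p <= 1)
  x$tab$const <- 1L
  expect_error(run_interaction_test(x$tab, "const", "driver_PTEN"),
               class = "hx_error")
  x$tab$polyclonal <- 0L
  expect_error(run_interaction_test(x$tab, "hypoxia_class", "driver_PTEN"),
               class = "hx_error")
})

test_that("logistic engine agrees qualitatively with the linear one", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_cancer_types = 6, samples_per_type = 100,
                    signatures = c(buffa = 25), n_background_genes = 5,
                    expression_effect = 2,
                    clonality_interaction_effect = 2.5, seed = 47)
  x <- make_analysis_table(cfg)
  lin <- run_interaction_test(x$tab, "hypoxia_class", "driver_PTEN")
  logi <- suppressMessages(suppressWarnings(
    run_interaction_test(x$tab, "hypoxia_class", "driver_PTEN",
                         engine = "logistic")))
  expect_lt(lin$p, 0.05)
  expect_lt(logi$p, 0.05)
})

test_that("stratified mRNA summary orders strata as constructed", {
  set.seed(48)
  n <- 400
  d <- data.frame(
    cancer_type = rep(c("A", "B", "C", "D"), each = 100),
    purity = runif(n, 0.3, 1), age = sample(30:80, n, TRUE),
    sex = rbinom(n, 1, 0.5),
    status = rbinom(n, 1, 0.5), class = rbinom(n, 1, 0.5))
  # abundance decreasing in both factors: doubly altered stratum lowest
  d$abund <- 10 - 2 * d$status - 3 * d$class + rnorm(n, 0, 0.5)
  res <- stratified_mrna_summary(d, "abund", "status", "class")
  expect_true(res$complete)
  med <- res$strata$median
  lab <- paste(res$strata$status, res$strata$class)
  expect_identical(lab[which.min(med)], "mutated hypoxic")
  expect_lt(res$p_status, 1e-6)
  expect_lt(res$p_class, 1e-6)
  # empty stratum flagged, no p
  d2 <- d[!(d$status == 1 & d$class == 1), ]
  res2 <- quietly(stratified_mrna_summary(d2, "abund", "status", "class"))
  expect_false(res2$complete)
  expect_true(is.na(res2$p_status))
})
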