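rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_samples, rate = 0.2), n_genes, n_samples)
  dimnames(m) <- list(sprintf("G%02d", seq_len(n_genes)),
                      sprintf("S%02d", seq_len(n_samples)))
  m
}

test_that("median-vote scores follow the +1/-1 rule", {
  m <- rbind(HIF1A = c(1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  sc <- compute_hypoxia_scores(m, "HIF1A")
  expect_identical(sc$score, c(-1L, -1L, 1L, 1L))
  expect_identical(sc$n_genes_used, rep(1L, 4))

  # two genes with identical values: additivity
  m2 <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4))
  colnames(m2) <- paste0("s", 1:4)
  expect_identical(compute_hypoxia_scores(m2, c("A", "B"))$score,
                   c(-2L, -2L, 2L, 2L))

  # ties at the median vote -1
  m3 <- rbind(A = c(5, 5, 5, 9))
  colnames(m3) <- paste0("s", 1:4)
  expect_identical(compute_hypoxia_scores(m3, "A")$score, c(-1L, -1L, -1L, 1L))
})

test_that("scores equal the brute-force rank oracle on random matrices", {
  for (seed in 1:25) {
    m <- rand_expr(3, 6, seed)
    sc <- compute_hypoxia_scores(m, rownames(m))
    expect_identical(sc$score, as.integer(oracle_scores(m)))
  }
})

test_that("signed genes flip their votes", {
  m <- rand_expr(4, 8, 99)
  signs <- c(G01 = 1, G02 = -1, G03 = 1, G04 = -1)
  sc <- compute_hypoxia_scores(m, signs)
  expect_identical(sc$score,
                   as.integer(oracle_scores(m, names(signs), unname(signs))))
})

test_that("score invariants: parity, bound, monotone invariance, zero-sum", {
  for (seed in c(7, 8)) {
    m <- rand_expr(5, 10, seed)
    sc <- compute_hypoxia_scores(m, rownames(m))
    expect_true(all(abs(sc$score) <= sc$n_genes_used))
    expect_true(all((sc$score - sc$n_genes_used) %% 2 == 0))
    # even n, continuous values: each gene's votes cancel
    expect_identical(sum(sc$score), 0L)
    # strictly increasing transform of one gene changes nothing
    m2 <- m
    m2["G03", ] <- exp(m2["G03", ] / 3)
    expect_identical(compute_hypoxia_scores(m2, rownames(m2))$score, sc$score)
  }
})

test_that("missing signature genes are skipped; zero overlap errors", {
  m <- rand_expr(3, 6, 1)
  expect_message(sc <- compute_hypoxia_scores(m, c("G01", "G02", "NOPE")),
                 "absent")
  expect_identical(unique(sc$n_genes_used), 2L)
  expect_error(compute_hypoxia_scores(m, c("X", "Y")), class = "hx_error")
  expect_error(compute_hypoxia_scores(m[, 1, drop = FALSE], "G01"),
               class = "hx_error")
})

test_that("scale_median_scores is the affine [-1, 1] map", {
  expect_equal(scale_median_scores(c(A = 0, B = 5, C = 10)),
               c(A = -1, B = 0, C = 1))
  expect_equal(scale_median_scores(c(A = 3, B = 7)), c(A = -1, B = 1))
  expect_equal(scale_median_scores(c(A = 1, B = 2, C = 4)),
               c(A = -1, B = -1 / 3, C = 1))
  expect_error(scale_median_scores(c(A = 2, B = 2)), class = "hx_error")
  expect_error(scale_median_scores(c(A = 2)), class = "hx_error")
})

test_that("within-type variance fraction matches direct sums of squares", {
  expect_equal(within_type_variance_fraction(c(0, 2, 10, 12),
                                             c("a", "a", "b", "b")), 4 / 104)
  # equal group means, nonzero spread -> all variance within
  expect_equal(within_type_variance_fraction(c(-1, 1, -2, 2),
                                             c("a", "a", "b", "b")), 1)
  # internally constant groups with distinct means -> none within
  expect_equal(within_type_variance_fraction(c(3, 3, 9, 9),
                                             c("a", "a", "b", "b")), 0)
  expect_error(within_type_variance_fraction(c(1, 1, 1, 1),
                                             c("a", "a", "b", "b")),
               class = "hx_error")
})

test_that("summarize_scores reports median, type-7 IQR, elevated fraction", {
  s <- summarize_scores(c(-2, 0, 2, 4), rep("A", 4))
  expect_equal(s$median, 1)
  expect_equal(s$fraction_elevated, 0.5)
  expect_equal(summarize_scores(c(1, 2, 3, 4, 5), rep("A", 5))$iqr, 2)
  expect_equal(summarize_scores(rep(3, 6), rep("A", 6))$iqr, 0)
  # sorted by decreasing median
  s2 <- summarize_scores(c(0, 0, 5, 5), c("lo", "lo", "hi", "hi"))
  expect_identical(s2$cancer_type, c("hi", "lo"))
})

test_that("dichotomize_scores splits strictly above the median", {
  cls <- quietly(dichotomize_scores(c(a = 1, b = 2, c = 3, d = 4)))
  expect_identical(as.character(cls), c("normoxic", "normoxic", "hypoxic", "hypoxic"))
  expect_warning(quietly(x <- dichotomize_scores(c(5, 5, 5))), "identical")
  expect_true(all(x == "normoxic"))
  # class sizes differ by at most the number of median ties
  set.seed(3)
  v <- sample(-20:20, 1000, replace = TRUE)
  cls <- quietly(dichotomize_scores(v))
  ties <- sum(v == median(v))
  expect_lte(abs(sum(cls == "hypoxic") - sum(cls == "normoxic")), ties)
})

test_that("tumour_vs_normal_test: exact two-sided rank-sum and skipping", {
  # all 3 tumour values above all 3 normals: 2 * 1/choose(6,3) = 0.1
  res <- tumour_vs_normal_test(data.frame(tissue = "t", score = c(7, 8, 9)),
                               data.frame(tissue = "t", score = c(1, 2, 3)),
                               min_normals = 3)
  expect_equal(res$p, 0.1)
  # 14 normals under the default threshold: skipped, no p
  res2 <- quietly(tumour_vs_normal_test(
    data.frame(tissue = "t", score = rnorm(20)),
    data.frame(tissue = "t", score = rnorm(14))))
  expect_true(res2$skipped)
  expect_true(is.na(res2$p))
})

test_that("null tumour/normal p-values are approximately uniform", {
  set.seed(42)
  ps <- replicate(200, {
    pooled <- rnorm(60)
    tumour_vs_normal_test(pooled[1:30], pooled[31:60])$p
  })
  # p-values are mildly discrete; suppress the KS ties warning
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
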