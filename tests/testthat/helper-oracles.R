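# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: medians via explicit sorting, step-up
# adjustment via a literal double loop, GLS via lme4, OLS via the normal
# equations.

# per-gene rank-vote scorer: loops, sort-based median, no shared code
oracle_scores <- function(expr, genes = rownames(expr), signs = NULL) {
  if (is.null(signs)) signs <- rep(1, length(genes))
  n <- ncol(expr)
  total <- numeric(n)
  for (j in seq_along(genes)) {
    v <- expr[genes[j], ]
    s <- sort(v)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    for (i in seq_len(n)) {
      total[i] <- total[i] + signs[j] * (if (v[i] > med) 1 else -1)
    }
  }
  total
}

# literal Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} min(1, m p_(j)/j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj_sorted[i] <- best
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

oracle_bonferroni <- function(p) pmin(1, length(p) * p)

# OLS fixed effects from the normal equations
oracle_ols <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# small simulated LMM dataset
make_lmm_data <- function(n_groups = 8, per_group = 25, beta = 0.5,
                          tau = 1, sigma = 1, seed = 1) {
  set.seed(seed)
  n <- n_groups * per_group
  g <- factor(rep(seq_len(n_groups), each = per_group))
  x <- rnorm(n)
  purity <- runif(n, 0.3, 1)
  u <- rnorm(n_groups, 0, tau)
  y <- 1 + beta * x - 0.4 * purity + u[g] + rnorm(n, 0, sigma)
  data.frame(y = y, x = x, purity = purity, g = g)
}

# quiet wrapper: hypoxscan logs exclusions via message()
quietly <- function(expr) suppressMessages(expr)

# tiny cohort config for fast tests
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cancer_types = 4L, samples_per_type = 20L,
                   signatures = c(buffa = 15L), n_background_genes = 20L,
                   seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# minimal analysis frame for interaction/calibration runs: score-based
# hypoxia class, one driver indicator, polyclonality, covariates
light_analysis_frame <- function(bundle, driver_gene = "PTEN") {
  sc <- compute_hypoxia_scores(bundle$expression, bundle$signatures[[1]],
                               names(bundle$signatures)[1])
  d <- bundle$covariates
  d$hypoxia_score <- sc$score[match(d$sample, sc$sample)]
  cls <- suppressMessages(dichotomize_scores(d$hypoxia_score))
  d$hypoxia_class <- as.integer(cls == "hypoxic")
  ev <- bundle$driver_events
  d$driver <- as.integer(d$sample %in% ev$sample[ev$gene == driver_gene])
  d$polyclonal <- as.integer(
    bundle$subclonality$n_clusters[match(d$sample, bundle$subclonality$sample)] > 1)
  d
}
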