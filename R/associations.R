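#' Drop cancer types with too few samples
#'
#' Removes every row belonging to a group with fewer than `k` samples
#' (the standard cohort filter applied before each association scan);
#' removal counts are logged.
#'
#' @param data data.frame.
#' @param grouping grouping column name (default `"cancer_type"`).
#' @param k minimum samples per retained group (default 15).
#' @return filtered data.frame.
#' @export
apply_min_samples_filter <- function(data, grouping = "cancer_type", k = 15L) {
  stopifnot_columns(data, grouping, "data")
  if (k < 1L) hx_stop("min samples per group must be >= 1")
  sizes <- table(data[[grouping]])
  keep <- names(sizes)[sizes >= k]
  if (length(keep) == 0L) {
    hx_stop(sprintf("no %s has >= %d samples; cohort is empty after filtering",
                    grouping, k))
  }
  dropped <- sizes[sizes < k]
  if (length(dropped) > 0L) {
    hx_log(sprintf("min-samples filter (k=%d): dropped %d group(s), %d sample(s): %s",
                   k, length(dropped), sum(dropped),
                   paste(sprintf("%s(%d)", names(dropped), dropped), collapse = ", ")))
  }
  data[data[[grouping]] %in% keep, , drop = FALSE]
}

fit_feature_pair <- function(data, response, feature_terms, adjusters, grouping) {
  cols <- unique(c(response, unlist(lapply(c(feature_terms, adjusters),
                                           function(t) all.vars(reformulate(t)))),
                   grouping))
  cc <- stats::complete.cases(data[cols])
  d <- data[cc, cols, drop = FALSE]
  full <- fit_lmm(d, response, c(feature_terms, adjusters), grouping, method = "ML")
  null <- fit_lmm(d, response, adjusters, grouping, method = "ML")
  list(full = full, null = null, lrt = lrt_compare(full, null), n = nrow(d))
}

#' Full-versus-null mixed-model association scan
#'
#' For each feature, fits `response ~ feature + adjusters + (1|grouping)`
#' and the matching null without the feature (both by ML on the same
#' complete-case rows), records the likelihood-ratio p-value, the full
#' model's marginal/conditional R-squared and the sign of the feature
#' coefficient, then applies the multiple-testing rule: Bonferroni when
#' the scan ran fewer than 20 tests, Benjamini-Hochberg FDR otherwise
#' (each scan is its own correction family). Binary features mutated in
#' fewer than `min_mutated` retained samples are skipped with a log
#' entry; per-feature fit failures flag the record and the scan
#' continues.
#'
#' @param data analysis table (already filtered, see
#'   [apply_min_samples_filter()]).
#' @param features character vector of feature column names.
#' @param response response column (default `"hypoxia_score"`).
#' @param adjusters fixed adjusters (default purity, age, sex).
#' @param grouping random-intercept grouping column.
#' @param correction `"auto"` (the < 20-test rule), `"bonferroni"` or
#'   `"bh_fdr"`.
#' @param min_mutated minimum mutated samples for 0/1 features.
#' @return data.frame of class `"assoc_scan"`, one row per feature,
#'   sorted by adjusted p (stable ties): `feature`, `p`, `p_adj`,
#'   `r2_marginal`, `r2_conditional`, `direction`, `n`, `boundary`,
#'   `failed`, `skipped`; attributes `correction` and `n_tests`.
#' @export
run_association_scan <- function(data, features,
                                 response = "hypoxia_score",
                                 adjusters = c("purity", "age", "sex"),
                                 grouping = "cancer_type",
                                 correction = c("auto", "bonferroni", "bh_fdr"),
                                 min_mutated = 5L) {
  correction <- match.arg(correction)
  empty <- data.frame(feature = character(0), p = numeric(0), p_adj = numeric(0),
                      r2_marginal = numeric(0), r2_conditional = numeric(0),
                      direction = numeric(0), n = integer(0),
                      boundary = logical(0), failed = logical(0),
                      skipped = logical(0))
  if (length(features) == 0L) {
    return(structure(empty, class = c("assoc_scan", "data.frame"),
                     correction = NA_character_, n_tests = 0L))
  }
  stopifnot_columns(data, c(features, response, adjusters, grouping), "scan data")
  rows <- lapply(features, function(f) {
    v <- data[[f]]
    if (all(v %in% c(0L, 1L, NA)) && sum(v == 1L, na.rm = TRUE) < min_mutated) {
      hx_log(sprintf("feature '%s' skipped: only %d mutated sample(s) < %d",
                     f, sum(v == 1L, na.rm = TRUE), min_mutated))
      return(data.frame(feature = f, p = NA_real_, p_adj = NA_real_,
                        r2_marginal = NA_real_, r2_conditional = NA_real_,
                        direction = NA_real_, n = sum(!is.na(v)),
                        boundary = NA, failed = FALSE, skipped = TRUE))
    }
    res <- tryCatch(fit_feature_pair(data, response, f, adjusters, grouping),
                    hx_error = function(e) e)
    if (inherits(res, "hx_error")) {
      hx_log(sprintf("feature '%s' fit failed: %s", f, conditionMessage(res)))
      return(data.frame(feature = f, p = NA_real_, p_adj = NA_real_,
                        r2_marginal = NA_real_, r2_conditional = NA_real_,
                        direction = NA_real_, n = NA_integer_,
                        boundary = NA, failed = TRUE, skipped = FALSE))
    }
    r2 <- nakagawa_r2(res$full)
    coef_name <- setdiff(colnames(res$full$X), colnames(res$null$X))[1L]
    data.frame(feature = f, p = res$lrt$p, p_adj = NA_real_,
               r2_marginal = r2$marginal, r2_conditional = r2$conditional,
               direction = sign(res$full$coefficients[[coef_name]]),
               n = res$n, boundary = res$full$boundary,
               failed = FALSE, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  n_tests <- sum(tested)
  if (correction == "auto") {
    correction <- if (n_tests < 20L) "bonferroni" else "bh_fdr"
  }
  if (n_tests > 0L) out$p_adj[tested] <- adjust_pvalues(out$p[tested], correction)
  ord <- order(out$p_adj, out$p, seq_len(nrow(out)), na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("assoc_scan", "data.frame"),
            correction = correction, n_tests = n_tests)
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("Association scan: %d feature(s), %d tested, correction = %s\n",
              nrow(x), attr(x, "n_tests"), attr(x, "correction")))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Independence test with an extra adjuster
#'
#' Tests whether `feature` remains associated with the response after
#' adjusting for one or more additional covariates (present in both the
#' full and the null model), e.g. SNVs per megabase adjusted for total
#' deletions.
#'
#' @inheritParams run_association_scan
#' @param feature feature column of interest.
#' @param adjust_for_extra extra adjuster column(s), distinct from
#'   `feature`.
#' @return list with `p`, `statistic`, `df`, `n`, and both fits.
#' @export
run_independence_test <- function(data, feature, adjust_for_extra,
                                  response = "hypoxia_score",
                                  adjusters = c("purity", "age", "sex"),
                                  grouping = "cancer_type") {
  if (feature %in% adjust_for_extra) {
    hx_stop("feature and extra adjuster must be distinct columns")
  }
  res <- fit_feature_pair(data, response, feature,
                          c(adjust_for_extra, adjusters), grouping)
  list(p = res$lrt$p, statistic = res$lrt$statistic, df = res$lrt$df,
       n = res$n, full = res$full, null = res$null)
}

#' Hypoxia-by-driver interaction test on clonality
#'
#' Compares an interaction model
#' `clonality ~ A * B + adjusters + (1|grouping)` with the additive model
#' `clonality ~ A + B + adjusters + (1|grouping)` by a df = 1
#' likelihood-ratio test. The default engine follows the linear-probability
#' convention (the 0/1 response fitted with the Gaussian mixed model); a
#' logistic mixed model is available via `engine = "logistic"` (requires
#' lme4).
#'
#' @param data analysis table.
#' @param factor_a,factor_b binary factor columns (0/1 or two-level),
#'   both levels present; typically the dichotomized hypoxia class and a
#'   driver gene status.
#' @param response binary 0/1 response column (default `"polyclonal"`).
#' @param adjusters,grouping as in [run_association_scan()].
#' @param engine `"linear"` (default) or `"logistic"`.
#' @return list with `p`, `statistic`, `df`, `n`, `fit_interaction`,
#'   `fit_additive`, `engine`.
#' @export
run_interaction_test <- function(data, factor_a, factor_b,
                                 response = "polyclonal",
                                 adjusters = c("purity", "age", "sex"),
                                 grouping = "cancer_type",
                                 engine = c("linear", "logistic")) {
  engine <- match.arg(engine)
  stopifnot_columns(data, c(factor_a, factor_b, response, adjusters, grouping),
                    "interaction data")
  for (f in c(factor_a, factor_b)) {
    lev <- unique(stats::na.omit(data[[f]]))
    if (length(lev) != 2L) {
      hx_stop(sprintf("factor '%s' must have exactly 2 observed levels (has %d)",
                      f, length(lev)))
    }
  }
  yv <- stats::na.omit(data[[response]])
  if (length(unique(yv)) < 2L) {
    hx_stop(sprintf("response '%s' is constant; interaction test is degenerate",
                    response))
  }
  d <- data
  to01 <- function(v) if (is.numeric(v)) v else as.integer(factor(v)) - 1L
  d[[factor_a]] <- to01(d[[factor_a]])
  d[[factor_b]] <- to01(d[[factor_b]])
  d[[response]] <- to01(d[[response]])
  add_terms <- c(factor_a, factor_b, adjusters)
  int_terms <- c(add_terms, paste0(factor_a, ":", factor_b))
  if (engine == "linear") {
    cols <- unique(c(response, factor_a, factor_b, adjusters, grouping))
    d <- d[stats::complete.cases(d[cols]), , drop = FALSE]
    fit_int <- fit_lmm(d, response, int_terms, grouping, method = "ML")
    fit_add <- fit_lmm(d, response, add_terms, grouping, method = "ML")
    lrt <- lrt_compare(fit_int, fit_add)
  } else {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      hx_stop("engine = 'logistic' requires the lme4 package")
    }
    cols <- unique(c(response, factor_a, factor_b, adjusters, grouping))
    d <- d[stats::complete.cases(d[cols]), , drop = FALSE]
    fml_int <- stats::as.formula(paste(response, "~",
                                       paste(int_terms, collapse = " + "),
                                       "+ (1|", grouping, ")"))
    fml_add <- stats::as.formula(paste(response, "~",
                                       paste(add_terms, collapse = " + "),
                                       "+ (1|", grouping, ")"))
    fit_int <- lme4::glmer(fml_int, data = d, family = stats::binomial())
    fit_add <- lme4::glmer(fml_add, data = d, family = stats::binomial())
    stat <- max(0, 2 * (as.numeric(stats::logLik(fit_int)) -
                          as.numeric(stats::logLik(fit_add))))
    lrt <- list(statistic = stat, df = 1L,
                p = stats::pchisq(stat, 1L, lower.tail = FALSE))
  }
  list(p = lrt$p, statistic = lrt$statistic, df = lrt$df, n = nrow(d),
       fit_interaction = fit_int, fit_additive = fit_add, engine = engine)
}

#' Stratified mRNA abundance summary
#'
#' Summarizes a gene's mRNA abundance across the four strata defined by
#' driver status (mutated vs wildtype) and hypoxia class (hypoxic vs
#' normoxic): per-stratum n, median and quartiles, plus mixed-model
#' likelihood-ratio p-values for the driver and hypoxia terms with
#' abundance as the response. Empty strata are reported with `n = 0` and
#' flagged; p-values are then omitted.
#'
#' @param data analysis table.
#' @param abundance numeric abundance column (e.g. the gene's FPKM-UQ).
#' @param status_col binary driver status column (0/1).
#' @param class_col hypoxia class column (factor or 0/1).
#' @param adjusters,grouping as in [run_association_scan()].
#' @return list with `strata` (data.frame), `p_status`, `p_class`,
#'   `complete` (logical: all four strata non-empty).
#' @export
stratified_mrna_summary <- function(data, abundance, status_col, class_col,
                                    adjusters = c("purity", "age", "sex"),
                                    grouping = "cancer_type") {
  stopifnot_columns(data, c(abundance, status_col, class_col, adjusters, grouping),
                    "stratified summary data")
  st <- factor(ifelse(as.integer(factor(data[[status_col]])) - 1L > 0,
                      "mutated", "wildtype"), levels = c("wildtype", "mutated"))
  cl <- factor(ifelse(as.integer(factor(data[[class_col]])) - 1L > 0,
                      "hypoxic", "normoxic"), levels = c("normoxic", "hypoxic"))
  grid <- expand.grid(status = levels(st), class = levels(cl),
                      KEEP.OUT.ATTRS = FALSE)
  strata <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    v <- data[[abundance]][st == grid$status[i] & cl == grid$class[i]]
    v <- v[!is.na(v)]
    data.frame(status = grid$status[i], class = grid$class[i], n = length(v),
               q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_)
  }))
  complete <- all(strata$n > 0L)
  if (!complete) {
    hx_log("one or more strata are empty; mixed-model p-values omitted")
    return(list(strata = strata, p_status = NA_real_, p_class = NA_real_,
                complete = FALSE))
  }
  d <- data
  d$.status <- as.integer(st) - 1L
  d$.class <- as.integer(cl) - 1L
  p_status <- fit_feature_pair(d, abundance, ".status", c(".class", adjusters),
                               grouping)$lrt$p
  p_class <- fit_feature_pair(d, abundance, ".class", c(".status", adjusters),
                              grouping)$lrt$p
  list(strata = strata, p_status = p_status, p_class = p_class, complete = TRUE)
}
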