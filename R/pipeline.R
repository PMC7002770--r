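#' Run the end-to-end analysis pipeline
#'
#' Executes the full analysis in the order of the study it reproduces:
#' score every signature, summarize the hypoxia landscape, dichotomize,
#' assemble the feature table, run the association scans (mutational
#' density; drivers; SBS exposures; ID exposures; subclonality), the
#' independence test, the hypoxia-by-driver interaction test on
#' clonality, and residual diagnostics for each density full model.
#' All outputs are TSV/JSON files under `out_dir`, listed in
#' `manifest.json` together with the package version and a config hash.
#' Outputs are deterministic given `config$seed`.
#'
#' Missing input tables degrade gracefully: scans whose inputs are
#' absent are skipped with a logged reason and the rest of the pipeline
#' completes.
#'
#' @param config either a named list or a path to a JSON config file.
#'   Recognized fields: `input_dir` (a cohort directory as written by
#'   [write_cohort()]; required), `out_dir` (required), `signature`
#'   (signature used for modelling; default first in the GMT),
#'   `min_samples_per_type` (default 15), `n_sim_residuals` (default
#'   1000), `independence` (list with `feature`, `adjust_for`; default
#'   snvs_per_mb adjusted for total_deletions when both exist),
#'   `interaction_gene` (default PTEN), `seed` (default 1).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$input_dir) || is.null(config$out_dir)) {
    hx_stop("config must provide 'input_dir' and 'out_dir'")
  }
  seed <- as.integer(config$seed %||% 1L)
  min_k <- as.integer(config$min_samples_per_type %||% 15L)
  n_sim <- as.integer(config$n_sim_residuals %||% 1000L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, f) {
    tryCatch(f, error = function(e) {
      partial <- list(stage_failed = name, error = conditionMessage(e),
                      files = files)
      jsonlite::write_json(partial, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      hx_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)),
              class = if (inherits(e, "hx_fit_error")) "hx_fit_error"
                      else "hx_validation_error")
    })
  }
  emit <- function(df, name) {
    write_tsv_file(df, file.path(out_dir, name))
    files <<- c(files, name)
  }
  emit_json <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }

  bundle <- stage("read", read_cohort(config$input_dir))
  sig_name <- config$signature %||% names(bundle$signatures)[1L]

  # -- scoring ---------------------------------------------------------
  scores <- stage("score", {
    do.call(rbind, lapply(names(bundle$signatures), function(s) {
      compute_hypoxia_scores(bundle$expression, bundle$signatures[[s]],
                             sig_name = s)
    }))
  })
  emit(scores, "scores.tsv")

  main <- scores[scores$signature == sig_name, , drop = FALSE]
  covs <- bundle$covariates
  lab <- covs$cancer_type[match(main$sample, covs$sample)]
  summary_tab <- stage("summarize", summarize_scores(main$score, lab))
  summary_tab$scaled_median <- tryCatch(
    scale_median_scores(stats::setNames(summary_tab$median,
                                        summary_tab$cancer_type)),
    hx_error = function(e) NA_real_)
  emit(summary_tab, "score_summary.tsv")
  wvf <- within_type_variance_fraction(main$score, lab)

  # -- feature assembly ------------------------------------------------
  analysis <- stage("features", {
    status <- if (!is.null(bundle$driver_events) && nrow(bundle$driver_events)) {
      summarize_driver_status(bundle$driver_events,
                              samples = covs$sample)
    } else NULL
    props <- if (!is.null(bundle$exposures)) {
      compute_signature_proportions(bundle$exposures)
    } else NULL
    tab <- assemble_feature_table(covs, scores, density = bundle$features,
                                  status = status, proportions = props,
                                  subclonality = bundle$subclonality,
                                  signature = sig_name)
    cls <- dichotomize_scores(stats::setNames(tab$hypoxia_score, tab$sample))
    tab$hypoxia_class <- as.integer(cls == "hypoxic")
    tab
  })
  emit(analysis, "analysis_table.tsv")
  emit_json(stats::setNames(as.list(names(analysis)), names(analysis)),
            "column_dictionary.json")

  filtered <- stage("filter", apply_min_samples_filter(analysis,
                                                       "cancer_type", min_k))

  scans <- list()
  run_scan <- function(label, feats) {
    feats <- intersect(feats, names(filtered))
    if (length(feats) == 0L) {
      hx_log(sprintf("scan '%s' skipped: no input columns available", label))
      return(NULL)
    }
    sc <- stage(paste0("scan_", label),
                run_association_scan(filtered, feats))
    df <- as.data.frame(sc)
    df$correction <- attr(sc, "correction")
    emit(df, sprintf("scan_%s.tsv", label))
    scans[[label]] <<- sc
    sc
  }
  density_feats <- setdiff(names(bundle$features), "sample")
  run_scan("density", density_feats)
  run_scan("drivers", grep("^driver_", names(filtered), value = TRUE))
  run_scan("sbs", grep("^SBS", names(filtered), value = TRUE))
  run_scan("id", grep("^ID", names(filtered), value = TRUE))
  run_scan("subclonality",
           intersect(c("n_clusters", "n_clonal", "n_subclonal"),
                     names(filtered)))

  # -- independence test ----------------------------------------------
  ind_cfg <- config$independence %||%
    list(feature = "snvs_per_mb", adjust_for = "total_deletions")
  if (all(c(ind_cfg$feature, ind_cfg$adjust_for) %in% names(filtered))) {
    ind <- stage("independence",
                 run_independence_test(filtered, ind_cfg$feature,
                                       ind_cfg$adjust_for))
    emit_json(list(feature = ind_cfg$feature, adjust_for = ind_cfg$adjust_for,
                   p = ind$p, statistic = ind$statistic, df = ind$df,
                   n = ind$n),
              "independence.json")
  } else {
    hx_log("independence test skipped: requested columns absent")
  }

  # -- interaction test ------------------------------------------------
  int_gene <- config$interaction_gene %||% "PTEN"
  drv_col <- paste0("driver_", int_gene)
  if (all(c(drv_col, "polyclonal", "hypoxia_class") %in% names(filtered))) {
    it <- stage("interaction",
                run_interaction_test(filtered, "hypoxia_class", drv_col))
    emit_json(list(factor_a = "hypoxia_class", factor_b = drv_col,
                   p = it$p, statistic = it$statistic, df = it$df, n = it$n,
                   engine = it$engine),
              "interaction.json")
  } else {
    hx_log("interaction test skipped: clonality or driver columns absent")
  }

  # -- diagnostics on the density full models -------------------------
  if (!is.null(scans$density)) {
    diag_tab <- stage("diagnostics", {
      feats <- scans$density$feature[!scans$density$failed &
                                       !scans$density$skipped]
      do.call(rbind, lapply(seq_along(feats), function(i) {
        f <- feats[i]
        fit <- fit_feature_pair(filtered, "hypoxia_score", f,
                                c("purity", "age", "sex"), "cancer_type")$full
        r <- simulated_residuals(fit, n_sim = n_sim,
                                 seed = (seed + i) %% .Machine$integer.max)
        data.frame(feature = f, ks_statistic = r$ks_statistic, ks_p = r$ks_p,
                   trend_rho = r$trend_rho, trend_p = r$trend_p,
                   n_sim = r$n_sim)
      }))
    })
    emit(diag_tab, "diagnostics.tsv")
  }

  # -- manifest --------------------------------------------------------
  cfg_path <- file.path(out_dir, "config_used.json")
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  jsonlite::write_json(cfg_for_hash, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, "config_used.json")
  manifest <- list(
    package = "hypoxscan",
    version = as.character(utils::packageVersion("hypoxscan")),
    seed = seed,
    signature = sig_name,
    min_samples_per_type = min_k,
    within_type_variance_fraction = wvf,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = sort(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
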