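DRIVER_CLASSES <- c("SNV", "CNA", "SV")

#' Per-gene driver mutation status
#'
#' Collapses a long table of driver events (one row per sample, gene and
#' event class) to a single status per (sample, gene) over the full
#' sample-by-gene grid: `wildtype` when no event is recorded, the event
#' class when exactly one distinct class occurred, and `compound` when a
#' tumour carries more than one class of event in the same gene.
#'
#' @param events data.frame with columns `sample`, `gene`, `class`
#'   (values in `SNV`, `CNA`, `SV`); duplicates per (sample, gene, class)
#'   are collapsed.
#' @param samples,genes identifiers defining the output grid; default to
#'   those observed in `events`.
#' @return data.frame `sample`, `gene`, `status` (factor with levels
#'   wildtype, SNV, CNA, SV, compound).
#' @export
summarize_driver_status <- function(events, samples = NULL, genes = NULL) {
  stopifnot_columns(events, c("sample", "gene", "class"), "driver events")
  bad <- setdiff(unique(events$class), DRIVER_CLASSES)
  if (length(bad) > 0L) {
    hx_stop(sprintf("unknown driver event class token(s): %s",
                    paste(bad, collapse = ", ")))
  }
  samples <- samples %||% unique(events$sample)
  genes <- genes %||% unique(events$gene)
  events <- unique(events[c("sample", "gene", "class")])
  key <- paste(events$sample, events$gene, sep = "\r")
  n_classes <- tapply(events$class, key, function(cl) length(unique(cl)))
  one_class <- tapply(events$class, key, function(cl) cl[1L])
  grid <- expand.grid(sample = samples, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gkey <- paste(grid$sample, grid$gene, sep = "\r")
  nc <- n_classes[gkey]
  status <- ifelse(is.na(nc), "wildtype",
                   ifelse(nc > 1L, "compound", one_class[gkey]))
  grid$status <- factor(status, levels = c("wildtype", DRIVER_CLASSES, "compound"))
  grid
}

#' Mutational-signature exposure proportions
#'
#' Divides the mutation count attributed to each signature by the
#' sample's total mutation count. Samples with a zero total cannot be
#' normalized; they are excluded and logged.
#'
#' @param exposures data.frame with columns `sample`, `signature`,
#'   `count` (non-negative integers).
#' @return data.frame `sample`, `signature`, `proportion`; proportions
#'   sum to 1 per retained sample (to within 1e-12).
#' @export
compute_signature_proportions <- function(exposures) {
  stopifnot_columns(exposures, c("sample", "signature", "count"), "exposures")
  if (any(exposures$count < 0)) hx_stop("exposure counts must be >= 0")
  totals <- tapply(exposures$count, exposures$sample, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0L) {
    hx_log(sprintf("%d sample(s) with zero total mutations excluded from proportions: %s",
                   length(zero), paste(zero, collapse = ", ")))
    exposures <- exposures[!(exposures$sample %in% zero), , drop = FALSE]
  }
  if (nrow(exposures) == 0L) hx_stop("no samples with positive mutation totals")
  data.frame(sample = exposures$sample,
             signature = exposures$signature,
             proportion = exposures$count / as.numeric(totals[exposures$sample]))
}

#' Clonality from subclonal reconstruction
#'
#' A tumour with exactly one inferred cluster of cells is `monoclonal`;
#' more than one cluster is `polyclonal`.
#'
#' @param n_clusters integer vector of cluster counts (>= 1), or a
#'   data.frame with an `n_clusters` column.
#' @return factor with levels `monoclonal`, `polyclonal`.
#' @export
classify_clonality <- function(n_clusters) {
  if (is.data.frame(n_clusters)) {
    stopifnot_columns(n_clusters, "n_clusters", "subclonality table")
    n_clusters <- n_clusters$n_clusters
  }
  if (anyNA(n_clusters) || any(n_clusters < 1L)) {
    hx_stop("n_clusters must be >= 1 for every sample")
  }
  factor(ifelse(n_clusters > 1L, "polyclonal", "monoclonal"),
         levels = c("monoclonal", "polyclonal"))
}

#' Assemble the analysis-ready feature table
#'
#' Inner-joins covariates, hypoxia scores and the optional feature blocks
#' on the sample identifier, widening long tables as needed: driver
#' status becomes one binary indicator per gene (`driver_<gene>` = 1
#' unless wildtype, matching a mutated-vs-wildtype modelling contract,
#' with the full status retained as `status_<gene>`), signature
#' proportions become one column per signature, and the subclonality
#' block contributes `n_clusters`, `n_clonal`, `n_subclonal`,
#' `clonality` and a 0/1 `polyclonal` indicator. Samples missing from
#' any supplied block are dropped and reported.
#'
#' @param covariates data.frame with `sample`, `cancer_type`, `purity`,
#'   `age`, `sex`.
#' @param scores `hypoxia_scores` table; the signature selected by
#'   `signature` supplies the `hypoxia_score` column (default: first
#'   signature present).
#' @param density optional per-sample data.frame of numeric mutational
#'   density features (must contain `sample`).
#' @param status optional output of [summarize_driver_status()].
#' @param proportions optional output of [compute_signature_proportions()].
#' @param subclonality optional data.frame `sample`, `n_clusters`,
#'   `n_clonal`, `n_subclonal`.
#' @param signature which signature's scores to use.
#' @return data.frame keyed by `sample`, with an attribute
#'   `"missingness"` recording per-block dropped-sample counts.
#' @export
assemble_feature_table <- function(covariates, scores, density = NULL,
                                   status = NULL, proportions = NULL,
                                   subclonality = NULL, signature = NULL) {
  stopifnot_columns(covariates, c("sample", "cancer_type", "purity", "age", "sex"),
                    "covariates")
  stopifnot_columns(scores, c("sample", "signature", "score"), "scores")
  signature <- signature %||% scores$signature[1L]
  sc <- scores[scores$signature == signature, , drop = FALSE]
  if (nrow(sc) == 0L) hx_stop(sprintf("no scores for signature '%s'", signature))
  blocks <- list(covariates = covariates,
                 scores = data.frame(sample = sc$sample, hypoxia_score = sc$score))
  if (!is.null(density)) {
    stopifnot_columns(density, "sample", "density features")
    num <- density[setdiff(names(density), "sample")]
    if (!all(vapply(num, is.numeric, logical(1)))) {
      hx_stop("density features must be numeric")
    }
    if (any(!is.finite(as.matrix(num)))) hx_stop("density features must be finite")
    blocks$density <- density
  }
  if (!is.null(status)) {
    stopifnot_columns(status, c("sample", "gene", "status"), "driver status")
    wide_bin <- stats::reshape(
      data.frame(sample = status$sample, gene = paste0("driver_", status$gene),
                 v = as.integer(status$status != "wildtype")),
      idvar = "sample", timevar = "gene", direction = "wide")
    names(wide_bin) <- sub("^v\\.", "", names(wide_bin))
    wide_st <- stats::reshape(
      data.frame(sample = status$sample, gene = paste0("status_", status$gene),
                 v = as.character(status$status)),
      idvar = "sample", timevar = "gene", direction = "wide")
    names(wide_st) <- sub("^v\\.", "", names(wide_st))
    blocks$drivers <- merge(wide_bin, wide_st, by = "sample")
  }
  if (!is.null(proportions)) {
    stopifnot_columns(proportions, c("sample", "signature", "proportion"),
                      "signature proportions")
    wide <- stats::reshape(proportions, idvar = "sample", timevar = "signature",
                           direction = "wide")
    names(wide) <- sub("^proportion\\.", "", names(wide))
    blocks$exposures <- wide
  }
  if (!is.null(subclonality)) {
    stopifnot_columns(subclonality, c("sample", "n_clusters", "n_clonal", "n_subclonal"),
                      "subclonality")
    sb <- subclonality
    sb$clonality <- classify_clonality(sb$n_clusters)
    sb$polyclonal <- as.integer(sb$clonality == "polyclonal")
    blocks$subclonality <- sb
  }

  ids <- Reduce(intersect, lapply(blocks, function(b) unique(b$sample)))
  if (length(ids) == 0L) {
    hx_stop(sprintf(
      "sample sets have empty intersection; block sizes: %s",
      paste(sprintf("%s=%d", names(blocks),
                    vapply(blocks, function(b) length(unique(b$sample)), 1L)),
            collapse = ", ")))
  }
  missingness <- vapply(blocks, function(b) length(setdiff(unique(b$sample), ids)), 1L)
  dropped_from <- vapply(blocks,
                         function(b) length(ids) - sum(ids %in% b$sample), 1L)
  for (nm in names(blocks)) {
    lost <- length(unique(blocks[[nm]]$sample)) - length(ids)
    if (lost > 0L) hx_log(sprintf("block '%s': %d sample(s) outside the join dropped", nm, lost))
  }
  out <- Reduce(function(a, b) merge(a, b, by = "sample"), blocks)
  out <- out[match(sort(ids), out$sample), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missingness") <- missingness
  attr(out, "hypoxia_signature") <- signature
  out
}
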