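# Canonical on-disk formats: tab-delimited UTF-8 TSV with a header row
# for tables, GMT for gene sets, JSON for configs / manifests / truth.

read_tsv_file <- function(path, required = NULL, id_col = NULL) {
  if (!file.exists(path)) hx_stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L) {
      hx_stop(sprintf("schema error in '%s': missing column(s) %s",
                      basename(path), paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(id_col) && id_col %in% names(df)) {
    df[[id_col]] <- trimws(df[[id_col]])
    if (anyDuplicated(df[[id_col]])) {
      hx_stop(sprintf("duplicated %s identifier(s) in '%s'", id_col, basename(path)))
    }
  }
  df
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read an expression TSV
#'
#' Genes in rows; first column (named `gene`) holds gene identifiers,
#' remaining columns are samples. Duplicate genes or samples raise a
#' validation error.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_file(path, required = "gene")
  genes <- trimws(df$gene)
  if (anyDuplicated(genes)) hx_stop(sprintf("duplicated gene row(s) in '%s'", basename(path)))
  m <- as.matrix(df[setdiff(names(df), "gene")])
  if (!is.numeric(m)) hx_stop("expression values must be numeric")
  rownames(m) <- genes
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#' @param expr genes x samples numeric matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write_tsv_file(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) hx_stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) hx_stop("malformed GMT line (need name, description, >=1 gene)")
    trimws(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    trimws(strsplit(l, "\t", fixed = TRUE)[[1L]][1L])
  }, "")
  if (anyDuplicated(names(sets))) hx_stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    hx_stop("gene sets must be named")
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "hypoxia signature", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic cohort bundle to a directory
#'
#' Emits the same TSV/GMT files the readers consume, plus the ground
#' truth as a JSON sidecar.
#'
#' @param bundle a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, dir) {
  if (!inherits(bundle, "cohort_bundle")) hx_stop("expected a 'cohort_bundle'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(bundle$expression, p("expression.tsv"))
  write_gmt(bundle$signatures, p("signatures.gmt"))
  write_tsv_file(bundle$covariates, p("covariates.tsv"))
  write_tsv_file(bundle$features, p("features.tsv"))
  write_tsv_file(bundle$driver_events, p("driver_events.tsv"))
  write_tsv_file(bundle$exposures, p("exposures.tsv"))
  write_tsv_file(bundle$subclonality, p("subclonality.tsv"))
  truth <- bundle$truth
  truth$latent_hypoxia <- as.list(truth$latent_hypoxia)
  truth$type_intercepts <- as.data.frame(truth$type_intercepts)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file.path(dir, c("expression.tsv", "signatures.gmt", "covariates.tsv",
                             "features.tsv", "driver_events.tsv", "exposures.tsv",
                             "subclonality.tsv", "truth.json")))
}

#' Read a cohort directory back into a bundle
#'
#' Validates schemas and re-assembles the tables written by
#' [write_cohort()] (the `truth.json` sidecar is optional: real cohorts
#' have none).
#'
#' @param dir directory containing the cohort files.
#' @return list of class `"cohort_bundle"`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  expr <- read_expression_tsv(p("expression.tsv"))
  sigs <- read_gmt(p("signatures.gmt"))
  covariates <- read_tsv_file(p("covariates.tsv"),
                              required = c("sample", "cancer_type", "purity",
                                           "age", "sex"),
                              id_col = "sample")
  features <- read_tsv_file(p("features.tsv"), required = "sample",
                            id_col = "sample")
  driver_events <- if (file.exists(p("driver_events.tsv"))) {
    read_tsv_file(p("driver_events.tsv"), required = c("sample", "gene", "class"))
  } else NULL
  exposures <- if (file.exists(p("exposures.tsv"))) {
    read_tsv_file(p("exposures.tsv"), required = c("sample", "signature", "count"))
  } else NULL
  subclonality <- if (file.exists(p("subclonality.tsv"))) {
    sb <- read_tsv_file(p("subclonality.tsv"),
                        required = c("sample", "n_clusters", "n_clonal",
                                     "n_subclonal"),
                        id_col = "sample")
    sb$clonality <- classify_clonality(sb$n_clusters)
    sb
  } else NULL
  truth <- if (file.exists(p("truth.json"))) {
    tr <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    tr$latent_hypoxia <- unlist(tr$latent_hypoxia)
    tr
  } else NULL
  structure(list(expression = expr, signatures = sigs, covariates = covariates,
                 features = features, driver_events = driver_events,
                 exposures = exposures, subclonality = subclonality,
                 truth = truth),
            class = "cohort_bundle")
}
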