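#' Signature-based hypoxia scores
#'
#' For each signature gene present in the expression matrix, samples with
#' abundance strictly above the per-gene cohort median vote +1 and all
#' other samples vote -1 (multiplied by the gene's sign for signed
#' signatures); a sample's score is the sum of its votes over the genes
#' used. Scores are cohort-relative: they depend on the set of samples
#' scored together.
#'
#' Ties at the median vote -1 ("top 50%" is implemented as strictly
#' greater than the median). Signature genes absent from the matrix are
#' skipped and reported.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); finite, non-negative.
#' @param sig a signature: either a character vector of gene ids or a
#'   named numeric vector of gene signs (+1/-1).
#' @param sig_name label stored in the output (default
#'   `"signature"`).
#' @return data.frame of class `"hypoxia_scores"` with columns `sample`,
#'   `signature`, `score`, `n_genes_used`. `|score| <= n_genes_used` and
#'   `score` has the parity of `n_genes_used`.
#' @examples
#' m <- rbind(HIF1A = c(1, 2, 3, 4))
#' colnames(m) <- paste0("s", 1:4)
#' compute_hypoxia_scores(m, "HIF1A")$score  # -1 -1 +1 +1
#' @export
compute_hypoxia_scores <- function(expr, sig, sig_name = "signature") {
  validate_expression(expr)
  if (ncol(expr) < 2L) hx_stop("at least 2 samples are required to score a cohort")
  if (is.character(sig)) {
    genes <- sig
    signs <- rep(1, length(sig))
  } else if (is.numeric(sig) && !is.null(names(sig))) {
    genes <- names(sig)
    signs <- unname(sig)
    if (!all(signs %in% c(-1, 1))) hx_stop("gene signs must be +1 or -1")
  } else {
    hx_stop("`sig` must be a character vector of genes or a named +1/-1 vector")
  }
  if (anyDuplicated(genes)) hx_stop("signature contains duplicate genes")
  if (length(genes) == 0L) hx_stop("signature is empty")
  present <- genes %in% rownames(expr)
  if (!any(present)) {
    hx_stop(sprintf("signature '%s' has zero genes in the expression matrix", sig_name))
  }
  if (any(!present)) {
    hx_log(sprintf("signature '%s': %d/%d genes absent from the matrix and skipped",
                   sig_name, sum(!present), length(genes)))
  }
  genes <- genes[present]
  signs <- signs[present]
  sub <- expr[genes, , drop = FALSE]
  med <- apply(sub, 1L, stats::median)
  votes <- sweep(ifelse(sub > med, 1L, -1L), 1L, signs, `*`)
  structure(data.frame(sample = colnames(expr),
                       signature = sig_name,
                       score = as.integer(colSums(votes)),
                       n_genes_used = length(genes),
                       stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("hypoxia_scores", "data.frame"))
}

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    hx_stop("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    hx_stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) hx_stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr))) hx_stop("duplicate sample identifiers in expression matrix")
  if (any(!is.finite(expr)) || any(expr < 0)) {
    hx_stop("expression values must be finite and >= 0")
  }
  invisible(expr)
}

#' Rescale per-cancer-type median scores to [-1, +1]
#'
#' Affine map sending the smallest median to -1 and the largest to +1,
#' used to put scores from different signatures (or cohorts) on a common
#' scale before comparing them.
#'
#' @param medians named numeric vector, one median score per cancer type.
#' @return Named numeric vector in `[-1, 1]`, order preserved.
#' @export
scale_median_scores <- function(medians) {
  if (length(medians) < 2L) hx_stop("need medians for at least 2 cancer types")
  rng <- range(medians)
  if (diff(rng) == 0) hx_stop("all medians are equal; the [-1, 1] rescaling is degenerate")
  2 * (medians - rng[1]) / diff(rng) - 1
}

#' Concordance of two signatures' scores
#'
#' Spearman rank correlation over the samples shared by two score tables,
#' with a two-sided p-value from the AS89 algorithm (exact permutation
#' enumeration for small tie-free cohorts, Edgeworth approximation
#' otherwise).
#'
#' @param scores_a,scores_b `hypoxia_scores` data.frames (or any
#'   data.frame with `sample` and `score` columns).
#' @return list with `rho`, `p`, `n` (shared samples) and `p_method`.
#' @export
cross_signature_concordance <- function(scores_a, scores_b) {
  stopifnot_columns(scores_a, c("sample", "score"), "scores_a")
  stopifnot_columns(scores_b, c("sample", "score"), "scores_b")
  shared <- intersect(scores_a$sample, scores_b$sample)
  if (length(shared) < 4L) hx_stop("fewer than 4 shared samples")
  a <- scores_a$score[match(shared, scores_a$sample)]
  b <- scores_b$score[match(shared, scores_b$sample)]
  sp <- spearman_as89(a, b)
  list(rho = sp$rho, p = sp$p, n = length(shared), p_method = sp$method)
}

#' Tumour versus normal score comparison per tissue
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of tumour against
#' normal hypoxia scores, run only for tissues with at least
#' `min_normals` normal samples; tissues below the threshold are skipped
#' with a logged reason.
#'
#' @param tumour,normal data.frames with columns `tissue` and `score`
#'   (a plain numeric vector is treated as a single unnamed tissue).
#' @param min_normals minimum normal-sample count per tissue (default 15).
#' @return data.frame with one row per tissue present in both inputs:
#'   `tissue`, `n_tumour`, `n_normal`, `p` (NA when skipped), `skipped`.
#' @export
tumour_vs_normal_test <- function(tumour, normal, min_normals = 15L) {
  as_tab <- function(x, what) {
    if (is.numeric(x)) x <- data.frame(tissue = "all", score = x)
    stopifnot_columns(x, c("tissue", "score"), what)
    x
  }
  tumour <- as_tab(tumour, "tumour")
  normal <- as_tab(normal, "normal")
  tissues <- intersect(unique(tumour$tissue), unique(normal$tissue))
  if (length(tissues) == 0L) hx_stop("no tissue appears in both tumour and normal tables")
  rows <- lapply(tissues, function(tt) {
    ts <- tumour$score[tumour$tissue == tt]
    ns <- normal$score[normal$tissue == tt]
    if (length(ns) < min_normals) {
      hx_log(sprintf("tissue '%s' skipped: %d normal samples < threshold %d",
                     tt, length(ns), min_normals))
      return(data.frame(tissue = tt, n_tumour = length(ts), n_normal = length(ns),
                        p = NA_real_, skipped = TRUE))
    }
    p <- suppressWarnings(
      stats::wilcox.test(ts, ns, alternative = "two.sided")$p.value)
    data.frame(tissue = tt, n_tumour = length(ts), n_normal = length(ns),
               p = p, skipped = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of score variance lying within cancer types
#'
#' One-way sum-of-squares decomposition: within-group SS divided by total
#' SS. The complement is the fraction attributable to differences between
#' cancer-type means.
#'
#' @param scores numeric vector of scores.
#' @param cancer_labels grouping vector, same length.
#' @return Scalar in `[0, 1]`.
#' @export
within_type_variance_fraction <- function(scores, cancer_labels) {
  if (length(scores) != length(cancer_labels)) hx_stop("length mismatch")
  if (length(scores) < 2L) hx_stop("need at least 2 samples")
  g <- factor(cancer_labels)
  if (nlevels(g) < 2L) hx_stop("need at least 2 cancer types")
  tot <- sum((scores - mean(scores))^2)
  if (tot == 0) hx_stop("total score variance is zero; fraction undefined")
  within <- sum(tapply(scores, g, function(v) sum((v - mean(v))^2)))
  within / tot
}

#' Per-cancer-type score summaries
#'
#' Median, interquartile range (linear-interpolation / type-7 quantiles)
#' and the fraction of tumours with elevated hypoxia (score > 0), per
#' cancer type.
#'
#' @param scores numeric score vector.
#' @param cancer_labels grouping vector, same length.
#' @return data.frame with `cancer_type`, `n`, `median`, `iqr`,
#'   `fraction_elevated`, sorted by decreasing median.
#' @export
summarize_scores <- function(scores, cancer_labels) {
  if (length(scores) != length(cancer_labels) || length(scores) == 0L) {
    hx_stop("scores and cancer labels must be non-empty and aligned")
  }
  g <- factor(cancer_labels)
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- scores[g == lv]
    data.frame(cancer_type = lv, n = length(v),
               median = stats::median(v),
               iqr = unname(stats::quantile(v, 0.75, type = 7) -
                              stats::quantile(v, 0.25, type = 7)),
               fraction_elevated = mean(v > 0))
  }))
  out[order(-out$median, out$cancer_type), , drop = FALSE]
}

#' Median-dichotomize hypoxia scores
#'
#' Samples strictly above the cohort median are classed `hypoxic`, the
#' rest `normoxic`. If every score is identical the whole cohort is
#' `normoxic` and a warning is raised.
#'
#' @param scores numeric vector (names, if present, are preserved).
#' @return factor with levels `normoxic`, `hypoxic`.
#' @export
dichotomize_scores <- function(scores) {
  if (length(scores) < 2L) hx_stop("need at least 2 samples to dichotomize")
  med <- stats::median(scores)
  if (all(scores == scores[1L])) {
    warning("all scores identical; every sample classed normoxic")
  }
  cls <- factor(ifelse(scores > med, "hypoxic", "normoxic"),
                levels = c("normoxic", "hypoxic"))
  names(cls) <- names(scores)
  hx_log(sprintf("dichotomized %d samples: %d hypoxic, %d normoxic",
                 length(cls), sum(cls == "hypoxic"), sum(cls == "normoxic")))
  cls
}
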