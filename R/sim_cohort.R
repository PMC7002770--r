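# Seed substream offsets: fixed so that adding a table never perturbs
# the draws of earlier tables.
SEED_OFFSETS <- c(covariates = 1L, latent = 2L, expression = 3L,
                  features = 4L, exposures = 5L, drivers = 6L,
                  subclonality = 7L)

sub_seed <- function(cfg, stage) {
  (cfg$seed + SEED_OFFSETS[[stage]] * 10007L) %% .Machine$integer.max
}

#' Generate a synthetic multi-cancer cohort with known ground truth
#'
#' Draws covariates, a latent hypoxia axis, an expression matrix whose
#' signature genes co-vary with latent hypoxia, and the downstream
#' outcome tables (mutational-density features, driver events, signature
#' exposures, subclonal architecture), all deterministic given
#' `config$seed`. The returned bundle records the exact planted
#' parameters and the per-sample latent hypoxia in `truth`.
#'
#' @param config a [sim_config()].
#' @return list of class `"cohort_bundle"` with elements `expression`
#'   (genes x samples matrix), `signatures` (named list of gene-id
#'   vectors), `covariates`, `features`, `driver_events`, `exposures`,
#'   `subclonality` and `truth`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  n_per <- rep_len(cfg$samples_per_type, cfg$n_cancer_types)
  n <- sum(n_per)
  samples <- sprintf("SP%04d", seq_len(n))
  types <- sprintf("CT%02d", seq_len(cfg$n_cancer_types))
  cancer_type <- rep(types, times = n_per)

  set.seed(sub_seed(cfg, "covariates"))
  covariates <- data.frame(
    sample = samples,
    cancer_type = cancer_type,
    purity = pmax(stats::rbeta(n, cfg$purity_shape1, cfg$purity_shape2), 1e-3),
    age = as.integer(sample(seq(cfg$age_min, cfg$age_max), n, replace = TRUE)),
    sex = stats::rbinom(n, 1L, cfg$sex_p))

  set.seed(sub_seed(cfg, "latent"))
  h <- stats::rnorm(n, 0, cfg$latent_hypoxia_sd)
  names(h) <- samples

  expr <- generate_expression(h, cfg)
  out <- generate_outcomes(h, covariates, cfg)

  truth <- list(latent_hypoxia = h,
                config = unclass(cfg),
                type_intercepts = out$type_intercepts)
  structure(list(expression = expr$matrix,
                 signatures = expr$signatures,
                 covariates = covariates,
                 features = out$features,
                 driver_events = out$driver_events,
                 exposures = out$exposures,
                 subclonality = out$subclonality,
                 truth = truth),
            class = "cohort_bundle")
}

#' Generate the expression matrix from latent hypoxia
#'
#' Signature genes: log2 abundance = per-gene baseline +
#' `expression_effect * h` + Gaussian noise, so the downstream median-vote
#' scorer can recover the latent axis. Background genes are independent
#' of hypoxia. Abundances are exponentiated, hence non-negative.
#'
#' @param h named latent hypoxia vector (names = sample ids).
#' @param config a [sim_config()].
#' @return list with `matrix` (genes x samples) and `signatures`
#'   (named list of gene-id vectors).
#' @export
generate_expression <- function(h, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  if (any(!is.finite(h))) hx_stop("latent hypoxia must be finite")
  n <- length(h)
  samples <- names(h) %||% sprintf("SP%04d", seq_len(n))
  set.seed(sub_seed(cfg, "expression"))
  sig_genes <- lapply(names(cfg$signatures), function(sname) {
    sprintf("%s_G%03d", toupper(sname), seq_len(cfg$signatures[[sname]]))
  })
  names(sig_genes) <- names(cfg$signatures)
  all_sig <- unlist(sig_genes, use.names = FALSE)
  bg <- if (cfg$n_background_genes > 0L) {
    sprintf("BG_G%04d", seq_len(cfg$n_background_genes))
  } else character(0)
  genes <- c(all_sig, bg)
  baseline <- stats::rnorm(length(genes), mean = 5, sd = 1.5)
  eff <- c(rep(cfg$expression_effect, length(all_sig)), rep(0, length(bg)))
  log2x <- outer(baseline, rep(1, n)) + outer(eff, h) +
    matrix(stats::rnorm(length(genes) * n, sd = cfg$expression_noise_sd),
           length(genes), n)
  m <- 2^log2x
  dimnames(m) <- list(genes, samples)
  list(matrix = m, signatures = sig_genes)
}

#' Generate outcome tables from latent hypoxia and covariates
#'
#' Continuous density features follow
#' `feature = alpha_type + beta * h + gamma * purity + delta * age + eps`
#' with per-type intercepts `alpha_type ~ N(0, random_intercept_sd)`.
#' Driver gene g is mutated with
#' `logit p = driver_logit_intercept + slope_g * h`; mutated tumours are
#' assigned one event class (SNV/CNA/SV), and a second distinct class with
#' probability 0.15 (a compound event). Signature exposures are
#' Dirichlet-multinomial with per-signature weights tilted by
#' `exp(slope * h)`, so exposure counts always sum to the tumour's total
#' mutation count. Polyclonality is Bernoulli-logit with the planted
#' hypoxia-by-driver interaction; monoclonal tumours have one cluster and
#' zero subclonal mutations.
#'
#' @param h named latent hypoxia vector.
#' @param covariates covariate table aligned with `h`.
#' @param config a [sim_config()].
#' @return list with `features`, `driver_events`, `exposures`,
#'   `subclonality` and `type_intercepts`.
#' @export
generate_outcomes <- function(h, covariates, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  n <- length(h)
  if (nrow(covariates) != n) hx_stop("h and covariates are not aligned")
  samples <- covariates$sample
  types <- unique(covariates$cancer_type)
  gidx <- match(covariates$cancer_type, types)

  # continuous density features, conditionally independent given h
  set.seed(sub_seed(cfg, "features"))
  fnames <- names(cfg$feature_slopes)
  alpha <- matrix(stats::rnorm(length(types) * length(fnames),
                               sd = cfg$random_intercept_sd),
                  length(types), length(fnames),
                  dimnames = list(types, fnames))
  feat <- sapply(fnames, function(f) {
    alpha[gidx, f] + cfg$feature_slopes[[f]] * h +
      cfg$purity_effect * covariates$purity +
      cfg$age_effect * covariates$age +
      stats::rnorm(n, sd = cfg$residual_sd)
  })
  rownames(feat) <- NULL
  features <- data.frame(sample = samples, feat, check.names = FALSE)

  # total mutation burden and signature exposures (conserved per sample)
  set.seed(sub_seed(cfg, "exposures"))
  total_mut <- stats::rnbinom(n, size = cfg$mutation_count_size,
                              mu = cfg$mutation_count_mean) + 1L
  K <- length(cfg$exposure_signatures)
  base_w <- rep(cfg$exposure_concentration / K, K)
  counts <- matrix(0L, n, K, dimnames = list(samples, cfg$exposure_signatures))
  for (i in seq_len(n)) {
    a <- base_w * exp(cfg$exposure_slopes * h[i])
    g <- stats::rgamma(K, shape = a, rate = 1)
    pr <- g / sum(g)
    counts[i, ] <- stats::rmultinom(1L, size = total_mut[i], prob = pr)[, 1L]
  }
  exposures <- data.frame(sample = rep(samples, each = K),
                          signature = rep(cfg$exposure_signatures, times = n),
                          count = as.integer(t(counts)))

  # driver events: Bernoulli-logit mutation, class mixture, compound events
  set.seed(sub_seed(cfg, "drivers"))
  ev <- list()
  for (gene in cfg$driver_genes) {
    p <- stats::plogis(cfg$driver_logit_intercept +
                         cfg$driver_logit_slopes[[gene]] * h)
    mut <- stats::rbinom(n, 1L, p) == 1L
    if (!any(mut)) next
    first <- sample(DRIVER_CLASSES, sum(mut), replace = TRUE,
                    prob = c(0.55, 0.30, 0.15))
    ev[[gene]] <- data.frame(sample = samples[mut], gene = gene, class = first)
    second <- stats::runif(sum(mut)) < 0.15
    if (any(second)) {
      other <- vapply(first[second],
                      function(cl) sample(setdiff(DRIVER_CLASSES, cl), 1L), "")
      ev[[paste0(gene, ".2")]] <- data.frame(sample = samples[mut][second],
                                             gene = gene, class = other)
    }
  }
  driver_events <- if (length(ev)) {
    dd <- do.call(rbind, ev)
    dd <- dd[order(dd$sample, dd$gene, dd$class), , drop = FALSE]
    rownames(dd) <- NULL
    dd
  } else {
    data.frame(sample = character(0), gene = character(0), class = character(0))
  }

  # subclonal architecture with the planted hypoxia x driver interaction
  set.seed(sub_seed(cfg, "subclonality"))
  drv_gene <- cfg$clonality_driver_gene
  drv <- as.integer(samples %in% driver_events$sample[driver_events$gene == drv_gene])
  hyp <- as.integer(h > stats::median(h))
  logit <- cfg$clonality_intercept +
    cfg$clonality_hypoxia_effect * hyp +
    cfg$clonality_driver_effect * drv +
    cfg$clonality_interaction_effect * hyp * drv
  poly <- stats::rbinom(n, 1L, stats::plogis(logit)) == 1L
  n_clusters <- ifelse(poly, 2L + stats::rpois(n, 0.8), 1L)
  sub_frac <- ifelse(poly, stats::runif(n, 0.1, 0.4), 0)
  n_subclonal <- stats::rbinom(n, total_mut, sub_frac)
  subclonality <- data.frame(sample = samples,
                             n_clusters = as.integer(n_clusters),
                             n_clonal = as.integer(total_mut - n_subclonal),
                             n_subclonal = as.integer(n_subclonal))
  subclonality$clonality <- classify_clonality(subclonality$n_clusters)

  list(features = features, driver_events = driver_events,
       exposures = exposures, subclonality = subclonality,
       type_intercepts = alpha)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d cancer types, %d genes\n",
              nrow(x$covariates), length(unique(x$covariates$cancer_type)),
              nrow(x$expression)))
  cat(sprintf("  signatures: %s\n",
              paste(sprintf("%s(%d)", names(x$signatures), lengths(x$signatures)),
                    collapse = ", ")))
  cat(sprintf("  tables: features(%d x %d), driver_events(%d), exposures(%d), subclonality(%d)\n",
              nrow(x$features), ncol(x$features) - 1L, nrow(x$driver_events),
              nrow(x$exposures), nrow(x$subclonality)))
  invisible(x)
}
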