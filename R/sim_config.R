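DENSITY_FEATURES <- c(
  "pga", "snvs_per_mb", "indels_per_mb", "svs_per_genome",
  "total_snvs", "total_indels", "total_deletions", "total_duplications",
  "total_inversions", "total_translocations", "total_truncations",
  "mean_deletion_size", "mean_cna_size", "n_cna_segments", "wgd_score")

SBS_SIGNATURES <- c("SBS1", "SBS3", "SBS5", "SBS6", "SBS12", "SBS17a", "SBS17b", "SBS21")
ID_SIGNATURES <- c("ID2", "ID5", "ID6", "ID9")

DRIVER_GENES <- c("PTEN", "TP53", "VHL", "MYC", "EGFR",
                  "CDKN2A", "KRAS", "BRCA2", "RB1", "PIK3CA")

#' Configuration for the synthetic multi-cancer cohort
#'
#' Defines the generative world: a continuous latent hypoxia axis per
#' sample, cancer-type random intercepts on every generated feature,
#' planted fixed-effect slopes linking latent hypoxia to continuous
#' features, logistic links for driver mutation status, a
#' Dirichlet-multinomial model for mutational-signature exposures, and a
#' logistic clonality model with a hypoxia-by-driver interaction. All
#' randomness flows from `seed`; each table draws from a substream at a
#' fixed offset so adding a table never perturbs earlier ones.
#'
#' Defaults emulate a cohort of the scale analysed in pan-cancer work
#' (27 cancer types of 44 tumours each, ~1188 tumours), with three
#' expression signatures sized like the published hypoxia signatures
#' (52, 99 and 32 genes) and one planted hypoxia-to-deletions effect.
#'
#' @param n_cancer_types number of cancer types (>= 1).
#' @param samples_per_type samples per type (scalar or per-type vector,
#'   each >= 2).
#' @param signatures named integer vector: genes per expression signature.
#' @param n_background_genes background genes independent of hypoxia.
#' @param latent_hypoxia_sd SD of the latent hypoxia axis.
#' @param random_intercept_sd SD tau of per-cancer-type baselines on
#'   generated features.
#' @param residual_sd residual SD of continuous features.
#' @param expression_effect shift of signature-gene log2 abundance per
#'   unit latent hypoxia.
#' @param expression_noise_sd SD of log2 expression noise.
#' @param feature_slopes named vector of planted hypoxia slopes, one per
#'   density feature (missing names default to 0).
#' @param purity_effect,age_effect fixed covariate effects on every
#'   continuous feature.
#' @param driver_genes driver gene identifiers.
#' @param driver_logit_slopes named vector: log-odds of mutation per unit
#'   latent hypoxia (missing genes default to 0).
#' @param driver_logit_intercept baseline mutation log-odds.
#' @param exposure_signatures mutational signature identifiers (SBS/ID).
#' @param exposure_slopes named vector: per-unit-hypoxia log-tilt of each
#'   signature's Dirichlet weight.
#' @param exposure_concentration total Dirichlet concentration.
#' @param mutation_count_mean,mutation_count_size negative-binomial total
#'   mutation count per tumour.
#' @param clonality_intercept,clonality_hypoxia_effect,clonality_driver_effect
#'   logit coefficients of the polyclonality model.
#' @param clonality_interaction_effect planted logit interaction between
#'   elevated hypoxia (latent above median) and mutation of
#'   `clonality_driver_gene`.
#' @param clonality_driver_gene driver gene entering the interaction.
#' @param purity_shape1,purity_shape2 Beta parameters of tumour purity.
#' @param age_min,age_max integer age range.
#' @param sex_p Bernoulli probability of sex = 1.
#' @param seed integer master seed.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cancer_types = 27L,
                       samples_per_type = 44L,
                       signatures = c(buffa = 52L, winter = 99L, ragnum = 32L),
                       n_background_genes = 200L,
                       latent_hypoxia_sd = 1,
                       random_intercept_sd = 1,
                       residual_sd = 1,
                       expression_effect = 1,
                       expression_noise_sd = 1,
                       feature_slopes = c(total_deletions = 0.5),
                       purity_effect = 0.3,
                       age_effect = 0.005,
                       driver_genes = DRIVER_GENES,
                       driver_logit_slopes = c(PTEN = 0.7, TP53 = 0.5),
                       driver_logit_intercept = -0.85,
                       exposure_signatures = c(SBS_SIGNATURES, ID_SIGNATURES),
                       exposure_slopes = c(SBS1 = -0.4, SBS3 = 0.4, ID6 = 0.3),
                       exposure_concentration = 25,
                       mutation_count_mean = 5000,
                       mutation_count_size = 1.5,
                       clonality_intercept = -0.5,
                       clonality_hypoxia_effect = 0.4,
                       clonality_driver_effect = 0.4,
                       clonality_interaction_effect = 1.5,
                       clonality_driver_gene = "PTEN",
                       purity_shape1 = 3.5,
                       purity_shape2 = 1.5,
                       age_min = 20L,
                       age_max = 90L,
                       sex_p = 0.5,
                       seed = 17L) {
  cfg <- list(
    n_cancer_types = as.integer(n_cancer_types),
    samples_per_type = as.integer(samples_per_type),
    signatures = signatures, n_background_genes = as.integer(n_background_genes),
    latent_hypoxia_sd = latent_hypoxia_sd,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    expression_effect = expression_effect,
    expression_noise_sd = expression_noise_sd,
    feature_slopes = expand_named(feature_slopes, DENSITY_FEATURES, "feature_slopes"),
    purity_effect = purity_effect, age_effect = age_effect,
    driver_genes = driver_genes,
    driver_logit_slopes = expand_named(driver_logit_slopes, driver_genes,
                                       "driver_logit_slopes"),
    driver_logit_intercept = driver_logit_intercept,
    exposure_signatures = exposure_signatures,
    exposure_slopes = expand_named(exposure_slopes, exposure_signatures,
                                   "exposure_slopes"),
    exposure_concentration = exposure_concentration,
    mutation_count_mean = mutation_count_mean,
    mutation_count_size = mutation_count_size,
    clonality_intercept = clonality_intercept,
    clonality_hypoxia_effect = clonality_hypoxia_effect,
    clonality_driver_effect = clonality_driver_effect,
    clonality_interaction_effect = clonality_interaction_effect,
    clonality_driver_gene = clonality_driver_gene,
    purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    sex_p = sex_p,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

# fill a partial named vector out to the full name set, zeros elsewhere
expand_named <- function(x, full_names, what) {
  if (is.null(names(x)) && length(x) == length(full_names)) names(x) <- full_names
  bad <- setdiff(names(x), full_names)
  if (length(bad) > 0L) {
    hx_stop(sprintf("configuration error in '%s': unknown name(s) %s",
                    what, paste(bad, collapse = ", ")))
  }
  out <- stats::setNames(numeric(length(full_names)), full_names)
  out[names(x)] <- x
  out
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) hx_stop(sprintf("configuration error in '%s': %s", field, why))
  }
  chk(cfg$n_cancer_types >= 1L, "n_cancer_types", "must be >= 1")
  chk(all(cfg$samples_per_type >= 2L), "samples_per_type", "each type needs >= 2 samples")
  chk(length(cfg$samples_per_type) %in% c(1L, cfg$n_cancer_types),
      "samples_per_type", "scalar or one count per cancer type")
  chk(length(cfg$signatures) >= 1L && all(cfg$signatures >= 1L) &&
        !is.null(names(cfg$signatures)), "signatures",
      "named vector of per-signature gene counts >= 1")
  chk(cfg$n_background_genes >= 0L, "n_background_genes", "must be >= 0")
  for (f in c("latent_hypoxia_sd", "random_intercept_sd", "residual_sd",
              "expression_noise_sd")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f, "must be a non-negative real")
  }
  chk(cfg$exposure_concentration > 0, "exposure_concentration", "must be > 0")
  chk(cfg$mutation_count_mean > 0, "mutation_count_mean", "must be > 0")
  chk(cfg$purity_shape1 > 0 && cfg$purity_shape2 > 0, "purity_shape1/2", "must be > 0")
  chk(cfg$age_min >= 0L && cfg$age_max >= cfg$age_min, "age_min/age_max",
      "need 0 <= age_min <= age_max")
  chk(cfg$sex_p >= 0 && cfg$sex_p <= 1, "sex_p", "must be in [0, 1]")
  chk(cfg$clonality_driver_gene %in% cfg$driver_genes, "clonality_driver_gene",
      "must be one of driver_genes")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n <- sum(rep_len(x$samples_per_type, x$n_cancer_types))
  cat(sprintf("Synthetic cohort config: %d cancer types, %d samples, seed %d\n",
              x$n_cancer_types, n, x$seed))
  cat(sprintf("  signatures: %s; %d background genes\n",
              paste(sprintf("%s(%d)", names(x$signatures), x$signatures),
                    collapse = ", "), x$n_background_genes))
  planted <- x$feature_slopes[x$feature_slopes != 0]
  cat(sprintf("  planted feature slopes: %s\n",
              if (length(planted)) paste(sprintf("%s=%.3g", names(planted), planted),
                                         collapse = ", ") else "none"))
  invisible(x)
}
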