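# Covariate metadata and simulation configuration for the synthetic
# multimorbidity cohort.

#' Risk-factor levels and baselines used throughout the package
#'
#' Categorical risk factors with their levels, first level = baseline:
#' never smoker, rarely drink, brisk walking pace, no diabetes, degree-level
#' education, minimum deprivation tertile, and (women only) no HRT use and
#' no children.
#'
#' @return Named list of character level vectors.
#' @export
risk_factor_levels <- function() {
  list(
    smoking     = c("never", "previous", "current"),
    alcohol     = c("rarely", "sometimes", "regularly"),
    pace        = c("brisk", "average", "slow"),
    diabetes    = c("no", "yes"),
    education   = c("degree", "post16", "age16"),
    deprivation = c("depriv1", "depriv2", "depriv3"),
    hrt         = c("no", "yes"),
    children    = c("no", "yes")
  )
}

women_only_factors <- function() c("hrt", "children")

continuous_factors <- function() c("bmi", "height", "sbp")

# Dummy-indicator names for the non-baseline levels of a factor.
factor_dummies <- function(fac) {
  lv <- risk_factor_levels()[[fac]]
  paste(fac, lv[-1], sep = "_")
}

#' Model terms of the per-disease proportional hazards model
#'
#' Returns the ordered coefficient names of the sex-specific Cox model.
#' Continuous measures (BMI, height, SBP) enter either as jointly
#' standardised linear terms (`coding = "linear"`) or as sex-specific
#' tertile indicators with the bottom tertile as baseline
#' (`coding = "tertile"`).  Categorical factors enter as treatment-coded
#' indicators against the baselines of [risk_factor_levels()].  Adjustment
#' covariates (education, deprivation, entry age, and for women HRT and
#' children) are fitted but excluded from the default comparison subset.
#'
#' @param sex `"male"` or `"female"`.
#' @param coding `"linear"` or `"tertile"` coding of the continuous measures.
#' @return Character vector of coefficient names, in model order.
#' @seealso [comparison_terms()]
#' @export
model_terms <- function(sex = c("male", "female"),
                        coding = c("linear", "tertile")) {
  sex <- match.arg(sex)
  coding <- match.arg(coding)
  cont <- if (coding == "linear") {
    continuous_factors()
  } else {
    as.vector(vapply(continuous_factors(),
                     function(v) paste0(v, c("_t2", "_t3")), character(2)))
  }
  terms <- c(cont,
             factor_dummies("smoking"), factor_dummies("alcohol"),
             factor_dummies("pace"), factor_dummies("diabetes"),
             factor_dummies("education"), factor_dummies("deprivation"))
  if (sex == "female") {
    terms <- c(terms, factor_dummies("hrt"), factor_dummies("children"))
  }
  c(terms, "entry_age")
}

#' Default comparison subset for marginalisation
#'
#' The six strong, biologically meaningful comparison parameters used for
#' between-sex tests, identification and clustering: BMI, height, SBP,
#' slow (versus brisk) walking pace, regular (versus rare) drinking, and
#' current (versus never) smoking.  Under tertile coding the three
#' continuous measures are represented by their top-versus-bottom tertile
#' contrasts.
#'
#' @inheritParams model_terms
#' @param drop_bmi Drop the BMI coordinate (used by the sensitivity rerun
#'   of the sex-difference scan without BMI).
#' @return Character vector of six (or five) coefficient names.
#' @export
comparison_terms <- function(coding = c("linear", "tertile"), drop_bmi = FALSE) {
  coding <- match.arg(coding)
  cont <- if (coding == "linear") c("bmi", "height", "sbp")
          else c("bmi_t3", "height_t3", "sbp_t3")
  out <- c(cont, "pace_slow", "alcohol_regularly", "smoking_current")
  if (drop_bmi) out <- out[-1]
  out
}

#' Define a synthetic disease by its planted risk profile
#'
#' A disease profile fixes the true log hazard ratios of the
#' data-generating proportional hazards model for one disease, per sex,
#' together with its per-year baseline hazard (optionally one rate per
#' year-of-birth stratum) and a planted cluster label used as ground truth
#' by recovery tests.
#'
#' @param disease_id Character label.
#' @param cluster_id Planted ground-truth cluster label.
#' @param effects Named numeric vector of true log hazard ratios; names
#'   must be model terms (see [model_terms()]); omitted terms are zero.
#' @param female_effects Optional named numeric vector of *additive*
#'   modifications applied to `effects` for women only (e.g.
#'   `c(bmi = 0.3)` plants a sex-specific BMI association).  Women-only
#'   terms (`hrt_yes`, `children_yes`) may only appear here.
#' @param baseline_rate Per-year baseline hazard; scalar, or one value per
#'   year-of-birth stratum.  Must be positive.
#' @return An object of class `disease_profile`.
#' @export
disease_profile <- function(disease_id, cluster_id = disease_id,
                            effects = numeric(0), female_effects = NULL,
                            baseline_rate = 2e-3) {
  stopifnot(is.character(disease_id), length(disease_id) == 1L)
  male_terms <- model_terms("male")
  female_terms <- model_terms("female")
  chk <- function(x, valid, what) {
    if (length(x) && (is.null(names(x)) || !all(names(x) %in% valid))) {
      bad <- setdiff(names(x) %||% "<unnamed>", valid)
      stop("unknown ", what, " term(s): ", paste(bad, collapse = ", "),
           "; valid terms are: ", paste(valid, collapse = ", "), call. = FALSE)
    }
  }
  chk(effects, male_terms, "shared effect")
  chk(female_effects, female_terms, "female effect")
  if (any(!is.finite(c(effects, female_effects)))) {
    stop("effects must be finite", call. = FALSE)
  }
  if (any(baseline_rate <= 0) || any(!is.finite(baseline_rate))) {
    stop("baseline_rate must be positive and finite", call. = FALSE)
  }
  beta_male <- setNames(numeric(length(male_terms)), male_terms)
  beta_male[names(effects)] <- effects
  beta_female <- setNames(numeric(length(female_terms)), female_terms)
  beta_female[male_terms] <- beta_male
  if (!is.null(female_effects)) {
    beta_female[names(female_effects)] <-
      beta_female[names(female_effects)] + female_effects
  }
  structure(
    list(disease_id = disease_id,
         cluster_id = as.character(cluster_id),
         beta_male = beta_male,
         beta_female = beta_female,
         baseline_rate = as.numeric(baseline_rate),
         sex_specific = !all(beta_female[male_terms] == beta_male)),
    class = "disease_profile")
}

#' @export
print.disease_profile <- function(x, ...) {
  nz <- x$beta_male[x$beta_male != 0]
  cat("Disease profile ", x$disease_id, " (cluster ", x$cluster_id, ")\n",
      sep = "")
  cat("  baseline rate/yr:", paste(signif(x$baseline_rate, 3), collapse = ", "),
      "\n")
  if (length(nz)) {
    cat("  non-zero log HRs:",
        paste(names(nz), signif(nz, 3), sep = "=", collapse = ", "), "\n")
  }
  if (x$sex_specific) cat("  sex-specific profile (female differs)\n")
  invisible(x)
}

#' Default covariate distributions of the synthetic cohort
#'
#' Plausible per-sex means/SDs of the raw continuous measures (before
#' joint standardisation) and level frequencies of the categorical risk
#' factors for a middle-aged population cohort.  Override individual
#' entries via the corresponding [cohort_config()] arguments.
#'
#' @return A named list, one entry per factor, each with per-sex values.
#' @export
default_continuous_params <- function() {
  list(
    bmi    = list(male = c(mean = 27.8, sd = 4.2),
                  female = c(mean = 27.1, sd = 5.1)),
    height = list(male = c(mean = 175.5, sd = 6.8),
                  female = c(mean = 162.5, sd = 6.2)),
    sbp    = list(male = c(mean = 141, sd = 17),
                  female = c(mean = 135, sd = 19))
  )
}

#' @rdname default_continuous_params
#' @export
default_categorical_probs <- function() {
  list(
    smoking     = list(male = c(never = 0.55, previous = 0.35, current = 0.10),
                       female = c(never = 0.60, previous = 0.30, current = 0.10)),
    alcohol     = list(male = c(rarely = 0.25, sometimes = 0.25, regularly = 0.50),
                       female = c(rarely = 0.35, sometimes = 0.25, regularly = 0.40)),
    pace        = list(male = c(brisk = 0.40, average = 0.52, slow = 0.08),
                       female = c(brisk = 0.40, average = 0.52, slow = 0.08)),
    diabetes    = list(male = c(no = 0.94, yes = 0.06),
                       female = c(no = 0.96, yes = 0.04)),
    education   = list(male = c(degree = 0.33, post16 = 0.40, age16 = 0.27),
                       female = c(degree = 0.33, post16 = 0.40, age16 = 0.27)),
    deprivation = list(male = c(depriv1 = 1, depriv2 = 1, depriv3 = 1) / 3,
                       female = c(depriv1 = 1, depriv2 = 1, depriv3 = 1) / 3),
    hrt         = list(female = c(no = 0.63, yes = 0.37)),
    children    = list(female = c(no = 0.15, yes = 0.85))
  )
}

#' Configure a synthetic cohort simulation
#'
#' Bundles everything [simulate_cohort()] needs: cohort size, seed, entry-age
#' range, administrative follow-up, year-of-birth stratification, the
#' competing cancer-censoring hazard, covariate distributions per sex, and
#' the list of [disease_profile()]s whose events are generated.
#'
#' @param n_participants Number of participants (> 0).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param disease_profiles Non-empty list of [disease_profile()] objects.
#' @param entry_age_range Two ages (years) between which entry ages are
#'   drawn uniformly; default 40--69.
#' @param study_end_age_offset Administrative follow-up after entry (years).
#' @param yob_strata Number of year-of-birth strata (entry-age bands).
#' @param cancer_hazard Per-year rate of the competing cancer event that
#'   right-censors all subsequent disease events.
#' @param onset_age Age (years) at which the disease hazards switch on
#'   (the baseline is piecewise-constant: zero before `onset_age`,
#'   per-stratum rates after).  Defaults to the lower entry age, so that
#'   pre-entry (prevalent) disease burden stays at realistic levels for
#'   age-related diseases in a middle-aged cohort.
#' @param continuous_factor_params Per-factor, per-sex mean/SD of the raw
#'   continuous measures before joint (both-sex) standardisation.
#' @param categorical_factor_probs Per-factor, per-sex level probabilities;
#'   each probability vector must sum to one.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants, seed, disease_profiles,
                          entry_age_range = c(40, 69),
                          study_end_age_offset = 10,
                          yob_strata = 3,
                          cancer_hazard = 5e-3,
                          onset_age = NULL,
                          continuous_factor_params = default_continuous_params(),
                          categorical_factor_probs = default_categorical_probs()) {
  stopifnot(length(n_participants) == 1L, n_participants > 0,
            length(seed) == 1L, is.finite(seed))
  if (!length(disease_profiles)) {
    stop("disease_profiles must be a non-empty list", call. = FALSE)
  }
  if (!all(vapply(disease_profiles, inherits, logical(1), "disease_profile"))) {
    stop("disease_profiles must all be disease_profile objects", call. = FALSE)
  }
  ids <- vapply(disease_profiles, `[[`, character(1), "disease_id")
  if (anyDuplicated(ids)) stop("duplicate disease ids", call. = FALSE)
  if (length(entry_age_range) != 2L || entry_age_range[1] >= entry_age_range[2] ||
      entry_age_range[1] <= 0 || entry_age_range[2] >= 120) {
    stop("entry_age_range must be increasing and within (0, 120)", call. = FALSE)
  }
  stopifnot(study_end_age_offset > 0, yob_strata >= 1,
            cancer_hazard >= 0)
  onset_age <- onset_age %||% entry_age_range[1]
  if (onset_age < 0 || onset_age > entry_age_range[1]) {
    stop("onset_age must lie in [0, min entry age]", call. = FALSE)
  }
  for (pr in disease_profiles) {
    if (!length(pr$baseline_rate) %in% c(1L, yob_strata)) {
      stop("baseline_rate of disease ", pr$disease_id,
           " must have length 1 or yob_strata", call. = FALSE)
    }
  }
  lv <- risk_factor_levels()
  for (fac in names(categorical_factor_probs)) {
    for (sx in names(categorical_factor_probs[[fac]])) {
      p <- categorical_factor_probs[[fac]][[sx]]
      if (abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
        stop("level probabilities of ", fac, " (", sx,
             ") must be non-negative and sum to 1", call. = FALSE)
      }
      if (!identical(names(p), lv[[fac]])) {
        stop("probabilities of ", fac, " must be named by its levels in order: ",
             paste(lv[[fac]], collapse = ", "), call. = FALSE)
      }
    }
  }
  names(disease_profiles) <- ids
  structure(
    list(n_participants = as.integer(n_participants),
         seed = as.integer(seed),
         disease_profiles = disease_profiles,
         entry_age_range = as.numeric(entry_age_range),
         study_end_age_offset = as.numeric(study_end_age_offset),
         yob_strata = as.integer(yob_strata),
         cancer_hazard = as.numeric(cancer_hazard),
         onset_age = as.numeric(onset_age),
         continuous_factor_params = continuous_factor_params,
         categorical_factor_probs = categorical_factor_probs),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  participants:", x$n_participants, " seed:", x$seed, "\n")
  cat("  entry ages:", paste(x$entry_age_range, collapse = "-"),
      " follow-up:", x$study_end_age_offset, "y ",
      " YOB strata:", x$yob_strata, "\n")
  cat("  diseases:", length(x$disease_profiles),
      " planted clusters:",
      length(unique(vapply(x$disease_profiles, `[[`, character(1),
                           "cluster_id"))), "\n")
  cat("  cancer (competing censoring) hazard:", x$cancer_hazard, "/yr\n")
  invisible(x)
}

#' Generate a battery of disease profiles with planted cluster structure
#'
#' Draws `n_clusters` cluster centres in the six-dimensional comparison
#' space (see [comparison_terms()]) and jitters each disease around its
#' centre, enforcing minimum separations so that the planted structure is
#' recoverable: cluster centres at least `min_cluster_sep` apart and any
#' two realised per-sex profiles of different diseases at least
#' `min_disease_sep` apart.  A fraction of diseases receives a
#' sex-specific BMI association (`+/- bmi_shift` for women), mirroring the
#' strongly sex-dependent BMI associations seen for a minority of real
#' diseases.
#'
#' Separations are measured in *information-weighted* coordinates: each
#' log-hazard-ratio difference is scaled by the SD of its covariate (1 for
#' the standardised continuous measures, \eqn{\sqrt{\pi(1-\pi)}} for an
#' indicator with prevalence \eqn{\pi}), because a log hazard ratio on a
#' rare level is estimated with proportionally larger uncertainty.  A
#' separation floor in these units therefore guarantees statistical, not
#' merely numerical, distinguishability at a given case count.
#'
#' @param n_diseases,n_clusters Number of diseases and planted clusters.
#' @param seed Integer seed for profile generation.
#' @param center_sd SD of cluster-centre coordinates (log hazard ratio).
#' @param jitter_sd SD of per-disease jitter around its centre.
#' @param min_cluster_sep,min_disease_sep Separation floors between cluster
#'   centres / realised per-sex disease profiles, in information-weighted
#'   units; enforced by resampling.
#' @param coord_weights Covariate SDs used for the information weighting,
#'   named by [comparison_terms()]; defaults match
#'   [default_categorical_probs()].
#' @param frac_sex_specific Fraction of diseases given a sex-specific BMI
#'   effect; signs alternate.
#' @param bmi_shift Magnitude of the planted female-minus-male BMI
#'   difference (log hazard ratio per SD).
#' @param rate_range Range of per-disease per-year baseline hazards.
#' @param stratum_multipliers Baseline-rate multipliers per year-of-birth
#'   stratum (makes stratification in fitting non-trivial).
#' @return List of [disease_profile()] objects.
#' @export
planted_profiles <- function(n_diseases = 100, n_clusters = 12, seed = 1,
                             center_sd = 1.1, jitter_sd = 0.3,
                             min_cluster_sep = 1.6, min_disease_sep = 0.5,
                             coord_weights = NULL,
                             frac_sex_specific = 0.05, bmi_shift = 0.3,
                             rate_range = c(4e-3, 8e-3),
                             stratum_multipliers = c(0.8, 1, 1.25)) {
  stopifnot(n_diseases >= 1, n_clusters >= 1, n_clusters <= n_diseases)
  terms6 <- comparison_terms("linear")
  p <- length(terms6)
  if (is.null(coord_weights)) {
    # SDs of the default covariates: continuous are standardised; the
    # indicator prevalences come from default_categorical_probs()
    coord_weights <- c(bmi = 1, height = 1, sbp = 1,
                       pace_slow = sqrt(0.08 * 0.92),
                       alcohol_regularly = sqrt(0.45 * 0.55),
                       smoking_current = sqrt(0.10 * 0.90))
  }
  w <- coord_weights[terms6]
  stopifnot(all(is.finite(w)), all(w > 0))
  wdist <- function(m) dist(sweep(m, 2, w, "*"))
  with_seed(seed, {
    # Cluster centres with a separation floor (resample violators).
    centers <- matrix(rnorm(n_clusters * p, sd = center_sd), n_clusters, p)
    bad <- integer(0)
    for (iter in seq_len(2000)) {
      d <- as.matrix(wdist(centers))
      diag(d) <- Inf
      bad <- which(apply(d, 1, min) < min_cluster_sep)
      if (!length(bad)) break
      centers[bad[1], ] <- rnorm(p, sd = center_sd)
    }
    if (length(bad)) {
      stop("could not place ", n_clusters, " cluster centres at separation ",
           min_cluster_sep, "; lower min_cluster_sep or raise center_sd",
           call. = FALSE)
    }
    cluster_of <- rep_len(seq_len(n_clusters), n_diseases)
    betas <- centers[cluster_of, , drop = FALSE] +
      matrix(rnorm(n_diseases * p, sd = jitter_sd), n_diseases, p)
    n_ss <- round(frac_sex_specific * n_diseases)
    sex_specific <- seq_len(n_diseases) %in%
      (if (n_ss > 0) round(seq(1, n_diseases, length.out = n_ss)) else integer(0))
    shift <- ifelse(seq_len(n_diseases) %% 2 == 0, bmi_shift, -bmi_shift)
    # Enforce separation between realised per-sex profiles of distinct
    # diseases (female profiles include any planted BMI shift).
    realised <- function() {
      fem <- betas
      fem[sex_specific, 1] <- fem[sex_specific, 1] + shift[sex_specific]
      rbind(betas, fem)
    }
    viol <- integer(0)
    for (iter in seq_len(5000)) {
      rl <- realised()
      d <- as.matrix(wdist(rl))
      diag(d) <- Inf
      did <- rep(seq_len(n_diseases), 2)
      same <- outer(did, did, "==")
      d[same] <- Inf
      viol <- which(apply(d, 1, min) < min_disease_sep)
      if (!length(viol)) break
      i <- ((viol[1] - 1) %% n_diseases) + 1
      betas[i, ] <- centers[cluster_of[i], ] + rnorm(p, sd = jitter_sd)
    }
    if (length(viol)) {
      stop("could not separate disease profiles by ", min_disease_sep,
           "; lower min_disease_sep or n_diseases", call. = FALSE)
    }
    rates <- runif(n_diseases, rate_range[1], rate_range[2])
    width <- max(2L, nchar(as.character(n_diseases)))
    lapply(seq_len(n_diseases), function(i) {
      disease_profile(
        disease_id = sprintf(paste0("D%0", width, "d"), i),
        cluster_id = sprintf("C%02d", cluster_of[i]),
        effects = setNames(betas[i, ], terms6),
        female_effects = if (sex_specific[i]) c(bmi = shift[i]) else NULL,
        baseline_rate = rates[i] * stratum_multipliers)
    })
  })
}
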