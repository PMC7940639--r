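# Synthetic multimorbidity cohort generation.
#
# Events are drawn from the same model family the fitter assumes: a
# proportional hazards model on the age timescale with a piecewise-constant
# (per year-of-birth stratum) baseline hazard and a per-sex linear predictor
# beta' x.  With a constant per-stratum rate the age at first event is
# exponential given covariates, so inverse-transform sampling is exact and
# the simulator is oracle-checkable against closed forms.

#' Simulate a synthetic cohort and disease-event table
#'
#' Draws participants (entry age, year-of-birth stratum, standardised
#' continuous risk factors, categorical risk factors, women-only factors)
#' and, for every [disease_profile()] in the configuration, an age at first
#' event from a proportional hazards model with the profile's true log
#' hazard ratios.  Events before entry are retained and flagged as
#' prevalent (they are not incident observations but are needed by the
#' prior-disease sensitivity rerun); a competing cancer event censors all
#' later disease events; administrative censoring occurs at
#' `entry_age + study_end_age_offset`.
#'
#' Continuous factors are generated with sex-specific means and SDs and
#' then standardised by their joint (both-sex) mean and SD, so per-sex
#' means can differ (heights do) while the pooled scale is 0/1.
#'
#' @param config A [cohort_config()].
#' @return An object of class `riskclust_cohort`: a list with
#'   `participants` (one row per participant, including `cancer_age` where
#'   a cancer censoring event occurred during follow-up), `events`
#'   (participant_id, disease_id, event_age, prevalent) and the `config`.
#'   Output is byte-identical for a fixed seed.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    sex <- sample(c("male", "female"), n, replace = TRUE)
    entry_age <- runif(n, config$entry_age_range[1], config$entry_age_range[2])
    end_age <- entry_age + config$study_end_age_offset

    # Year-of-birth strata: with a narrow recruitment window, birth year is
    # (up to a constant) the negative of entry age, so strata are
    # equal-width entry-age bands; stratum 1 = earliest births (oldest).
    breaks <- seq(config$entry_age_range[1], config$entry_age_range[2],
                  length.out = config$yob_strata + 1)
    band <- findInterval(entry_age, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
    yob_stratum <- config$yob_strata + 1L - band

    participants <- data.frame(
      id = seq_len(n), sex = sex, yob_stratum = yob_stratum,
      entry_age = entry_age, end_age = end_age,
      stringsAsFactors = FALSE)

    for (v in continuous_factors()) {
      pars <- config$continuous_factor_params[[v]]
      raw <- numeric(n)
      raw[sex == "male"] <- rnorm(sum(sex == "male"),
                                  pars$male["mean"], pars$male["sd"])
      raw[sex == "female"] <- rnorm(sum(sex == "female"),
                                    pars$female["mean"], pars$female["sd"])
      participants[[v]] <- (raw - mean(raw)) / sd(raw)
    }

    lv <- risk_factor_levels()
    for (fac in setdiff(names(config$categorical_factor_probs),
                        women_only_factors())) {
      pr <- config$categorical_factor_probs[[fac]]
      x <- character(n)
      x[sex == "male"] <- sample(lv[[fac]], sum(sex == "male"),
                                 replace = TRUE, prob = pr$male)
      x[sex == "female"] <- sample(lv[[fac]], sum(sex == "female"),
                                   replace = TRUE, prob = pr$female)
      participants[[fac]] <- x
    }
    for (fac in women_only_factors()) {
      pr <- config$categorical_factor_probs[[fac]]
      x <- rep(NA_character_, n)
      x[sex == "female"] <- sample(lv[[fac]], sum(sex == "female"),
                                   replace = TRUE, prob = pr$female)
      participants[[fac]] <- x
    }

    # Competing cancer event: an independent exponential clock started at
    # entry; only occurrences inside the administrative follow-up matter.
    if (config$cancer_hazard > 0) {
      cancer_age <- entry_age + rexp(n, rate = config$cancer_hazard)
      cancer_age[cancer_age > end_age] <- NA_real_
    } else {
      cancer_age <- rep(NA_real_, n)
    }
    participants$cancer_age <- cancer_age
    censor_age <- pmin(end_age, cancer_age, na.rm = TRUE)

    Xm <- risk_model_matrix(participants[sex == "male", ], "male", "linear")
    Xf <- risk_model_matrix(participants[sex == "female", ], "female", "linear")

    ev_list <- vector("list", length(config$disease_profiles))
    for (k in seq_along(config$disease_profiles)) {
      pr <- config$disease_profiles[[k]]
      rate_strat <- rep_len(pr$baseline_rate, config$yob_strata)
      lp <- numeric(n)
      lp[sex == "male"] <- drop(Xm %*% pr$beta_male[colnames(Xm)])
      lp[sex == "female"] <- drop(Xf %*% pr$beta_female[colnames(Xf)])
      rate <- rate_strat[yob_stratum] * exp(lp)
      t_event <- config$onset_age + rexp(n) / rate
      prevalent <- t_event <= entry_age
      incident <- !prevalent & t_event <= censor_age
      keep <- prevalent | incident
      if (any(keep)) {
        ev_list[[k]] <- data.frame(
          participant_id = participants$id[keep],
          disease_id = pr$disease_id,
          event_age = t_event[keep],
          prevalent = prevalent[keep],
          stringsAsFactors = FALSE)
      }
    }
    events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
    if (is.null(events)) {
      events <- data.frame(participant_id = integer(0),
                           disease_id = character(0),
                           event_age = numeric(0), prevalent = logical(0))
    }
    rownames(events) <- NULL
    structure(list(participants = participants, events = events,
                   config = config),
              class = "riskclust_cohort")
  })
}

#' @export
print.riskclust_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$participants), "participants (",
      sum(x$participants$sex == "male"), "male /",
      sum(x$participants$sex == "female"), "female )\n")
  inc <- !x$events$prevalent
  cat("  incident events:", sum(inc), "over",
      length(unique(x$events$disease_id)), "diseases;",
      sum(x$events$prevalent), "prevalent records\n")
  cat("  cancer-censored participants:", sum(!is.na(x$participants$cancer_age)),
      "\n")
  invisible(x)
}

#' @export
summary.riskclust_cohort <- function(object, ...) {
  inc <- object$events[!object$events$prevalent, ]
  counts <- table(disease = inc$disease_id,
                  sex = object$participants$sex[inc$participant_id])
  out <- list(n = nrow(object$participants),
              case_counts = counts,
              follow_up = object$config$study_end_age_offset)
  class(out) <- "summary.riskclust_cohort"
  out
}

#' @export
print.summary.riskclust_cohort <- function(x, ...) {
  cat("Cohort of", x$n, "participants,", x$follow_up, "years follow-up\n")
  cc <- as.data.frame(x$case_counts)
  cat("incident case counts per disease-sex: median",
      stats::median(cc$Freq), ", range",
      paste(range(cc$Freq), collapse = "-"), "\n")
  invisible(x)
}

#' Ground truth behind a simulated cohort
#'
#' Exports one row per disease and sex with the planted cluster label and
#' the true log-hazard-ratio vector, in the covariate order used by the
#' cohort and the fitter (men's rows carry `NA` for the women-only terms).
#'
#' @param config A [cohort_config()].
#' @return A data.frame with columns `disease_id`, `sex`, `cluster_id`,
#'   `sex_specific`, then one column per model term.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  terms_f <- model_terms("female")
  terms_m <- model_terms("male")
  rows <- lapply(config$disease_profiles, function(pr) {
    bm <- setNames(rep(NA_real_, length(terms_f)), terms_f)
    bm[terms_m] <- pr$beta_male
    rbind(
      data.frame(disease_id = pr$disease_id, sex = "male",
                 cluster_id = pr$cluster_id, sex_specific = pr$sex_specific,
                 t(bm), check.names = FALSE),
      data.frame(disease_id = pr$disease_id, sex = "female",
                 cluster_id = pr$cluster_id, sex_specific = pr$sex_specific,
                 t(pr$beta_female[terms_f]), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Numeric model matrix (treatment-coded indicators, canonical term names)
# for the participants of one sex.  Tertile cut points for the continuous
# measures are computed within sex, as in the tertile sensitivity model.
risk_model_matrix <- function(pp, sex, coding) {
  terms <- model_terms(sex, coding)
  X <- matrix(0, nrow(pp), length(terms), dimnames = list(NULL, terms))
  if (coding == "linear") {
    for (v in continuous_factors()) X[, v] <- pp[[v]]
  } else {
    for (v in continuous_factors()) {
      qs <- quantile(pp[[v]], c(1 / 3, 2 / 3), names = FALSE)
      ter <- findInterval(pp[[v]], qs) + 1L
      X[, paste0(v, "_t2")] <- as.numeric(ter == 2L)
      X[, paste0(v, "_t3")] <- as.numeric(ter == 3L)
    }
  }
  lv <- risk_factor_levels()
  facs <- c("smoking", "alcohol", "pace", "diabetes", "education",
            "deprivation")
  if (sex == "female") facs <- c(facs, women_only_factors())
  for (fac in facs) {
    for (level in lv[[fac]][-1]) {
      X[, paste(fac, level, sep = "_")] <- as.numeric(pp[[fac]] == level)
    }
  }
  X[, "entry_age"] <- pp$entry_age
  X
}

#' Write / read a cohort as delimited text
#'
#' Persists a simulated cohort as `participants.csv`, `events.csv`, the
#' configuration as `config.json`, and a `manifest.json` recording the seed
#' and a 32-bit configuration fingerprint.  `read_cohort()` restores an
#' object usable by [fit_disease_models()]; any external data matching the
#' same schema can be read the same way.
#'
#' @param cohort A `riskclust_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `riskclust_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "riskclust_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  write.csv(cohort$events, file.path(dir, "events.csv"), row.names = FALSE)
  cfg <- cohort$config
  # named numeric vectors must become JSON objects, not nameless arrays
  namedl <- function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else if (is.list(x) && !is.data.frame(x)) lapply(x, namedl)
    else x
  }
  cfg_json <- jsonlite::toJSON(
    namedl(list(n_participants = cfg$n_participants, seed = cfg$seed,
         entry_age_range = cfg$entry_age_range,
         study_end_age_offset = cfg$study_end_age_offset,
         yob_strata = cfg$yob_strata, cancer_hazard = cfg$cancer_hazard,
         onset_age = cfg$onset_age,
         continuous_factor_params = cfg$continuous_factor_params,
         categorical_factor_probs = cfg$categorical_factor_probs,
         disease_profiles = lapply(unname(cfg$disease_profiles), unclass))),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(cfg_json, file.path(dir, "config.json"))
  manifest <- jsonlite::toJSON(
    list(seed = cfg$seed, config_hash = fnv1a32(cfg_json),
         n_participants = cfg$n_participants,
         n_diseases = length(cfg$disease_profiles)),
    auto_unbox = TRUE, pretty = TRUE)
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pp <- read.csv(file.path(dir, "participants.csv"), stringsAsFactors = FALSE)
  ev <- read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  config <- NULL
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    cj <- jsonlite::fromJSON(cfg_path, simplifyVector = FALSE)
    profiles <- lapply(cj$disease_profiles, function(row) {
      structure(list(
        disease_id = row$disease_id, cluster_id = row$cluster_id,
        beta_male = unlist(row$beta_male),
        beta_female = unlist(row$beta_female),
        baseline_rate = as.numeric(unlist(row$baseline_rate)),
        sex_specific = isTRUE(row$sex_specific)), class = "disease_profile")
    })
    config <- cohort_config(
      n_participants = cj$n_participants, seed = cj$seed,
      disease_profiles = profiles,
      entry_age_range = as.numeric(unlist(cj$entry_age_range)),
      study_end_age_offset = cj$study_end_age_offset,
      yob_strata = cj$yob_strata, cancer_hazard = cj$cancer_hazard,
      onset_age = cj$onset_age,
      continuous_factor_params = lapply(cj$continuous_factor_params,
                                        function(f) lapply(f, unlist)),
      categorical_factor_probs = lapply(cj$categorical_factor_probs,
                                        function(f) lapply(f, unlist)))
  }
  structure(list(participants = pp, events = ev, config = config),
            class = "riskclust_cohort")
}
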