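# Per-disease, per-sex proportional hazards fitting and the statistical
# inclusion cascade.

#' Fit the proportional hazards model for one disease and sex
#'
#' Fits a Cox model on the age timescale, left-truncated at entry age,
#' stratified by year-of-birth stratum, right-censored at the
#' administrative end of follow-up or at a prior cancer event, with Efron
#' handling of ties.  Women's models additionally include the HRT and
#' children terms.  Continuous measures enter linearly (jointly
#' standardised) or, under `coding = "tertile"`, as sex-specific tertile
#' indicators.
#'
#' A disease with fewer than `min_cases` incident cases is not fitted and
#' is marked failed with reason `"insufficient cases"`; non-convergence,
#' undefined coefficients or a non-positive-definite covariance give
#' reason `"fit failure"`.
#'
#' @param cohort A `riskclust_cohort` (simulated or read from CSV).
#' @param disease_id Disease to fit (opaque label; must occur in the
#'   event table).
#' @param sex `"male"` or `"female"`.
#' @param coding Coding of continuous measures, see [model_terms()].
#' @param exclusions Optional character vector of disease ids: participants
#'   with a prevalent event for any of these diseases, or an incident event
#'   for one of them before the end of their own follow-up for
#'   `disease_id`, are dropped before fitting (prior-disease sensitivity
#'   rerun).
#' @param min_cases Case floor below which the fit is not attempted.
#' @param ph_test Run the global Schoenfeld-residual proportional hazards
#'   test and store its p-value (skippable to save time in replicate
#'   batteries).
#' @return An object of class `disease_fit` with elements `disease_id`,
#'   `sex`, `ok`, `reason`, `n_cases`, `n_at_risk`, `mu_hat` (named MLE
#'   vector), `sigma_hat` (its covariance), `covariate_names`,
#'   `global_chi2_p`, `ph_test_p`, `ph_global` and `coding`.
#' @export
fit_disease <- function(cohort, disease_id, sex = c("male", "female"),
                        coding = c("linear", "tertile"),
                        exclusions = NULL, min_cases = 50L, ph_test = TRUE) {
  sex <- match.arg(sex)
  coding <- match.arg(coding)
  stopifnot(inherits(cohort, "riskclust_cohort"))
  pp <- cohort$participants[cohort$participants$sex == sex, , drop = FALSE]
  if (!nrow(pp)) stop("cohort contains no ", sex, " participants", call. = FALSE)
  ev <- cohort$events

  # prevalent cases of this disease cannot have an incident first event and
  # are not part of the left-truncated risk set
  prev_ids <- ev$participant_id[ev$disease_id == disease_id & ev$prevalent]
  if (length(prev_ids)) pp <- pp[!pp$id %in% prev_ids, , drop = FALSE]

  stop_age <- pmin(pp$end_age, pp$cancer_age, na.rm = TRUE)
  own <- ev[ev$disease_id == disease_id & !ev$prevalent &
              ev$participant_id %in% pp$id, , drop = FALSE]
  idx <- match(own$participant_id, pp$id)
  status <- integer(nrow(pp))
  stop_age[idx] <- own$event_age
  status[idx] <- 1L

  if (!is.null(exclusions) && length(exclusions)) {
    ex <- ev[ev$disease_id %in% setdiff(exclusions, disease_id) &
               ev$participant_id %in% pp$id, , drop = FALSE]
    if (nrow(ex)) {
      cut_age <- stop_age[match(ex$participant_id, pp$id)]
      drop_ids <- unique(ex$participant_id[ex$prevalent |
                                             ex$event_age < cut_age])
      keep <- !(pp$id %in% drop_ids)
      pp <- pp[keep, , drop = FALSE]
      stop_age <- stop_age[keep]
      status <- status[keep]
    }
  }

  n_cases <- sum(status)
  base <- list(disease_id = disease_id, sex = sex, coding = coding,
               n_cases = n_cases, n_at_risk = nrow(pp),
               mu_hat = NULL, sigma_hat = NULL,
               covariate_names = model_terms(sex, coding),
               global_chi2_p = NA_real_, ph_test_p = NA_real_,
               ph_global = NULL)
  fail <- function(reason) {
    structure(c(base, list(ok = FALSE, reason = reason)),
              class = "disease_fit")
  }
  if (n_cases < min_cases) return(fail("insufficient cases"))

  X <- risk_model_matrix(pp, sex, coding)
  dat <- data.frame(X, check.names = FALSE)
  dat$.entry <- pp$entry_age
  dat$.stop <- stop_age
  dat$.status <- status
  dat$.stratum <- pp$yob_stratum
  fml <- stats::as.formula(paste(
    "survival::Surv(.entry, .stop, .status) ~",
    paste(colnames(X), collapse = " + "),
    "+ survival::strata(.stratum)"))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron", x = ph_test),
    error = function(e) NULL)
  if (is.null(fit) || any(is.na(coef(fit)))) return(fail("fit failure"))
  mu <- coef(fit)
  Sigma <- vcov(fit)
  if (!is_spd(Sigma, tol = 1e-8)) return(fail("fit failure"))

  out <- base
  out$mu_hat <- mu
  out$sigma_hat <- Sigma
  out$covariate_names <- names(mu)
  out$ok <- TRUE
  out$reason <- NA_character_
  gt <- tryCatch(chi2_quadratic(mu, Sigma), error = function(e) NULL)
  if (is.null(gt)) return(fail("fit failure"))
  out$global_chi2_p <- gt$p_value
  if (ph_test) {
    zph <- tryCatch(survival::cox.zph(fit, global = TRUE),
                    error = function(e) NULL)
    if (!is.null(zph)) {
      gl <- zph$table["GLOBAL", , drop = TRUE]
      out$ph_test_p <- unname(gl["p"])
      out$ph_global <- list(statistic = unname(gl["chisq"]),
                            df = unname(gl["df"]),
                            p_value = unname(gl["p"]))
    }
  }
  structure(out, class = "disease_fit")
}

#' @export
print.disease_fit <- function(x, ...) {
  cat("Cox fit:", x$disease_id, "(", x$sex, ",", x$coding, "coding )\n")
  if (!x$ok) {
    cat("  FAILED:", x$reason, "( n_cases =", x$n_cases, ")\n")
    return(invisible(x))
  }
  cat("  cases:", x$n_cases, "of", x$n_at_risk, "at risk\n")
  cat("  global chi-squared p:", format.pval(x$global_chi2_p, digits = 3),
      "; PH test p:", format.pval(x$ph_test_p, digits = 3), "\n")
  print(round(x$mu_hat, 3))
  invisible(x)
}

#' @export
coef.disease_fit <- function(object, ...) object$mu_hat

#' @export
vcov.disease_fit <- function(object, ...) object$sigma_hat

#' Fit all disease/sex proportional hazards models of a cohort
#'
#' Applies [fit_disease()] to every disease in the cohort's event table
#' (or a supplied subset) for each requested sex.
#'
#' @inheritParams fit_disease
#' @param diseases Character vector of disease ids; defaults to all
#'   diseases present in the event table, in order of appearance.
#' @param sexes Sexes to fit.
#' @param exclusions Optional *named list* mapping a disease id to the
#'   disease set whose prior events exclude participants from its refit.
#' @return An object of class `disease_fits`: a list of `disease_fit`
#'   objects named `"<disease>|<sex>"`, with the coding as an attribute.
#' @export
fit_disease_models <- function(cohort, coding = c("linear", "tertile"),
                               diseases = NULL,
                               sexes = c("male", "female"),
                               exclusions = NULL, min_cases = 50L,
                               ph_test = TRUE) {
  coding <- match.arg(coding)
  if (is.null(diseases)) diseases <- unique(cohort$events$disease_id)
  fits <- list()
  for (d in diseases) {
    for (s in sexes) {
      fits[[paste(d, s, sep = "|")]] <-
        fit_disease(cohort, d, s, coding = coding,
                    exclusions = exclusions[[d]],
                    min_cases = min_cases, ph_test = ph_test)
    }
  }
  structure(fits, coding = coding, class = "disease_fits")
}

#' @export
print.disease_fits <- function(x, ...) {
  ok <- vapply(x, `[[`, logical(1), "ok")
  cat("disease_fits:", length(x), "fits (",
      sum(ok), "successful ) with", attr(x, "coding"), "coding\n")
  if (any(!ok)) {
    rs <- table(vapply(x[!ok], `[[`, character(1), "reason"))
    cat("  failures:", paste(names(rs), rs, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

# Quadratic-form chi-squared test of mu' Sigma^-1 mu.
chi2_quadratic <- function(mu, Sigma, label = "covariance") {
  stat <- drop(crossprod(mu, solve_sym(Sigma, mu, label = label)))
  df <- length(mu)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Multivariate chi-squared significance test of a fitted parameter vector
#'
#' Tests whether all fitted log hazard ratios of a disease are zero, using
#' the asymptotic normality of the MLE: the statistic
#' \eqn{\hat\mu^T \Sigma^{-1} \hat\mu} is referred to a chi-squared
#' distribution with as many degrees of freedom as parameters.
#'
#' @param fit A successful `disease_fit`, or a numeric MLE vector (in which
#'   case `sigma` must be its covariance matrix).
#' @param sigma Covariance matrix when `fit` is a plain vector.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
global_significance_test <- function(fit, sigma = NULL) {
  if (inherits(fit, "disease_fit")) {
    if (!fit$ok) stop("fit failed (", fit$reason, ")", call. = FALSE)
    return(chi2_quadratic(fit$mu_hat, fit$sigma_hat))
  }
  stopifnot(is.numeric(fit), is.matrix(sigma),
            length(fit) == nrow(sigma), nrow(sigma) == ncol(sigma))
  chi2_quadratic(fit, sigma)
}

#' Global Schoenfeld-residual test of the proportional hazards assumption
#'
#' Returns the global chi-squared test computed from the Schoenfeld
#' residuals at fitting time ([fit_disease()] with `ph_test = TRUE`).
#'
#' @param fit A successful `disease_fit`.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
proportional_hazards_test <- function(fit) {
  stopifnot(inherits(fit, "disease_fit"))
  if (!fit$ok) stop("fit failed (", fit$reason, ")", call. = FALSE)
  if (is.null(fit$ph_global)) {
    stop("degenerate residuals: no proportional hazards test is stored ",
         "(was the fit run with ph_test = TRUE?)", call. = FALSE)
  }
  fit$ph_global
}

#' Screen fitted covariance matrices for extreme eigenvalues
#'
#' For each successful fit, takes the log of the largest and smallest
#' eigenvalue of its covariance matrix and flags fits whose value deviates
#' from the across-fit mean by more than `n_sd` across-fit standard
#' deviations (mean and SD computed with all fits included, i.e. outliers
#' are not removed first).  Extreme covariance eigenvalues indicate
#' excessively wide confidence intervals for some parameter combination,
#' typically from sparse categories.
#'
#' @param fits A `disease_fits` object or list of `disease_fit`s with at
#'   least 3 successful fits.
#' @param n_sd Flagging threshold in across-fit standard deviations.
#' @return A data.frame with one row per fit: `disease_id`, `sex`, the log
#'   extreme eigenvalues, and `flagged` (`NA` for failed fits).
#' @export
eigenvalue_screen <- function(fits, n_sd = 2.5) {
  fl <- if (inherits(fits, "disease_fit")) list(fits) else fits
  ok <- vapply(fl, `[[`, logical(1), "ok")
  if (sum(ok) < 3) {
    stop("eigenvalue screen undefined for fewer than 3 successful fits",
         call. = FALSE)
  }
  out <- data.frame(
    disease_id = vapply(fl, `[[`, character(1), "disease_id"),
    sex = vapply(fl, `[[`, character(1), "sex"),
    log_ev_max = NA_real_, log_ev_min = NA_real_, flagged = NA,
    stringsAsFactors = FALSE)
  for (i in which(ok)) {
    ev <- eigen((fl[[i]]$sigma_hat + t(fl[[i]]$sigma_hat)) / 2,
                symmetric = TRUE, only.values = TRUE)$values
    out$log_ev_max[i] <- log(max(ev))
    out$log_ev_min[i] <- log(min(ev))
  }
  flag_col <- function(x) {
    m <- mean(x[ok])
    s <- sd(x[ok])
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
    abs(x - m) > n_sd * s
  }
  out$flagged[ok] <- (flag_col(out$log_ev_max) | flag_col(out$log_ev_min))[ok]
  rownames(out) <- names(fl) %||% NULL
  out
}

#' Apply the statistical inclusion cascade to a set of fits
#'
#' Reproduces the disease-selection cascade: (1) successful fit with at
#' least the case-floor number of cases; (2) covariance eigenvalue screen
#' ([eigenvalue_screen()]); (3) keep diseases whose risk factors are
#' statistically significant at `alpha` after a Bonferroni adjustment of
#' the multivariate chi-squared test; (4) exclude diseases whose global
#' Schoenfeld proportional hazards test is significant at `alpha` after a
#' Benjamini-Hochberg FDR adjustment; (5) keep diseases surviving in both
#' sexes.  Adjustment families are the successfully fitted diseases within
#' each sex.
#'
#' @param fits A `disease_fits` object covering both sexes.
#' @param alpha Significance level of stages 3 and 4.
#' @return An object of class `selection_report`: list with `counts`
#'   (stage-by-sex table of surviving diseases), `excluded` (disease, sex,
#'   stage, reason), `flags` (per-fit pass/fail per stage) and `included`
#'   (character vector of unisex diseases).
#' @export
run_selection <- function(fits, alpha = 0.05) {
  stopifnot(inherits(fits, "disease_fits") || is.list(fits))
  info <- data.frame(
    disease_id = vapply(fits, `[[`, character(1), "disease_id"),
    sex = vapply(fits, `[[`, character(1), "sex"),
    ok = vapply(fits, `[[`, logical(1), "ok"),
    reason = vapply(fits, `[[`, character(1), "reason"),
    n_cases = vapply(fits, `[[`, numeric(1), "n_cases"),
    global_p = vapply(fits, `[[`, numeric(1), "global_chi2_p"),
    ph_p = vapply(fits, `[[`, numeric(1), "ph_test_p"),
    stringsAsFactors = FALSE)
  info$pass_fit <- info$ok
  info$pass_eigen <- NA
  info$pass_signif <- NA
  info$pass_ph <- NA

  for (s in unique(info$sex)) {
    in_sex <- info$sex == s
    if (sum(info$ok & in_sex) >= 3) {
      scr <- eigenvalue_screen(fits[in_sex])
      info$pass_eigen[in_sex] <- info$pass_fit[in_sex] & !scr$flagged
    } else {
      # screen undefined with < 3 successful fits; pass through
      info$pass_eigen[in_sex] <- info$pass_fit[in_sex]
    }
    fam <- in_sex & info$pass_eigen
    if (any(fam)) {
      adj <- p.adjust(info$global_p[fam], method = "bonferroni")
      info$pass_signif[fam] <- adj < alpha
      fam2 <- fam & info$pass_signif %in% TRUE
      if (any(fam2)) {
        q <- p.adjust(info$ph_p[fam2], method = "BH")
        info$pass_ph[fam2] <- !is.na(q) & q >= alpha
      }
    }
  }
  info$pass_eigen <- info$pass_eigen %in% TRUE & info$pass_fit
  info$pass_signif <- info$pass_signif %in% TRUE & info$pass_eigen
  info$pass_ph <- info$pass_ph %in% TRUE & info$pass_signif

  surv_by_sex <- function(pass) {
    vapply(c("male", "female"), function(s) sum(pass & info$sex == s),
           numeric(1))
  }
  per_sex_final <- split(info$disease_id[info$pass_ph], info$sex[info$pass_ph])
  included <- intersect(per_sex_final$male %||% character(0),
                        per_sex_final$female %||% character(0))
  info$pass_unisex <- info$pass_ph & info$disease_id %in% included

  counts <- rbind(
    diseases_fitted = surv_by_sex(rep(TRUE, nrow(info))),
    successful_fit = surv_by_sex(info$pass_fit),
    eigenvalue_screen = surv_by_sex(info$pass_eigen),
    bonferroni_significant = surv_by_sex(info$pass_signif),
    proportional_hazards = surv_by_sex(info$pass_ph),
    unisex = surv_by_sex(info$pass_unisex))

  stage_of <- function(row) {
    if (!row$pass_fit) return(c("successful_fit", row$reason))
    if (!row$pass_eigen) return(c("eigenvalue_screen", "extreme eigenvalue"))
    if (!row$pass_signif) return(c("bonferroni_significant",
                                   "not significant after Bonferroni"))
    if (!row$pass_ph) return(c("proportional_hazards",
                               "PH deviation significant after FDR"))
    if (!row$pass_unisex) return(c("unisex", "absent in other sex"))
    c(NA_character_, NA_character_)
  }
  st <- t(vapply(seq_len(nrow(info)), function(i) stage_of(info[i, ]),
                 character(2)))
  excluded <- data.frame(disease_id = info$disease_id, sex = info$sex,
                         stage = st[, 1], reason = st[, 2],
                         stringsAsFactors = FALSE)
  excluded <- excluded[!is.na(excluded$stage), , drop = FALSE]
  rownames(excluded) <- NULL
  structure(list(counts = counts, excluded = excluded, flags = info,
                 included = included, alpha = alpha),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Statistical inclusion cascade (alpha =", x$alpha, ")\n")
  print(x$counts)
  cat("unisex disease set:", length(x$included), "diseases\n")
  invisible(x)
}
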