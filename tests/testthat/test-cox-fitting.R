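# A single planted-effect cohort shared by several fitting tests.
planted_fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pr <- list(disease_profile(
        "A", effects = c(bmi = log(2), sbp = 0.3, smoking_current = -0.5),
        baseline_rate = 1.2e-2))
      cfg <- quick_config(pr, n = 25000, seed = 77)
      co <- simulate_cohort(cfg)
      cache <<- list(cohort = co,
                     fit = fit_disease(co, "A", "male"))
    }
    cache
  }
})

test_that("fitted log hazard ratios recover the planted effects", {
  fx <- planted_fit_fixture()
  f <- fx$fit
  expect_true(f$ok)
  expect_gt(f$n_cases, 500)
  se <- sqrt(diag(f$sigma_hat))
  for (term in c("bmi", "sbp", "smoking_current")) {
    truth <- c(bmi = log(2), sbp = 0.3, smoking_current = -0.5)[term]
    expect_lt(abs(f$mu_hat[term] - truth), 4 * se[term])
  }
  # null terms stay near zero
  expect_lt(abs(f$mu_hat["height"]), 4 * se["height"])
  # covariance is symmetric positive-definite with matching order
  expect_equal(f$sigma_hat, t(f$sigma_hat))
  expect_equal(length(f$mu_hat), nrow(f$sigma_hat))
  expect_identical(names(f$mu_hat), f$covariate_names)
})

test_that("estimates have negligible bias over seeded replicates", {
  set.seed(5150)
  est <- replicate(25, {
    i <- sample.int(1e6, 1)
    pr <- list(disease_profile("A", effects = c(bmi = log(2)),
                               baseline_rate = 1.5e-2))
    co <- simulate_cohort(quick_config(pr, n = 12000, seed = i))
    f <- fit_disease(co, "A", "male", ph_test = FALSE)
    c(f$mu_hat["bmi"], sqrt(f$sigma_hat["bmi", "bmi"]))
  })
  bias <- mean(est[1, ]) - log(2)
  mc_se <- sd(est[1, ]) / sqrt(ncol(est))
  expect_lt(abs(bias), 0.05 + 3 * mc_se)
})

test_that("fitting is invariant to participant and event row order", {
  fx <- planted_fit_fixture()
  co <- fx$cohort
  co2 <- co
  set.seed(99)
  co2$participants <- co2$participants[sample(nrow(co2$participants)), ]
  co2$events <- co2$events[sample(nrow(co2$events)), ]
  f2 <- fit_disease(co2, "A", "male", ph_test = FALSE)
  expect_equal(f2$mu_hat, fx$fit$mu_hat, tolerance = 1e-8)
})

test_that("the case floor fails fits with fewer than 50 cases", {
  fx <- planted_fit_fixture()
  co <- fx$cohort
  # truncate the incident stream of disease A to exactly 49 female cases
  ev <- co$events
  fem <- co$participants$id[co$participants$sex == "female"]
  inc_f <- which(ev$disease_id == "A" & !ev$prevalent &
                   ev$participant_id %in% fem)
  drop <- inc_f[-seq_len(49)]
  co$events <- ev[-drop, ]
  f <- fit_disease(co, "A", "female")
  expect_false(f$ok)
  expect_identical(f$reason, "insufficient cases")
  expect_identical(f$n_cases, 49L)
})

test_that("global significance test matches closed forms and oracles", {
  # zero vector: statistic 0, p = 1
  z <- global_significance_test(setNames(rep(0, 3), c("a", "b", "c")),
                                diag(3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # 1-D mu = 2, sigma = 1: statistic 4; tail checked by Monte Carlo
  g <- global_significance_test(2, matrix(1))
  expect_equal(g$statistic, 4)
  mc <- with_seed(1, mean(stats::rchisq(4e5, df = 1) > 4))
  expect_lt(abs(g$p_value - mc), 4 * sqrt(mc * (1 - mc) / 4e5))
  # invariance under joint invertible reparameterisation
  set.seed(42)
  for (rep in 1:10) {
    p <- sample(2:6, 1)
    mu <- rnorm(p)
    S <- random_spd(p)
    A <- matrix(rnorm(p * p), p) + diag(p)
    g1 <- global_significance_test(mu, S)
    g2 <- global_significance_test(drop(A %*% mu), A %*% S %*% t(A))
    expect_equal(g1$statistic, g2$statistic, tolerance = 1e-8)
  }
  expect_error(global_significance_test(c(1, 1), matrix(c(1, 1, 1, 1), 2)),
               "degenerate")
})

test_that("eigenvalue screen flags only inflated covariances", {
  base <- lapply(1:20, function(i) fake_fit(sprintf("D%02d", i), "male"))
  scr <- eigenvalue_screen(as_disease_fits(base))
  expect_false(any(scr$flagged))
  # one covariance scaled by 1e6 is flagged, the rest are not
  infl <- base
  infl[[7]] <- fake_fit("D07", "male", sigma_scale = 1e6)
  scr2 <- eigenvalue_screen(as_disease_fits(infl))
  expect_true(scr2$flagged[7])
  expect_equal(sum(scr2$flagged), 1L)
  # screen is invariant under permutation of fit order
  set.seed(3)
  perm <- sample(length(infl))
  scr3 <- eigenvalue_screen(as_disease_fits(infl[perm]))
  expect_equal(scr3$flagged, scr2$flagged[perm])
  expect_error(eigenvalue_screen(as_disease_fits(base[1:2])), "fewer than 3")
})

test_that("null p-values are uniform for the global and Schoenfeld tests", {
  set.seed(8181)
  ps <- replicate(80, {
    i <- sample.int(1e6, 1)
    co <- simulate_cohort(quick_config(null_profiles(1, rate = 1.5e-2),
                                       n = 6000, seed = i, cancer = 0))
    f <- fit_disease(co, "N01", "male")
    c(f$global_chi2_p, f$ph_test_p)
  })
  expect_gt(suppressWarnings(stats::ks.test(ps[1, ], "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(ps[2, ], "punif"))$p.value, 0.01)
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("the Schoenfeld test detects a sign-flipping age-varying effect", {
  # piecewise hazard on the bmi covariate: log HR +0.8 before age 55,
  # -0.8 after; event ages drawn by inverting the cumulative hazard
  gen_flip <- function(seed) {
    co <- simulate_cohort(quick_config(null_profiles(1, rate = 1e-4),
                                       n = 4000, seed = seed, cancer = 0))
    pp <- co$participants
    r0 <- 2e-2
    b <- 0.8
    a0 <- 55
    u <- with_seed(seed + 1, rexp(nrow(pp)))
    h1 <- r0 * exp(b * pp$bmi)   # hazard before a0
    h2 <- r0 * exp(-b * pp$bmi)  # hazard after a0
    t1 <- pp$entry_age + u / h1
    pre <- pmax(0, a0 - pp$entry_age) * h1
    t_ev <- ifelse(pp$entry_age >= a0, pp$entry_age + u / h2,
                   ifelse(u <= pre, t1, a0 + (u - pre) / h2))
    keep <- t_ev <= pp$end_age
    co$events <- data.frame(participant_id = pp$id[keep], disease_id = "F",
                            event_age = t_ev[keep], prevalent = FALSE)
    fit_disease(co, "F", "male")$ph_test_p
  }
  ps <- vapply(1:30, function(i) gen_flip(1000 + i), numeric(1))
  expect_lt(stats::median(ps), 0.05)
})

test_that("the selection cascade applies its stages in order", {
  mk <- function(d, sex, global_p, ph_p = 0.5, ok = TRUE,
                 reason = NA_character_, n_cases = 500, sigma_scale = 1) {
    fake_fit(d, sex, global_p = global_p, ph_p = ph_p, ok = ok,
             reason = reason, n_cases = n_cases, sigma_scale = sigma_scale)
  }
  fits <- as_disease_fits(list(
    mk("A", "male", 1e-9), mk("A", "female", 1e-9),          # survives all
    mk("B", "male", 1e-9), mk("B", "female", 0.9),           # male-only
    mk("C", "male", 0.5), mk("C", "female", 0.5),            # not significant
    mk("D", "male", 1e-9, ph_p = 1e-8),                      # PH failure
    mk("D", "female", 1e-9, ph_p = 1e-8),
    mk("E", "male", NA, ok = FALSE, reason = "insufficient cases",
       n_cases = 30),
    mk("E", "female", 1e-9),
    mk("F", "male", 1e-9, sigma_scale = 1e8),                # eigen outlier
    mk("F", "female", 1e-9),
    mk("G", "male", 1e-9), mk("G", "female", 1e-9)))         # survives all
  # filler diseases passing every stage, so the across-fit eigenvalue
  # screen has a meaningful family size in each sex
  filler <- unlist(lapply(sprintf("H%02d", 1:10), function(d)
    list(mk(d, "male", 1e-9), mk(d, "female", 1e-9))), recursive = FALSE)
  fits <- as_disease_fits(c(unclass(fits), filler))
  sel <- run_selection(fits)
  expect_identical(sort(sel$included),
                   sort(c("A", "G", sprintf("H%02d", 1:10))))
  # counts are non-increasing along the cascade, per sex
  expect_true(all(diff(sel$counts[, "male"]) <= 0))
  expect_true(all(diff(sel$counts[, "female"]) <= 0))
  ex <- sel$excluded
  expect_identical(ex$reason[ex$disease_id == "E" & ex$sex == "male"],
                   "insufficient cases")
  expect_identical(ex$stage[ex$disease_id == "F" & ex$sex == "male"],
                   "eigenvalue_screen")
  expect_identical(ex$stage[ex$disease_id == "B" & ex$sex == "male"],
                   "unisex")
  expect_identical(ex$reason[ex$disease_id == "D" & ex$sex == "male"],
                   "PH deviation significant after FDR")
  expect_identical(ex$stage[ex$disease_id == "C" & ex$sex == "male"],
                   "bonferroni_significant")
})

test_that("tertile and linear codings rank disease effects consistently", {
  profs <- planted_profiles(10, 5, seed = 55, rate_range = c(8e-3, 1.2e-2),
                            center_sd = 0.8, min_cluster_sep = 2.0)
  co <- simulate_cohort(quick_config(profs, n = 20000, seed = 56))
  lin <- fit_disease_models(co, coding = "linear", sexes = "male",
                            ph_test = FALSE)
  ter <- fit_disease_models(co, coding = "tertile", sexes = "male",
                            ph_test = FALSE)
  ok <- vapply(lin, `[[`, logical(1), "ok") &
    vapply(ter, `[[`, logical(1), "ok")
  b_lin <- vapply(lin[ok], function(f) f$mu_hat[["bmi"]], numeric(1))
  b_ter <- vapply(ter[ok], function(f) f$mu_hat[["bmi_t3"]], numeric(1))
  expect_gt(stats::cor(b_lin, b_ter, method = "spearman"), 0.5)
  # tertile top-vs-bottom contrasts carry the planted monotone signal
  expect_gt(stats::cor(b_lin, b_ter, method = "pearson"), 0.5)
})

test_that("fits round-trip through the CSV + sidecar format", {
  fx <- planted_fit_fixture()
  co <- fx$cohort
  fits <- fit_disease_models(co)
  path <- file.path(withr::local_tempdir(), "fits.csv")
  write_fits(fits, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".meta.json")))
  back <- read_fits(path)
  expect_identical(names(back), names(fits))
  for (nm in names(fits)) {
    if (fits[[nm]]$ok) {
      expect_equal(back[[nm]]$mu_hat, fits[[nm]]$mu_hat, tolerance = 1e-12)
      expect_equal(back[[nm]]$sigma_hat, fits[[nm]]$sigma_hat,
                   tolerance = 1e-12)
    } else {
      expect_identical(back[[nm]]$reason, fits[[nm]]$reason)
    }
  }
})
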