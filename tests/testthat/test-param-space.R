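test_that("marginalisation slices means and covariances without refitting", {
  set.seed(11)
  p <- 5
  mu <- setNames(rnorm(p), paste0("b", 1:p))
  S <- random_spd(p)
  dimnames(S) <- list(names(mu), names(mu))
  f <- marginal_fit("X", "male", mu, S)
  # full subset reproduces the parent exactly
  full <- marginalise(f, names(mu))
  expect_equal(full$mu, f$mu)
  expect_equal(full$sigma, f$sigma)
  # single coordinate gives the scalar mean and variance
  one <- marginalise(f, "b2")
  expect_equal(unname(one$mu), mu[["b2"]])
  expect_equal(drop(one$sigma), S["b2", "b2"])
  # order of subset names is respected
  rev2 <- marginalise(f, c("b4", "b1"))
  expect_equal(unname(rev2$mu), unname(mu[c("b4", "b1")]))
  expect_equal(unname(rev2$sigma), unname(S[c("b4", "b1"), c("b4", "b1")]))
  expect_error(marginalise(f, "nope"), "unknown parameter")
})

test_that("marginal distribution matches the sampling distribution", {
  set.seed(12)
  p <- 4
  mu <- rnorm(p)
  S <- random_spd(p)
  L <- chol(S)
  draws <- matrix(rnorm(40000 * p), ncol = p) %*% L +
    matrix(mu, 40000, p, byrow = TRUE)
  f <- marginal_fit("X", "male", setNames(mu, paste0("b", 1:p)), S)
  m3 <- marginalise(f, "b3")
  expect_lt(abs(mean(draws[, 3]) - m3$mu), 4 * sqrt(S[3, 3] / 40000))
  expect_lt(abs(stats::var(draws[, 3]) - drop(m3$sigma)),
            4 * S[3, 3] * sqrt(2 / 40000))
})

test_that("equality test matches closed forms and is calibrated", {
  cn <- "b1"
  a <- marginal_fit("A", "male", setNames(0, cn), matrix(1))
  b <- marginal_fit("A", "female", setNames(2, cn), matrix(1))
  # identical distributions: statistic 0, p 1
  same <- equality_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # 1-D, means 0 and 2, unit variances: statistic 2^2 / (1+1) = 2
  et <- equality_test(a, b)
  expect_equal(et$statistic, 2)
  mc <- with_seed(2, mean(stats::rchisq(4e5, 1) > 2))
  expect_lt(abs(et$p_value - mc), 4 * sqrt(mc * (1 - mc) / 4e5))
  # null calibration: equal true means give uniform p-values
  set.seed(13)
  p <- 3
  S1 <- random_spd(p); S2 <- random_spd(p)
  L1 <- chol(S1); L2 <- chol(S2)
  truth <- rnorm(p)
  ps <- replicate(1500, {
    m1 <- drop(truth + rnorm(p) %*% L1)
    m2 <- drop(truth + rnorm(p) %*% L2)
    equality_test(marginal_fit("A", "male", setNames(m1, paste0("b", 1:p)), S1),
                  marginal_fit("A", "female", setNames(m2, paste0("b", 1:p)), S2))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Bhattacharyya distance matches the overlap-integral oracle", {
  cn <- "b1"
  mk <- function(mu, var) marginal_fit("X", "male", setNames(mu, cn),
                                       matrix(var))
  # identical distributions
  expect_equal(bhattacharyya_distance(mk(0, 1), mk(0, 1)), 0)
  # mean shift: closed form 0.5, against numerical integration
  d1 <- bhattacharyya_distance(mk(0, 1), mk(2, 1))
  expect_equal(d1, 0.5, tolerance = 1e-12)
  expect_lt(abs(d1 - bhatt_1d_integrate(0, 1, 2, 1)), 1e-6)
  # variance mismatch: 0.5 * log(2 / sqrt(3))
  d2 <- bhattacharyya_distance(mk(1, 1), mk(1, 3))
  expect_equal(d2, 0.5 * log(2 / sqrt(3)), tolerance = 1e-12)
  expect_lt(abs(d2 - bhatt_1d_integrate(1, 1, 1, sqrt(3))), 1e-6)
  # generic 1-D case against the integration oracle
  d3 <- bhattacharyya_distance(mk(-0.7, 0.4), mk(0.9, 2.3))
  expect_lt(abs(d3 - bhatt_1d_integrate(-0.7, sqrt(0.4), 0.9, sqrt(2.3))),
            1e-6)
})

test_that("Bhattacharyya distance is symmetric, non-negative, and shrinks
           with growing covariances", {
  set.seed(14)
  for (rep in 1:20) {
    p <- sample(2:6, 1)
    cn <- paste0("b", 1:p)
    a <- marginal_fit("A", "male", setNames(rnorm(p), cn), random_spd(p))
    b <- marginal_fit("B", "male", setNames(rnorm(p), cn), random_spd(p))
    dab <- bhattacharyya_distance(a, b)
    expect_identical(dab, bhattacharyya_distance(b, a))
    expect_gte(dab, 0)
    expect_equal(bhattacharyya_distance(a, a), 0)
    # equal covariances: D_B equals the equality chi-squared / 4
    b_eq <- marginal_fit("B", "male", b$mu, a$sigma)
    expect_equal(bhattacharyya_distance(a, b_eq),
                 equality_test(a, b_eq)$statistic / 4, tolerance = 1e-10)
    # scaling both covariances by c > 1 strictly shrinks the distance
    # (log-determinant term is scale-invariant, the quadratic term shrinks)
    sc <- function(f, c) marginal_fit(f$disease_id, f$sex, f$mu, f$sigma * c)
    expect_lt(bhattacharyya_distance(sc(a, 4), sc(b, 4)), dab)
  }
})

test_that("sex-difference scan recovers planted BMI differences", {
  # 8 diseases, 3 with +/-0.3 sex-specific BMI effects, large case counts
  profs <- planted_profiles(8, 4, seed = 21, frac_sex_specific = 3 / 8,
                            bmi_shift = 0.3, rate_range = c(1.5e-2, 2e-2),
                            center_sd = 0.8, min_cluster_sep = 2.0)
  truth_ss <- vapply(profs, `[[`, logical(1), "sex_specific")
  expect_equal(sum(truth_ss), 3L)
  co <- simulate_cohort(quick_config(profs, n = 40000, seed = 22))
  fits <- fit_disease_models(co, ph_test = FALSE)
  scan <- sex_difference_scan(fits)
  hit <- scan$disease_id[scan$significant]
  planted <- vapply(profs[truth_ss], `[[`, character(1), "disease_id")
  expect_gte(mean(planted %in% hit), 0.8)
  # dropping BMI removes the flags for BMI-only planted differences
  scan2 <- sex_difference_scan(fits,
                               subset_names = comparison_terms(drop_bmi = TRUE))
  expect_false(any(scan2$significant[scan2$disease_id %in% planted]))
})

test_that("sex-difference scan is calibrated under sex-identical truths", {
  set.seed(23)
  p <- 6
  cn <- comparison_terms()
  n_dis <- 40
  flagged <- replicate(30, {
    fits <- list()
    for (i in seq_len(n_dis)) {
      truth <- rnorm(p, sd = 0.3)
      S <- random_spd(p, scale = 0.01)
      L <- chol(S)
      for (s in c("male", "female")) {
        mu <- drop(truth + rnorm(p) %*% L)
        fits[[paste0("D", i, "|", s)]] <-
          fake_fit(paste0("D", i), s, p_dim = p, mu = mu, sigma = S, cn = cn)
      }
    }
    scan <- sex_difference_scan(as_disease_fits(fits))
    mean(scan$significant)
  })
  expect_lte(mean(flagged), 0.05)
})

test_that("partner identification works on constructed geometries", {
  cn <- comparison_terms()
  tight <- diag(1e-4, 6)
  mk <- function(d, s, center) {
    marginal_fit(d, s, setNames(center, cn), tight)
  }
  # two diseases, both sexes, far apart: everyone finds their counterpart
  mf <- list(mk("A", "male", rep(0, 6)), mk("A", "female", rep(0.01, 6)),
             mk("B", "male", rep(3, 6)), mk("B", "female", rep(3.01, 6)))
  names(mf) <- vapply(mf, function(f) paste(f$disease_id, f$sex, sep = "|"),
                      character(1))
  dm <- bhattacharyya_matrix(mf)
  pt <- identify_partners(dm)
  expect_true(all(pt$partner_rank == 1))
  expect_equal(summary(pt, k = 1)$top1_fraction, 1)
  # rank is invariant under relabelling (permutation) of entries
  perm <- c(3, 1, 4, 2)
  dm2 <- bhattacharyya_matrix(mf[perm])
  pt2 <- identify_partners(dm2)
  expect_equal(setNames(pt2$partner_rank, pt2$entry)[pt$entry],
               setNames(pt$partner_rank, pt$entry))
  # a missing counterpart yields an undefined rank
  dm3 <- bhattacharyya_matrix(mf[1:3])
  pt3 <- identify_partners(dm3)
  expect_true(is.na(pt3$partner_rank[pt3$entry == "B|male"]))
})

test_that("cluster homogeneity follows the pairwise-sum construction", {
  set.seed(31)
  p <- 6
  cn <- paste0("b", 1:p)
  mk_batch <- function(m) {
    lapply(seq_len(m), function(i)
      marginal_fit(sprintf("D%02d", i), "male",
                   setNames(rnorm(p), cn), random_spd(p)))
  }
  mf <- mk_batch(5)
  names(mf) <- sprintf("D%02d|male", 1:5)
  clusters <- c(1, 1, 2, 2, 2)
  h <- cluster_homogeneity(mf, clusters)
  # dof: p * sum n_g (n_g - 1) / 2 = 6 * (1 + 3) = 24
  expect_identical(h$dof, 24)
  # independent oracle: the full double sum, halved
  dbl <- 0
  for (g in unique(clusters)) {
    idx <- which(clusters == g)
    for (i in idx) for (j in idx) {
      if (i == j) next
      delta <- mf[[i]]$mu - mf[[j]]$mu
      dbl <- dbl + drop(crossprod(delta,
        solve(mf[[i]]$sigma + mf[[j]]$sigma) %*% delta))
    }
  }
  expect_equal(h$statistic, dbl / 2, tolerance = 1e-10)
  # all singletons: statistic 0, dof 0, p 1
  h0 <- cluster_homogeneity(mf, seq_along(mf))
  expect_identical(h0$statistic, 0)
  expect_identical(h0$dof, 0)
  expect_identical(h0$p_value, 1)
})

test_that("homogeneity statistic is chi-squared for pair clusters and
           mean-exact but overdispersed for larger clusters", {
  set.seed(32)
  p <- 6
  cn <- paste0("b", 1:p)
  sigmas <- lapply(1:8, function(i) random_spd(p))
  chols <- lapply(sigmas, chol)
  draw_stat <- function(sizes) {
    clusters <- rep(seq_along(sizes), sizes)
    means <- lapply(seq_along(sizes), function(g) rnorm(p))
    mf <- lapply(seq_along(clusters), function(i) {
      g <- clusters[i]
      marginal_fit(sprintf("D%02d", i), "male",
                   setNames(drop(means[[g]] + rnorm(p) %*% chols[[i]]), cn),
                   sigmas[[i]])
    })
    names(mf) <- sprintf("D%02d|male", seq_along(clusters))
    cluster_homogeneity(mf, clusters)
  }
  # pair clusters: differences are independent, the chi-squared is exact
  st2 <- replicate(600, draw_stat(c(2, 2))$statistic)
  expect_gt(suppressWarnings(
    stats::ks.test(st2, stats::pchisq, df = 12))$p.value, 0.01)
  # a size-3 cluster keeps the mean at dof but inflates the variance
  h3 <- replicate(600, draw_stat(3)$statistic)
  expect_lt(abs(mean(h3) - 18) / (sd(h3) / sqrt(600)), 4)
  expect_gt(stats::var(h3), 1.15 * 2 * 18)
})
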