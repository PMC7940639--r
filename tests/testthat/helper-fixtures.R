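# Shared fixture builders and independent oracles for the test suite.
# All fixtures are generated in code under fixed seeds.

with_seed <- riskclust:::with_seed

# A minimal cohort configuration with fully controllable profiles.
quick_config <- function(profiles, n = 6000, seed = 1, cancer = 5e-3, ...) {
  cohort_config(n_participants = n, seed = seed,
                disease_profiles = profiles, cancer_hazard = cancer, ...)
}

# Profiles with zero effects everywhere (null diseases).
null_profiles <- function(n_diseases, rate = 5e-3) {
  lapply(seq_len(n_diseases), function(i) {
    disease_profile(sprintf("N%02d", i), cluster_id = "C1",
                    baseline_rate = rate)
  })
}

# Hand-built disease_fit, for unit-testing selection logic without the
# cost of real model fits.
fake_fit <- function(disease_id, sex, p_dim = 3, mu = NULL, sigma = NULL,
                     n_cases = 500, global_p = NULL, ph_p = 0.5, ok = TRUE,
                     reason = NA_character_, sigma_scale = 1, cn = NULL) {
  if (is.null(cn)) cn <- paste0("b", seq_len(p_dim))
  if (is.null(mu)) mu <- setNames(rep(0.2, p_dim), cn)
  if (is.null(sigma)) sigma <- diag(sigma_scale, p_dim)
  dimnames(sigma) <- list(cn, cn)
  if (is.null(global_p)) {
    global_p <- global_significance_test(mu, sigma)$p_value
  }
  structure(list(disease_id = disease_id, sex = sex, coding = "linear",
                 n_cases = n_cases, n_at_risk = 10 * n_cases,
                 mu_hat = setNames(as.numeric(mu), cn), sigma_hat = sigma,
                 covariate_names = cn, global_chi2_p = global_p,
                 ph_test_p = ph_p,
                 ph_global = list(statistic = 1, df = p_dim, p_value = ph_p),
                 ok = ok, reason = reason),
            class = "disease_fit")
}

as_disease_fits <- function(fits, coding = "linear") {
  names(fits) <- vapply(fits, function(f)
    paste(f$disease_id, f$sex, sep = "|"), character(1))
  structure(fits, coding = coding, class = "disease_fits")
}

# Random symmetric positive-definite matrix.
random_spd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p * scale + diag(1e-3, p)
}

# Independent oracle: 1-D Bhattacharyya distance by numerical integration
# of -log int sqrt(p q).
bhatt_1d_integrate <- function(mu1, s1, mu2, s2) {
  f <- function(x) sqrt(dnorm(x, mu1, s1) * dnorm(x, mu2, s2))
  lim <- c(min(mu1 - 12 * s1, mu2 - 12 * s2), max(mu1 + 12 * s1, mu2 + 12 * s2))
  -log(stats::integrate(f, lim[1], lim[2], rel.tol = 1e-12)$value)
}

# Independent oracle: within-cluster pair counts by explicit enumeration.
pair_overlap_bruteforce <- function(a, b) {
  stopifnot(identical(sort(names(a)), sort(names(b))))
  ids <- names(a)
  pairs <- t(combn(ids, 2))
  in_a <- a[pairs[, 1]] == a[pairs[, 2]]
  in_b <- b[pairs[, 1]] == b[pairs[, 2]]
  list(n_A = sum(in_a), n_B = sum(in_b), n_AB = sum(in_a & in_b))
}

# A small battery of marginal fits with known structure.
mvn_marginal_fits <- function(means, sigmas, sexes = NULL, ids = NULL) {
  m <- length(means)
  if (is.null(ids)) ids <- sprintf("D%02d", seq_len(m))
  if (is.null(sexes)) sexes <- rep("male", m)
  out <- lapply(seq_len(m), function(i) {
    marginal_fit(ids[i], sexes[i], means[[i]], sigmas[[i]])
  })
  names(out) <- paste(ids, sexes, sep = "|")
  out
}
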