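# End-to-end orchestration: simulate -> fit -> select -> compare ->
# identify -> cluster -> sensitivity reruns, with persisted intermediates
# and a machine-readable report.

#' Configure a full pipeline run
#'
#' Every stage option has a config twin so that multi-stage reruns are
#' reproducible from a single JSON document.
#'
#' @param seed Integer master seed (drives profile generation and the
#'   cohort simulation).
#' @param n_participants,n_diseases,n_clusters Synthetic cohort scale.
#' @param profile_args Extra arguments passed to [planted_profiles()].
#' @param cohort_args Extra arguments passed to [cohort_config()].
#' @param coding Main-analysis coding of continuous measures.
#' @param alpha Significance level of the selection cascade, sex scans and
#'   homogeneity threshold.
#' @param k_range Cluster counts scanned for the elbow curve (`NULL`:
#'   1 to min(60, entries - 1)).
#' @param selected_k Manual cluster-count override (`NULL`: elbow rule).
#' @param partner_k Rank cut-off of the identification summary (`NULL`:
#'   nearest 5% of the candidate pool).
#' @param exclude_prior_rerun Rerun fits excluding participants with prior
#'   disease from the same cluster, and report the clustering overlap
#'   `p_AB` against the main run.
#' @param tertile_rerun Rerun with sex-specific tertile coding and report
#'   `p_AB` against the main run.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n_participants = 50000, n_diseases = 100,
                       n_clusters = 12, profile_args = list(),
                       cohort_args = list(), coding = c("linear", "tertile"),
                       alpha = 0.05, k_range = NULL, selected_k = NULL,
                       partner_k = NULL, exclude_prior_rerun = FALSE,
                       tertile_rerun = FALSE) {
  coding <- match.arg(coding)
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 n_diseases = as.integer(n_diseases),
                 n_clusters = as.integer(n_clusters),
                 profile_args = profile_args, cohort_args = cohort_args,
                 coding = coding, alpha = alpha, k_range = k_range,
                 selected_k = selected_k, partner_k = partner_k,
                 exclude_prior_rerun = isTRUE(exclude_prior_rerun),
                 tertile_rerun = isTRUE(tertile_rerun)),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON document whose keys mirror [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cj$profile_args <- as.list(cj$profile_args)
  cj$cohort_args <- as.list(cj$cohort_args)
  do.call(run_config, cj)
}

#' Run the full characterisation/identification/clustering pipeline
#'
#' Simulates a cohort, fits all per-disease per-sex proportional hazards
#' models, applies the statistical inclusion cascade, marginalises to the
#' comparison parameters, scans for sex differences (with and without
#' BMI), computes the Bhattacharyya distance matrix, identifies
#' opposite-sex partners, clusters with Ward.D2 and the elbow criterion,
#' and optionally reruns the fits under the prior-disease-exclusion and
#' tertile sensitivity settings, reporting the clustering overlap `p_AB`
#' of each rerun against the main clustering.
#'
#' With `out_dir` set, every intermediate artifact is persisted
#' (cohort/fits/distances/clusters as CSV, tree as Newick, report and
#' manifest as JSON), so every number in the report can be recomputed from
#' stored intermediates.
#'
#' @param config A [run_config()] (or path to its JSON form).
#' @param out_dir Optional output directory.
#' @return An object of class `riskclust_run`; see Details.  Identical
#'   seeds and configuration give identical reports.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  profiles <- do.call(planted_profiles, c(
    list(n_diseases = config$n_diseases, n_clusters = config$n_clusters,
         seed = config$seed), config$profile_args))
  sim_cfg <- do.call(cohort_config, c(
    list(n_participants = config$n_participants, seed = config$seed + 1L,
         disease_profiles = profiles), config$cohort_args))
  cohort <- simulate_cohort(sim_cfg)
  if (persist) write_cohort(cohort, file.path(out_dir, "cohort"))

  fits <- fit_disease_models(cohort, coding = config$coding)
  if (persist) write_fits(fits, file.path(out_dir, "fits.csv"))

  sel <- run_selection(fits, alpha = config$alpha)
  if (persist) {
    writeLines(jsonlite::toJSON(list(
      counts = as.data.frame(sel$counts), excluded = sel$excluded,
      included = sel$included), dataframe = "rows", auto_unbox = TRUE,
      pretty = TRUE, digits = NA), file.path(out_dir, "selection.json"))
  }

  scan_full <- sex_difference_scan(fits, diseases = sel$included,
                                   alpha = config$alpha)
  scan_nobmi <- sex_difference_scan(
    fits, diseases = sel$included,
    subset_names = comparison_terms(config$coding, drop_bmi = TRUE),
    alpha = config$alpha)
  if (persist) {
    write.csv(scan_full, file.path(out_dir, "sex_differences.csv"),
              row.names = FALSE)
    write.csv(scan_nobmi, file.path(out_dir, "sex_differences_nobmi.csv"),
              row.names = FALSE)
  }

  mf <- marginalise_all(fits, diseases = sel$included)
  dm <- bhattacharyya_matrix(mf)
  partners <- identify_partners(dm)
  pk <- config$partner_k %||% max(1L, round(0.05 * (nrow(partners) - 1)))
  ident <- summary(partners, k = pk)
  truth <- planted_truth(sim_cfg)
  ns_key <- paste(truth$disease_id, truth$sex, sep = "|")
  non_ss <- partners$entry %in% ns_key[!truth$sex_specific]
  ident_non_ss <- mean(partners$partner_rank[non_ss] == 1, na.rm = TRUE)
  if (persist) {
    write.csv(cbind(entry = rownames(dm), as.data.frame(unclass(dm))),
              file.path(out_dir, "distance_matrix.csv"), row.names = FALSE)
    write.csv(partners, file.path(out_dir, "partners.csv"), row.names = FALSE)
  }

  tree <- hierarchical_cluster(dm)
  clus <- select_k(tree, mf, k_range = config$k_range, alpha = config$alpha,
                   selected_k = config$selected_k)
  hm <- heatmap_values(mf)
  if (persist) {
    write.csv(clus$curve, file.path(out_dir, "elbow_curve.csv"),
              row.names = FALSE)
    write.csv(data.frame(entry = names(clus$labels), cluster = clus$labels),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
    write.csv(cbind(entry = rownames(hm), as.data.frame(hm)),
              file.path(out_dir, "heatmap.csv"), row.names = FALSE)
    write_dendrogram_newick(tree, file.path(out_dir, "tree.nwk"))
  }

  # planted-structure recovery diagnostics (ground truth is known here)
  truth_cluster <- setNames(truth$cluster_id, ns_key)[names(clus$labels)]

  sensitivity <- list()
  if (config$exclude_prior_rerun) {
    sensitivity$exclude_prior <- sensitivity_rerun(
      cohort, fits, sel, clus, mf, coding = config$coding,
      mode = "exclude_prior",
      out_dir = if (persist) file.path(out_dir, "rerun_exclude_prior"))
  }
  if (config$tertile_rerun) {
    sensitivity$tertile <- sensitivity_rerun(
      cohort, fits, sel, clus, mf, coding = config$coding,
      mode = "tertile",
      out_dir = if (persist) file.path(out_dir, "rerun_tertile"))
  }

  report <- list(
    seed = config$seed,
    n_participants = config$n_participants,
    n_diseases = config$n_diseases,
    selection_counts = apply(sel$counts, 1, as.list),
    n_included_unisex = length(sel$included),
    identification = list(
      n_entries = ident$n_entries, k = ident$k,
      top1_fraction = ident$top1_fraction,
      topk_fraction = ident$topk_fraction,
      top1_fraction_non_sex_specific = ident_non_ss),
    sex_differences = list(
      n_tested = nrow(scan_full),
      n_significant = sum(scan_full$significant),
      fraction_significant = mean(scan_full$significant),
      n_significant_without_bmi = sum(scan_nobmi$significant),
      fraction_significant_without_bmi = mean(scan_nobmi$significant)),
    clustering = list(
      selected_k = clus$selected_k, elbow_k = clus$elbow_k,
      n_nonsignificant = clus$n_nonsignificant,
      planted_k = config$n_clusters,
      planted_ari = adjusted_rand_index(
        cutree(tree, k = config$n_clusters), truth_cluster)),
    sensitivity = lapply(sensitivity, function(s)
      list(p_AB = s$stability$p_AB,
           n_sensitive = length(s$stability$sensitive_entries))),
    specificity_note = list(
      n_factors = 7, n_levels = 3,
      combinations = risk_profile_combinations(7, 3)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(report = report, config = config, selection = sel,
                        partners = partners, scan_full = scan_full,
                        scan_nobmi = scan_nobmi, clustering = clus,
                        distance = dm, heatmap = hm, fits = fits,
                        cohort = cohort, sensitivity = sensitivity),
                   class = "riskclust_run")
  if (persist) {
    rep_json <- jsonlite::toJSON(report[setdiff(names(report), "elapsed_s")],
                                 auto_unbox = TRUE, pretty = TRUE,
                                 digits = NA)
    writeLines(rep_json, file.path(out_dir, "report.json"))
    writeLines(jsonlite::toJSON(list(
      seed = config$seed,
      config_hash = fnv1a32(jsonlite::toJSON(unclass(config),
                                             auto_unbox = TRUE, digits = NA)),
      report_hash = fnv1a32(rep_json)), auto_unbox = TRUE, pretty = TRUE),
      file.path(out_dir, "manifest.json"))
  }
  run
}

# One sensitivity rerun: refit the included diseases under a modified
# model, recluster at the main run's selected k, and compare clusterings.
sensitivity_rerun <- function(cohort, fits, sel, clus, mf, coding, mode,
                              out_dir = NULL) {
  if (mode == "exclude_prior") {
    # diseases sharing a cluster with each disease's entries in the main run
    labels <- clus$labels
    entry_dis <- sub("\\|(male|female)$", "", names(labels))
    excl <- lapply(sel$included, function(d) {
      cl <- unique(labels[entry_dis == d])
      setdiff(unique(entry_dis[labels %in% cl]), d)
    })
    names(excl) <- sel$included
    refit <- fit_disease_models(cohort, coding = coding,
                                diseases = sel$included,
                                exclusions = excl, ph_test = FALSE)
    subset <- comparison_terms(coding)
  } else if (mode == "tertile") {
    refit <- fit_disease_models(cohort, coding = "tertile",
                                diseases = sel$included, ph_test = FALSE)
    subset <- comparison_terms("tertile")
  } else {
    stop("unknown sensitivity mode: ", mode, call. = FALSE)
  }
  mf2 <- marginalise_all(refit, subset_names = subset)
  if (length(mf2) < 3) {
    stop("sensitivity rerun left fewer than 3 fitted entries", call. = FALSE)
  }
  dm2 <- bhattacharyya_matrix(mf2)
  tree2 <- hierarchical_cluster(dm2)
  k <- min(clus$selected_k, nrow(dm2) - 1L)
  labels2 <- cutree(tree2, k = k)
  common <- intersect(names(clus$labels), names(labels2))
  stab <- compare_clusterings(clus$labels[common], labels2[common])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fits(refit, file.path(out_dir, "fits.csv"))
    write.csv(data.frame(entry = names(labels2), cluster = labels2),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
  }
  list(stability = stab, labels = labels2, n_common = length(common),
       fits = refit)
}

#' @export
print.riskclust_run <- function(x, ...) {
  r <- x$report
  cat("riskclust pipeline run (seed", r$seed, ")\n")
  cat("  cohort:", r$n_participants, "participants,", r$n_diseases,
      "diseases;", r$n_included_unisex, "in the unisex set\n")
  cat(sprintf("  identification: top-1 %.1f%%, top-%d %.1f%%\n",
              100 * r$identification$top1_fraction, r$identification$k,
              100 * r$identification$topk_fraction))
  cat(sprintf("  sex differences: %d/%d significant (%.1f%%); without BMI %d (%.1f%%)\n",
              r$sex_differences$n_significant, r$sex_differences$n_tested,
              100 * r$sex_differences$fraction_significant,
              r$sex_differences$n_significant_without_bmi,
              100 * r$sex_differences$fraction_significant_without_bmi))
  cat("  clustering: selected k =", r$clustering$selected_k,
      "; smallest non-significant N =", r$clustering$n_nonsignificant,
      "; ARI vs planted clusters =", round(r$clustering$planted_ari, 3), "\n")
  for (nm in names(r$sensitivity)) {
    cat(sprintf("  sensitivity %s: p_AB = %.3f (%d sensitive entries)\n",
                nm, r$sensitivity[[nm]]$p_AB, r$sensitivity[[nm]]$n_sensitive))
  }
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' entries; 1 for identical partitions (up to relabelling), ~0 for
#' independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Count distinct discrete risk-factor profiles
#'
#' With `n_factors` risk factors each taking `n_levels` discrete values
#' there are `n_levels ^ n_factors` distinct profiles -- e.g. 7 trinary
#' factors give 2187 combinations, doubling the factors to 14 exceeds 4
#' million.  Used in the run report's specificity commentary.
#'
#' @param n_factors Number of risk factors (>= 0).
#' @param n_levels Levels per factor (>= 1).
#' @return Number of distinct profiles.
#' @export
risk_profile_combinations <- function(n_factors, n_levels) {
  stopifnot(n_factors >= 0, n_levels >= 1,
            n_factors == round(n_factors), n_levels == round(n_levels))
  n_levels^n_factors
}

#' Persist fitted models as CSV plus a JSON sidecar
#'
#' One record per disease-sex with the MLE vector (`mu_` columns), the
#' upper triangle of its covariance (`sig_i_j` columns), case counts and
#' test p-values; the sidecar stores the covariate ordering per sex.
#' `read_fits()` restores a `disease_fits` object.
#'
#' @param fits A `disease_fits`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `write_fits()` the path, invisibly; `read_fits()` a
#'   `disease_fits`.
#' @export
write_fits <- function(fits, path) {
  stopifnot(inherits(fits, "disease_fits"))
  terms_by_sex <- list()
  rows <- lapply(fits, function(f) {
    terms_by_sex[[f$sex]] <<- f$covariate_names
    row <- data.frame(disease_id = f$disease_id, sex = f$sex, ok = f$ok,
                      reason = f$reason, n_cases = f$n_cases,
                      n_at_risk = f$n_at_risk,
                      global_chi2_p = f$global_chi2_p,
                      ph_test_p = f$ph_test_p, stringsAsFactors = FALSE)
    if (f$ok) {
      p <- length(f$mu_hat)
      mu <- setNames(as.list(f$mu_hat), paste0("mu_", seq_len(p)))
      iu <- which(upper.tri(f$sigma_hat, diag = TRUE), arr.ind = TRUE)
      sg <- setNames(as.list(f$sigma_hat[iu]),
                     paste0("sig_", iu[, 1], "_", iu[, 2]))
      row <- cbind(row, as.data.frame(mu), as.data.frame(sg))
    }
    row
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE)
  meta <- list(coding = attr(fits, "coding"), covariates = terms_by_sex)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"),
                             simplifyVector = TRUE)
  fits <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    cn <- meta$covariates[[r$sex]]
    p <- length(cn)
    out <- list(disease_id = r$disease_id, sex = r$sex,
                coding = meta$coding, ok = isTRUE(r$ok),
                reason = if (is.na(r$reason)) NA_character_ else r$reason,
                n_cases = r$n_cases, n_at_risk = r$n_at_risk,
                covariate_names = cn, global_chi2_p = r$global_chi2_p,
                ph_test_p = r$ph_test_p,
                ph_global = if (!is.na(r$ph_test_p))
                  list(statistic = NA_real_, df = NA_real_,
                       p_value = r$ph_test_p),
                mu_hat = NULL, sigma_hat = NULL)
    if (out$ok) {
      out$mu_hat <- setNames(as.numeric(r[paste0("mu_", seq_len(p))]), cn)
      S <- matrix(0, p, p, dimnames = list(cn, cn))
      iu <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
      S[iu] <- as.numeric(r[paste0("sig_", iu[, 1], "_", iu[, 2])])
      S[lower.tri(S)] <- t(S)[lower.tri(S)]
      out$sigma_hat <- S
    }
    structure(out, class = "disease_fit")
  })
  names(fits) <- paste(tab$disease_id, tab$sex, sep = "|")
  structure(fits, coding = meta$coding, class = "disease_fits")
}
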