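# Comparison machinery on fitted parameters viewed as multivariate normals.

#' Construct a marginal parameter distribution directly
#'
#' Wraps a mean vector and covariance matrix as a `marginal_fit`, the
#' container used by the comparison, identification and clustering
#' functions.  Normally produced by [marginalise()]; the constructor is
#' exported so that parameter distributions from other sources (or
#' simulated MLEs in validation studies) can enter the same machinery.
#'
#' @param disease_id,sex Entry labels.
#' @param mu Named numeric mean vector.
#' @param sigma Symmetric positive-definite covariance matrix.
#' @param subset_names Parameter names; defaults to `names(mu)`.
#' @return An object of class `marginal_fit`.
#' @export
marginal_fit <- function(disease_id, sex, mu, sigma,
                         subset_names = names(mu)) {
  subset_names <- subset_names %||% paste0("p", seq_along(mu))
  mu <- as.numeric(mu)
  stopifnot(length(mu) == length(subset_names),
            is.matrix(sigma), nrow(sigma) == length(mu),
            ncol(sigma) == length(mu))
  if (!is_spd(sigma)) {
    stop("sigma must be symmetric positive-definite", call. = FALSE)
  }
  dimnames(sigma) <- list(subset_names, subset_names)
  structure(list(disease_id = as.character(disease_id),
                 sex = as.character(sex),
                 mu = setNames(mu, subset_names),
                 sigma = sigma, subset_names = subset_names),
            class = "marginal_fit")
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat("Marginal parameter distribution:", x$disease_id, "(", x$sex, ")\n")
  tab <- cbind(estimate = x$mu, se = sqrt(diag(x$sigma)))
  print(round(tab, 3))
  invisible(x)
}

#' Marginalise a fit to a parameter subset
#'
#' Because maximum-likelihood estimates are asymptotically multivariate
#' normal, the distribution of any parameter subset is obtained by taking
#' the corresponding rows and columns of the mean vector and covariance
#' matrix -- no refit.  This keeps the full multiple adjustment of the
#' model while comparing and clustering only the biologically meaningful
#' subset (default: [comparison_terms()]).
#'
#' @param fit A successful `disease_fit` (or a `marginal_fit` to subset
#'   further).
#' @param subset_names Parameter names to keep, in the requested order.
#' @return A `marginal_fit`.
#' @export
marginalise <- function(fit, subset_names = NULL) {
  if (inherits(fit, "disease_fit")) {
    if (!fit$ok) {
      stop("cannot marginalise failed fit ", fit$disease_id, " (", fit$sex,
           "): ", fit$reason, call. = FALSE)
    }
    mu <- fit$mu_hat
    sigma <- fit$sigma_hat
    if (is.null(subset_names)) subset_names <- comparison_terms(fit$coding)
  } else if (inherits(fit, "marginal_fit")) {
    mu <- fit$mu
    sigma <- fit$sigma
    if (is.null(subset_names)) subset_names <- fit$subset_names
  } else {
    stop("fit must be a disease_fit or marginal_fit", call. = FALSE)
  }
  unknown <- setdiff(subset_names, names(mu))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(names(mu), collapse = ", "),
         call. = FALSE)
  }
  marginal_fit(fit$disease_id, fit$sex, mu[subset_names],
               sigma[subset_names, subset_names, drop = FALSE],
               subset_names)
}

#' Marginalise every successful fit of a battery
#'
#' @param fits A `disease_fits` object.
#' @param diseases Diseases to include; default all with a successful fit
#'   in every requested sex.
#' @param subset_names Parameter subset, default [comparison_terms()] for
#'   the fits' coding.
#' @param sexes Sexes to include.
#' @return Named list of `marginal_fit`s, names `"<disease>|<sex>"`.
#' @export
marginalise_all <- function(fits, diseases = NULL, subset_names = NULL,
                            sexes = c("male", "female")) {
  stopifnot(inherits(fits, "disease_fits"))
  if (is.null(subset_names)) {
    subset_names <- comparison_terms(attr(fits, "coding") %||% "linear")
  }
  ok <- vapply(fits, `[[`, logical(1), "ok")
  dis <- vapply(fits, `[[`, character(1), "disease_id")
  sx <- vapply(fits, `[[`, character(1), "sex")
  if (is.null(diseases)) {
    diseases <- Reduce(intersect, lapply(sexes, function(s) dis[ok & sx == s]))
  }
  keep <- ok & dis %in% diseases & sx %in% sexes
  lapply(fits[keep], marginalise, subset_names = subset_names)
}

#' Multivariate equality test of two parameter distributions
#'
#' Tests the null hypothesis that two normally distributed MLE vectors
#' share the same mean: under the null
#' \eqn{(\hat\mu_1-\hat\mu_2) \sim N(0, \Sigma_1+\Sigma_2)}, so
#' \eqn{(\hat\mu_1-\hat\mu_2)^T(\Sigma_1+\Sigma_2)^{-1}(\hat\mu_1-\hat\mu_2)}
#' is chi-squared with as many degrees of freedom as parameters.
#'
#' @param a,b `marginal_fit`s with matching `subset_names`.
#' @return An object of class `pair_test`: list with `statistic`, `df`,
#'   `p_value` and the entry labels.
#' @export
equality_test <- function(a, b) {
  stopifnot(inherits(a, "marginal_fit"), inherits(b, "marginal_fit"))
  if (!identical(a$subset_names, b$subset_names)) {
    stop("parameter subsets do not match", call. = FALSE)
  }
  delta <- a$mu - b$mu
  stat <- drop(crossprod(delta, solve_sym(a$sigma + b$sigma, delta,
                                          label = "summed covariance")))
  df <- length(delta)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 a = paste(a$disease_id, a$sex, sep = "|"),
                 b = paste(b$disease_id, b$sex, sep = "|")),
            class = "pair_test")
}

#' @export
print.pair_test <- function(x, ...) {
  cat("Equality test ", x$a, " vs ", x$b, ": chi2(", x$df, ") = ",
      signif(x$statistic, 4), ", p = ", format.pval(x$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Scan diseases for sex differences in their risk-factor associations
#'
#' For each disease with a successful fit in both sexes, compares the
#' marginalised comparison parameters of the male and female fits with
#' [equality_test()] and applies a Benjamini-Hochberg FDR adjustment over
#' the scan family.  Re-running with `subset_names =
#' comparison_terms(drop_bmi = TRUE)` reproduces the sensitivity scan
#' without BMI.
#'
#' @param fits A `disease_fits` object.
#' @param diseases Diseases to scan (default: all with successful fits in
#'   both sexes; typically the unisex set from [run_selection()]).
#' @param subset_names Comparison parameters, default [comparison_terms()].
#' @param alpha Significance level applied to the FDR q-values.
#' @return A data.frame of class `sex_difference_scan` with one row per
#'   disease: `statistic`, `df`, `p_value`, `q_value`, `significant`.
#' @export
sex_difference_scan <- function(fits, diseases = NULL, subset_names = NULL,
                                alpha = 0.05) {
  mf <- marginalise_all(fits, diseases = diseases,
                        subset_names = subset_names)
  dis <- unique(vapply(mf, `[[`, character(1), "disease_id"))
  rows <- lapply(dis, function(d) {
    et <- equality_test(mf[[paste(d, "male", sep = "|")]],
                        mf[[paste(d, "female", sep = "|")]])
    data.frame(disease_id = d, statistic = et$statistic, df = et$df,
               p_value = et$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha
  rownames(out) <- NULL
  class(out) <- c("sex_difference_scan", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.sex_difference_scan <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat("Sex-difference scan over", nrow(x), "diseases:",
      sum(x$significant), "significant at FDR", alpha, "\n")
  if (any(x$significant)) {
    print.data.frame(x[x$significant, , drop = FALSE], row.names = FALSE)
  }
  invisible(x)
}

#' Bhattacharyya distance between two parameter distributions
#'
#' The Bhattacharyya distance is the negative log of the overlap integral
#' \eqn{\int \sqrt{p q}} of two densities.  For multivariate normals it has
#' the closed form
#' \deqn{D_B = \tfrac{1}{8}(\mu_1-\mu_2)^T \bar\Sigma^{-1} (\mu_1-\mu_2)
#'   + \tfrac{1}{2}\log\frac{\det\bar\Sigma}{\sqrt{\det\Sigma_1\det\Sigma_2}},
#'   \quad \bar\Sigma = (\Sigma_1+\Sigma_2)/2.}
#' The first term is a quarter of the [equality_test()] chi-squared
#' statistic when \eqn{\Sigma_1 = \Sigma_2}; the second compares the
#' shapes of the two covariances, so identical estimates with larger
#' uncertainties are closer.  (The related Hellinger distance is
#' \eqn{\sqrt{1 - e^{-D_B}}}.)
#'
#' @param a,b `marginal_fit`s with matching `subset_names` and
#'   positive-definite covariances.
#' @return Non-negative scalar distance.
#' @export
bhattacharyya_distance <- function(a, b) {
  stopifnot(inherits(a, "marginal_fit"), inherits(b, "marginal_fit"))
  if (!identical(a$subset_names, b$subset_names)) {
    stop("parameter subsets do not match", call. = FALSE)
  }
  Sbar <- (a$sigma + b$sigma) / 2
  delta <- a$mu - b$mu
  quad <- drop(crossprod(delta, solve_sym(Sbar, delta,
                                          label = "average covariance")))
  ld <- logdet_sym(Sbar) -
    0.5 * (logdet_sym(a$sigma) + logdet_sym(b$sigma))
  db <- quad / 8 + ld / 2
  # exact non-negativity can be lost to rounding for near-identical inputs
  max(db, 0)
}

#' Bhattacharyya distance matrix over disease-sex entries
#'
#' @param mfits Named list of `marginal_fit`s (one entry per disease-sex,
#'   as from [marginalise_all()]).
#' @return A symmetric matrix of class `bhatt_dist` with zero diagonal and
#'   an `entry_info` attribute (entry, disease_id, sex).
#' @export
bhattacharyya_matrix <- function(mfits) {
  stopifnot(is.list(mfits), length(mfits) >= 2)
  labs <- names(mfits) %||% vapply(mfits, function(f)
    paste(f$disease_id, f$sex, sep = "|"), character(1))
  m <- length(mfits)
  D <- matrix(0, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      D[i, j] <- D[j, i] <- bhattacharyya_distance(mfits[[i]], mfits[[j]])
    }
  }
  attr(D, "entry_info") <- data.frame(
    entry = labs,
    disease_id = vapply(mfits, `[[`, character(1), "disease_id"),
    sex = vapply(mfits, `[[`, character(1), "sex"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(D) <- c("bhatt_dist", "matrix")
  D
}

#' @export
print.bhatt_dist <- function(x, ...) {
  cat("Bhattacharyya distance matrix over", nrow(x), "disease-sex entries\n")
  off <- x[upper.tri(x)]
  cat("  distances: min", signif(min(off), 3), " median",
      signif(stats::median(off), 3), " max", signif(max(off), 3), "\n")
  invisible(x)
}

entry_info_of <- function(dm) {
  info <- attr(dm, "entry_info")
  if (is.null(info)) {
    labs <- rownames(dm)
    parts <- strsplit(labs, "|", fixed = TRUE)
    info <- data.frame(
      entry = labs,
      disease_id = vapply(parts, `[[`, character(1), 1),
      sex = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_,
                   character(1)),
      stringsAsFactors = FALSE)
  }
  info
}

#' Identify each disease by its nearest parameter-space neighbour
#'
#' For every disease-sex entry, finds the nearest other entry by
#' Bhattacharyya distance and the rank of the entry's own opposite-sex
#' counterpart among all other entries (ascending distance; ties share the
#' minimum rank).  A disease is "identified" when its counterpart is the
#' nearest entry (rank 1).  The candidate pool is all other entries of
#' both sexes.
#'
#' @param dm A `bhatt_dist` matrix.
#' @return A data.frame of class `partner_table`: per entry the nearest
#'   entry, its distance, and `partner_rank` (`NA` when the counterpart is
#'   not in the matrix).  `summary()` reports top-1 and top-k fractions.
#' @export
identify_partners <- function(dm) {
  stopifnot(inherits(dm, "bhatt_dist") ||
              (is.matrix(dm) && isSymmetric(unclass(dm))))
  info <- entry_info_of(dm)
  m <- nrow(dm)
  out <- info
  out$nearest <- NA_character_
  out$nearest_distance <- NA_real_
  out$partner_rank <- NA_integer_
  for (i in seq_len(m)) {
    d <- dm[i, -i]
    labs <- info$entry[-i]
    j <- which.min(d)
    out$nearest[i] <- labs[j]
    out$nearest_distance[i] <- d[j]
    cp <- which(info$disease_id[-i] == info$disease_id[i] &
                  info$sex[-i] != info$sex[i])
    if (length(cp) == 1) {
      out$partner_rank[i] <- 1L + sum(d < d[cp])
    }
  }
  class(out) <- c("partner_table", "data.frame")
  out
}

#' @param object A `partner_table`.
#' @param k Rank cut-off for the top-k fraction; default 5% of the
#'   candidate pool (nearest 8 of ~160 entries at full scale).
#' @param ... Unused.
#' @rdname identify_partners
#' @export
summary.partner_table <- function(object, k = NULL, ...) {
  has <- !is.na(object$partner_rank)
  if (is.null(k)) k <- max(1L, round(0.05 * (nrow(object) - 1)))
  out <- list(n_entries = nrow(object),
              n_with_counterpart = sum(has),
              k = k,
              top1_fraction = mean(object$partner_rank[has] == 1),
              topk_fraction = mean(object$partner_rank[has] <= k))
  class(out) <- "summary.partner_table"
  out
}

#' @export
print.summary.partner_table <- function(x, ...) {
  cat("Opposite-sex identification over", x$n_with_counterpart,
      "entries (of", x$n_entries, "):\n")
  cat(sprintf("  nearest neighbour is own counterpart: %.1f%%\n",
              100 * x$top1_fraction))
  cat(sprintf("  counterpart within nearest %d: %.1f%%\n",
              x$k, 100 * x$topk_fraction))
  invisible(x)
}

#' Within-cluster homogeneity test of fitted parameters
#'
#' Tests the null hypothesis that diseases in the same cluster share the
#' same mean parameter vector.  The statistic is half the double sum of
#' pairwise equality-test quadratic forms over each cluster,
#' \deqn{\tfrac12 \sum_g \sum_{i \in C_g}\sum_{j \in C_g}
#'   (\hat\mu_i-\hat\mu_j)^T(\Sigma_i+\Sigma_j)^{-1}(\hat\mu_i-\hat\mu_j),}
#' i.e. the sum over unordered within-cluster pairs, referred to a
#' chi-squared distribution with \eqn{p \sum_g n_g(n_g-1)/2} degrees of
#' freedom (p = parameter count).  The chi-squared reference is exact for
#' clusters of size at most two and approximate (mean-exact, variance
#' understated) for larger clusters, because pairwise differences sharing
#' an estimate are correlated.
#'
#' @param mfits Named list of `marginal_fit`s.
#' @param clusters Cluster assignment: vector (optionally named by entry)
#'   with one label per element of `mfits`.
#' @return An object of class `homogeneity_result`: `statistic`, `dof`,
#'   `p_value`, `n_groups`, `group_sizes`, `p_dim`.  With all clusters
#'   singleton the statistic and dof are 0 and the p-value 1.
#' @export
cluster_homogeneity <- function(mfits, clusters) {
  stopifnot(is.list(mfits), length(clusters) == length(mfits))
  if (!is.null(names(clusters)) && !is.null(names(mfits))) {
    if (!setequal(names(clusters), names(mfits))) {
      stop("cluster names do not match entry names", call. = FALSE)
    }
    clusters <- clusters[names(mfits)]
  }
  p_dim <- length(mfits[[1]]$subset_names)
  groups <- split(seq_along(mfits), as.character(clusters))
  stat <- 0
  npairs <- 0
  for (g in groups) {
    if (length(g) < 2) next
    for (pair in combn(g, 2, simplify = FALSE)) {
      i <- pair[1]; j <- pair[2]
      et <- tryCatch(
        equality_test(mfits[[i]], mfits[[j]]),
        error = function(e) {
          stop("singular pairwise covariance sum for entries ",
               names(mfits)[i] %||% i, " and ", names(mfits)[j] %||% j,
               call. = FALSE)
        })
      stat <- stat + et$statistic
      npairs <- npairs + 1
    }
  }
  dof <- p_dim * npairs
  structure(list(statistic = stat, dof = dof,
                 p_value = if (dof == 0) 1 else
                   pchisq(stat, dof, lower.tail = FALSE),
                 n_groups = length(groups),
                 group_sizes = lengths(groups), p_dim = p_dim),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat("Cluster homogeneity: chi2(", x$dof, ") = ", signif(x$statistic, 5),
      ", p = ", format.pval(x$p_value, digits = 3), " over ", x$n_groups,
      " clusters\n", sep = "")
  invisible(x)
}
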