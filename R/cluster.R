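# Hierarchical clustering of diseases on the Bhattacharyya distance matrix,
# cluster-count selection, heat-map transform, and clustering stability.

#' Ward.D2 hierarchical clustering of a Bhattacharyya distance matrix
#'
#' Builds an agglomerative tree with the Ward.D2 update rule applied
#' directly to the supplied distances.  The Bhattacharyya distance is not
#' Euclidean, so Ward.D2's within-cluster variance interpretation is
#' heuristic here; the tree is nonetheless deterministic and well defined,
#' and this is the standard practice for divergence-based disease
#' clustering.
#'
#' @param dm A `bhatt_dist` (or any symmetric non-negative matrix with
#'   labelled rows).
#' @return An [stats::hclust] tree with entry labels.
#' @export
hierarchical_cluster <- function(dm) {
  m <- unclass(dm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(!is.finite(m))) stop("distances must be finite", call. = FALSE)
  if (any(m < 0)) stop("distances must be non-negative", call. = FALSE)
  hclust(as.dist(m), method = "ward.D2")
}

#' Elbow of a quality curve by the maximum-distance-to-chord rule
#'
#' Formalises the qualitative elbow criterion: the elbow is the point with
#' maximum perpendicular distance to the straight chord joining the first
#' and last points of the curve.  Ties take the smallest `x`.
#'
#' @param x,y Coordinates of the curve (e.g. cluster count and
#'   within-cluster homogeneity statistic).
#' @return The `x` value at the elbow.
#' @export
elbow_point <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (length(x) <= 2) return(x[1])
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  cross <- abs(dx * (y - y[1]) - dy * (x - x[1]))
  x[which.max(cross)]
}

#' Choose a cluster count from the homogeneity elbow curve
#'
#' Cuts the tree at every `N` in `k_range`, evaluates the within-cluster
#' homogeneity statistic ([cluster_homogeneity()]) on each cut, picks the
#' elbow of the statistic-versus-N curve by [elbow_point()], and reports
#' the smallest `N` whose homogeneity p-value exceeds `alpha` (no
#' statistically significant within-cluster differences).
#'
#' @param tree An [stats::hclust] tree over the entries of `mfits`.
#' @param mfits Named list of `marginal_fit`s matching `tree$labels`.
#' @param k_range Integer cluster counts to evaluate; default `1` to
#'   `min(60, entries - 1)`.
#' @param alpha Level for the non-significance threshold.
#' @param selected_k Manual override of the elbow choice (the elbow is a
#'   qualitative criterion; the curve is always reported).
#' @return An object of class `disease_clustering`: the tree, the elbow
#'   curve (`N`, `statistic`, `dof`, `p_value`), `selected_k`,
#'   `n_nonsignificant`, and `labels` (entry to cluster at `selected_k`).
#' @export
select_k <- function(tree, mfits, k_range = NULL, alpha = 0.05,
                     selected_k = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n_entries <- length(tree$labels)
  if (!setequal(tree$labels, names(mfits))) {
    stop("tree labels and marginal fits do not match", call. = FALSE)
  }
  mfits <- mfits[tree$labels]
  if (is.null(k_range)) k_range <- seq_len(max(1, min(60, n_entries - 1)))
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > n_entries) {
    stop("k_range must lie within [1, ", n_entries, "]", call. = FALSE)
  }
  curve <- data.frame(N = k_range, statistic = NA_real_, dof = NA_integer_,
                      p_value = NA_real_)
  for (r in seq_along(k_range)) {
    cl <- cutree(tree, k = k_range[r])
    h <- cluster_homogeneity(mfits, cl)
    curve$statistic[r] <- h$statistic
    curve$dof[r] <- h$dof
    curve$p_value[r] <- h$p_value
  }
  auto_k <- elbow_point(curve$N, curve$statistic)
  k <- as.integer(selected_k %||% auto_k)
  nonsig <- curve$N[curve$p_value > alpha]
  structure(list(tree = tree, curve = curve,
                 selected_k = k, elbow_k = as.integer(auto_k),
                 n_nonsignificant = if (length(nonsig)) min(nonsig) else
                   NA_integer_,
                 alpha = alpha,
                 labels = cutree(tree, k = k)),
            class = "disease_clustering")
}

#' @export
print.disease_clustering <- function(x, ...) {
  cat("Disease clustering over", length(x$labels), "entries\n")
  cat("  selected k:", x$selected_k,
      if (x$selected_k != x$elbow_k) paste0("(manual; elbow at ", x$elbow_k, ")")
      else "(elbow criterion)", "\n")
  cat("  smallest N with homogeneity p >", x$alpha, ":",
      x$n_nonsignificant, "\n")
  invisible(x)
}

#' @param x A `disease_clustering`.
#' @param which `"dendrogram"`, `"elbow"` or both.
#' @param ... Passed to the underlying plot calls.
#' @rdname select_k
#' @export
plot.disease_clustering <- function(x, which = c("dendrogram", "elbow"),
                                    ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("dendrogram" %in% which) {
    plot(x$tree, hang = -1, cex = 0.6,
         main = paste("Ward.D2 on Bhattacharyya distances, k =",
                      x$selected_k),
         xlab = "", sub = "", ...)
    if (x$selected_k > 1 && x$selected_k < length(x$labels)) {
      stats::rect.hclust(x$tree, k = x$selected_k, border = "red3")
    }
  }
  if ("elbow" %in% which) {
    plot(x$curve$N, x$curve$statistic, type = "b", pch = 16,
         xlab = "number of clusters N",
         ylab = "within-cluster homogeneity statistic", ...)
    graphics::abline(v = x$selected_k, lty = 2, col = "red3")
  }
  invisible(x)
}

#' Map fitted coefficients to a 0-1 heat-map scale
#'
#' Applies the inverse logit \eqn{1/(1+e^{-\beta})} to each marginalised
#' coefficient: 0.5 is neutral, values above 0.5 indicate association with
#' higher risk, below 0.5 with lower risk.  Monotone in the coefficient.
#'
#' @param mfits Named list of `marginal_fit`s.
#' @return Matrix in \[0, 1\], entries by comparison parameters.
#' @export
heatmap_values <- function(mfits) {
  stopifnot(is.list(mfits), length(mfits) >= 1)
  subset_names <- mfits[[1]]$subset_names
  t(vapply(mfits, function(f) plogis(f$mu), numeric(length(subset_names))))
}

#' Plot a risk-factor heat map
#'
#' @param hm Matrix from [heatmap_values()] (values in \[0, 1\]).
#' @param order Optional row order (e.g. a dendrogram order).
#' @export
plot_risk_heatmap <- function(hm, order = NULL) {
  if (!is.null(order)) hm <- hm[order, , drop = FALSE]
  pal <- grDevices::colorRampPalette(c("white", "orange", "red3"))(101)
  graphics::image(seq_len(ncol(hm)), seq_len(nrow(hm)), t(hm),
                  zlim = c(0, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(hm)), labels = colnames(hm), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(hm)), labels = rownames(hm), las = 2,
                 cex.axis = 0.5)
  invisible(hm)
}

#' Export a clustering dendrogram as Newick text
#'
#' Writes the tree in Newick format with merge heights as branch lengths,
#' readable by standard phylogenetics tooling.
#'
#' @param tree An [stats::hclust] or `disease_clustering`.
#' @param file Output path.
#' @export
write_dendrogram_newick <- function(tree, file) {
  if (inherits(tree, "disease_clustering")) tree <- tree$tree
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = file)
  invisible(file)
}

#' Overlap between two clusterings of the same entries
#'
#' Quantifies clustering stability through preserved within-cluster pairs:
#' with `n_A` and `n_B` the numbers of unordered same-cluster pairs in the
#' two clusterings and `n_AB` the pairs common to both, the overlap is
#' \eqn{p_{AB} = n_{AB} / \min(n_A, n_B)} (1 for identical clusterings, ~0
#' for unrelated ones).  Entries with no co-clustered partner common to
#' both clusterings are reported as sensitive to the clustering procedure.
#'
#' @param a,b Cluster assignments: named vectors over the same entry set,
#'   or `disease_clustering` objects.
#' @return An object of class `stability_comparison`: `n_A`, `n_B`,
#'   `n_AB`, `p_AB`, `sensitive_entries`.
#' @export
compare_clusterings <- function(a, b) {
  lab <- function(x) if (inherits(x, "disease_clustering")) x$labels else x
  a <- lab(a); b <- lab(b)
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) {
      stop("clusterings must cover the same entries", call. = FALSE)
    }
    names(a) <- names(b) <- paste0("e", seq_along(a))
  }
  if (!setequal(names(a), names(b))) {
    stop("clusterings must cover the same entries", call. = FALSE)
  }
  b <- b[names(a)]
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  n_a <- sum(same_a[ut])
  n_b <- sum(same_b[ut])
  n_ab <- sum((same_a & same_b)[ut])
  p_ab <- if (min(n_a, n_b) == 0) {
    if (n_a == 0 && n_b == 0) 1 else NA_real_
  } else {
    n_ab / min(n_a, n_b)
  }
  both <- same_a & same_b
  diag(both) <- FALSE
  sensitive <- names(a)[rowSums(both) == 0]
  structure(list(n_A = n_a, n_B = n_b, n_AB = n_ab, p_AB = p_ab,
                 sensitive_entries = sensitive),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat("Clustering overlap: n_A =", x$n_A, ", n_B =", x$n_B,
      ", n_AB =", x$n_AB, "\n")
  cat("  p_AB =", signif(x$p_AB, 4), ";", length(x$sensitive_entries),
      "sensitive entries\n")
  invisible(x)
}
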