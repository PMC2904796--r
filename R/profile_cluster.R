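#' K-means clustering of averaged aging profiles
#'
#' Clusters strains by their averaged aging profile using Lloyd's algorithm
#' with Euclidean distance on the non-reference-day columns (the reference
#' column is identically zero and carries no information). The best of
#' `n_init` seeded restarts by within-cluster sum of squares is kept, ties
#' broken by the lowest restart index; clusters that empty during iteration
#' are re-seeded from the point farthest from its current centroid. Strains
#' are processed in sorted-id order so the result is independent of input
#' row order for a fixed seed.
#'
#' @param profiles An `aging_profiles` object (typically `qc_report$profiles`);
#'   strains with a missing value at any non-reference day are dropped with
#'   a message.
#' @param k Number of clusters (default 10).
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts (default 20).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return A list of class `cluster_model`: `k`, `centroids`
#'   (k x non-reference-day matrix), `assignment` (named integer vector),
#'   `within_ss`, `days` (feature days), `cluster_labels` (NULL until
#'   [classify_clusters()]), `seed`, `n_init`, `iterations`.
#' @export
kmeans_profiles <- function(profiles, k = 10, seed = 1L, n_init = 20,
                            max_iter = 100) {
  if (k < 2) abort("`k` must be at least 2")
  feat_days <- profiles$days[profiles$days != profiles$reference_day]
  x <- profiles$average[, as.character(feat_days), drop = FALSE]
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    inform(sprintf("dropping %d strain(s) with incomplete averaged profiles",
                   sum(!complete)))
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < k) abort("`k` exceeds the number of complete profiles")
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      fit <- lloyd_once(x, k, max_iter)
      if (is.null(best) || fit$within_ss < best$within_ss) {
        best <- fit
        best$restart <- init
      }
    }
  })
  structure(
    list(k = k, centroids = best$centroids,
         assignment = stats::setNames(best$assignment, rownames(x)),
         within_ss = best$within_ss, days = feat_days,
         cluster_labels = NULL, seed = seed, n_init = n_init,
         iterations = best$iterations, restart = best$restart),
    class = "cluster_model"
  )
}

# One Lloyd run from a random k-point initialization. Uses the current RNG
# stream (caller controls seeding).
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centroids <- x[sample.int(n, k), , drop = FALSE]
  assignment <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(x, centroids)
    new_assignment <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the globally farthest point
    repeat {
      sizes <- tabulate(new_assignment, nbins = k)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      nearest <- d2[cbind(seq_len(n), new_assignment)]
      far <- which.max(nearest)
      centroids[empty[1], ] <- x[far, ]
      d2[, empty[1]] <- rowSums(sweep(x, 2, centroids[empty[1], ])^2)
      new_assignment <- max.col(-d2, ties.method = "first")
    }
    converged <- identical(new_assignment, assignment)
    assignment <- new_assignment
    for (j in seq_len(k)) {
      centroids[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
    }
    if (converged) break
  }
  d2 <- sq_dist(x, centroids)
  within_ss <- sum(d2[cbind(seq_len(n), assignment)])
  list(centroids = centroids, assignment = assignment,
       within_ss = within_ss, iterations = iter)
}

# Squared Euclidean distances between rows of x and rows of c (n x k).
sq_dist <- function(x, centroids) {
  xc <- x %*% t(centroids)
  outer(rowSums(x^2), rep(1, nrow(centroids))) - 2 * xc +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k, "on", length(x$assignment),
      "strains; within-cluster SS =", format(x$within_ss, digits = 6), "\n")
  if (!is.null(x$cluster_labels)) {
    cat("  labels:", paste(sprintf("%d=%s", seq_len(x$k), x$cluster_labels),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Classify clusters as short-lived, long-lived or neutral
#'
#' Replaces by-eye inspection of cluster trajectories with an explicit
#' boundary in log2-ratio space: each cluster's centroid is summarized by
#' its mean over non-reference days, and the cluster is labeled short-lived
#' if that mean is at or below `-theta_short`, long-lived if at or above
#' `+theta_long`, neutral otherwise. A strain whose relative abundance halves
#' on average (centroid mean -1) is unambiguously short-lived; the default
#' thresholds of 0.5 log2 units place the boundary halfway to that.
#'
#' @param model A `cluster_model`.
#' @param theta_short,theta_long Boundary magnitudes in log2 units
#'   (default 0.5 each).
#' @return The model with `cluster_labels` filled in (character vector of
#'   length k).
#' @export
classify_clusters <- function(model, theta_short = 0.5, theta_long = 0.5) {
  m <- rowMeans(model$centroids)
  model$cluster_labels <- ifelse(m <= -theta_short, "short",
                                 ifelse(m >= theta_long, "long", "neutral"))
  model$theta_short <- theta_short
  model$theta_long <- theta_long
  model
}

#' Per-strain lifespan class from cluster labels
#'
#' Each strain inherits the label of its cluster.
#'
#' @param model A labeled `cluster_model` (see [classify_clusters()]).
#' @return Tibble with columns `strain_id`, `cluster`, `class`.
#' @export
strain_classes <- function(model) {
  if (is.null(model$cluster_labels)) {
    abort("model has no cluster labels; run classify_clusters() first")
  }
  tibble::tibble(
    strain_id = names(model$assignment),
    cluster = unname(model$assignment),
    class = model$cluster_labels[model$assignment]
  )
}
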