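# Sample clustering on relative signature exposures and the cross-caller
# consensus of stable samples.

#' K-means clustering of relative signature exposures
#'
#' @param rel_exposures Samples x signatures matrix of relative exposures
#'   (rows sum to one).
#' @param k Number of clusters (>= 1).
#' @param seed Seed for the restarts.
#' @param n_restarts Random restarts; the best within-cluster sum of
#'   squares wins. Default 50.
#' @return A `cluster_assignment`: list with `sample_ids`, `labels`
#'   (integers 1..k), `k`, `centroids` (k x signatures) and
#'   `dominant_signature` (per-cluster argmax of the centroid).
#' @export
kmeans_exposures <- function(rel_exposures, k, seed = 1L, n_restarts = 50L) {
  rel_exposures <- as.matrix(rel_exposures)
  if (k > nrow(rel_exposures))
    stop("k exceeds the number of samples")
  if (is.null(rownames(rel_exposures)))
    rownames(rel_exposures) <- paste0("S", seq_len(nrow(rel_exposures)))
  set.seed(seed)
  km <- if (k == 1L) {
    list(cluster = rep(1L, nrow(rel_exposures)),
         centers = matrix(colMeans(rel_exposures), 1,
                          dimnames = list(NULL, colnames(rel_exposures))))
  } else {
    stats::kmeans(rel_exposures, centers = k, nstart = n_restarts,
                  iter.max = 100L)
  }
  centroids <- km$centers
  structure(list(sample_ids = rownames(rel_exposures),
                 labels = stats::setNames(as.integer(km$cluster),
                                          rownames(rel_exposures)),
                 k = as.integer(k), centroids = centroids,
                 dominant_signature = colnames(centroids)[
                   apply(centroids, 1, which.max)]),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d samples, k=%d (sizes %s)>\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

# Hungarian algorithm (O(n^3), potentials formulation) for the minimum-cost
# square assignment problem; returns for each row its assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Align per-caller cluster labels and intersect stable samples
#'
#' Aligns each caller's cluster labels to the first caller's by
#' maximum-overlap assignment (Hungarian algorithm on the negated
#' contingency table), then keeps the samples whose aligned label agrees
#' across all callers. The instability rate is 1 - |stable| / |union of
#' samples|.
#'
#' @param assignments List of [kmeans_exposures()] assignments (>= 2), all
#'   with the same k, over overlapping sample sets.
#' @return A `consensus_assignment`: list with `assignments`,
#'   `aligned_labels` (samples x callers matrix, NA where absent),
#'   `stable_samples`, `final_labels` (aligned labels of the stable
#'   samples), `instability_rate`.
#' @export
align_and_intersect <- function(assignments) {
  stopifnot(length(assignments) >= 2)
  ks <- vapply(assignments, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1) stop("assignments differ in k")
  k <- ks[1]
  all_samples <- sort(unique(unlist(lapply(assignments, `[[`, "sample_ids"))))
  lab <- matrix(NA_integer_, length(all_samples), length(assignments),
                dimnames = list(all_samples, NULL))
  for (a in seq_along(assignments))
    lab[assignments[[a]]$sample_ids, a] <- assignments[[a]]$labels
  # align every caller to the first by maximizing label overlap
  aligned <- lab
  for (a in seq_along(assignments)[-1]) {
    shared <- !is.na(lab[, 1]) & !is.na(lab[, a])
    tab <- table(factor(lab[shared, a], levels = seq_len(k)),
                 factor(lab[shared, 1], levels = seq_len(k)))
    perm <- solve_assignment(-as.matrix(tab))
    aligned[, a] <- perm[lab[, a]]
  }
  agree <- rowSums(!is.na(aligned)) == ncol(aligned) &
    apply(aligned, 1, function(x) length(unique(x[!is.na(x)])) == 1)
  stable <- all_samples[agree]
  structure(list(assignments = assignments,
                 aligned_labels = aligned,
                 stable_samples = stable,
                 final_labels = stats::setNames(aligned[stable, 1], stable),
                 instability_rate = 1 - length(stable) / length(all_samples)),
            class = "consensus_assignment")
}

#' @export
print.consensus_assignment <- function(x, ...) {
  cat(sprintf(paste0("<consensus_assignment: %d callers, %d/%d stable ",
                     "samples (instability %.1f%%)>\n"),
              ncol(x$aligned_labels), length(x$stable_samples),
              nrow(x$aligned_labels), 100 * x$instability_rate))
  invisible(x)
}
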