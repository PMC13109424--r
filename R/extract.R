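# De novo signature extraction: replicated KL-NMF on bootstrap-resampled
# catalogs, consensus signatures by medoid partitioning of the pooled
# replicate solutions, and stability-based selection of the number of
# signatures.

#' Extract de novo mutational signatures
#'
#' For each candidate number of signatures k, runs `n_replicates` KL-NMF
#' fits on bootstrap-resampled catalogs (random initialization, one seed per
#' replicate), pools the replicate signature profiles, partitions them into
#' k consensus clusters by k-medoids on the distance 1 - cosine, and takes
#' the renormalized cluster medoids as the consensus signatures. Stability
#' per k is the mean silhouette width of that partition; goodness of fit is
#' the mean over samples of the cosine between the observed spectrum and
#' its reconstruction from NNLS-refit exposures on the un-resampled catalog.
#'
#' @param catalog A [mutation_catalog()] (outlier-filtered).
#' @param k_range Candidate k values. Default 2:10.
#' @param n_replicates Bootstrap/NMF replicates per k. Default 30.
#' @param seed Master seed; replicate streams are derived from it.
#' @param max_iter,tol Passed to [nmf_kl()].
#' @return An `extraction_report`: list with `per_k` (one record per k:
#'   `k`, `signatures` ([signature_matrix()]), `activities` (samples x k),
#'   `mean_silhouette`, `mean_sample_cosine`, `n_replicates_used`) and
#'   `chosen_k` from [select_k()] with default thresholds.
#' @export
extract_signatures <- function(catalog, k_range = 2:10, n_replicates = 30L,
                               seed = 1L, max_iter = 500L, tol = 1e-6) {
  schema <- catalog_schema(catalog)
  k_range <- as.integer(k_range)
  totals <- rowSums(catalog)
  if (any(totals == 0)) {
    warning("dropping ", sum(totals == 0),
            " zero-total sample(s) from extraction")
    catalog <- catalog[totals > 0, , drop = FALSE]
    catalog <- mutation_catalog(unclass(catalog), schema)
  }
  V <- t(unclass(catalog))  # channels x samples
  per_k <- vector("list", length(k_range))
  names(per_k) <- as.character(k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    fits <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      rs <- stage_seed(seed, sprintf("nmf_k%d_rep%d", k, r))
      fits[[r]] <- tryCatch({
        boot <- bootstrap_catalog(catalog, rs)
        nmf_kl(t(unclass(boot)), k, seed = rs, max_iter = max_iter,
               tol = tol, init = "random")
      }, error = function(e) NULL)
    }
    ok <- !vapply(fits, is.null, logical(1))
    if (sum(ok) < max(1L, ceiling(n_replicates / 2)))
      stop("fewer than half of the NMF replicates succeeded at k = ", k)
    fits <- fits[ok]
    pooled <- do.call(cbind, lapply(fits, `[[`, "W"))  # channels x (reps*k)
    cons <- consensus_signatures(pooled, k, n_used = length(fits))
    W <- signature_matrix(cons$profiles, schema)
    colnames(W) <- paste0(sub("SBS", "SBS", schema$name), LETTERS[seq_len(k)])
    acts <- t(.nnls_solve_multi(unclass(W), V))
    dimnames(acts) <- list(rownames(catalog), colnames(W))
    recon <- unclass(W) %*% t(acts)
    cosines <- vapply(seq_len(ncol(V)), function(j)
      cosine_sim(V[, j], recon[, j]), numeric(1))
    per_k[[ki]] <- list(k = k, signatures = W, activities = acts,
                        mean_silhouette = cons$mean_silhouette,
                        mean_sample_cosine = mean(cosines),
                        n_replicates_used = length(fits))
    log_stage("extract", k = k, silhouette = round(cons$mean_silhouette, 3),
              sample_cosine = round(mean(cosines), 4))
  }
  report <- structure(list(per_k = per_k, k_range = k_range,
                           sample_ids = rownames(catalog)),
                      class = "extraction_report")
  report$chosen_k <- select_k(report)
  report
}

# Partition pooled replicate signature profiles (channels x m) into k
# consensus clusters; returns medoid profiles and mean silhouette width.
consensus_signatures <- function(pooled, k, n_used) {
  if (n_used == 1L) {
    # single replicate: stability is undefined; sentinel 1 with a flag
    return(list(profiles = pooled,
                mean_silhouette = structure(1, degenerate = TRUE)))
  }
  sim <- cosine_matrix(t(pooled))
  D <- stats::as.dist(1 - sim)
  if (k == 1L) {
    # one cluster: report mean pairwise profile cosine as stability
    med <- which.min(colSums(1 - sim))
    return(list(profiles = pooled[, med, drop = FALSE],
                mean_silhouette = mean(sim[lower.tri(sim)])))
  }
  pm <- cluster::pam(D, k, diss = TRUE)
  list(profiles = pooled[, pm$id.med, drop = FALSE],
       mean_silhouette = pm$silinfo$avg.width)
}

#' @export
print.extraction_report <- function(x, ...) {
  cat("<extraction_report>\n")
  for (rec in x$per_k)
    cat(sprintf("  k=%d  silhouette=%.3f  sample_cosine=%.4f%s\n",
                rec$k, rec$mean_silhouette, rec$mean_sample_cosine,
                if (rec$k == x$chosen_k) "  <- chosen" else ""))
  invisible(x)
}

#' Select the number of de novo signatures
#'
#' Chooses the largest k whose replicate-consensus stability (mean
#' silhouette) reaches `stability_floor` and whose mean sample cosine
#' improves on the previous candidate k by more than `min_gain` (the
#' smallest candidate is exempt from the gain requirement). If no k
#' qualifies, falls back to the k with maximal silhouette, with a warning.
#'
#' @param report An [extract_signatures()] report.
#' @param stability_floor Minimum mean silhouette. Default 0.8.
#' @param min_gain Minimum sample-cosine improvement over the previous k.
#'   Default 0.01.
#' @return Integer k.
#' @export
select_k <- function(report, stability_floor = 0.8, min_gain = 0.01) {
  ks <- as.integer(vapply(report$per_k, function(r) as.numeric(r$k),
                          numeric(1)))
  sil <- vapply(report$per_k, function(r) as.numeric(r$mean_silhouette),
                numeric(1))
  cosine <- vapply(report$per_k, `[[`, numeric(1), "mean_sample_cosine")
  ord <- order(ks)
  ks <- ks[ord]; sil <- sil[ord]; cosine <- cosine[ord]
  gain <- c(Inf, diff(cosine))
  eligible <- sil >= stability_floor & gain > min_gain
  if (!any(eligible)) {
    warning("no k meets the stability/gain rule; ",
            "falling back to the most stable k")
    return(ks[which.max(sil)])
  }
  max(ks[eligible])
}
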