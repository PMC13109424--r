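# Rare-spectrum screening: joint NMF extraction can ascribe a signature that
# exists only in a few hypermutated samples to the whole cohort ("signature
# bleeding"). Samples with high burden and an unusual 96-channel spectrum
# are therefore flagged and removed before extraction.

#' Select high-mutation-burden samples
#'
#' @param catalog A [mutation_catalog()] (collapsed to SBS96 internally if
#'   strand-aware).
#' @param threshold Burden threshold; samples with total count strictly
#'   greater than it are returned. Default 600.
#' @return Character vector of sample ids.
#' @export
select_high_burden <- function(catalog, threshold = 600) {
  totals <- rowSums(catalog)
  rownames(catalog)[totals > threshold]
}

#' Cluster high-burden mutation spectra by cosine similarity
#'
#' Computes pairwise cosine similarity between relative 96-channel spectra,
#' performs average-linkage hierarchical clustering on the distance
#' 1 - cosine, and cuts the tree at a fixed height into spectrum groups.
#' Zero-total samples are excluded with a warning.
#'
#' @param catalog A [mutation_catalog()] restricted to the high-burden
#'   samples (any schema; collapsed to SBS96).
#' @param cut_height Tree-cut distance. Default 0.25.
#' @return A `spectrum_cluster_report`: list with `samples`,
#'   `pairwise_cosine`, `hclust` (the merge tree), `groups` (integer
#'   partition), `group_sizes` and `group_mean_spectra` (per-group mean
#'   relative 96-channel profile).
#' @export
cosine_cluster <- function(catalog, cut_height = 0.25) {
  cat96 <- collapse_catalog(catalog, "SBS96")
  totals <- rowSums(cat96)
  if (any(totals == 0)) {
    warning("excluding ", sum(totals == 0), " zero-total sample(s)")
    cat96 <- cat96[totals > 0, , drop = FALSE]
  }
  if (nrow(cat96) < 2) stop("need at least 2 positive-total samples")
  rel <- unclass(cat96) / rowSums(cat96)
  sim <- cosine_matrix(rel)
  dimnames(sim) <- list(rownames(rel), rownames(rel))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  groups <- stats::cutree(hc, h = cut_height)
  means <- rowsum(rel, groups) / as.vector(table(groups))
  structure(list(samples = rownames(rel), pairwise_cosine = sim,
                 hclust = hc, groups = groups,
                 group_sizes = as.vector(table(groups)),
                 group_mean_spectra = means,
                 cut_height = cut_height),
            class = "spectrum_cluster_report")
}

#' @export
print.spectrum_cluster_report <- function(x, ...) {
  cat(sprintf("<spectrum_cluster_report: %d samples, %d groups (sizes %s)>\n",
              length(x$samples), length(x$group_sizes),
              paste(sort(x$group_sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Flag samples with rare mutation spectra
#'
#' Samples whose spectrum group contains fewer than `min_size` members are
#' flagged as rare and should be excluded from de novo extraction.
#'
#' @param report A [cosine_cluster()] report.
#' @param min_size Groups smaller than this are rare. Default 5.
#' @return Character vector of flagged sample ids.
#' @export
flag_rare <- function(report, min_size = 5) {
  sizes <- table(report$groups)
  rare_groups <- as.integer(names(sizes)[sizes < min_size])
  flagged <- report$samples[report$groups %in% rare_groups]
  log_stage("flag_rare", groups = length(sizes), rare_groups =
              length(rare_groups), flagged = length(flagged))
  flagged
}

#' Annotate rare spectrum groups against a reference catalog
#'
#' For human review only: reports, for each spectrum group, the reference
#' signature whose profile is closest (best cosine) to the group's mean
#' spectrum. Not used to decide removal.
#'
#' @param report A [cosine_cluster()] report.
#' @param reference A [signature_matrix()] in SBS96 (or collapsible) schema.
#' @return Data.frame with one row per group: `group`, `size`,
#'   `best_match`, `cosine`.
#' @export
annotate_groups <- function(report, reference) {
  ref96 <- collapse_signatures(reference, "SBS96")
  means <- report$group_mean_spectra[, rownames(ref96), drop = FALSE]
  sims <- apply(means, 1, function(m)
    apply(unclass(ref96), 2, cosine_sim, x = m))
  if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1,
                                         dimnames = list(colnames(ref96)))
  best <- apply(sims, 2, which.max)
  data.frame(group = as.integer(rownames(means)),
             size = as.vector(table(report$groups)),
             best_match = rownames(sims)[best],
             cosine = sims[cbind(best, seq_along(best))],
             stringsAsFactors = FALSE)
}
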