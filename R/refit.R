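# Reference-signature refitting: NNLS decomposition of spectra and de novo
# signatures, and per-sample attribution with bootstrap confidence
# intervals and zero-in-CI pruning to prevent over-attribution.

#' Nonnegative least-squares signature fit
#'
#' Solves `min || reference %*% a - spectrum ||_2` over nonnegative
#' activities `a` (Lawson-Hanson active set). Deterministic.
#'
#' @param spectrum Channel count vector (named or in the reference's
#'   canonical channel order).
#' @param reference A [signature_matrix()].
#' @return Named nonnegative activity vector (mutation counts per
#'   signature).
#' @export
nnls_fit <- function(spectrum, reference) {
  spectrum <- align_spectrum(spectrum, reference)
  a <- as.vector(.nnls_solve(unclass(reference), spectrum))
  stats::setNames(a, colnames(reference))
}

align_spectrum <- function(spectrum, reference) {
  if (!is.null(names(spectrum))) {
    if (!setequal(names(spectrum), rownames(reference)))
      stop("spectrum channels do not match the reference schema")
    spectrum <- spectrum[rownames(reference)]
  } else if (length(spectrum) != nrow(reference)) {
    stop("spectrum length does not match the reference channel dimension")
  }
  as.numeric(spectrum)
}

#' Decompose de novo signatures into reference signatures
#'
#' Fits each de novo signature profile against a reference catalog by NNLS
#' and reports the weights as percentages, together with the reconstruction
#' cosine. Schemas are made compatible by collapsing the higher-dimensional
#' side.
#'
#' @param denovo,reference [signature_matrix()] objects.
#' @return List with `weights` (de novo x reference percentage matrix, rows
#'   sum to 100 for nonzero fits) and `cosine` (per de novo signature).
#' @export
decompose_denovo <- function(denovo, reference) {
  sc_d <- as_channel_schema(attr(denovo, "schema"))
  sc_r <- as_channel_schema(attr(reference, "schema"))
  if (sc_d$name != sc_r$name) {
    dims <- c(SBS96 = 96L, SBS288 = 288L, SBS384 = 384L)
    target <- names(which.min(dims[c(sc_d$name, sc_r$name)]))
    denovo <- collapse_signatures(denovo, target)
    reference <- collapse_signatures(reference, target)
  }
  X <- .nnls_solve_multi(unclass(reference), unclass(denovo))
  recon <- unclass(reference) %*% X
  cosine <- vapply(seq_len(ncol(denovo)), function(j)
    cosine_sim(denovo[, j], recon[, j]), numeric(1))
  tot <- colSums(X)
  tot[tot == 0] <- 1
  weights <- t(sweep(X, 2, tot, "/")) * 100
  dimnames(weights) <- list(colnames(denovo), colnames(reference))
  list(weights = weights,
       cosine = stats::setNames(cosine, colnames(denovo)))
}

#' Signature attribution with bootstrap CIs and zero-in-CI pruning
#'
#' Attributes a sample's spectrum to a candidate signature set: NNLS point
#' estimate, percentile bootstrap confidence intervals from multinomial
#' resamples of the spectrum, then iterative pruning — all signatures whose
#' CI lower bound does not exceed zero are removed simultaneously and the
#' reduced set refit (same resamples) — until every retained signature's CI
#' excludes zero or the set is empty. Final CIs are recomputed on the final
#' set. Pruning implements the attribution rule that activities whose
#' confidence interval includes zero are discarded to prevent overfitting.
#'
#' @param spectrum Channel count vector with positive total.
#' @param candidates A [signature_matrix()] of candidate signatures.
#' @param n_bootstrap Bootstrap resamples (>= 50). Default 200.
#' @param ci_alpha Two-sided miscoverage; 0.05 gives 95% CIs.
#' @param seed Integer seed for the resampling.
#' @return A `fit_result`: data.frame with one row per candidate
#'   (`signature`, `activity`, `ci_low`, `ci_high`, `pruned`) and
#'   attributes `residual_cosine`, `n_rounds`, `total`.
#' @export
attribute_with_ci <- function(spectrum, candidates, n_bootstrap = 200L,
                              ci_alpha = 0.05, seed = 1L) {
  spectrum <- align_spectrum(spectrum, candidates)
  total <- sum(spectrum)
  if (total <= 0) stop("spectrum total must be positive")
  if (n_bootstrap < 50) stop("n_bootstrap must be at least 50")
  sigs <- colnames(candidates)
  S <- unclass(candidates)
  set.seed(seed)
  B <- stats::rmultinom(n_bootstrap, total, spectrum / total)
  keep <- seq_along(sigs)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    boot_act <- .nnls_solve_multi(S[, keep, drop = FALSE], B)
    ci <- apply(boot_act, 1, stats::quantile,
                probs = c(ci_alpha / 2, 1 - ci_alpha / 2), names = FALSE)
    zero_in <- ci[1, ] <= 1e-9
    if (!any(zero_in)) break
    if (all(zero_in)) { keep <- integer(0); break }
    keep <- keep[!zero_in]
  }
  activity <- stats::setNames(numeric(length(sigs)), sigs)
  ci_low <- ci_high <- activity
  if (length(keep)) {
    fit <- .nnls_solve(S[, keep, drop = FALSE], spectrum)
    activity[keep] <- as.vector(fit)
    ci_low[keep] <- ci[1, ]
    ci_high[keep] <- ci[2, ]
    recon <- S[, keep, drop = FALSE] %*% fit
  } else recon <- rep(0, length(spectrum))
  res <- data.frame(signature = sigs, activity = activity,
                    ci_low = ci_low, ci_high = ci_high,
                    pruned = !(seq_along(sigs) %in% keep),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("fit_result", "data.frame"),
            residual_cosine = cosine_sim(spectrum, as.vector(recon)),
            n_rounds = rounds, total = total, seed = seed)
}

#' Attribute every sample of a catalog
#'
#' Applies [attribute_with_ci()] (or plain [nnls_fit()] when
#' `prune = FALSE`) to each row of a catalog.
#'
#' @param catalog A [mutation_catalog()].
#' @param candidates A [signature_matrix()] sharing the catalog's schema
#'   (or collapsible to it).
#' @param prune Use CI pruning (TRUE) or plain NNLS (FALSE).
#' @param n_bootstrap,ci_alpha,seed As in [attribute_with_ci()].
#' @return Samples x signatures activity matrix; when `prune = TRUE`, the
#'   per-sample `fit_result`s are attached as attribute `fits`.
#' @export
attribute_catalog <- function(catalog, candidates, prune = TRUE,
                              n_bootstrap = 200L, ci_alpha = 0.05,
                              seed = 1L) {
  sc_cat <- catalog_schema(catalog)$name
  sc_ref <- attr(candidates, "schema")
  if (sc_cat != sc_ref) catalog <- collapse_catalog(catalog, sc_ref)
  counts <- unclass(catalog)
  acts <- matrix(0, nrow(counts), ncol(candidates),
                 dimnames = list(rownames(counts), colnames(candidates)))
  if (!prune) {
    pos <- rowSums(counts) > 0
    if (any(pos))
      acts[pos, ] <- t(.nnls_solve_multi(unclass(candidates),
                                         t(counts[pos, , drop = FALSE])))
    return(acts)
  }
  fits <- vector("list", nrow(counts))
  names(fits) <- rownames(counts)
  for (i in seq_len(nrow(counts))) {
    if (sum(counts[i, ]) == 0) next
    fr <- attribute_with_ci(counts[i, ], candidates, n_bootstrap, ci_alpha,
                            seed = stage_seed(seed, rownames(counts)[i]))
    acts[i, ] <- fr$activity
    fits[[i]] <- fr
  }
  attr(acts, "fits") <- fits
  acts
}
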