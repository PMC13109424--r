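#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the stratification pipeline. Defaults
#' reflect the analysis the package implements: high-burden samples are those
#' with strictly more than 600 mutations, spectrum groups seen in fewer than
#' 5 such samples are rare, de novo extraction scans 2..10 signatures, and
#' reference attribution prunes signatures whose 95% bootstrap confidence
#' interval includes zero.
#'
#' @param burden_threshold Mutation count above which (strictly) a sample
#'   enters rare-spectrum screening. Default 600.
#' @param rare_max_size Spectrum groups smaller than this are rare. Default 5.
#' @param rare_cut_height Cosine-distance height at which the spectrum
#'   dendrogram is cut into groups. Default 0.25.
#' @param k_range Candidate numbers of de novo signatures. Default 2:10.
#' @param n_nmf_replicates Bootstrap-resampled NMF replicates per k.
#'   Default 30.
#' @param n_bootstrap Bootstrap resamples for attribution confidence
#'   intervals. Default 200.
#' @param ci_alpha Two-sided miscoverage of the attribution CIs (0.05 gives
#'   95% intervals). Default 0.05.
#' @param stability_floor Minimum mean silhouette for a k to be considered
#'   stable. Default 0.8.
#' @param min_cosine_gain Minimum improvement in mean sample cosine over k-1
#'   for a larger k to be preferred. Default 0.01.
#' @param kmeans_k Number of sample clusters, or `"auto"` to reuse the chosen
#'   number of de novo signatures.
#' @param seed Integer master seed; each stage derives its own stream.
#' @param channel_schema Extraction schema name. Default `"SBS384"`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(burden_threshold = 600L, rare_max_size = 5L,
                       rare_cut_height = 0.25, k_range = 2:10,
                       n_nmf_replicates = 30L, n_bootstrap = 200L,
                       ci_alpha = 0.05, stability_floor = 0.8,
                       min_cosine_gain = 0.01, kmeans_k = "auto",
                       seed = 1L,
                       channel_schema = c("SBS384", "SBS288", "SBS96")) {
  channel_schema <- match.arg(channel_schema)
  stopifnot(burden_threshold > 0, rare_max_size > 0,
            length(k_range) >= 1, all(k_range >= 1),
            n_nmf_replicates >= 1, n_bootstrap >= 1,
            ci_alpha > 0, ci_alpha < 1,
            rare_cut_height > 0,
            identical(kmeans_k, "auto") || kmeans_k >= 1)
  structure(list(burden_threshold = as.integer(burden_threshold),
                 rare_max_size = as.integer(rare_max_size),
                 rare_cut_height = rare_cut_height,
                 k_range = as.integer(sort(unique(k_range))),
                 n_nmf_replicates = as.integer(n_nmf_replicates),
                 n_bootstrap = as.integer(n_bootstrap),
                 ci_alpha = ci_alpha,
                 stability_floor = stability_floor,
                 min_cosine_gain = min_cosine_gain,
                 kmeans_k = kmeans_k,
                 seed = as.integer(seed),
                 channel_schema = channel_schema),
            class = "run_config")
}
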