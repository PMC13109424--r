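# Synthetic cohorts with the statistical structure the pipeline assumes:
# spectra are multinomial draws from mixtures of planted signature profiles
# (weights uniform-drawn and normalized, or cluster plans with a dominant
# process), burdens are heterogeneous, variants are placed at
# context-matching genomic sites of a mini-genome with stranded genes, and
# three imperfect pseudo-callers report them with dropout and false calls.
# A ledger records every ground truth for oracle testing.

SYNTH_PROCESSES <- c("clock", "apobec", "smoking", "alcohol", "flat",
                     "uv", "mmr")

# Hand-built 96-channel profiles sketching well-known mutational processes.
process_profile96 <- function(process) {
  labels <- sbs96_labels()
  p <- parse_channel(labels)
  w <- rep(0, 96)
  sub <- paste0(p$ref, ">", p$alt)
  smooth <- switch(process,
    clock = { w[sub == "C>T" & p$three == "G"] <- 0.55 / 4
              w[sub == "C>T" & p$three != "G"] <- 0.17 / 12; 0.28 },
    apobec = { w[p$five == "T" & p$three %in% c("A", "T") &
                   sub %in% c("C>T", "C>G")] <- 0.78 / 8; 0.22 },
    smoking = { w[sub == "C>A"] <- 0.70 / 16
                w[sub == "C>A" & p$five == "C"] <- 0.10 / 4; 0.20 },
    alcohol = { w[sub == "T>C"] <- 0.55 / 16
                w[sub == "T>C" & p$five == "A"] <- 0.25 / 4; 0.20 },
    flat = { w[] <- 0; 1.0 },
    uv = { w[sub == "C>T" & p$five %in% c("C", "T")] <- 0.90 / 8; 0.10 },
    mmr = { w[sub == "C>T" & p$five == "G"] <- 0.45 / 4
            w[sub == "T>C" & p$five == "G"] <- 0.35 / 4; 0.20 },
    stop("unknown process: ", process))
  w <- w + smooth / 96
  stats::setNames(w / sum(w), labels)
}

# Transcription-strand mass fractions (T, U, B, N) per process. Damage-type
# processes (bulky adducts on purines, as in tobacco; alcohol-linked T>C)
# get an asymmetric T/U split reflecting transcription-coupled repair;
# replication-linked processes are near-symmetric.
process_strand_fractions <- function(process) {
  switch(process,
    smoking = c(T = 0.30, U = 0.12, B = 0.02, N = 0.56),
    alcohol = c(T = 0.33, U = 0.08, B = 0.02, N = 0.57),
    uv      = c(T = 0.28, U = 0.14, B = 0.02, N = 0.56),
    c(T = 0.20, U = 0.20, B = 0.02, N = 0.58))
}

#' Planted signature profiles for simulation
#'
#' Builds a pool of hand-designed signature profiles sketching familiar
#' mutagenic processes: `clock` (C>T at XCG, spontaneous deamination),
#' `apobec` (C>T/C>G at TCW), `smoking` (broad C>A with transcription
#' strand bias), `alcohol` (T>C, strongly strand-biased), `flat`
#' (near-uniform), `uv` (C>T at dipyrimidines) and `mmr` (mismatch-repair
#' deficiency-like). Strand-aware schemas distribute each 96-channel
#' profile over the T/U/B/N categories with process-specific asymmetry.
#'
#' @param processes Subset of the available process names.
#' @param schema Target schema name. Default `"SBS384"`.
#' @return A [signature_matrix()].
#' @export
simulate_signatures <- function(processes = c("clock", "apobec", "smoking",
                                              "alcohol"),
                                schema = "SBS384") {
  stopifnot(all(processes %in% SYNTH_PROCESSES))
  schema <- as_channel_schema(schema)
  prof <- vapply(processes, function(pr) {
    p96 <- process_profile96(pr)
    if (schema$name == "SBS96") return(p96)
    f <- process_strand_fractions(pr)
    if (schema$name == "SBS288") {
      f <- c(f["T"], f["U"], N = unname(f["B"] + f["N"]))
    }
    as.vector(outer(p96, f[schema$strand_categories], "*"))
  }, numeric(length(schema$channels)))
  rownames(prof) <- schema$channels
  colnames(prof) <- processes
  signature_matrix(prof, schema)
}

#' Draw one synthetic mutation spectrum
#'
#' Signature contributions are drawn uniformly on (0, 1) and normalized to
#' sum to one (or taken as given); the per-channel mutation probability is
#' the weighted sum of the signature profiles, and counts are sampled with
#' replacement (multinomially) until the requested burden is reached.
#'
#' @param signatures A [signature_matrix()] pool.
#' @param weights `"random"` or a nonnegative vector over the pool.
#' @param mutation_count Total mutations to emit.
#' @param seed Integer seed.
#' @return List with `counts` (named channel count vector) and `weights`
#'   (the normalized contribution vector).
#' @export
generate_profile <- function(signatures, weights = "random", mutation_count,
                             seed = 1L) {
  set.seed(seed)
  k <- ncol(signatures)
  if (identical(weights, "random")) weights <- stats::runif(k)
  if (length(weights) != k || any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative over the pool with positive sum")
  weights <- weights / sum(weights)
  p <- as.vector(unclass(signatures) %*% weights)
  counts <- if (mutation_count > 0)
    as.vector(stats::rmultinom(1, mutation_count, p))
  else rep(0L, nrow(signatures))
  list(counts = stats::setNames(counts, rownames(signatures)),
       weights = stats::setNames(weights, colnames(signatures)))
}

#' Synthetic genome with stranded gene annotation
#'
#' Uniform-random contigs with four non-overlapping genes per contig
#' (alternating strands) plus one opposite-strand overlapping gene pair, so
#' that all four transcription-strand categories (T, U, B, N) have sites.
#'
#' @param n_contigs Number of contigs. Default 10.
#' @param contig_length Contig length in bp. Default 1e5.
#' @param seed Integer seed.
#' @return List with `genome` (named character vector) and `annotation`
#'   (`GRanges` with strand).
#' @export
synthetic_genome <- function(n_contigs = 10L, contig_length = 1e5L,
                             seed = 1L) {
  set.seed(stage_seed(seed, "genome"))
  L <- as.integer(contig_length)
  contigs <- paste0("ctg", seq_len(n_contigs))
  genome <- vapply(contigs, function(ct)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
    character(1))
  u <- function(x) as.integer(round(x * L))
  starts <- c(u(0.05), u(0.25), u(0.45), u(0.65), u(0.82), u(0.84))
  ends   <- c(u(0.20), u(0.40), u(0.60), u(0.80), u(0.90), u(0.92))
  strands <- c("+", "-", "+", "-", "+", "-")
  ann <- GenomicRanges::GRanges(
    rep(contigs, each = length(starts)),
    IRanges::IRanges(rep(starts, n_contigs), rep(ends, n_contigs)),
    strand = rep(strands, n_contigs))
  ann$gene_id <- paste0("gene", seq_along(ann))
  list(genome = genome, annotation = ann)
}

# Index genomic sites by (pyrimidine-strand trinucleotide, strand category).
# Returns a list keyed "TRINUC|CAT" of data.frames (chrom, pos, pyr_strand).
site_index <- function(genome, annotation) {
  seqs <- genome_as_strings(genome)
  pieces <- lapply(names(seqs), function(ct) {
    s <- seqs[[ct]]
    L <- nchar(s)
    pos <- 2:(L - 1)
    tri <- substring(s, pos - 1, pos + 1)
    center <- substr(tri, 2, 2)
    pyr <- center %in% c("C", "T")
    tri_pyr <- ifelse(pyr, tri, revcomp_chars(tri))
    strand <- ifelse(pyr, "+", "-")
    keep <- !grepl("N", tri_pyr)
    data.frame(chrom = ct, pos = pos[keep], tri = tri_pyr[keep],
               pyr_strand = strand[keep], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, pieces)
  tab$cat <- strand_category(tab$chrom, tab$pos, tab$pyr_strand, annotation)
  split(tab[c("chrom", "pos", "pyr_strand")],
        paste(tab$tri, tab$cat, sep = "|"))
}

#' Generate a full synthetic cohort with pseudo-callers
#'
#' Emits a positioned-variant cohort on a synthetic genome. Each cluster in
#' `cluster_plan` plants a dominant signature: the dominant process takes
#' `share` of the weight and the rest is split uniformly-at-random over the
#' other pool signatures. Per-sample burdens are log-normal around the
#' cluster's median burden. Channel counts are drawn by
#' [generate_profile()] and realized as substitutions placed uniformly
#' among genomic sites matching each channel's trinucleotide context and
#' strand category. Each pseudo-caller reports each true variant
#' independently with its sensitivity and adds uniformly-placed false calls
#' at its false-call rate. Optional outlier samples with extreme profiles
#' can be injected.
#'
#' @param signature_pool A [signature_matrix()] (SBS384 recommended).
#' @param cluster_plan Data.frame with columns `size`, `dominant` (pool
#'   signature name), `share` (dominant weight), `burden` (median).
#' @param callers Data.frame with columns `caller`, `sensitivity`,
#'   `false_rate` (expected false calls per true call). Default: three
#'   pseudo-callers at sensitivities 0.95/0.92/0.90 with 2% false calls.
#' @param outlier_pool Optional [signature_matrix()] of outlier profiles.
#' @param outlier_plan Optional data.frame with columns `profile` (name in
#'   `outlier_pool`), `n` (samples), `burden`.
#' @param burden_sd Log-scale burden spread. Default 0.35.
#' @param genome Optional [synthetic_genome()] result; generated otherwise.
#' @param seed Integer master seed.
#' @return List with `genome`, `annotation`, `calls` (all callers pooled,
#'   tabular dialect), `caller_tables` (per-caller list) and `ledger`
#'   (true weights, true channel counts, cluster labels, outlier flags,
#'   emitted variants).
#' @export
generate_cohort <- function(signature_pool,
                            cluster_plan = data.frame(
                              size = c(20, 20, 20, 20),
                              dominant = c("clock", "apobec", "alcohol",
                                           "smoking"),
                              share = 0.7,
                              burden = c(150, 350, 250, 700)),
                            callers = data.frame(
                              caller = c("callerA", "callerB", "callerC"),
                              sensitivity = c(0.95, 0.92, 0.90),
                              false_rate = 0.02),
                            outlier_pool = NULL, outlier_plan = NULL,
                            burden_sd = 0.35, genome = NULL, seed = 1L) {
  schema <- as_channel_schema(attr(signature_pool, "schema"))
  if (is.null(genome)) genome <- synthetic_genome(seed = seed)
  index <- site_index(genome$genome, genome$annotation)
  pool_names <- colnames(signature_pool)
  stopifnot(all(cluster_plan$dominant %in% pool_names))

  # --- plan samples ---------------------------------------------------
  n_core <- sum(cluster_plan$size)
  sample_plan <- data.frame(
    sample = sprintf("S%03d", seq_len(n_core)),
    cluster = rep(seq_len(nrow(cluster_plan)), cluster_plan$size),
    stringsAsFactors = FALSE)
  n_out <- if (is.null(outlier_plan)) 0L else sum(outlier_plan$n)
  if (n_out > 0) {
    stopifnot(!is.null(outlier_pool),
              all(outlier_plan$profile %in% colnames(outlier_pool)))
    sample_plan <- rbind(sample_plan, data.frame(
      sample = sprintf("OUT%02d", seq_len(n_out)),
      cluster = NA_integer_, stringsAsFactors = FALSE))
  }
  n_total <- nrow(sample_plan)

  # --- spectra ---------------------------------------------------------
  set.seed(stage_seed(seed, "burdens"))
  burdens <- integer(n_total)
  core <- !is.na(sample_plan$cluster)
  burdens[core] <- pmax(10L, as.integer(round(stats::rlnorm(
    n_core, log(cluster_plan$burden[sample_plan$cluster[core]]),
    burden_sd))))
  if (n_out > 0)
    burdens[!core] <- rep(outlier_plan$burden, outlier_plan$n)

  weights <- matrix(0, n_total, length(pool_names),
                    dimnames = list(sample_plan$sample, pool_names))
  channel_counts <- matrix(0, n_total, length(schema$channels),
                           dimnames = list(sample_plan$sample,
                                           schema$channels))
  out_profiles <- if (n_out > 0) rep(outlier_plan$profile, outlier_plan$n)
  variants <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    si <- sample_plan$sample[i]
    sseed <- stage_seed(seed, paste0("sample_", si))
    if (core[i]) {
      cl <- sample_plan$cluster[i]
      set.seed(sseed)
      w <- stats::runif(length(pool_names))
      w[pool_names == cluster_plan$dominant[cl]] <- 0
      w <- w / sum(w) * (1 - cluster_plan$share[cl])
      w[pool_names == cluster_plan$dominant[cl]] <- cluster_plan$share[cl]
      prof <- generate_profile(signature_pool, w, burdens[i], seed = sseed + 1L)
      weights[i, ] <- prof$weights
      sigs_i <- signature_pool
    } else {
      pr <- out_profiles[i - n_core]
      w <- as.numeric(colnames(outlier_pool) == pr)
      prof <- generate_profile(outlier_pool, w, burdens[i], seed = sseed + 1L)
      sigs_i <- outlier_pool
    }
    channel_counts[i, ] <- prof$counts
    variants[[i]] <- place_variants(prof$counts, schema, index, genome$genome,
                                    si, seed = sseed + 2L)
  }
  true_variants <- do.call(rbind, variants)

  # --- pseudo-callers --------------------------------------------------
  caller_tables <- vector("list", nrow(callers))
  names(caller_tables) <- callers$caller
  for (j in seq_len(nrow(callers))) {
    set.seed(stage_seed(seed, paste0("caller_", callers$caller[j])))
    det <- stats::runif(nrow(true_variants)) < callers$sensitivity[j]
    tv <- true_variants[det, , drop = FALSE]
    rep_vaf <- pmin(0.99, pmax(0.01,
      tv$vaf + stats::rnorm(nrow(tv), 0, 0.02)))
    tab <- data.frame(sample = tv$sample, caller = callers$caller[j],
                      chrom = tv$chrom, pos = tv$pos, ref = tv$ref,
                      alt = tv$alt, filter = "PASS",
                      vaf = round(rep_vaf, 4), stringsAsFactors = FALSE)
    n_false <- stats::rpois(1, callers$false_rate[j] * nrow(true_variants))
    if (n_false > 0) {
      fc <- random_false_calls(genome$genome, n_false,
                               sample(sample_plan$sample, n_false,
                                      replace = TRUE))
      fc$caller <- callers$caller[j]
      tab <- rbind(tab, fc[names(tab)])
    }
    caller_tables[[j]] <- tab[order(tab$sample, tab$chrom, tab$pos), ]
  }
  calls <- do.call(rbind, caller_tables)
  rownames(calls) <- NULL

  list(genome = genome$genome, annotation = genome$annotation,
       calls = calls, caller_tables = caller_tables,
       ledger = list(samples = sample_plan$sample,
                     weights = weights,
                     channel_counts = channel_counts,
                     burdens = stats::setNames(burdens, sample_plan$sample),
                     cluster = stats::setNames(sample_plan$cluster,
                                               sample_plan$sample),
                     outlier = stats::setNames(!core, sample_plan$sample),
                     variants = true_variants))
}

# Realize a channel count vector as positioned substitutions by drawing
# sites uniformly (without replacement) among those matching each channel's
# trinucleotide context and strand category.
place_variants <- function(counts, schema, index, genome, sample_id, seed) {
  set.seed(seed)
  nz <- which(counts > 0)
  if (length(nz) == 0)
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), vaf = numeric(0),
                      channel = character(0), stringsAsFactors = FALSE))
  p <- parse_channel(schema$channels[nz])
  out <- vector("list", length(nz))
  for (ii in seq_along(nz)) {
    m <- counts[nz[ii]]
    cat <- if (is.na(p$strand[ii])) "N" else p$strand[ii]
    key <- paste0(p$five[ii], p$ref[ii], p$three[ii], "|", cat)
    sites <- index[[key]]
    if (is.null(sites) || nrow(sites) < m)
      stop("not enough genomic sites for channel ",
           schema$channels[nz[ii]], "; enlarge the synthetic genome")
    pick <- sites[sample.int(nrow(sites), m), , drop = FALSE]
    flip <- pick$pyr_strand == "-"
    out[[ii]] <- data.frame(
      sample = sample_id, chrom = pick$chrom, pos = pick$pos,
      ref = ifelse(flip, comp_base(p$ref[ii]), p$ref[ii]),
      alt = ifelse(flip, comp_base(p$alt[ii]), p$alt[ii]),
      vaf = round(stats::rbeta(m, 2, 5), 4),
      channel = schema$channels[nz[ii]], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

random_false_calls <- function(genome, n, samples) {
  seqs <- genome_as_strings(genome)
  chrom <- sample(names(seqs), n, replace = TRUE)
  pos <- vapply(chrom, function(ct)
    sample.int(nchar(seqs[[ct]]) - 4L, 1) + 2L, integer(1))
  ref <- substr(seqs[chrom], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                character(1))
  data.frame(sample = samples, chrom = chrom, pos = pos, ref = ref,
             alt = alt, filter = "PASS",
             vaf = round(stats::runif(n, 0.02, 0.15), 4),
             stringsAsFactors = FALSE)
}

#' Signature over-attribution benchmark
#'
#' Quantifies how strongly a fitter attributes activity to a signature that
#' is absent from the truth, as a function of mutation burden. For each
#' burden, `n_per_burden` samples are generated whose true weights are
#' uniform-random over the pool excluding `absent`; both a plain NNLS
#' fitter and the CI-pruned fitter ([attribute_with_ci()]) then fit the
#' full pool. Over-attribution is reported as the mean attributed activity
#' of the absent signature relative to the burden.
#'
#' @param signature_pool A [signature_matrix()] including the absent
#'   signature.
#' @param absent Name of the signature excluded from the truth.
#' @param burden_grid Mutation burdens to scan.
#' @param n_per_burden Samples per burden. Default 500.
#' @param n_bootstrap Bootstrap resamples for the pruned fitter.
#'   Default 100.
#' @param ci_alpha CI miscoverage. Default 0.05.
#' @param seed Integer seed.
#' @return Data.frame with one row per (burden, fitter): `burden`,
#'   `signature`, `fitter` (`"nnls"` or `"ci_pruned"`), `mean_attributed`
#'   (mean activity in mutations), `mean_true` (always 0),
#'   `over_attribution` (mean attributed / burden).
#' @export
benchmark_overattribution <- function(signature_pool, absent = "flat",
                                      burden_grid = c(50, 100, 200, 500,
                                                      1000),
                                      n_per_burden = 500L,
                                      n_bootstrap = 100L, ci_alpha = 0.05,
                                      seed = 1L) {
  stopifnot(absent %in% colnames(signature_pool), length(burden_grid) >= 1)
  truth_pool <- signature_matrix(
    unclass(signature_pool)[, setdiff(colnames(signature_pool), absent),
                            drop = FALSE],
    attr(signature_pool, "schema"))
  rows <- list()
  for (b in burden_grid) {
    spectra <- matrix(0, nrow(signature_pool), n_per_burden)
    for (i in seq_len(n_per_burden)) {
      spectra[, i] <- generate_profile(
        truth_pool, "random", b,
        seed = stage_seed(seed, sprintf("bench_b%d_i%d", b, i)))$counts
    }
    nnls_acts <- .nnls_solve_multi(unclass(signature_pool), spectra)
    rownames(nnls_acts) <- colnames(signature_pool)
    pruned_abs <- vapply(seq_len(n_per_burden), function(i) {
      fr <- attribute_with_ci(
        stats::setNames(spectra[, i], rownames(signature_pool)),
        signature_pool, n_bootstrap = n_bootstrap, ci_alpha = ci_alpha,
        seed = stage_seed(seed, sprintf("bench_fit_b%d_i%d", b, i)))
      fr$activity[fr$signature == absent]
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      burden = b, signature = absent,
      fitter = c("nnls", "ci_pruned"),
      mean_attributed = c(mean(nnls_acts[absent, ]), mean(pruned_abs)),
      mean_true = 0,
      over_attribution = c(mean(nnls_acts[absent, ] / b),
                           mean(pruned_abs / b)),
      stringsAsFactors = FALSE)
    log_stage("benchmark_overattribution", burden = b,
              nnls = round(mean(nnls_acts[absent, ] / b), 4),
              pruned = round(mean(pruned_abs / b), 4))
  }
  do.call(rbind, rows)
}
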