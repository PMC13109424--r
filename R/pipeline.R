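# End-to-end stratification pipeline and on-disk cohort helpers.

#' Read a genome FASTA / gene annotation BED
#'
#' Thin wrappers: FASTA via Biostrings, BED6/GFF3 via rtracklayer. FASTA
#' contig names are truncated at the first whitespace.
#'
#' @param path File path.
#' @return `read_genome_fasta`: named character vector of contig sequences;
#'   `read_annotation`: a `GRanges` with strand.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  stats::setNames(as.character(seqs), names(seqs))
}

#' @rdname read_genome_fasta
#' @export
read_annotation <- function(path) {
  rtracklayer::import(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes the genome as FASTA, the annotation as BED, one tabular variant
#' file per pseudo-caller and the ledger as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$genome),
                              file.path(dir, "genome.fa"))
  rtracklayer::export(cohort$annotation, file.path(dir, "genes.bed"))
  for (cl in names(cohort$caller_tables))
    write_variant_table(cohort$caller_tables[[cl]],
                        file.path(dir, paste0("calls_", cl, ".tsv")))
  ledger <- cohort$ledger
  ledger$variants <- NULL  # bulky; the caller tables carry the positions
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Run the full stratification pipeline
#'
#' Chains the pipeline stages on per-caller somatic calls: build
#' strand-aware catalogs, screen high-burden samples for rare spectra (on
#' the first caller's SBS96 catalog) and drop the flagged samples, extract
#' de novo signatures per caller, cluster samples on relative exposures
#' with K-means, and intersect the caller-specific clusterings into the
#' stable consensus. When a reference catalog is supplied, de novo
#' signatures are decomposed against it and stable samples are attributed
#' with CI pruning.
#'
#' @param caller_calls Named list of per-caller call data.frames (tabular
#'   dialect columns).
#' @param genome Named character vector (or `DNAStringSet`) of contigs.
#' @param annotation `GRanges` of genes with strand.
#' @param config A [run_config()].
#' @param reference Optional [signature_matrix()] of reference signatures
#'   for refitting.
#' @return List with `catalogs`, `rare_samples`, `extraction` (first
#'   caller's report), `per_caller_k`, `assignments`, `consensus`,
#'   and (when `reference` is given) `decomposition` and `attribution`.
#' @export
run_stratification <- function(caller_calls, genome, annotation,
                               config = run_config(), reference = NULL) {
  stopifnot(length(caller_calls) >= 1)
  samples <- sort(unique(unlist(lapply(caller_calls, `[[`, "sample"))))
  catalogs <- lapply(caller_calls, build_catalog, genome = genome,
                     annotation = annotation,
                     schema = config$channel_schema, samples = samples)

  cat96 <- collapse_catalog(catalogs[[1]], "SBS96")
  high <- select_high_burden(cat96, config$burden_threshold)
  rare <- character(0)
  if (length(high) >= 2) {
    hb <- mutation_catalog(unclass(cat96)[high, , drop = FALSE], "SBS96")
    rep_rare <- cosine_cluster(hb, cut_height = config$rare_cut_height)
    rare <- flag_rare(rep_rare, config$rare_max_size)
  }
  keep <- setdiff(samples, rare)
  catalogs <- lapply(catalogs, function(ct)
    mutation_catalog(unclass(ct)[keep, , drop = FALSE],
                     catalog_schema(ct)))

  extraction <- extract_signatures(
    catalogs[[1]], k_range = config$k_range,
    n_replicates = config$n_nmf_replicates,
    seed = stage_seed(config$seed, "extract_caller1"))
  k <- extraction$chosen_k
  kk <- if (identical(config$kmeans_k, "auto")) k else config$kmeans_k

  assignments <- vector("list", length(catalogs))
  names(assignments) <- names(catalogs)
  for (ci in seq_along(catalogs)) {
    rec <- if (ci == 1) extraction$per_k[[as.character(k)]] else {
      rep_c <- extract_signatures(
        catalogs[[ci]], k_range = k,
        n_replicates = config$n_nmf_replicates,
        seed = stage_seed(config$seed, paste0("extract_caller", ci)))
      rep_c$per_k[[as.character(k)]]
    }
    assignments[[ci]] <- kmeans_exposures(
      relative_exposures(rec$activities), kk,
      seed = stage_seed(config$seed, paste0("kmeans", ci)))
  }
  consensus <- if (length(assignments) >= 2)
    align_and_intersect(assignments) else NULL

  out <- list(catalogs = catalogs, rare_samples = rare,
              extraction = extraction, chosen_k = k,
              assignments = assignments, consensus = consensus)
  if (!is.null(reference)) {
    denovo <- extraction$per_k[[as.character(k)]]$signatures
    out$decomposition <- decompose_denovo(denovo, reference)
    stable <- if (is.null(consensus)) keep else consensus$stable_samples
    cat_ref <- collapse_catalog(catalogs[[1]],
                                attr(reference, "schema"))
    cat_stable <- mutation_catalog(
      unclass(cat_ref)[stable, , drop = FALSE], attr(reference, "schema"))
    out$attribution <- attribute_catalog(
      cat_stable, reference, prune = TRUE,
      n_bootstrap = config$n_bootstrap, ci_alpha = config$ci_alpha,
      seed = stage_seed(config$seed, "attribution"))
  }
  out
}
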