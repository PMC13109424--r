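# APOBEC context dissection: APOBEC3A preferentially deaminates C in YTCA
# tetranucleotides (Y = pyrimidine at -2) while APOBEC3B prefers RTCA
# (R = purine at -2). Splitting TCA-context APOBEC-like mutations by the -2
# base therefore separates the two enzymes' footprints.

#' Count YTCA / RTCA tetranucleotide contexts per sample
#'
#' For every APOBEC-like mutation (C>T or C>G at TCW after pyrimidine
#' normalization), reads the base two positions 5' of the mutated C on the
#' pyrimidine strand. Mutations with 3' base A (TCA context) are split into
#' `ytca` (-2 base C or T) and `rtca` (-2 base A or G); TCT-context
#' mutations contribute to `apobec_like_total` only. Mutations whose -2
#' base falls outside the contig are excluded and counted in `edge_skipped`.
#'
#' @param variants Data.frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt` (e.g. consensus variants or per-caller calls).
#' @param genome Named `DNAStringSet` or character vector.
#' @return Data.frame with one row per sample: `sample`, `ytca`, `rtca`,
#'   `tca_total`, `apobec_like_total`, `edge_skipped`. Always
#'   `ytca + rtca == tca_total`.
#' @export
count_tetra <- function(variants, genome) {
  samples <- unique(variants$sample)
  sbs <- is_sbs_call(variants$ref, variants$alt)
  v <- variants[sbs, , drop = FALSE]
  ctx <- context_window(genome, v$chrom, v$pos, 1L)
  five <- substr(ctx, 1, 1); three <- substr(ctx, 3, 3)
  cls <- classify_motif_core(five, v$ref, v$alt, three)
  apo <- !is.na(ctx) & cls == "APOBEC_like"
  # pyrimidine-normalized 3' base and the -2 base on the pyrimidine strand
  flip <- v$ref %in% c("A", "G")
  three_pyr <- ifelse(flip, comp_base(five), three)
  w2 <- context_window(genome, v$chrom, ifelse(flip, v$pos + 2L, v$pos - 2L),
                       0L, clip = TRUE)
  minus2 <- ifelse(flip, comp_base(w2), w2)
  tca <- apo & three_pyr == "A"
  edge <- tca & (is.na(minus2) | !(minus2 %in% DNA_BASES))
  ytca_hit <- tca & !edge & minus2 %in% c("C", "T")
  rtca_hit <- tca & !edge & minus2 %in% c("A", "G")
  tally <- function(flag) as.integer(table(factor(v$sample[flag],
                                                  levels = samples)))
  out <- data.frame(sample = samples,
                    ytca = tally(ytca_hit), rtca = tally(rtca_hit),
                    tca_total = tally(ytca_hit | rtca_hit),
                    apobec_like_total = tally(apo),
                    edge_skipped = tally(edge),
                    stringsAsFactors = FALSE)
  log_stage("count_tetra", samples = length(samples),
            apobec_like = sum(out$apobec_like_total),
            edge_skipped = sum(out$edge_skipped))
  out
}

#' Per-group motif-class distribution
#'
#' Fractions of mutations in each motif class ([classify_motif()]) per
#' sample group, e.g. per patient cluster — for all mutations or any subset
#' of interest (such as genes under selection). Empty groups are omitted
#' with a warning.
#'
#' @param classes Factor of motif classes, one per mutation.
#' @param sample Sample id per mutation.
#' @param grouping Named vector mapping sample ids to group labels.
#' @return Groups x motif-class matrix of fractions; each row sums to one.
#' @export
motif_distribution <- function(classes, sample, grouping) {
  group <- grouping[as.character(sample)]
  if (any(is.na(group)))
    stop("grouping does not cover ", sum(is.na(group)), " mutation(s)")
  tab <- table(group, classes)
  counts <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("omitting empty group(s): ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  counts / rowSums(counts)
}
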