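# Building strand-bias-aware SBS catalogs from variant calls: trinucleotide
# context lookup, pyrimidine normalization, transcription-strand category
# assignment, multi-caller consensus and motif-defined process classes.

# Normalize a genome to a named list of uppercase character strings.
genome_as_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    s <- as.character(genome)
  } else if (is.character(genome)) {
    s <- toupper(genome)
  } else stop("genome must be a DNAStringSet or a named character vector")
  if (is.null(names(s))) stop("genome contigs must be named")
  s
}

# Sequence context around 1-based positions; NA where the window leaves the
# contig. `chrom`/`pos` are parallel vectors.
context_window <- function(genome, chrom, pos, flank, clip = FALSE) {
  seqs <- genome_as_strings(genome)
  unknown <- setdiff(unique(chrom), names(seqs))
  if (length(unknown))
    stop("position(s) on unknown contig(s): ", paste(unknown, collapse = ", "))
  len <- nchar(seqs)[chrom]
  if (!clip && any(pos < 1 | pos > len))
    stop("variant position outside contig bounds")
  out <- rep(NA_character_, length(pos))
  ok <- pos - flank >= 1 & pos + flank <= len
  out[ok] <- substr(seqs[chrom[ok]], pos[ok] - flank, pos[ok] + flank)
  out
}

is_sbs_call <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 & ref %in% DNA_BASES &
    alt %in% DNA_BASES & ref != alt
}

# Transcription-strand category of the pyrimidine strand at each position:
# U when the pyrimidine lies on the coding strand of every overlapping gene,
# T when on the template strand, B when genes overlap on both strands,
# N when intergenic.
strand_category <- function(chrom, pos, pyr_strand, annotation) {
  n <- length(pos)
  if (is.null(annotation) || length(annotation) == 0L)
    return(rep("N", n))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  ann_strand <- as.character(BiocGenerics::strand(annotation))
  plus <- logical(n); minus <- logical(n)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  plus[unique(qh[ann_strand[sh] == "+"])] <- TRUE
  minus[unique(qh[ann_strand[sh] == "-"])] <- TRUE
  cat <- rep("N", n)
  both <- plus & minus
  cat[both] <- "B"
  same <- !both & ((pyr_strand == "+" & plus) | (pyr_strand == "-" & minus))
  opp  <- !both & ((pyr_strand == "+" & minus) | (pyr_strand == "-" & plus))
  cat[same] <- "U"
  cat[opp] <- "T"
  cat
}

#' Classify single-base substitutions into catalog channels
#'
#' Assigns each SBS call its channel label under the requested schema:
#' the substitution is reverse-complemented to its pyrimidine representation
#' when the reference base is a purine, the trinucleotide context is read
#' from the genome on the pyrimidine strand, and (for the strand-aware
#' schemas) the transcription-strand category is taken from overlap with the
#' gene annotation: `U` when the pyrimidine lies on the coding
#' (untranscribed) strand, `T` on the template (transcribed) strand, `B`
#' when genes on both strands overlap the site, `N` when intergenic.
#'
#' @param calls Data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single uppercase bases).
#' @param genome Named `DNAStringSet` or character vector of contig
#'   sequences.
#' @param annotation `GRanges` of transcribed intervals with strand, or NULL
#'   for an unannotated genome (every call gets category `N`).
#' @param schema Target [channel_schema()] (or name).
#' @return Character vector of channel labels, `NA` for calls whose context
#'   contains an ambiguous base or leaves the contig (these are skipped with
#'   a logged count).
#' @export
classify_sbs <- function(calls, genome, annotation = NULL,
                         schema = "SBS384") {
  schema <- as_channel_schema(schema)
  stopifnot(all(is_sbs_call(calls$ref, calls$alt)))
  ctx <- context_window(genome, calls$chrom, calls$pos, 1L)
  ref <- calls$ref; alt <- calls$alt
  # context must agree with the reported reference base
  mid <- substr(ctx, 2, 2)
  mismatch <- !is.na(ctx) & mid != ref
  if (any(mismatch))
    stop("reference base mismatch at ", calls$chrom[mismatch][1], ":",
         calls$pos[mismatch][1])
  pyr_strand <- ifelse(ref %in% c("C", "T"), "+", "-")
  flip <- pyr_strand == "-"
  five <- substr(ctx, 1, 1); three <- substr(ctx, 3, 3)
  f2 <- ifelse(flip, comp_base(three), five)
  t2 <- ifelse(flip, comp_base(five), three)
  r2 <- ifelse(flip, comp_base(ref), ref)
  a2 <- ifelse(flip, comp_base(alt), alt)
  ok <- !is.na(ctx) & f2 %in% DNA_BASES & t2 %in% DNA_BASES
  labels <- rep(NA_character_, nrow(calls))
  base96 <- paste0(f2, "[", r2, ">", a2, "]", t2)
  if (length(schema$strand_categories) == 0L) {
    labels[ok] <- base96[ok]
  } else {
    cat4 <- strand_category(calls$chrom, calls$pos, pyr_strand, annotation)
    if (schema$name == "SBS288") cat4[cat4 == "B"] <- "N"
    labels[ok] <- paste0(cat4[ok], ":", base96[ok])
  }
  n_skip <- sum(!ok)
  if (n_skip) log_stage("classify_sbs", skipped_ambiguous_context = n_skip)
  labels
}

#' Build a mutation catalog from variant calls
#'
#' Counts each sample's classified SBS calls per channel. Indels and calls
#' with unresolvable context are excluded from the counts and reported in
#' the `unclassified` attribute. Duplicate identical records are counted
#' twice; caller-level deduplication is [consensus_filter()]'s job.
#'
#' @inheritParams classify_sbs
#' @param calls Data.frame of passing calls including a `sample` column.
#' @param samples Sample universe; samples with no calls keep zero rows.
#'   Defaults to the samples present in `calls`.
#' @return A [mutation_catalog()]; attribute `unclassified` gives per-sample
#'   counts of skipped calls (indels, ambiguous context).
#' @export
build_catalog <- function(calls, genome, annotation = NULL,
                          schema = "SBS384", samples = NULL) {
  schema <- as_channel_schema(schema)
  if (is.null(samples)) samples <- unique(calls$sample)
  sbs <- is_sbs_call(calls$ref, calls$alt)
  labels <- rep(NA_character_, nrow(calls))
  if (any(sbs))
    labels[sbs] <- classify_sbs(calls[sbs, , drop = FALSE], genome,
                                annotation, schema)
  keep <- !is.na(labels)
  counts <- table(factor(calls$sample[keep], levels = samples),
                  factor(labels[keep], levels = schema$channels))
  counts <- matrix(as.numeric(counts), nrow = length(samples),
                   dimnames = list(samples, schema$channels))
  unclassified <- table(factor(calls$sample[!keep], levels = samples))
  log_stage("build_catalog", samples = length(samples),
            classified = sum(keep), unclassified = sum(!keep))
  out <- mutation_catalog(counts, schema)
  attr(out, "unclassified") <- as.integer(unclassified)
  out
}

#' Multi-caller consensus variants
#'
#' Collapses per-caller calls onto unique variants keyed by
#' (sample, chrom, pos, ref, alt) and retains those reported by at least
#' `min_callers` distinct callers, recording the arithmetic mean of the
#' available VAFs.
#'
#' @param calls Data.frame of passing calls from several callers.
#' @param min_callers Minimum number of distinct reporting callers.
#'   Default 2.
#' @return Data.frame of consensus variants with columns `sample, chrom,
#'   pos, ref, alt, n_callers, mean_vaf`.
#' @export
consensus_filter <- function(calls, min_callers = 2L) {
  key <- paste(calls$sample, calls$chrom, calls$pos, calls$ref, calls$alt,
               sep = "\r")
  n_callers <- tapply(calls$caller, key, function(x) length(unique(x)))
  mean_vaf <- tapply(calls$vaf, key, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  first <- calls[!duplicated(key), , drop = FALSE]
  fkey <- key[!duplicated(key)]
  out <- data.frame(sample = first$sample, chrom = first$chrom,
                    pos = first$pos, ref = first$ref, alt = first$alt,
                    n_callers = as.integer(n_callers[fkey]),
                    mean_vaf = as.numeric(mean_vaf[fkey]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_callers >= min_callers, , drop = FALSE]
  out <- out[order(out$sample, out$chrom, out$pos, out$ref, out$alt), ,
             drop = FALSE]
  rownames(out) <- NULL
  log_stage("consensus_filter", input_keys = length(unique(key)),
            retained = nrow(out))
  out
}

MOTIF_CLASSES <- c("APOBEC_like", "SBS1_like", "C_to_A", "T_to_C",
                   "other_sbs", "indel")

# Core motif classifier on pyrimidine-normalized components. NA context is
# tolerated: classes that need flanks are then unreachable.
classify_motif_core <- function(five, ref, alt, three) {
  flip <- !is.na(ref) & ref %in% c("A", "G")
  f <- ifelse(flip, comp_base(three), five)
  t3 <- ifelse(flip, comp_base(five), three)
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  out <- rep("other_sbs", length(ref))
  out[!is.na(r) & r == "C" & !is.na(a) & a == "A"] <- "C_to_A"
  out[!is.na(r) & r == "T" & !is.na(a) & a == "C"] <- "T_to_C"
  sbs1 <- !is.na(r) & r == "C" & a == "T" & !is.na(t3) & t3 == "G"
  out[sbs1] <- "SBS1_like"
  apo <- !is.na(r) & r == "C" & a %in% c("T", "G") &
    !is.na(f) & f == "T" & !is.na(t3) & t3 %in% c("A", "T")
  out[apo] <- "APOBEC_like"
  out
}

#' Classify mutations into motif-defined process classes
#'
#' Maps each mutation to one of six mutually exclusive classes under the
#' precedence APOBEC_like > SBS1_like > C_to_A > T_to_C > other_sbs, with
#' indels their own class. APOBEC_like is a C>T or C>G substitution in TCW
#' context (W = A or T); SBS1_like is C>T at XCG (any 5' base); C_to_A and
#' T_to_C are the remaining substitutions of those classes.
#'
#' @param x Either a character vector of channel labels (strand prefixes
#'   allowed) or a data.frame of variants with columns `ref`, `alt` and
#'   (for context-dependent classes) `five`, `three` — the flanking bases on
#'   the reference strand. In a data.frame, multi-base ref/alt rows are
#'   classified `indel`; missing flanks draw a warning and fall through to
#'   the context-free classes.
#' @return Factor over the six motif classes.
#' @export
classify_motif <- function(x) {
  if (is.character(x)) {
    p <- parse_channel(x)
    cls <- classify_motif_core(p$five, p$ref, p$alt, p$three)
  } else {
    stopifnot(is.data.frame(x), all(c("ref", "alt") %in% names(x)))
    five <- if ("five" %in% names(x)) x$five else rep(NA_character_, nrow(x))
    three <- if ("three" %in% names(x)) x$three else rep(NA_character_, nrow(x))
    sbs <- is_sbs_call(x$ref, x$alt)
    if (any(sbs & (is.na(five) | is.na(three))))
      warning("missing flanking context for ",
              sum(sbs & (is.na(five) | is.na(three))),
              " substitution(s); context-dependent classes unavailable")
    cls <- rep("indel", nrow(x))
    cls[sbs] <- classify_motif_core(five[sbs], x$ref[sbs], x$alt[sbs],
                                    three[sbs])
  }
  factor(cls, levels = MOTIF_CLASSES)
}
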