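# Readers and writers for the pipeline's file formats: the tabular variant
# dialect, VCF, COSMIC-style signature TSVs and catalog TSVs.

VARIANT_COLUMNS <- c("sample", "caller", "chrom", "pos", "ref", "alt",
                     "filter", "vaf")

#' Read somatic variant calls
#'
#' Reads per-caller somatic calls from either the package's tabular dialect
#' (TSV with header `sample, caller, chrom, pos, ref, alt, filter, vaf`) or
#' a VCF 4.x file. Only records whose FILTER equals `pass_value` are
#' returned; the discard count is logged. VCF files carry no per-caller
#' provenance, so `sample_id` and `caller_id` must be supplied for them.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tabular"` or `"vcf"`.
#' @param sample_id,caller_id Identity of the calls in a VCF (ignored for
#'   tabular input, which carries both per row).
#' @param pass_value FILTER value marking a passing call. Default `"PASS"`.
#' @return A data.frame of variant calls with columns
#'   `sample, caller, chrom, pos, ref, alt, filter, vaf` (positions 1-based),
#'   containing only passing records.
#' @export
read_variant_table <- function(path, format = c("auto", "tabular", "vcf"),
                               sample_id = NULL, caller_id = NULL,
                               pass_value = "PASS") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tabular"
  calls <- if (format == "vcf")
    read_vcf_calls(path, sample_id, caller_id)
  else
    read_tabular_calls(path)
  n_in <- nrow(calls)
  calls <- calls[calls$filter == pass_value, , drop = FALSE]
  rownames(calls) <- NULL
  log_stage("read_variant_table", path = basename(path), records = n_in,
            passing = nrow(calls), discarded = n_in - nrow(calls))
  calls
}

read_tabular_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(VARIANT_COLUMNS, names(tab))
  if (length(missing))
    stop("variant table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$pos))
  bad <- which(is.na(pos) & nzchar(tab$pos))
  if (length(bad))
    stop("malformed position in ", path, " at data line ", bad[1])
  vaf <- suppressWarnings(as.numeric(tab$vaf))
  data.frame(sample = tab$sample, caller = tab$caller, chrom = tab$chrom,
             pos = pos, ref = toupper(tab$ref), alt = toupper(tab$alt),
             filter = tab$filter, vaf = vaf, stringsAsFactors = FALSE)
}

read_vcf_calls <- function(path, sample_id, caller_id) {
  if (is.null(sample_id) || is.null(caller_id))
    stop("VCF input needs explicit sample_id and caller_id ",
         "(VCF carries no caller provenance)")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    return(data.frame(sample = character(0), caller = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      filter = character(0), vaf = numeric(0)))
  info <- fix[, "INFO"]
  vaf <- suppressWarnings(as.numeric(sub(".*(?:^|;)AF=([0-9.eE+-]+).*", "\\1",
                                         info)))
  vaf[!grepl("(^|;)AF=", info)] <- NA_real_
  filt <- fix[, "FILTER"]
  filt[is.na(filt) | filt == "."] <- "."
  data.frame(sample = sample_id, caller = caller_id,
             chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
             filter = filt, vaf = vaf, stringsAsFactors = FALSE)
}

#' Write variant calls in the tabular dialect
#'
#' @param calls Data.frame as returned by [read_variant_table()].
#' @param path Output TSV path.
#' @export
write_variant_table <- function(calls, path) {
  utils::write.table(calls[, VARIANT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a COSMIC-style signature catalog
#'
#' Expects a TSV whose first column holds channel labels of a supported
#' schema (96, 288 or 384 channels) and remaining columns one signature
#' each. Rows may be in any order; they are canonicalized. Columns are
#' renormalized to sum to one.
#'
#' @param path TSV path.
#' @return A [signature_matrix()].
#' @export
read_signature_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("signature catalog needs a label column plus ",
                          "at least one signature column")
  labels <- as.character(tab[[1]])
  prof <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(prof)) stop("non-numeric signature entries in ", path)
  if (any(prof < 0)) stop("negative signature entries in ", path)
  rownames(prof) <- labels
  signature_matrix(prof)  # validates labels against supported schemas
}

#' Write a signature matrix as a COSMIC-style TSV
#'
#' @param signatures A [signature_matrix()].
#' @param path Output path.
#' @export
write_signature_catalog <- function(signatures, path) {
  tab <- data.frame(MutationType = rownames(signatures),
                    as.data.frame(unclass(signatures), check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write mutation catalog TSVs
#'
#' Catalog files follow the matrix-generator convention: channel labels as
#' rows (first column `MutationType`) and samples as columns.
#'
#' @param path TSV path.
#' @return `read_catalog_tsv`: a [mutation_catalog()].
#' @export
read_catalog_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(tab[[1]])
  counts <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(counts) <- labels
  mutation_catalog(counts, match_schema(labels))
}

#' @param catalog A [mutation_catalog()].
#' @rdname read_catalog_tsv
#' @export
write_catalog_tsv <- function(catalog, path) {
  tab <- data.frame(MutationType = colnames(catalog),
                    as.data.frame(t(unclass(catalog)), check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
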