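# Core containers: mutation catalogs, signature matrices, exposures.
#
# A mutation catalog is a samples x channels integer count matrix under a
# declared channel schema (dimnames carry sample ids and channel labels).
# A signature matrix stores per-signature probability vectors over channels
# in the COSMIC file orientation, channels x signatures.

#' Construct a mutation catalog
#'
#' @param counts Nonnegative integer matrix, samples in rows, channels in
#'   columns. Column names must be exactly the schema's channels (any order;
#'   they are canonicalized).
#' @param schema A `channel_schema` or its name.
#' @return A `mut_catalog`: the count matrix in canonical channel order with
#'   attribute `schema`.
#' @export
mutation_catalog <- function(counts, schema) {
  schema <- as_channel_schema(schema)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), schema$channels))
    stop("catalog columns must be exactly the ", schema$name, " channels")
  if (any(counts < 0)) stop("catalog counts must be nonnegative")
  counts <- counts[, schema$channels, drop = FALSE]
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  storage.mode(counts) <- "double"
  structure(counts, class = c("mut_catalog", "matrix", "array"),
            schema = schema$name)
}

#' @export
print.mut_catalog <- function(x, ...) {
  cat(sprintf("<mut_catalog %s: %d samples x %d channels, %s mutations>\n",
              attr(x, "schema"), nrow(x), ncol(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

catalog_schema <- function(catalog) as_channel_schema(attr(catalog, "schema"))

#' Collapse a catalog to a lower-dimensional channel schema
#'
#' Supported directions: SBS384 to SBS288 (strand category B is assigned to
#' N, so per-sample totals are conserved exactly), SBS384 to SBS96 and
#' SBS288 to SBS96 (strand prefix stripped).
#'
#' @param catalog A `mut_catalog`.
#' @param target Target schema (`channel_schema` or name).
#' @return A `mut_catalog` under the target schema with identical per-sample
#'   totals.
#' @export
collapse_catalog <- function(catalog, target) {
  from <- catalog_schema(catalog)
  target <- as_channel_schema(target)
  if (from$name == target$name) return(catalog)
  map <- collapse_map(from, target)
  grp <- factor(map[colnames(catalog)], levels = target$channels)
  out <- t(rowsum(t(unclass(catalog)), grp))
  colnames(out) <- target$channels
  mutation_catalog(out, target)
}

#' Construct a signature matrix
#'
#' @param profiles Numeric matrix, channels in rows (rownames are channel
#'   labels of a supported schema), signatures in columns. Columns are
#'   renormalized to sum to one; columns summing to zero are an error.
#' @param schema Optional schema; inferred from the row labels when missing.
#' @return A `signature_matrix`: channels x signatures probability matrix in
#'   canonical channel order, attribute `schema`.
#' @export
signature_matrix <- function(profiles, schema = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    stop("signature profiles need channel labels as rownames")
  schema <- if (is.null(schema)) match_schema(rownames(profiles))
            else as_channel_schema(schema)
  if (!setequal(rownames(profiles), schema$channels))
    stop("profile rows do not match the ", schema$name, " channels")
  if (any(profiles < 0)) stop("signature profiles must be nonnegative")
  profiles <- profiles[schema$channels, , drop = FALSE]
  cs <- colSums(profiles)
  if (any(cs <= 0)) stop("signature column(s) sum to zero")
  profiles <- sweep(profiles, 2, cs, "/")
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("SIG", seq_len(ncol(profiles)))
  structure(profiles, class = c("signature_matrix", "matrix", "array"),
            schema = schema$name)
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix %s: %d signatures [%s]>\n",
              attr(x, "schema"), ncol(x),
              paste(utils::head(colnames(x), 6), collapse = ", ")))
  invisible(x)
}

# Collapse signature profiles to a lower schema (renormalized mass sums).
collapse_signatures <- function(signatures, target) {
  from <- as_channel_schema(attr(signatures, "schema"))
  target <- as_channel_schema(target)
  if (from$name == target$name) return(signatures)
  map <- collapse_map(from, target)
  grp <- factor(map[rownames(signatures)], levels = target$channels)
  out <- rowsum(unclass(signatures), grp)
  signature_matrix(as.matrix(out), target)
}

#' Row-normalize signature activities to relative exposures
#'
#' @param activities Samples x signatures nonnegative matrix of mutation
#'   counts attributed to each signature.
#' @return Matrix of the same shape whose rows sum to one (zero-total rows
#'   stay zero).
#' @export
relative_exposures <- function(activities) {
  tot <- rowSums(activities)
  tot[tot == 0] <- 1
  sweep(activities, 1, tot, "/")
}
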