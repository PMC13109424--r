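# Channel schemas for single-base-substitution catalogs.
#
# A channel is a pyrimidine-normalized substitution class (C>A, C>G, C>T,
# T>A, T>C, T>G) with its 5' and 3' flanking bases, optionally prefixed by a
# transcription-strand category:
#   T  pyrimidine on the transcribed (template) strand of an overlapping gene
#   U  pyrimidine on the untranscribed (coding) strand
#   B  overlapping annotated genes on both strands
#   N  intergenic
# SBS96 has no strand prefix; SBS288 uses {T, U, N}; SBS384 uses {T, U, B, N}.

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

sbs96_labels <- function() {
  grid <- expand.grid(three = DNA_BASES, five = DNA_BASES, sub = SBS_CLASSES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$sub, SBS_CLASSES), grid$five, grid$three), ]
  paste0(grid$five, "[", grid$sub, "]", grid$three)
}

#' Channel schema for mutation catalogs
#'
#' Builds one of the supported strand-bias-aware SBS channel schemas.
#' Channel labels follow the grammar `[strand:]5'[REF>ALT]3'`, e.g.
#' `T:A[C>T]G`; the reference base of the substitution class is always a
#' pyrimidine.
#'
#' @param name One of `"SBS96"`, `"SBS288"`, `"SBS384"`.
#' @return An object of class `channel_schema` with elements `name`,
#'   `channels` (ordered labels), `strand_categories` and `base96`
#'   (the unprefixed 96-channel labels).
#' @examples
#' sc <- channel_schema("SBS384")
#' length(sc$channels)  # 384
#' @export
channel_schema <- function(name = c("SBS96", "SBS288", "SBS384")) {
  name <- match.arg(name)
  base96 <- sbs96_labels()
  cats <- switch(name,
    SBS96  = character(0),
    SBS288 = c("T", "U", "N"),
    SBS384 = c("T", "U", "B", "N"))
  channels <- if (length(cats) == 0L) base96 else
    as.vector(vapply(cats, function(s) paste0(s, ":", base96),
                     character(length(base96))))
  structure(list(name = name, channels = channels,
                 strand_categories = cats, base96 = base96),
            class = "channel_schema")
}

as_channel_schema <- function(x) {
  if (inherits(x, "channel_schema")) return(x)
  channel_schema(x)
}

#' @export
print.channel_schema <- function(x, ...) {
  cat(sprintf("<channel_schema %s: %d channels", x$name, length(x$channels)))
  if (length(x$strand_categories))
    cat(", strand categories ", paste(x$strand_categories, collapse = "/"),
        sep = "")
  cat(">\n")
  invisible(x)
}

#' Parse channel labels into their components
#'
#' @param labels Character vector of channel labels such as `"A[C>T]G"` or
#'   `"T:A[C>T]G"`.
#' @return A data.frame with columns `strand` (NA when unprefixed), `five`,
#'   `ref`, `alt`, `three` and `base96` (the label with any strand prefix
#'   stripped).
#' @export
parse_channel <- function(labels) {
  m <- regmatches(labels,
    regexec("^(?:([TUBN]):)?([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", labels))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed channel label(s): ", paste(labels[bad], collapse = ", "))
  p <- do.call(rbind, m)
  data.frame(strand = ifelse(p[, 2] == "", NA_character_, p[, 2]),
             five = p[, 3], ref = p[, 4], alt = p[, 5], three = p[, 6],
             base96 = paste0(p[, 3], "[", p[, 4], ">", p[, 5], "]", p[, 6]),
             stringsAsFactors = FALSE)
}

# Identify which supported schema a set of channel labels belongs to.
match_schema <- function(labels) {
  for (nm in c("SBS96", "SBS288", "SBS384")) {
    sc <- channel_schema(nm)
    if (length(labels) == length(sc$channels) && setequal(labels, sc$channels))
      return(sc)
  }
  stop("channel label set does not match any supported schema ",
       "(SBS96/SBS288/SBS384)")
}

# Map each source channel to its label in the target schema.
# Directions supported: 384 -> 288 (B assigned to N), 384 -> 96, 288 -> 96.
collapse_map <- function(from, to) {
  from <- as_channel_schema(from); to <- as_channel_schema(to)
  dims <- c(SBS96 = 96L, SBS288 = 288L, SBS384 = 384L)
  if (dims[[from$name]] <= dims[[to$name]])
    stop("unsupported collapse direction: ", from$name, " -> ", to$name)
  p <- parse_channel(from$channels)
  target <- if (to$name == "SBS96") {
    p$base96
  } else {  # SBS384 -> SBS288: B mutations are treated as unassignable (N)
    strand <- ifelse(p$strand == "B", "N", p$strand)
    paste0(strand, ":", p$base96)
  }
  stopifnot(all(target %in% to$channels))
  stats::setNames(target, from$channels)
}
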