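# Shared numeric helpers and seeded-stage plumbing.

#' Cosine similarity between vectors
#'
#' @param x,y Nonnegative numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]` for nonnegative input; 0 if either
#'   vector is all-zero.
#' @export
cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# Pairwise cosine similarity between the rows of X (samples x channels).
cosine_matrix <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(X / nrm)
  S[S > 1] <- 1; S[S < 0] <- 0
  diag(S) <- 1
  S
}

# Derive an independent 32-bit seed for a named pipeline stage so that stages
# are reproducible in isolation.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L)
}

# One structured log line per stage; silenced unless
# options(sigstrata.verbose = TRUE).
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("sigstrata.verbose", FALSE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste(vapply(seq_along(kv), function(i)
    paste0(names(kv)[i], "=", paste(kv[[i]], collapse = ",")),
    character(1)), collapse = " ")
  message(sprintf("[sigstrata:%s] %s", stage, msg))
  invisible(NULL)
}

revcomp_chars <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""),
    function(ch) paste(rev(ch), collapse = ""), character(1)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)
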