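# Shared fixtures: a deterministic mini-genome with one gene per strand
# configuration, small signature pools, and catalog builders.

# A 1 kb contig with a known sequence and one gene on each strand plus an
# overlapping pair (B region). Sequence is seeded so tests are stable.
tiny_genome <- function(seed = 99) {
  set.seed(seed)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                         collapse = ""))
  ann <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(101, 401, 701, 751),
                     end   = c(300, 600, 820, 900)),
    strand = c("+", "-", "+", "-"))
  list(genome = seqs, annotation = ann)
}

# Multinomial catalog drawn from planted mixture weights; returns catalog
# plus the generating bookkeeping.
planted_catalog <- function(pool, weights_list, burdens, schema = "SBS384",
                            seed = 1) {
  stopifnot(length(weights_list) == length(burdens))
  counts <- matrix(0, length(burdens), nrow(pool),
                   dimnames = list(sprintf("P%03d", seq_along(burdens)),
                                   rownames(pool)))
  weights <- matrix(0, length(burdens), ncol(pool),
                    dimnames = list(rownames(counts), colnames(pool)))
  for (i in seq_along(burdens)) {
    pr <- generate_profile(pool, weights_list[[i]], burdens[i],
                           seed = seed + i)
    counts[i, ] <- pr$counts
    weights[i, ] <- pr$weights
  }
  list(catalog = mutation_catalog(counts, schema), weights = weights)
}

# Cluster-structured weights: dominant signature `dom` takes `share`, the
# rest is split over the others deterministically by seeded uniforms.
cluster_weights <- function(k, dom, share, seed) {
  set.seed(seed)
  w <- stats::runif(k)
  w[dom] <- 0
  w <- w / sum(w) * (1 - share)
  w[dom] <- share
  w
}

expect_cosine_gte <- function(x, y, floor) {
  expect_gte(cosine_sim(x, y), floor)
}

# Adjusted Rand index from the pair-counting formula (closed form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  e <- sr * sc / choose(n, 2)
  (sij - e) / ((sr + sc) / 2 - e)
}

# Brute-force oracle: classify a call by direct string lookup and manual
# interval overlap, independently of the package's GRanges/Biostrings path.
oracle_label <- function(seqs, ann, chrom, pos, ref, alt) {
  s <- seqs[[chrom]]
  tri <- substr(s, pos - 1, pos + 1)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc <- function(x) comp(paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  pyr_strand <- if (ref %in% c("C", "T")) "+" else "-"
  if (pyr_strand == "-") { tri <- rc(tri); ref <- comp(ref); alt <- comp(alt) }
  if (grepl("[^ACGT]", tri)) return(NA_character_)
  ov <- ann$chrom == chrom & ann$start <= pos & ann$end >= pos
  strands <- unique(ann$strand[ov])
  cat <- if (length(strands) == 0) "N"
         else if (all(c("+", "-") %in% strands)) "B"
         else if (strands == pyr_strand) "U" else "T"
  paste0(cat, ":", substr(tri, 1, 1), "[", ref, ">", alt, "]",
         substr(tri, 3, 3))
}

# All TCA-context cytosines (either strand) of a sequence with their -2
# base read on the pyrimidine strand; direct string scan, no package code.
find_tca_sites <- function(s) {
  n <- nchar(s)
  pos <- 3:(n - 1)
  tri <- substring(s, pos - 1, pos + 1)
  m2 <- substring(s, pos - 2, pos - 2)
  fwd <- tri == "TCA"
  out_f <- data.frame(pos = pos[fwd], strand = rep("+", sum(fwd)),
                      minus2 = m2[fwd], ref = rep("C", sum(fwd)))
  pos2 <- 2:(n - 2)
  tri2 <- substring(s, pos2 - 1, pos2 + 1)
  p2 <- substring(s, pos2 + 2, pos2 + 2)
  rev <- tri2 == "TGA"
  out_r <- data.frame(pos = pos2[rev], strand = rep("-", sum(rev)),
                      minus2 = chartr("ACGT", "TGCA", p2[rev]),
                      ref = rep("G", sum(rev)))
  rbind(out_f, out_r)
}

# Greedy one-to-one matching of recovered signatures to planted ones by
# best cosine; returns the cosine per planted signature.
match_cosines <- function(recovered, planted) {
  sim <- matrix(0, ncol(recovered), ncol(planted))
  for (a in seq_len(ncol(recovered)))
    for (b in seq_len(ncol(planted)))
      sim[a, b] <- cosine_sim(recovered[, a], planted[, b])
  out <- numeric(ncol(planted))
  for (step in seq_len(min(dim(sim)))) {
    ij <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    out[ij[2]] <- sim[ij[1], ij[2]]
    sim[ij[1], ] <- -1
    sim[, ij[2]] <- -1
  }
  out
}
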