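test_that("classification follows the pyrimidine/strand labeling convention", {
  # gene on + covering 101..300; C>T in A_A context inside it
  g <- tiny_genome()
  s <- g$genome[["chr1"]]
  substr(s, 149, 151) <- "ACA"
  genome <- c(chr1 = s)
  calls <- data.frame(chrom = "chr1", pos = 150L, ref = "C", alt = "T")
  expect_identical(classify_sbs(calls, genome, g$annotation, "SBS384"),
                   "U:A[C>T]A")
  # purine reference: reverse-complement representation, strand flipped
  substr(s, 159, 161) <- "TGT"
  genome <- c(chr1 = s)
  calls <- data.frame(chrom = "chr1", pos = 160L, ref = "G", alt = "A")
  expect_identical(classify_sbs(calls, genome, g$annotation, "SBS384"),
                   "T:A[C>T]A")
  # identical call without strand schema
  expect_identical(classify_sbs(calls, genome, g$annotation, "SBS96"),
                   "A[C>T]A")
})

test_that("labels are always pyrimidine-normalized regardless of ref base", {
  g <- tiny_genome()
  set.seed(5)
  pos <- sample(3:998, 50)
  s <- g$genome[["chr1"]]
  ref <- substring(s, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  calls <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt)
  lab <- classify_sbs(calls, g$genome, g$annotation, "SBS96")
  p <- parse_channel(lab)
  expect_true(all(p$ref %in% c("C", "T")))
  # purine-ref calls carry the reverse-complemented context
  pur <- ref %in% c("A", "G")
  rc1 <- chartr("ACGT", "TGCA", substring(s, pos + 1, pos + 1))
  expect_identical(p$five[pur], rc1[pur])
})

test_that("20 fixture calls match the brute-force context/strand oracle", {
  g <- tiny_genome()
  ann <- data.frame(chrom = "chr1", start = c(101, 401, 701, 751),
                    end = c(300, 600, 820, 900),
                    strand = c("+", "-", "+", "-"))
  set.seed(17)
  # spread across all strand categories incl. the B overlap and edges
  pos <- c(150, 155, 450, 455, 760, 780, 810, 50, 350, 650, 950, 990,
           102, 299, 402, 599, 702, 755, 899, 333)
  s <- g$genome[["chr1"]]
  ref <- substring(s, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  calls <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt)
  got <- classify_sbs(calls, g$genome, g$annotation, "SBS384")
  want <- vapply(seq_along(pos), function(i)
    oracle_label(g$genome, ann, "chr1", pos[i], ref[i], alt[i]), character(1))
  expect_identical(got, want)
})

test_that("ambiguous context is skipped, bad coordinates error", {
  g <- tiny_genome()
  s <- g$genome[["chr1"]]
  substr(s, 499, 499) <- "N"
  genome <- c(chr1 = s)
  calls <- data.frame(chrom = "chr1", pos = c(500L, 1L),
                      ref = substring(s, c(500, 1), c(500, 1)),
                      alt = c("A", "C"))
  calls$alt <- ifelse(calls$alt == calls$ref, "G", calls$alt)
  lab <- classify_sbs(calls, genome, g$annotation, "SBS96")
  expect_true(all(is.na(lab)))  # N in context; contig edge
  expect_error(
    classify_sbs(data.frame(chrom = "chr1", pos = 2000L, ref = "C",
                            alt = "T"), genome, g$annotation, "SBS96"),
    "outside")
  expect_error(
    classify_sbs(data.frame(chrom = "chrX", pos = 5L, ref = "C", alt = "T"),
                 genome, g$annotation, "SBS96"),
    "unknown contig")
})

test_that("build_catalog counts per sample and keeps zero rows", {
  g <- tiny_genome()
  s <- g$genome[["chr1"]]
  calls <- data.frame(
    sample = rep(c("a", "b"), each = 3),
    chrom = "chr1", pos = c(150L, 160L, 170L, 450L, 460L, 470L))
  calls$ref <- substring(s, calls$pos, calls$pos)
  calls$alt <- ifelse(calls$ref == "A", "C", "A")
  catal <- build_catalog(calls, g$genome, g$annotation, "SBS384",
                         samples = c("a", "b", "empty"))
  expect_equal(unname(rowSums(catal)), c(3, 3, 0))
  # duplicates are counted twice (dedup is consensus_filter's job)
  catal2 <- build_catalog(rbind(calls, calls[1, ]), g$genome, g$annotation,
                          "SBS384", samples = c("a", "b"))
  expect_equal(sum(catal2["a", ]), 4)
  # indels are excluded and ledgered, not counted
  ind <- calls[1, ]; ind$ref <- "AT"; ind$alt <- "A"
  catal3 <- build_catalog(rbind(calls, ind), g$genome, g$annotation,
                          "SBS384", samples = c("a", "b"))
  expect_equal(unname(rowSums(catal3)), c(3, 3))
  expect_equal(sum(attr(catal3, "unclassified")), 1)
})

test_that("consensus variants need two callers and average the VAFs", {
  calls <- data.frame(
    sample = "s1", caller = c("mutect2", "varscan2", "muse"),
    chrom = "chr1", pos = c(10L, 10L, 99L), ref = "C", alt = "T",
    filter = "PASS", vaf = c(0.30, 0.40, 0.5))
  cons <- consensus_filter(calls)
  expect_equal(nrow(cons), 1)       # the single-caller variant is dropped
  expect_equal(cons$n_callers, 2L)
  expect_equal(cons$mean_vaf, 0.35)
})

test_that("consensus retention matches a brute-force tally under dropout", {
  set.seed(23)
  n <- 1000
  truth <- data.frame(sample = sample(c("s1", "s2"), n, TRUE),
                      chrom = "chr1", pos = sample.int(1e6, n),
                      ref = "C", alt = "T")
  callers <- c("muse", "mutect2", "varscan2")
  seen <- matrix(runif(n * 3) > 0.4, n, 3)   # 0.4 dropout per caller
  rows <- do.call(rbind, lapply(1:3, function(j) {
    cbind(truth[seen[, j], ], caller = callers[j], filter = "PASS",
          vaf = 0.2)
  }))
  cons <- consensus_filter(rows)
  want_keys <- with(truth[rowSums(seen) >= 2, ],
                    paste(sample, chrom, pos, ref, alt))
  got_keys <- with(cons, paste(sample, chrom, pos, ref, alt))
  expect_setequal(got_keys, want_keys)
  expect_true(all(cons$n_callers == rowSums(seen)[rowSums(seen) >= 2][
    match(got_keys, want_keys)]))
})

test_that("motif classes claim exactly the stated channels and are disjoint", {
  labels <- channel_schema("SBS96")$channels
  cls <- classify_motif(labels)
  apo <- labels[cls == "APOBEC_like"]
  sbs1 <- labels[cls == "SBS1_like"]
  expect_setequal(apo, c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T"))
  expect_setequal(sbs1, c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G"))
  expect_length(intersect(apo, sbs1), 0)
  expect_equal(sum(cls == "C_to_A"), 16)           # every C>A channel
  expect_equal(sum(cls == "T_to_C"), 16)           # every T>C channel
  # spot checks from the template definitions
  expect_equal(as.character(classify_motif("T[C>G]A")), "APOBEC_like")
  expect_equal(as.character(classify_motif("A[C>T]G")), "SBS1_like")
  # strand prefixes are ignored for motif purposes
  expect_equal(as.character(classify_motif("T:T[C>G]A")), "APOBEC_like")
})

test_that("motif classification of variants handles indels and purines", {
  v <- data.frame(ref = c("G", "AT", "C", "A"),
                  alt = c("A", "A", "A", "G"),
                  five = c("C", NA, "T", "T"),
                  three = c("T", NA, "G", "T"))
  # G>A with 3' T on + strand is C>T with 5' A after normalization; the
  # normalized 3' base is the complement of the + strand 5' base (C -> G)
  cls <- classify_motif(v)
  expect_equal(as.character(cls),
               c("SBS1_like", "indel", "C_to_A", "T_to_C"))
  expect_warning(classify_motif(data.frame(ref = "C", alt = "T")),
                 "missing flanking context")
})
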