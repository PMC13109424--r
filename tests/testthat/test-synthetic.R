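test_that("profile generation follows the mixture-multinomial model", {
  pool <- simulate_signatures(c("clock", "apobec"), "SBS96")
  # law of large numbers: a single-signature draw converges to the profile
  pr <- generate_profile(pool, c(1, 0), 1e6, seed = 2)
  expect_gte(cosine_sim(pr$counts, unclass(pool)[, "clock"]), 0.9999)
  # n = 0 gives the zero vector
  expect_equal(sum(generate_profile(pool, c(1, 0), 0, seed = 1)$counts), 0)
  # weights are normalized and recorded
  pr2 <- generate_profile(pool, c(2, 2), 100, seed = 3)
  expect_equal(unname(pr2$weights), c(0.5, 0.5))
  expect_error(generate_profile(pool, c(0, 0), 10), "positive sum")
})

test_that("mass splits across disjoint supports as binomial theory predicts", {
  sc <- channel_schema("SBS96")
  prof <- matrix(0, 96, 2, dimnames = list(sc$channels, c("L", "R")))
  prof[1:48, 1] <- 1 / 48; prof[49:96, 2] <- 1 / 48
  pool <- signature_matrix(prof, sc)
  pr <- generate_profile(pool, c(0.5, 0.5), 10000, seed = 9)
  left <- sum(pr$counts[1:48])
  se <- sqrt(10000 * 0.25)
  expect_lt(abs(left - 5000), 3 * se)
})

test_that("the synthetic genome provides sites for every strand category", {
  g <- synthetic_genome(n_contigs = 2, contig_length = 2e4, seed = 3)
  idx <- sigstrata:::site_index(g$genome, g$annotation)
  cats <- unique(sub("^.*\\|", "", names(idx)))
  expect_setequal(cats, c("T", "U", "B", "N"))
  # every pyrimidine-centered trinucleotide is available in every category
  tris <- unique(sub("\\|.*$", "", names(idx)))
  expect_equal(length(tris), 32)
  expect_equal(length(names(idx)), 32 * 4)
})

test_that("cohorts are seed-deterministic with exact ledgers", {
  pool <- simulate_signatures(c("clock", "apobec"), "SBS384")
  plan <- data.frame(size = 3, dominant = "apobec", share = 0.7,
                     burden = 120)
  g <- synthetic_genome(n_contigs = 2, contig_length = 3e4, seed = 1)
  c1 <- generate_cohort(pool, plan, genome = g, seed = 21)
  c2 <- generate_cohort(pool, plan, genome = g, seed = 21)
  expect_identical(c1$ledger, c2$ledger)
  expect_identical(c1$calls, c2$calls)
  c3 <- generate_cohort(pool, plan, genome = g, seed = 22)
  expect_false(identical(c1$ledger$channel_counts,
                         c3$ledger$channel_counts))
  # ledger totals equal emitted variant counts
  expect_equal(unname(rowSums(c1$ledger$channel_counts)),
               unname(as.vector(table(factor(c1$ledger$variants$sample,
                                             levels = c1$ledger$samples)))))
})

test_that("emitted variants classify back to their ledger channels", {
  pool <- simulate_signatures(c("clock", "smoking"), "SBS384")
  g <- synthetic_genome(n_contigs = 2, contig_length = 3e4, seed = 2)
  coh <- generate_cohort(pool, data.frame(size = 4, dominant = "smoking",
                                          share = 0.8, burden = 150),
                         genome = g, seed = 31)
  v <- coh$ledger$variants
  lab <- classify_sbs(v, coh$genome, coh$annotation, "SBS384")
  expect_identical(lab, v$channel)
  # and the built catalog equals the ledger's channel counts
  catal <- build_catalog(v, coh$genome, coh$annotation, "SBS384",
                         samples = coh$ledger$samples)
  expect_equal(unclass(catal), coh$ledger$channel_counts,
               ignore_attr = TRUE)
})

test_that("perfect callers reproduce the emitted variants via consensus", {
  pool <- simulate_signatures(c("clock", "apobec"), "SBS384")
  g <- synthetic_genome(n_contigs = 2, contig_length = 3e4, seed = 4)
  coh <- generate_cohort(
    pool, data.frame(size = 3, dominant = "clock", share = 0.7,
                     burden = 100),
    callers = data.frame(caller = c("x", "y"), sensitivity = 1,
                         false_rate = 0),
    genome = g, seed = 41)
  cons <- consensus_filter(coh$calls)
  truth <- unique(coh$ledger$variants[, c("sample", "chrom", "pos", "ref",
                                          "alt")])
  expect_equal(nrow(cons), nrow(truth))
  expect_setequal(paste(cons$sample, cons$chrom, cons$pos, cons$alt),
                  paste(truth$sample, truth$chrom, truth$pos, truth$alt))
})

test_that("injected outlier samples carry their planted profiles", {
  pool <- simulate_signatures(c("clock", "apobec"), "SBS384")
  out_pool <- simulate_signatures(c("uv", "mmr"), "SBS384")
  g <- synthetic_genome(n_contigs = 2, contig_length = 3e4, seed = 6)
  coh <- generate_cohort(
    pool, data.frame(size = 3, dominant = "clock", share = 0.7,
                     burden = 80),
    outlier_pool = out_pool,
    outlier_plan = data.frame(profile = c("uv", "mmr"), n = c(2, 1),
                              burden = 900),
    genome = g, seed = 51)
  led <- coh$ledger
  expect_equal(sum(led$outlier), 3)
  expect_equal(unname(led$burdens[led$outlier]), rep(900, 3))
  uv_sample <- names(led$outlier)[led$outlier][1]
  expect_gte(cosine_sim(led$channel_counts[uv_sample, ],
                        unclass(out_pool)[, "uv"]), 0.9)
})

test_that("cohort files round-trip through the standard formats", {
  pool <- simulate_signatures(c("clock", "apobec"), "SBS384")
  g <- synthetic_genome(n_contigs = 2, contig_length = 2e4, seed = 7)
  coh <- generate_cohort(pool, data.frame(size = 2, dominant = "apobec",
                                          share = 0.7, burden = 60),
                         genome = g, seed = 61)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  genome2 <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome2, coh$genome)
  ann2 <- read_annotation(file.path(dir, "genes.bed"))
  expect_equal(length(ann2), length(coh$annotation))
  expect_identical(as.character(BiocGenerics::strand(ann2)),
                   as.character(BiocGenerics::strand(coh$annotation)))
  calls2 <- read_variant_table(file.path(dir, "calls_callerA.tsv"))
  expect_equal(nrow(calls2), nrow(coh$caller_tables[["callerA"]]))
})

test_that("the over-attribution table is reproducible and well-formed", {
  pool <- simulate_signatures(c("clock", "apobec", "flat"), "SBS96")
  t1 <- benchmark_overattribution(pool, absent = "flat", burden_grid = 100,
                                  n_per_burden = 3, n_bootstrap = 60,
                                  seed = 5)
  t2 <- benchmark_overattribution(pool, absent = "flat", burden_grid = 100,
                                  n_per_burden = 3, n_bootstrap = 60,
                                  seed = 5)
  expect_identical(t1, t2)
  expect_setequal(t1$fitter, c("nnls", "ci_pruned"))
  expect_true(all(t1$mean_true == 0))
  expect_true(all(t1$mean_attributed >= 0))
})
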