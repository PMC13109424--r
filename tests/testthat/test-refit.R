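pool96 <- simulate_signatures(c("clock", "apobec", "smoking", "alcohol",
                                "flat"), "SBS96")
sub_pool <- function(names) {
  signature_matrix(unclass(pool96)[, names, drop = FALSE], "SBS96")
}

test_that("NNLS recovers an exact member and rejects foreign spectra", {
  ref <- sub_pool(c("clock", "apobec"))
  spectrum <- 100 * unclass(ref)[, "clock"]
  a <- nnls_fit(spectrum, ref)
  expect_equal(unname(a), c(100, 0), tolerance = 1e-8)
  expect_equal(sum((unclass(ref) %*% a - spectrum)^2), 0, tolerance = 1e-12)
  # spectrum orthogonal to the references' support
  sc <- channel_schema("SBS96")
  disjoint <- rep(0, 96)
  ref2 <- matrix(0, 96, 2, dimnames = list(sc$channels, c("A", "B")))
  ref2[1:10, 1] <- 0.1; ref2[11:20, 2] <- 0.1
  disjoint[90:96] <- 5
  a2 <- nnls_fit(disjoint, signature_matrix(ref2, sc))
  expect_equal(unname(a2), c(0, 0))
})

test_that("NNLS is exactly scale-equivariant", {
  ref <- sub_pool(c("clock", "apobec", "flat"))
  pr <- generate_profile(ref, c(0.5, 0.3, 0.2), 700, seed = 12)
  a1 <- nnls_fit(pr$counts, ref)
  a7 <- nnls_fit(7 * pr$counts, ref)
  expect_equal(a7, 7 * a1, tolerance = 1e-8)
})

test_that("named spectra are reordered and schema mismatches error", {
  ref <- sub_pool(c("clock", "apobec"))
  pr <- generate_profile(ref, c(0.7, 0.3), 300, seed = 5)
  shuffled <- pr$counts[sample(96)]
  expect_equal(nnls_fit(shuffled, ref), nnls_fit(pr$counts, ref))
  bad <- stats::setNames(pr$counts, paste0("x", 1:96))
  expect_error(nnls_fit(bad, ref), "match")
})

test_that("de novo decomposition recovers exact and noisy mixtures", {
  sc <- channel_schema("SBS96")
  A <- rep(0, 96); A[1:8] <- 1 / 8
  B <- rep(0, 96); B[9:16] <- 1 / 8
  ref <- signature_matrix(matrix(c(A, B), 96, 2,
                                 dimnames = list(sc$channels, c("A", "B"))),
                          sc)
  dn <- signature_matrix(matrix(0.7 * A + 0.3 * B, 96, 1,
                                dimnames = list(sc$channels, "D1")), sc)
  dec <- decompose_denovo(dn, ref)
  expect_equal(unname(dec$weights["D1", ]), c(70, 30), tolerance = 1e-6)
  expect_equal(unname(dec$cosine["D1"]), 1, tolerance = 1e-9)
  # identity decomposition
  dec2 <- decompose_denovo(sub_pool("clock"), pool96)
  expect_equal(unname(dec2$weights[1, "clock"]), 100, tolerance = 1e-6)
  # noisy 3-way mixture at high count: within 2 percentage points
  set.seed(99)
  w <- c(0.5, 0.3, 0.2)
  mix <- as.vector(unclass(sub_pool(c("clock", "apobec", "alcohol"))) %*% w)
  noisy <- as.vector(rmultinom(1, 50000, mix))
  names(noisy) <- sc$channels
  dn3 <- signature_matrix(matrix(noisy / sum(noisy), 96, 1,
                                 dimnames = list(sc$channels, "D")), sc)
  dec3 <- decompose_denovo(dn3, sub_pool(c("clock", "apobec", "alcohol")))
  expect_true(all(abs(dec3$weights["D", ] - 100 * w) <= 2))
})

test_that("a planted single signature prunes the decoy and brackets truth", {
  ref <- sub_pool(c("clock", "smoking"))
  pr <- generate_profile(sub_pool("clock"), 1, 1000, seed = 3)
  fr <- attribute_with_ci(pr$counts, ref, n_bootstrap = 200, seed = 31)
  expect_true(fr$pruned[fr$signature == "smoking"])
  expect_false(fr$pruned[fr$signature == "clock"])
  expect_true(fr$ci_low[1] <= 1000 && 1000 <= fr$ci_high[1])
  expect_gte(attr(fr, "residual_cosine"), 0.9)
  expect_true(all(fr$activity[fr$pruned] == 0))
})

test_that("attribution grows sparser as the burden shrinks", {
  kept <- function(burden, seed) {
    pr <- generate_profile(pool96, rep(0.2, 5), burden, seed = seed)
    fr <- attribute_with_ci(pr$counts, pool96, n_bootstrap = 100,
                            seed = seed + 1)
    sum(!fr$pruned)
  }
  low <- mean(vapply(1:20, function(i) kept(20, 500 + i), numeric(1)))
  high <- mean(vapply(1:20, function(i) kept(2000, 900 + i), numeric(1)))
  expect_lt(low, high)   # CIs widen relative to burden at low counts
})

test_that("a near-degenerate CI level reduces pruning to zero activities", {
  ref <- sub_pool(c("clock", "apobec"))
  pr <- generate_profile(ref, c(0.6, 0.4), 1000, seed = 8)
  fr <- attribute_with_ci(pr$counts, pool96, n_bootstrap = 100,
                          ci_alpha = 0.999, seed = 9)
  point <- nnls_fit(pr$counts, pool96)
  # CIs collapse toward the median bootstrap activity: only signatures
  # whose typical fitted activity is zero get pruned
  expect_true(all(fr$activity[!fr$pruned] > 0))
  expect_false(fr$pruned[fr$signature == "clock"])
  expect_false(fr$pruned[fr$signature == "apobec"])
})

test_that("pruning hardly hurts the reconstruction at realistic burdens", {
  set.seed(71)
  for (i in 1:10) {
    w <- runif(5); w <- w / sum(w)
    pr <- generate_profile(pool96, w, 800, seed = 600 + i)
    full <- nnls_fit(pr$counts, pool96)
    recon_full <- as.vector(unclass(pool96) %*% full)
    fr <- attribute_with_ci(pr$counts, pool96, n_bootstrap = 100,
                            seed = 700 + i)
    cos_full <- cosine_sim(pr$counts, recon_full)
    expect_gte(attr(fr, "residual_cosine"), cos_full - 0.02)
  }
})

test_that("catalog-level attribution matches per-sample calls", {
  sc <- channel_schema("SBS96")
  counts <- rbind(generate_profile(pool96, c(1, 0, 0, 0, 0), 500,
                                   seed = 1)$counts,
                  generate_profile(pool96, c(0, 1, 0, 0, 0), 500,
                                   seed = 2)$counts)
  rownames(counts) <- c("s1", "s2")
  catal <- mutation_catalog(counts, sc)
  acts <- attribute_catalog(catal, pool96, prune = TRUE, n_bootstrap = 100,
                            seed = 5)
  expect_gt(acts["s1", "clock"], 400)
  expect_gt(acts["s2", "apobec"], 400)
  plain <- attribute_catalog(catal, pool96, prune = FALSE)
  expect_equal(unname(plain["s1", ]),
               unname(nnls_fit(counts["s1", ], pool96)), tolerance = 1e-8)
})
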