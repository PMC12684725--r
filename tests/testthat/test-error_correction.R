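test_that("fingerprint length follows floor(L / (K + 1))", {
  expect_equal(fingerprint_length(60, 6), 8L)
  expect_equal(fingerprint_length(16, 2), 5L)
  expect_equal(fingerprint_length(12, 0), 12L)  # K = 0: whole barcode
  expect_error(fingerprint_length(3, 4), "fingerprint")
})

test_that("fingerprints are the K+1 disjoint chunks, tail ignored", {
  expect_equal(fingerprints("ACGTACGT", 4, 1), c("ACGT", "ACGT"))
  expect_equal(fingerprints("ACGTACG", 2, 2), c("AC", "GT", "AC"))  # base 7 unused
  expect_equal(fingerprints("ACGTA", 5, 0), "ACGTA")
})

test_that("pre-clustering groups barcodes sharing an offset-tagged fingerprint", {
  sets <- precluster(c("AAAA", "AAAT", "GGGG"), K = 1)  # n = 2: AA@1 shared
  sets <- lapply(sets, sort)
  expect_setequal(sapply(sets, paste, collapse = ","), c("AAAA,AAAT", "GGGG"))
  expect_length(precluster(rep("ACGT", 1), K = 1), 1L)
  # K = 0 keeps every distinct barcode alone
  expect_length(precluster(c("AAAA", "AAAT"), K = 0), 2L)
})

test_that("pigeonhole completeness: pairs within Hamming K are never split", {
  set.seed(77)
  n_trials <- 2000
  for (trial in seq_len(n_trials)) {
    L <- sample(c(8, 12, 15), 1)
    K <- sample(1:3, 1)
    a <- random_dna(1, L)
    k <- sample.int(K, 1)
    s <- strsplit(a, "")[[1]]
    for (p in sample(L, k)) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    b <- paste(s, collapse = "")
    if (a == b) next
    sets <- precluster(c(a, b), K)
    expect_length(sets, 1L)
  }
})

test_that("forest refinement follows count order, distance and the ratio gate", {
  p1 <- correction_params(1)
  f1 <- forest_refine(c("AAAA", "AAAT"), c(100, 5), p1)
  expect_equal(unname(f1$assignment["AAAT"]), "AAAA")
  expect_length(f1$trees, 1L)

  f2 <- forest_refine(c("AAAA", "TTTT"), c(100, 90), p1)
  expect_length(f2$trees, 2L)   # distance 4 > 1

  p_ratio <- correction_params(1, ratio = 2)
  f3 <- forest_refine(c("AAAA", "AAAT"), c(100, 60), p_ratio)
  expect_length(f3$trees, 2L)   # 100 < 2 * 60: gate fails, new root
  f4 <- forest_refine(c("AAAA", "AAAT"), c(100, 50), p_ratio)
  expect_length(f4$trees, 1L)   # 100 >= 2 * 50
})

test_that("correction clusters globally and corrects counts per sample", {
  tal <- data.table::data.table(
    barcode = c("AAAA", "AAAT", "AAAT"),
    sample_id = c("s1", "s1", "s2"),
    count = c(10L, 2L, 7L))
  out <- correct_barcodes(tal, correction_params(1))
  expect_equal(sort(unique(out$tallies$barcode)), "AAAA")
  s1 <- out$tallies[sample_id == "s1"]$count
  s2 <- out$tallies[sample_id == "s2"]$count
  # AAAT is locally dominant in s2 but still rescued by the global cluster
  expect_equal(s1, 12L)
  expect_equal(s2, 7L)
})

test_that("K = 0 correction is the identity transform", {
  tal <- data.table::data.table(barcode = c("AAAA", "AAAT"),
                                sample_id = "s1", count = c(5L, 3L))
  out <- correct_barcodes(tal, correction_params(0))
  expect_equal(out$tallies[order(barcode)]$count, c(5L, 3L))
  expect_equal(unname(out$assignment), names(out$assignment))
})

test_that("per-sample counts are conserved through correction", {
  set.seed(41)
  for (trial in 1:10) {
    tal <- random_tally_instance()
    before <- tapply(tal$count, tal$sample_id, sum)
    out <- correct_barcodes(tal, correction_params(2))
    after <- tapply(out$tallies$count, out$tallies$sample_id, sum)
    expect_equal(after[names(before)], before)
  }
})

test_that("correction equals the brute-force all-pairs greedy oracle", {
  set.seed(55)
  for (trial in 1:25) {
    K <- sample(1:2, 1)
    ratio <- if (trial %% 3 == 0) 2 else NULL
    tal <- random_tally_instance(n_roots = sample(4:10, 1),
                                 n_variants = sample(10:40, 1), K = K)
    got <- correct_barcodes(tal, correction_params(K, ratio = ratio))
    want <- oracle_correct(tal, K, ratio = ratio)
    expect_equal(got$assignment[names(want)], want)
  }
})

test_that("correction is invariant under permutation of the tally rows", {
  set.seed(66)
  tal <- random_tally_instance()
  out1 <- correct_barcodes(tal, correction_params(2))
  out2 <- correct_barcodes(tal[sample(nrow(tal))], correction_params(2))
  expect_equal(out2$assignment[names(out1$assignment)], out1$assignment)
  expect_equal(out2$tallies, out1$tallies)
})

test_that("variable-length sets fall back to sliding n-grams and Levenshtein", {
  # deletion variant: Hamming is undefined, Levenshtein distance 1
  tal <- data.table::data.table(barcode = c("ACGTACGTACGT", "ACGTACGACGT"),
                                sample_id = "s1", count = c(50L, 2L))
  out <- correct_barcodes(tal, correction_params(1))
  expect_equal(out$tallies$barcode, "ACGTACGTACGT")
  expect_equal(out$tallies$count, 52L)
})

test_that("distance primitives match their definitions", {
  expect_equal(hamming_distance("ACGT", "ACGA"), 1L)
  expect_equal(levenshtein_distance("ACGT", "ACGTT"), 1L)
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein_distance("ACGT", "ACGT"), 0L)
  expect_error(hamming_distance("ACGT", "ACG"), "equal-length")
  # spot-check vectorized forms against independent oracles
  set.seed(8)
  a <- random_dna(20, 10); b <- random_dna(20, 10)
  expect_equal(hamming_distance(a, b),
               mapply(oracle_hamming, a, b, USE.NAMES = FALSE))
  expect_equal(levenshtein_distance(a, b),
               as.integer(diag(utils::adist(a, b))))
})
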