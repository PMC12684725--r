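test_that("generated barcode libraries respect the minimum Hamming distance", {
  bcs <- generate_barcodes(10, 20, 5, seed = 31)
  expect_length(bcs, 10L)
  expect_true(all(nchar(bcs) == 20))
  for (i in 1:9) for (j in (i + 1):10)
    expect_gte(oracle_hamming(bcs[i], bcs[j]), 5)
  expect_equal(generate_barcodes(10, 20, 5, seed = 31), bcs)  # determinism
  expect_error(generate_barcodes(100, 4, 4, seed = 1, max_attempts = 500),
               "reduce n or d")
})

test_that("abundance distributions sum to the total and match their shapes", {
  bcs <- paste0("B", 1:4)
  u <- assign_abundances(bcs, "uniform", total_reads = 100)
  expect_equal(unname(u), rep(25L, 4))
  u2 <- assign_abundances(bcs, "uniform", total_reads = 102)
  expect_equal(sum(u2), 102L)
  expect_equal(sort(unname(u2)), c(25L, 25L, 26L, 26L))

  # power law, exponent 1: proportions 1 : 1/2 : 1/3
  p <- assign_abundances(paste0("B", 1:3), "power_law", total_reads = 110,
                         exponent = 1)
  expect_equal(unname(p), c(60L, 30L, 20L))

  for (d in c("random", "normal", "power_law")) {
    x <- assign_abundances(bcs, d, total_reads = 997, seed = 5)
    expect_equal(sum(x), 997L)
    expect_true(all(x >= 0))
  }
})

test_that("chimeras join a prefix and a suffix at the split point", {
  expect_equal(nrow(generate_chimeras(c("AAAA", "TTTT"), 0)), 0L)
  expect_error(generate_chimeras("AAAA", 1), "at least two")
  ch <- generate_chimeras(c("AAAA", "TTTT"), 2, seed = 12)
  expect_equal(nrow(ch), 4L)
  expect_true(all(nchar(ch$chimera) == 4))
  for (i in seq_len(nrow(ch))) {
    expect_equal(ch$chimera[i],
                 paste0(substr(ch$parent[i], 1, ch$split[i]),
                        substr(ch$partner[i], ch$split[i] + 1, 4)))
  }
  # the spec example: parents AAAA/TTTT split at 2 -> AATT
  two <- ch[ch$parent == "AAAA" & ch$split == 2]
  if (nrow(two)) expect_true(all(two$chimera == "AATT"))
})

test_that("chimera counts are the floored fraction of the parent count", {
  cfg <- simulation_config(n_barcodes = 4, barcode_length = 12, min_hamming = 2,
                           n_samples = 1, reads_per_barcode = 100,
                           chimeras_per_barcode = 1,
                           chimera_relative_abundance = 0.1,
                           mode = "controlled", seed = 3)
  sim <- suppressMessages(synthesize_reads(cfg, tempfile()))
  truth <- sim$truth_table
  expect_equal(truth[is_chimera == TRUE]$true_count, rep(10L, 4))  # floor(0.1*100)
})

test_that("controlled mode emits exact counts with verbatim barcodes at Q40", {
  cfg <- simulation_config(n_barcodes = 2, barcode_length = 20, min_hamming = 3,
                           n_samples = 1, reads_per_barcode = 10,
                           mode = "controlled", seed = 17)
  sim <- suppressMessages(synthesize_reads(cfg, tempfile()))
  reads <- read_fastq(sim$fastq[[1]], "sample_1")
  expect_equal(nrow(reads), 20L)
  expect_true(all(reads$quality == strrep("I", nchar(reads$sequence[1]))))
  hits <- vapply(sim$barcodes, function(b)
    sum(grepl(b, reads$sequence, fixed = TRUE)), numeric(1))
  truth <- sim$truth_table
  expect_equal(unname(hits), truth$true_count[match(names(hits), truth$barcode)])
})

test_that("empirical mode at error rate 0 equals controlled output up to quality", {
  base <- list(n_barcodes = 3, barcode_length = 15, min_hamming = 3,
               n_samples = 1, reads_per_barcode = 5, seed = 23)
  simC <- suppressMessages(synthesize_reads(
    do.call(simulation_config, c(base, mode = "controlled")), tempfile()))
  simE <- suppressMessages(synthesize_reads(
    do.call(simulation_config, c(base, mode = "empirical", error_rate = 0)),
    tempfile()))
  rc <- read_fastq(simC$fastq[[1]], "s")
  re <- read_fastq(simE$fastq[[1]], "s")
  expect_equal(re$sequence, rc$sequence)
  expect_equal(re$read_id, rc$read_id)
  expect_false(any(re$quality == rc$quality))  # Q37 vs Q40
})

test_that("empirical error-free barcode fraction matches (1-e)^L binomially", {
  e <- 0.005
  L <- 30
  cfg <- simulation_config(n_barcodes = 50, barcode_length = L, min_hamming = 3,
                           n_samples = 1, reads_per_barcode = 200,
                           mode = "empirical", error_rate = e, seed = 29)
  sim <- suppressMessages(synthesize_reads(cfg, tempfile()))
  reads <- read_fastq(sim$fastq[[1]], "s")
  n <- nrow(reads)
  expect_gte(n, 1e4)
  # count reads whose barcode region is error-free
  flank_len <- nchar(cfg$flank5)
  emitted <- rep(sim$truth_table$barcode, sim$truth_table$true_count)
  observed_bc <- substr(reads$sequence, flank_len + 1, flank_len + L)
  frac <- mean(observed_bc == emitted)
  p <- (1 - e)^L
  sd3 <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), sd3)
})

test_that("identical configurations give byte-identical FASTQ", {
  cfg <- simulation_config(n_barcodes = 5, barcode_length = 20, min_hamming = 3,
                           n_samples = 2, reads_per_barcode = 20,
                           mode = "empirical", error_rate = 0.01, seed = 99)
  s1 <- suppressMessages(synthesize_reads(cfg, tempfile()))
  s2 <- suppressMessages(synthesize_reads(cfg, tempfile()))
  for (k in seq_along(s1$fastq)) {
    expect_identical(readLines(s1$fastq[[k]]), readLines(s2$fastq[[k]]))
  }
  expect_identical(readLines(s1$truth), readLines(s2$truth))
})

test_that("infeasible designs are rejected", {
  expect_error(simulation_config(min_hamming = 70, barcode_length = 60))
})
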