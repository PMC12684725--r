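ref_set <- function(...) {
  seqs <- c(...)
  data.table::data.table(name = paste0("B", seq_along(seqs)), sequence = seqs)
}

test_that("exact reference matching reports the leftmost unique hit", {
  refs <- ref_set("ACGTAC")
  hit <- match_reference_exact("TTACGTACTT", refs)
  expect_equal(hit$name, "B1")
  expect_equal(hit$position, 3L)  # 1-based (third base)
  expect_null(match_reference_exact("TTTTTTTT", refs))
})

test_that("reads matched by two references are ambiguous and discarded", {
  refs <- ref_set("AAAA", "TTTT")
  expect_null(match_reference_exact("AAAATTTT", refs))
  res <- match_references("AAAATTTT", refs, tolerance = 0)
  expect_equal(res$status, "ambiguous")
})

test_that("tolerant matching finds hits within budget and rejects tolerance 0", {
  refs <- ref_set("ACGTACGT")
  hit <- match_reference_tolerant("TTACGTACGATT", refs, 1)
  expect_equal(hit$name, "B1")
  expect_equal(hit$distance, 1L)
  expect_error(match_reference_tolerant("TTACGTACGATT", refs, 0), "exact")
  # two references tied at the minimum distance: discarded
  refs2 <- ref_set("AAAAAAAA", "AAAAAAAT")
  res <- match_references("CCAAAAAAACCC", refs2, tolerance = 1)
  expect_equal(res$status, "ambiguous")
})

test_that("tolerant matcher agrees with the exhaustive infix edit-distance oracle", {
  set.seed(21)
  refs <- ref_set(random_dna(4, 10))
  for (trial in 1:40) {
    # embed a mutated reference or pure noise
    if (trial %% 2 == 0) {
      base <- sample(refs$sequence, 1)
      mut <- strsplit(base, "")[[1]]
      for (p in sample(10, sample(0:3, 1)))
        mut[p] <- sample(c("A", "C", "G", "T"), 1)
      read <- paste0(paste(random_dna(1, sample(0:6, 1)), collapse = ""),
                     paste(mut, collapse = ""),
                     paste(random_dna(1, sample(0:6, 1)), collapse = ""))
    } else {
      read <- random_dna(1, sample(15:25, 1))
    }
    for (tol in 1:2) {
      got <- match_references(read, refs, tolerance = tol)
      oracle_d <- vapply(refs$sequence, oracle_infix_edit, numeric(1), text = read)
      best <- min(oracle_d)
      winners <- which(oracle_d == best)
      if (best > tol) {
        expect_true(got$status %in% c("none"))
      } else if (length(winners) > 1) {
        expect_equal(got$status, "ambiguous")
      } else {
        expect_equal(got$status, "hit")
        expect_equal(got$ref, refs$name[winners])
        expect_equal(got$distance, as.integer(best))
      }
    }
  }
})

test_that("exact path equals the tolerant oracle restricted to distance 0", {
  set.seed(33)
  refs <- ref_set(random_dna(5, 8))
  reads <- c(paste0("AA", refs$sequence[2], "TT"),
             random_dna(20, 20))
  got <- match_references(reads, refs, tolerance = 0)
  for (i in seq_along(reads)) {
    oracle_hits <- which(vapply(refs$sequence, function(r)
      grepl(r, reads[i], fixed = TRUE), logical(1)))
    if (length(oracle_hits) == 1) {
      expect_equal(got$status[i], "hit")
      expect_equal(got$ref[i], refs$name[oracle_hits])
    } else if (length(oracle_hits) > 1) {
      expect_equal(got$status[i], "ambiguous")
    } else {
      expect_equal(got$status[i], "none")
    }
  }
})

test_that("pattern extraction honours flanks, mask and length interval", {
  p <- barcode_pattern(flank5 = "TGGT", flank3 = "CCAA")
  m <- compile_pattern(p, 0)
  expect_equal(m("AATGGTACGTCCAA")$barcode, "ACGT")

  pm <- barcode_pattern(flank5 = "TGGT", mask = "NNTGNN")
  mm <- compile_pattern(pm, 0)
  expect_equal(mm("TGGTACTGAA")$barcode, "ACTGAA")
  expect_true(is.na(mm("TGGTACAGAA")$barcode))   # fixed position mismatch

  pl <- barcode_pattern(flank5 = "TGGT", flank3 = "CCAA",
                        min_length = 4, max_length = 6)
  ml <- compile_pattern(pl, 0)
  expect_true(is.na(ml("TGGTACGTACGCCAA")$barcode))  # length 7 rejected
  expect_equal(ml("TGGTACGTACCCAA")$barcode, "ACGTAC")
})

test_that("pattern validation rejects malformed specifications", {
  expect_error(barcode_pattern(), "at least one")
  expect_error(barcode_pattern(flank5 = "ACGT", mask = "NNXX"), "mask")
  expect_error(barcode_pattern(flank5 = "ACGT", mask = "NNN",
                               min_length = 4, max_length = 6), "mask length")
})

test_that("N in a read never matches except against mask N positions", {
  p <- barcode_pattern(flank5 = "TGGT", flank3 = "CCAA")
  m <- compile_pattern(p, 0)
  expect_true(is.na(m("TGGTACNTCCAA")$barcode))
  pm <- barcode_pattern(flank5 = "TGGT", flank3 = "CCAA", mask = "ANNT")
  mm <- compile_pattern(pm, 0)
  expect_equal(mm("TGGTACNTCCAA")$barcode, "ACNT")  # N at mask-N position
  expect_true(is.na(mm("TGGTNCGTCCAA")$barcode))    # N at fixed position
  refs <- ref_set("ACGT")
  expect_null(match_reference_exact("AANCGTAA", refs))
})

test_that("tolerant flank location survives flank substitutions", {
  bc <- "ACGTACGTAC"
  read <- paste0("TGCTA", bc, "GGATC")      # one sub in each 5-bp flank
  p <- barcode_pattern(flank5 = "TGGTA", flank3 = "GGTTC",
                       min_length = 10, max_length = 10)
  expect_true(is.na(compile_pattern(p, 0)(read)$barcode))
  expect_equal(compile_pattern(p, 1)(read)$barcode, bc)
})

test_that("extraction is order-independent and respects the revcomp flag", {
  set.seed(14)
  bcs <- random_dna(20, 12)
  reads <- make_reads(paste0("TGGTAC", bcs, "GGCCAT"))
  p <- barcode_pattern(flank5 = "TGGTAC", flank3 = "GGCCAT")
  obs <- suppressMessages(extract_tags(reads, "reference_free", p))
  perm <- sample(nrow(reads))
  obs2 <- suppressMessages(extract_tags(reads[perm], "reference_free", p))
  expect_equal(sort(obs$barcode), sort(obs2$barcode))
  expect_equal(obs$barcode, bcs)

  rc_reads <- make_reads(reverse_complement(paste0("TGGTAC", bcs[1], "GGCCAT")))
  expect_equal(nrow(suppressMessages(
    extract_tags(rc_reads, "reference_free", p))), 0L)
  obs_rc <- suppressMessages(
    extract_tags(rc_reads, "reference_free", p, scan_revcomp = TRUE))
  expect_equal(obs_rc$barcode, bcs[1])
})

test_that("extraction drops are counted by reason", {
  p <- barcode_pattern(flank5 = "TGGTAC", flank3 = "GGCCAT",
                       min_length = 4, max_length = 4)
  reads <- make_reads(c("TGGTACAAAAGGCCAT",    # good
                        "TGGTACAAAAAGGCCAT",   # bad length
                        "CCCCCCCCCCCCCCCC"))   # no flank
  obs <- suppressMessages(extract_tags(reads, "reference_free", p))
  expect_equal(nrow(obs), 1L)
  dl <- drop_log(obs)
  expect_equal(dl[["bad_length"]], 1L)
  expect_equal(sum(dl), 2L)
})
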