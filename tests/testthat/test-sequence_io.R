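test_that("FASTQ records parse with PHRED+33 qualities", {
  path <- write_temp_fastq(fastq_record("r1", "ACGT", "IIII"))
  reads <- read_fastq(path, "s1")
  expect_equal(nrow(reads), 1L)
  expect_equal(reads$read_id, "r1")
  expect_equal(reads$sequence, "ACGT")
  expect_equal(phred_scores(reads$quality)[[1]], rep(40L, 4))
  expect_equal(reads$sample_id, "s1")
})

test_that("empty FASTQ yields an empty stream without error", {
  path <- write_temp_fastq(character(0))
  reads <- read_fastq(path, "s1")
  expect_equal(nrow(reads), 0L)
})

test_that("paired-end FASTQ emits both mates; record-count mismatch is fatal", {
  p1 <- write_temp_fastq(c(fastq_record("a", "ACGT"), fastq_record("b", "GGGG"),
                           fastq_record("c", "TTTT")))
  p2 <- write_temp_fastq(c(fastq_record("a", "CCCC"), fastq_record("b", "AAAA"),
                           fastq_record("c", "ACAC")))
  reads <- read_fastq(c(p1, p2), "s1")
  expect_equal(nrow(reads), 6L)
  expect_equal(sort(unique(reads$mate)), c(1L, 2L))
  p3 <- write_temp_fastq(c(fastq_record("a", "ACGT")))
  expect_error(read_fastq(c(p1, p3), "s1"), "mismatch")
})

test_that("malformed FASTQ is fatal with the record index", {
  path <- write_temp_fastq(c(fastq_record("ok", "ACGT"),
                             c("@bad", "ACGT", "+", "III")))  # qual too short
  expect_error(read_fastq(path, "s1"), "record 2")
})

test_that("FASTQ round trip preserves records, plain and gzipped", {
  set.seed(11)
  reads <- make_reads(random_dna(25, 40),
                      quality = vapply(rep(40, 25), function(l)
                        intToUtf8(sample(33:73, l, replace = TRUE)), character(1)))
  for (ext in c(".fastq", ".fastq.gz")) {
    path <- tempfile(fileext = ext)
    write_fastq(reads, path)
    back <- read_fastq(path, "s1")
    expect_equal(back$read_id, reads$read_id)
    expect_equal(back$sequence, reads$sequence)
    expect_equal(back$quality, reads$quality)
  }
})

test_that("whitelists deduplicate, reject empty files, and accept gzip", {
  p <- tempfile(); writeLines(c("AAAC-1", "AAAC-1", "GGGT-1"), p)
  wl <- load_whitelist(p)
  expect_setequal(wl, c("AAAC-1", "GGGT-1"))
  pe <- tempfile(); file.create(pe)
  expect_error(load_whitelist(pe), "empty")
  pg <- tempfile(fileext = ".gz")
  con <- gzfile(pg, "wt"); writeLines(c("A-1", "B-1", "C-1"), con); close(con)
  expect_length(load_whitelist(pg), 3L)
})

test_that("reference sets load from FASTA and CSV with validation", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">B1", "ACGTAC", ">B2", "ggttaa"), fa)
  refs <- load_references(fa)
  expect_equal(refs$name, c("B1", "B2"))
  expect_equal(refs$sequence, c("ACGTAC", "GGTTAA"))  # uppercased

  csv <- tempfile(fileext = ".csv")
  writeLines(c("name,sequence", "B1,ACGTAC", "B2,ACGTAC"), csv)
  expect_error(load_references(csv), "duplicate reference sequences")
  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("name,sequence", "B1,ACGTAC", "B1,GGTTAA"), csv2)
  expect_error(load_references(csv2), "duplicate reference names")
  csv3 <- tempfile(fileext = ".csv")
  writeLines(c("name,sequence", "B1,ACGXAC"), csv3)
  expect_error(load_references(csv3), "non-ACGTN")
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">B1", "ACGTACGT", ">B2", "GTAC"), fa2)
  expect_warning(load_references(fa2), "substring")
})

# --- BAM fixture built from SAM text ---------------------------------------

make_test_bam <- function() {
  sam <- tempfile(fileext = ".sam")
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:100",
    "@SQ\tSN:chr2\tLN:100",
    "m1\t0\tchr1\t5\t60\t8M\t*\t0\t0\tACGTACGT\tIIIIIIII\tCB:Z:ACGT-1\tUB:Z:TTTT",
    "m2\t0\tchr1\t20\t60\t8M\t*\t0\t0\tGGGGCCCC\tIIIIIIII",
    "m3\t0\tchr2\t5\t60\t8M\t*\t0\t0\tTTTTAAAA\tIIIIIIII",
    "m4\t0\tchr2\t30\t60\t8M\t*\t0\t0\tCCCCGGGG\tIIIIIIII",
    "m5\t256\tchr1\t50\t60\t8M\t*\t0\t0\tACGTACGT\tIIIIIIII",  # secondary: skipped
    "u1\t4\t*\t0\t0\t*\t*\t0\t0\tAAAATTTT\tIIIIIIII",
    "u2\t4\t*\t0\t0\t*\t*\t0\t0\tCCCCTTTT\tIIIIIIII",
    "u3\t4\t*\t0\t0\t*\t*\t0\t0\tGGGGTTTT\tIIIIIIII")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE, indexDestination = TRUE)
  bam
}

test_that("BAM contig modes select the expected reads and populate tags", {
  bam <- make_test_bam()
  all <- read_bam(bam, "all", sample_id = "s1")
  expect_equal(nrow(all), 7L)  # 4 mapped primaries + 3 unmapped; secondary skipped
  unmapped <- read_bam(bam, "unmapped_only", sample_id = "s1")
  expect_setequal(unmapped$read_id, c("u1", "u2", "u3"))
  chr1 <- read_bam(bam, "chr1", sample_id = "s1")
  expect_setequal(chr1$read_id, c("m1", "m2"))
  expect_error(read_bam(bam, "chrV", sample_id = "s1"), "chrV")
  m1 <- all[all$read_id == "m1"]
  expect_equal(m1$cell_barcode, "ACGT-1")
  expect_equal(m1$umi, "TTTT")
  expect_true(is.na(all[all$read_id == "m2"]$cell_barcode))
})

test_that("read_bam(all) equals unmapped plus all contigs", {
  bam <- make_test_bam()
  all <- read_bam(bam, "all", sample_id = "s1")
  parts <- rbind(read_bam(bam, "unmapped_only", sample_id = "s1"),
                 read_bam(bam, c("chr1", "chr2"), sample_id = "s1"))
  expect_setequal(all$read_id, parts$read_id)
  expect_equal(nrow(all), nrow(parts))
})
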