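# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's C++ routines: Hamming via utf8ToInt, Levenshtein via utils::adist.

random_dna <- function(n, L) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = ""),
         character(1))
}

make_reads <- function(seqs, sample_id = "s1", quality = NULL,
                       cell_barcode = NA_character_, umi = NA_character_) {
  data.table::data.table(
    read_id = sprintf("r%03d", seq_along(seqs)),
    sequence = seqs,
    quality = quality %||% strrep("I", nchar(seqs)),
    sample_id = sample_id,
    cell_barcode = cell_barcode,
    umi = umi,
    mate = NA_integer_)
}

make_obs <- function(barcode, sample_id = "s1", cell_barcode = NA_character_,
                     umi = NA_character_, read_count = 1L) {
  data.table::data.table(barcode = barcode, sample_id = sample_id,
                         cell_barcode = cell_barcode, umi = umi,
                         read_count = as.integer(read_count))
}

write_temp_fastq <- function(records, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(records, con)
  close(con)
  path
}

fastq_record <- function(id, seq, qual = strrep("I", nchar(seq))) {
  c(paste0("@", id), seq, "+", qual)
}

# Independent oracle: minimum edit distance of `pattern` vs any infix of `text`,
# by enumerating all substrings and scoring them with utils::adist.
oracle_infix_edit <- function(pattern, text) {
  n <- nchar(text)
  best <- nchar(pattern)  # align against the empty infix: all deletions
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- utils::adist(pattern, substr(text, i, j))[1, 1]
      if (d < best) best <- d
    }
  }
  best
}

oracle_hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Brute-force greedy correction oracle: all pairwise distances, count-ordered
# root attachment with the same nearest/ratio rules, no fingerprint stage.
oracle_correct <- function(tallies, K, ratio = NULL, metric = NULL) {
  tot <- aggregate(count ~ barcode, data = tallies, FUN = sum)
  if (is.null(metric))
    metric <- if (length(unique(nchar(tot$barcode))) == 1L) "hamming" else "levenshtein"
  dfun <- if (metric == "hamming") {
    function(a, b) vapply(b, function(x) oracle_hamming(a, x), numeric(1))
  } else {
    function(a, b) as.numeric(utils::adist(a, b)[1, ])
  }
  ord <- order(-tot$count, tot$barcode, method = "radix")
  bcs <- tot$barcode[ord]
  cts <- tot$count[ord]
  roots <- character(0); root_counts <- numeric(0)
  assign <- character(length(bcs)); names(assign) <- bcs
  for (i in seq_along(bcs)) {
    d <- if (length(roots)) dfun(bcs[i], roots) else numeric(0)
    elig <- which(d <= K)
    if (length(elig)) {
      e <- elig[order(d[elig], -root_counts[elig], roots[elig], method = "radix")]
      nearest <- e[1]
      if (is.null(ratio) || root_counts[nearest] >= ratio * cts[i]) {
        assign[i] <- roots[nearest]
        next
      }
    }
    roots <- c(roots, bcs[i]); root_counts <- c(root_counts, cts[i])
    assign[i] <- bcs[i]
  }
  assign
}

# Random tally instances where some barcodes are close variants of others, so
# that correction actually has work to do.
random_tally_instance <- function(n_roots = 8, n_variants = 30, L = 12, K = 2,
                                  n_samples = 2) {
  roots <- unique(random_dna(n_roots, L))
  variants <- vapply(sample(roots, n_variants, replace = TRUE), function(b) {
    k <- sample.int(K + 1, 1)  # 1..K+1 mutations (some beyond threshold)
    pos <- sample.int(L, k)
    s <- strsplit(b, "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste(s, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  bcs <- unique(c(roots, variants))
  data.table::rbindlist(lapply(seq_len(n_samples), function(s) {
    data.table::data.table(barcode = bcs,
                           sample_id = paste0("s", s),
                           count = sample.int(50, length(bcs), replace = TRUE))
  }))[count > 0]
}

python_available <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") return(FALSE)
  code <- suppressWarnings(
    system2(py, c("-c", shQuote("import anndata")), stdout = NULL, stderr = NULL))
  identical(code, 0L)
}
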