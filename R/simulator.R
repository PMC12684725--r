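# Ground-truthed synthetic barcode datasets: controlled (error-free, exact
# abundances) and empirical (substitution error model) amplicon simulation.

# Default flanks: 20 bp each, chosen once with non-repeating bases at the
# flank/barcode boundary so that boundary substitutions cannot shift the
# semi-global flank alignment.
DEFAULT_FLANK5 <- "TCGATTGACTAGGCAACTGA"
DEFAULT_FLANK3 <- "CTTGAGGACTCAATGGCTCA"

#' Simulation configuration
#'
#' Defaults reproduce the package's validation benchmark: 4 samples sharing a
#' pool of 500 barcodes of 60 bp with minimum pairwise Hamming distance 6,
#' fixed 20-bp flanks, a uniform 200 reads per barcode per sample, and (in
#' empirical mode) a per-base substitution rate of 0.001.
#'
#' @param n_barcodes number of distinct true barcodes.
#' @param barcode_length barcode length L in bp.
#' @param min_hamming minimum pairwise Hamming distance d between true barcodes.
#' @param flank5,flank3 fixed flanking sequences placed around every barcode.
#' @param distribution abundance distribution: `"uniform"` (equal counts,
#'   remainder spread deterministically), `"random"` (multinomial around
#'   uniform), `"normal"` (counts proportional to sorted normal draws, clipped
#'   at >= 1), `"power_law"` (proportional to rank^-exponent).
#' @param mean,sd normal-distribution parameters.
#' @param exponent power-law exponent.
#' @param reads_per_barcode reads per barcode per sample (sets `total_reads`).
#' @param total_reads alternative to `reads_per_barcode`: total reads per sample.
#' @param chimeras_per_barcode PCR chimeras generated per true barcode.
#' @param chimera_relative_abundance chimera count as a fraction of the parent
#'   barcode's count (floored).
#' @param mode `"empirical"` (substitution errors at `error_rate` across the
#'   whole read) or `"controlled"` (no errors, constant Q40).
#' @param error_rate per-base substitution probability in empirical mode.
#' @param n_samples number of samples.
#' @param seed integer seed; all randomness flows from it.
#' @param gzip write gzip-compressed FASTQ.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_barcodes = 500L, barcode_length = 60L,
                              min_hamming = 6L,
                              flank5 = DEFAULT_FLANK5, flank3 = DEFAULT_FLANK3,
                              distribution = c("uniform", "random", "normal", "power_law"),
                              mean = 100, sd = 20, exponent = 1,
                              reads_per_barcode = 200L, total_reads = NULL,
                              chimeras_per_barcode = 0L,
                              chimera_relative_abundance = 0.1,
                              mode = c("empirical", "controlled"),
                              error_rate = 0.001, n_samples = 4L, seed = 1L,
                              gzip = FALSE) {
  distribution <- match.arg(distribution)
  mode <- match.arg(mode)
  stopifnot(n_barcodes >= 1, barcode_length >= 1, min_hamming >= 0,
            min_hamming <= barcode_length, n_samples >= 1,
            chimeras_per_barcode >= 0,
            chimera_relative_abundance >= 0, chimera_relative_abundance < 1,
            error_rate >= 0, error_rate < 1)
  assert_dna(toupper(flank5), "flank5", allow_n = FALSE)
  assert_dna(toupper(flank3), "flank3", allow_n = FALSE)
  if (is.null(total_reads)) total_reads <- as.integer(n_barcodes * reads_per_barcode)
  structure(list(n_barcodes = as.integer(n_barcodes),
                 barcode_length = as.integer(barcode_length),
                 min_hamming = as.integer(min_hamming),
                 flank5 = toupper(flank5), flank3 = toupper(flank3),
                 distribution = distribution, mean = mean, sd = sd,
                 exponent = exponent, total_reads = as.integer(total_reads),
                 chimeras_per_barcode = as.integer(chimeras_per_barcode),
                 chimera_relative_abundance = chimera_relative_abundance,
                 mode = mode, error_rate = error_rate,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 gzip = isTRUE(gzip)),
            class = "simulation_config")
}

#' Generate a barcode library with a minimum pairwise Hamming distance
#'
#' Rejection sampling: random length-L sequences are accepted when their Hamming
#' distance to every accepted barcode is at least `d`. Reproducible for a given
#' seed; a capped number of attempts guards against infeasible (n, L, d)
#' combinations.
#'
#' @param n number of barcodes.
#' @param L barcode length.
#' @param d minimum pairwise Hamming distance.
#' @param seed optional seed (omit to use the current RNG state).
#' @param max_attempts rejection-sampling cap.
#' @return character vector of n barcodes.
#' @export
generate_barcodes <- function(n, L, d, seed = NULL, max_attempts = 1000L * n) {
  stopifnot(n >= 1, L >= 1, d >= 0, d <= L)
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0L, nrow = n, ncol = L)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("could not place %d barcodes of length %d at minimum ",
                          "Hamming distance %d after %d attempts; reduce n or d"),
                   n, L, d, max_attempts), call. = FALSE)
    cand <- sample.int(4L, L, replace = TRUE)
    if (got > 0L && d > 0L) {
      diffs <- acc[seq_len(got), , drop = FALSE] !=
        matrix(cand, nrow = got, ncol = L, byrow = TRUE)
      if (min(rowSums(diffs)) < d) next
    }
    got <- got + 1L
    acc[got, ] <- cand
  }
  apply(acc, 1L, function(row) paste(DNA_BASES[row], collapse = ""))
}

#' Assign read abundances to barcodes
#'
#' Counts always sum exactly to `total_reads` (largest-remainder rounding).
#'
#' @param barcodes character vector.
#' @param distribution,mean,sd,exponent see [simulation_config()].
#' @param total_reads total read count to distribute.
#' @param seed optional seed.
#' @return named integer vector (barcode -> count).
#' @export
assign_abundances <- function(barcodes,
                              distribution = c("uniform", "random", "normal", "power_law"),
                              total_reads, mean = 100, sd = 20, exponent = 1,
                              seed = NULL) {
  distribution <- match.arg(distribution)
  if (!is.null(seed)) set.seed(seed)
  n <- length(barcodes)
  counts <- switch(distribution,
    uniform = {
      base <- total_reads %/% n
      rem <- total_reads %% n
      base + c(rep(1L, rem), rep(0L, n - rem))
    },
    random = as.integer(rmultinom(1L, total_reads, rep(1 / n, n))),
    normal = {
      draws <- sort(pmax(rnorm(n, mean, sd), 1), decreasing = TRUE)
      largest_remainder(draws, total_reads)
    },
    power_law = largest_remainder(seq_len(n)^(-exponent), total_reads))
  stats::setNames(as.integer(counts), barcodes)
}

# Integer apportionment: floor the scaled weights, then hand the remaining units
# to the largest fractional parts (ties by index).
largest_remainder <- function(weights, total) {
  x <- weights / sum(weights) * total
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    extra <- order(x - f, decreasing = TRUE)[seq_len(rem)]
    f[extra] <- f[extra] + 1
  }
  as.integer(f)
}

#' Generate PCR chimeras from a barcode library
#'
#' Each chimera joins the prefix of one real barcode with the suffix of another
#' at a random split point, preserving length — the structure of a
#' template-switching PCR artifact.
#'
#' @param barcodes character vector of real barcodes (>= 2 when chimeras are
#'   requested).
#' @param chimeras_per_barcode chimeras per parent barcode.
#' @param seed optional seed.
#' @return a `data.table` with columns `chimera`, `parent` (prefix donor),
#'   `partner` (suffix donor), `split`.
#' @export
generate_chimeras <- function(barcodes, chimeras_per_barcode, seed = NULL) {
  if (chimeras_per_barcode == 0L)
    return(data.table::data.table(chimera = character(0), parent = character(0),
                                  partner = character(0), split = integer(0)))
  if (length(barcodes) < 2)
    stop("chimera generation needs at least two barcodes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(barcodes[1])
  n <- length(barcodes)
  parent_idx <- rep(seq_len(n), each = chimeras_per_barcode)
  partner_idx <- vapply(parent_idx, function(i) sample(setdiff(seq_len(n), i), 1L),
                        integer(1))
  split <- sample(seq_len(L - 1L), length(parent_idx), replace = TRUE)
  data.table::data.table(
    chimera = paste0(substr(barcodes[parent_idx], 1L, split),
                     substr(barcodes[partner_idx], split + 1L, L)),
    parent = barcodes[parent_idx],
    partner = barcodes[partner_idx],
    split = split)
}

#' Synthesize FASTQ reads and a ground-truth table
#'
#' Per sample, each read is `flank5 + barcode + flank3`. Controlled mode emits
#' error-free reads at constant Q40. Empirical mode applies i.i.d. per-base
#' substitutions at `error_rate` across the whole read (flanks included) and
#' writes constant Q37 quality strings; read counts still match the assigned
#' abundances exactly, and the ground truth records the intended barcode
#' counts. The true barcodes are additionally written as FASTA so an external
#' read simulator can be substituted for the internal error model.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @return list with `fastq` (named per-sample paths), `truth` (ground-truth CSV
#'   path), `fasta` (true-barcode FASTA), `barcodes`, `truth_table`, `config`.
#' @export
synthesize_reads <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(config$seed)
  bcs <- generate_barcodes(config$n_barcodes, config$barcode_length,
                           config$min_hamming)
  fa <- Biostrings::DNAStringSet(bcs)
  names(fa) <- sprintf("barcode_%04d", seq_along(bcs))
  fasta_path <- file.path(out_dir, "true_barcodes.fasta")
  Biostrings::writeXStringSet(fa, fasta_path)

  chim <- generate_chimeras(bcs, config$chimeras_per_barcode)
  truth <- list()
  fastq_paths <- character(config$n_samples)
  qual_char <- if (config$mode == "controlled") "I" else "F"  # Q40 / Q37
  read_len <- nchar(config$flank5) + config$barcode_length + nchar(config$flank3)

  for (s in seq_len(config$n_samples)) {
    sample_id <- sprintf("sample_%d", s)
    counts <- assign_abundances(bcs, config$distribution, config$total_reads,
                                mean = config$mean, sd = config$sd,
                                exponent = config$exponent)
    truth_s <- data.table::data.table(sample_id = sample_id, barcode = bcs,
                                      true_count = as.integer(counts),
                                      is_chimera = FALSE)
    if (nrow(chim)) {
      chim_counts <- as.integer(floor(config$chimera_relative_abundance *
                                        counts[chim$parent]))
      truth_s <- rbind(truth_s,
                       data.table::data.table(sample_id = sample_id,
                                              barcode = chim$chimera,
                                              true_count = chim_counts,
                                              is_chimera = TRUE))
    }
    emit <- truth_s[true_count > 0]
    seqs <- paste0(config$flank5, rep(emit$barcode, emit$true_count), config$flank3)
    if (config$mode == "empirical" && config$error_rate > 0)
      seqs <- inject_substitutions(seqs, read_len, config$error_rate)
    ids <- sprintf("%s_read_%07d", sample_id, seq_along(seqs))
    stream <- data.table::data.table(
      read_id = ids, sequence = seqs,
      quality = strrep(qual_char, read_len),
      sample_id = sample_id, cell_barcode = NA_character_, umi = NA_character_,
      mate = NA_integer_)
    fq <- file.path(out_dir, paste0(sample_id, if (config$gzip) ".fastq.gz" else ".fastq"))
    write_fastq(stream, fq)
    fastq_paths[s] <- fq
    names(fastq_paths)[s] <- sample_id
    truth[[s]] <- truth_s
  }
  truth_table <- data.table::rbindlist(truth)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  data.table::fwrite(truth_table, truth_path)
  log_stage("simulate", "%d samples, %d true barcodes, %d reads/sample written to %s",
            config$n_samples, config$n_barcodes,
            sum(truth_table$true_count) / config$n_samples, out_dir)
  list(fastq = fastq_paths, truth = truth_path, fasta = fasta_path,
       barcodes = bcs, truth_table = truth_table, config = config)
}

# i.i.d. per-base substitutions over equal-length reads. The number of errors is
# binomial over all bases; each hit position is replaced by a different base.
inject_substitutions <- function(seqs, read_len, error_rate) {
  n_total <- length(seqs) * read_len
  n_err <- rbinom(1L, n_total, error_rate)
  if (n_err == 0L) return(seqs)
  idx <- sample.int(n_total, n_err)
  read_i <- (idx - 1L) %/% read_len + 1L
  pos <- (idx - 1L) %% read_len + 1L
  for (k in seq_len(n_err)) {
    i <- read_i[k]; p <- pos[k]
    cur <- substr(seqs[i], p, p)
    repl <- sample(setdiff(DNA_BASES, cur), 1L)
    substr(seqs[i], p, p) <- repl
  }
  seqs
}
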