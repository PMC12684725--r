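# Sequencing input/output: FASTQ and BAM readers producing a uniform read stream,
# plus whitelist and reference loaders. A read stream is a data.table with columns
# read_id, sequence, quality (PHRED+33 string), sample_id, cell_barcode, umi, mate.

#' Read single- or paired-end FASTQ into a uniform read stream
#'
#' Gzip compression is detected automatically. Sequences are uppercased; qualities
#' are kept as PHRED+33 strings. For paired files both mates are emitted, flagged
#' in the `mate` column; the files must contain the same number of records in
#' matching order.
#'
#' @param paths one (single-end) or two (paired-end) FASTQ paths.
#' @param sample_id sample identifier attached to every read.
#' @return a `data.table` read stream (possibly zero rows for an empty file).
#' @export
read_fastq <- function(paths, sample_id) {
  stopifnot(length(paths) %in% c(1L, 2L), is.character(sample_id), length(sample_id) == 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("FASTQ file not found: ", paste(missing, collapse = ", "), call. = FALSE)
  streams <- lapply(seq_along(paths), function(i) {
    s <- read_fastq_one(paths[i], sample_id)
    if (length(paths) == 2L) s$mate <- rep(as.integer(i), nrow(s))
    s
  })
  if (length(streams) == 2L && nrow(streams[[1]]) != nrow(streams[[2]]))
    stop(sprintf("mate-pair record count mismatch: %d vs %d records (%s, %s)",
                 nrow(streams[[1]]), nrow(streams[[2]]), paths[1], paths[2]),
         call. = FALSE)
  data.table::rbindlist(streams)
}

read_fastq_one <- function(path, sample_id) {
  malformed <- function(e) {
    idx <- diagnose_fastq(path)
    if (!is.na(idx))
      stop(sprintf("malformed FASTQ record %d in %s: %s", idx, path,
                   conditionMessage(e)), call. = FALSE)
    stop(sprintf("failed to read FASTQ %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  }
  fq <- tryCatch(
    quiet_mcols(Biostrings::readQualityScaledDNAStringSet(path,
                                                          quality.scoring = "phred")),
    error = malformed)
  if (length(fq) == 0) return(empty_read_stream())
  # a quality string shorter/longer than its sequence may only surface here
  quals <- tryCatch({
    q <- as.character(Biostrings::quality(fq))
    bad <- which(Biostrings::width(fq) != nchar(q))
    if (length(bad))
      stop(sprintf("sequence/quality length mismatch at record %d", bad[1]))
    q
  }, error = malformed)
  seqs <- toupper(quiet_mcols(as.character(fq)))
  ids <- sub("\\s.*$", "", names(fq))
  data.table::data.table(
    read_id = ids, sequence = seqs, quality = quals,
    sample_id = sample_id, cell_barcode = NA_character_, umi = NA_character_,
    mate = NA_integer_)
}

# Locate the first structurally broken 4-line record (for error reporting only).
diagnose_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- tryCatch(readLines(con, warn = FALSE), error = function(e) character(0))
  n <- length(lines)
  nrec <- n %/% 4L
  if (n %% 4L != 0L) return(nrec + 1L)
  for (i in seq_len(nrec)) {
    blk <- lines[(4L * (i - 1L) + 1L):(4L * i)]
    if (!startsWith(blk[1], "@") || !startsWith(blk[3], "+") ||
        nchar(blk[2]) != nchar(blk[4])) return(i)
  }
  NA_integer_
}

#' Write a read stream to FASTQ
#'
#' @param reads a read stream as returned by [read_fastq()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  compress <- grepl("\\.gz$", path)
  if (nrow(reads) == 0) {
    con <- if (compress) gzfile(path, "wb") else file(path, "wb")
    close(con)
    return(invisible(path))
  }
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$read_id
  x <- suppressWarnings(
    Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(reads$quality)))
  Biostrings::writeQualityScaledXStringSet(x, path, compress = compress)
  invisible(path)
}

#' Read a BAM file into a read stream
#'
#' Secondary and supplementary alignments are skipped so each physical read is
#' scanned exactly once. Cell and UMI annotations are pulled from BAM tags
#' (vendor convention: corrected tags CB/UB; set `cell_tag`/`umi_tag` to CR/UR
#' for raw ones). Reads lacking a requested tag get `NA` in that field and are
#' handled by downstream filters.
#'
#' @param path BAM file path.
#' @param contig_mode `"all"`, `"unmapped_only"`, or a character vector of contig
#'   names (requires a `.bai` index).
#' @param sample_id sample identifier attached to every read.
#' @param cell_tag,umi_tag 2-character SAM tag names for the cell barcode and UMI,
#'   or `NULL` to skip tag extraction.
#' @return a `data.table` read stream.
#' @export
read_bam <- function(path, contig_mode = "all", sample_id,
                     cell_tag = "CB", umi_tag = "UB") {
  if (!file.exists(path)) stop("BAM file not found: ", path, call. = FALSE)
  tags <- c(cell_tag, umi_tag)
  tags <- tags[!vapply(list(cell_tag, umi_tag), is.null, logical(1))]
  if (length(tags) && !all(nchar(tags) == 2L))
    stop("cell/UMI tag names must be 2-character SAM tags", call. = FALSE)
  what <- c("qname", "seq", "qual")
  base_flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE)
  if (identical(contig_mode, "all")) {
    param <- Rsamtools::ScanBamParam(what = what, tag = tags, flag = base_flag)
  } else if (identical(contig_mode, "unmapped_only")) {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = TRUE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(what = what, tag = tags, flag = flag)
  } else {
    contigs <- as.character(contig_mode)
    idx <- paste0(path, ".bai")
    if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", path)))
      stop("contig-restricted BAM access requires an index (.bai): ", path,
           call. = FALSE)
    targets <- Rsamtools::scanBamHeader(path)[[1]]$targets
    unknown <- setdiff(contigs, names(targets))
    if (length(unknown))
      stop(sprintf("unknown contig(s) %s; available: %s",
                   paste(unknown, collapse = ", "),
                   paste(names(targets), collapse = ", ")), call. = FALSE)
    which <- GenomicRanges::GRanges(contigs,
                                    IRanges::IRanges(1L, unname(targets[contigs])))
    param <- Rsamtools::ScanBamParam(what = what, tag = tags, flag = base_flag,
                                     which = which)
  }
  res <- Rsamtools::scanBam(path, param = param)
  chunks <- lapply(res, function(chunk) {
    n <- length(chunk$qname)
    if (n == 0) return(empty_read_stream())
    get_tag <- function(tg) {
      if (is.null(tg) || is.null(chunk$tag[[tg]])) rep(NA_character_, n)
      else as.character(chunk$tag[[tg]])
    }
    data.table::data.table(
      read_id = chunk$qname,
      sequence = toupper(as.character(chunk$seq)),
      quality = as.character(chunk$qual),
      sample_id = sample_id,
      cell_barcode = get_tag(cell_tag),
      umi = get_tag(umi_tag),
      mate = NA_integer_)
  })
  out <- data.table::rbindlist(chunks)
  # region queries return reads overlapping each range; dedupe defensively
  if (!identical(contig_mode, "all") && !identical(contig_mode, "unmapped_only"))
    out <- unique(out)
  out
}

#' Load a cell/spot whitelist
#'
#' Plain text, one barcode per line, optionally gzipped. Suffixes such as `-1`
#' are preserved verbatim; duplicates are removed.
#'
#' @param path whitelist file path.
#' @return character vector of unique barcodes.
#' @export
load_whitelist <- function(path) {
  if (!file.exists(path)) stop("whitelist file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- trimws(readLines(con, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stop("whitelist file is empty: ", path, call. = FALSE)
  unique(lines)
}

#' Load a reference barcode set (FASTA or CSV)
#'
#' CSV input must carry `name` and `sequence` columns. Sequences are uppercased
#' and validated against the ACGTN alphabet; duplicate names or duplicate
#' sequences are fatal. When one sequence is a substring of another, exact
#' (tolerance-0) matching cannot distinguish them on every read; a warning is
#' issued.
#'
#' @param path FASTA or CSV file.
#' @return a `data.table` with columns `name`, `sequence` (input order preserved).
#' @export
load_references <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L, warn = FALSE)
  close(con)
  is_fasta <- length(first) && startsWith(first, ">")
  if (is_fasta) {
    fa <- Biostrings::readDNAStringSet(path)
    refs <- data.table::data.table(name = sub("\\s.*$", "", names(fa)),
                                   sequence = toupper(as.character(fa)))
  } else {
    df <- data.table::fread(path, colClasses = "character")
    if (!all(c("name", "sequence") %in% names(df)))
      stop("reference CSV must have 'name' and 'sequence' columns", call. = FALSE)
    refs <- data.table::data.table(name = df$name, sequence = toupper(df$sequence))
  }
  assert_dna(refs$sequence, what = "reference sequence")
  if (anyDuplicated(refs$name))
    stop("duplicate reference names: ",
         paste(unique(refs$name[duplicated(refs$name)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(refs$sequence))
    stop("duplicate reference sequences (names: ",
         paste(refs$name[refs$sequence %in% refs$sequence[duplicated(refs$sequence)]],
               collapse = ", "), ")", call. = FALSE)
  if (has_substring_pair(refs$sequence))
    warning("some reference sequences are substrings of others; ",
            "exact matching will report the containing read as ambiguous",
            call. = FALSE)
  refs
}

has_substring_pair <- function(seqs) {
  if (length(seqs) < 2) return(FALSE)
  ord <- order(nchar(seqs))
  s <- seqs[ord]
  for (i in seq_len(length(s) - 1)) {
    hit <- grepl(s[i], s[(i + 1):length(s)], fixed = TRUE)
    if (any(hit)) return(TRUE)
  }
  FALSE
}
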