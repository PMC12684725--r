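`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert PHRED+33 quality strings to integer scores
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors, one per string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

scores_to_phred <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad))
    stop(sprintf("%s contains non-%s characters (first offender: '%s')",
                 what, if (allow_n) "ACGTN" else "ACGT", x[which(bad)[1]]),
         call. = FALSE)
  invisible(x)
}

# Minimal run log: timestamped stage messages with in/out counts and drop reasons.
log_stage <- function(stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

# Attach (or merge) a named integer vector of drop counts to an object.
set_drop_log <- function(x, drops) {
  attr(x, "drop_log") <- drops
  x
}

#' Retrieve the drop log attached to a filtered/extracted object
#'
#' Several pipeline steps count the reads they discard, by reason. The counts
#' travel with the returned object as an attribute.
#'
#' @param x an object returned by [filter_reads()] or [extract_tags()].
#' @return named integer vector of drop counts (possibly empty).
#' @export
drop_log <- function(x) {
  attr(x, "drop_log") %||% integer(0)
}

# Muffle Biostrings' harmless "metadata columns ... dropped" notice.
quiet_mcols <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w), fixed = TRUE))
      invokeRestart("muffleWarning")
  })
}

empty_read_stream <- function() {
  data.table::data.table(
    read_id = character(0), sequence = character(0), quality = character(0),
    sample_id = character(0), cell_barcode = character(0), umi = character(0),
    mate = integer(0))
}

empty_observations <- function() {
  data.table::data.table(
    barcode = character(0), sample_id = character(0),
    cell_barcode = character(0), umi = character(0), read_count = integer(0))
}
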