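# Read filtering, UMI dominant-barcode collapsing and count-based pre-filtering.

#' Quality-control parameters
#'
#' A read passes QC when at least `min_fraction` of its bases have a PHRED score
#' greater than or equal to `phred_threshold` (bases exactly at the threshold
#' count as passing).
#'
#' @param phred_threshold integer PHRED score, >= 0.
#' @param min_fraction fraction of bases in \[0, 1\] that must meet the threshold.
#' @return a validated list of class `qc_params`.
#' @export
qc_params <- function(phred_threshold = 20L, min_fraction = 0.75) {
  stopifnot(length(phred_threshold) == 1L, phred_threshold >= 0,
            length(min_fraction) == 1L, min_fraction >= 0, min_fraction <= 1)
  structure(list(phred_threshold = as.integer(phred_threshold),
                 min_fraction = as.numeric(min_fraction)),
            class = "qc_params")
}

#' Does a read pass the quality filter?
#'
#' @param qualities either a numeric vector of PHRED scores for one read, or a
#'   character vector of PHRED+33 quality strings (vectorized over reads).
#' @param params a [qc_params()] object.
#' @return logical (scalar for a score vector, vectorized for quality strings).
#' @export
passes_quality <- function(qualities, params) {
  stopifnot(inherits(params, "qc_params"))
  if (is.character(qualities)) {
    return(qc_pass_cpp(qualities, params$phred_threshold, params$min_fraction))
  }
  if (length(qualities) == 0) stop("qualities must be non-empty", call. = FALSE)
  mean(qualities >= params$phred_threshold) >= params$min_fraction
}

#' Filter a read stream by base quality and cell whitelist
#'
#' Emits, in input order, exactly the reads that pass QC and (when a whitelist is
#' supplied) carry a whitelisted cell barcode. Reads without a cell barcode are
#' dropped when a whitelist is given. Counts of dropped reads by reason are
#' attached as the drop log and reported via the run log.
#'
#' @param reads a read stream.
#' @param params a [qc_params()] object.
#' @param whitelist optional character vector from [load_whitelist()].
#' @return the filtered read stream with a [drop_log()] attribute.
#' @export
filter_reads <- function(reads, params, whitelist = NULL) {
  if (nrow(reads) == 0) return(set_drop_log(reads, c(fail_qc = 0L, not_whitelisted = 0L)))
  keep_qc <- passes_quality(reads$quality, params)
  keep_wl <- if (is.null(whitelist)) rep(TRUE, nrow(reads))
             else !is.na(reads$cell_barcode) & reads$cell_barcode %in% whitelist
  drops <- c(fail_qc = sum(!keep_qc),
             not_whitelisted = sum(keep_qc & !keep_wl))
  out <- reads[keep_qc & keep_wl]
  log_stage("filter_reads", "%d in, %d out (fail_qc=%d, not_whitelisted=%d)",
            nrow(reads), nrow(out), drops[["fail_qc"]], drops[["not_whitelisted"]])
  set_drop_log(out, drops)
}

#' Collapse UMIs to their dominant barcode
#'
#' Within each (sample, cell, UMI) group the barcode with the highest summed read
#' support is retained as the single molecule for that UMI (ties broken towards
#' the lexicographically smallest barcode) and its `read_count` is set to 1.
#' The raw read support of the winning barcode is kept in a `reads_supporting`
#' column for diagnostics. Observations without a UMI pass through unchanged.
#'
#' @param observations a tag observation `data.table` (columns `barcode`,
#'   `sample_id`, `cell_barcode`, `umi`, `read_count`).
#' @return collapsed observations, one row per (sample, cell, UMI).
#' @export
collapse_umis <- function(observations) {
  if (nrow(observations) == 0) return(data.table::copy(observations))
  obs <- data.table::as.data.table(observations)
  no_umi <- obs[is.na(umi)]
  with_umi <- obs[!is.na(umi)]
  if (nrow(with_umi) == 0) return(obs)
  grp <- with_umi[, .(read_count = sum(read_count)),
                  by = .(sample_id, cell_barcode, umi, barcode)]
  data.table::setorder(grp, sample_id, cell_barcode, umi, -read_count, barcode)
  winner <- grp[, .SD[1L], by = .(sample_id, cell_barcode, umi)]
  winner[, `:=`(reads_supporting = read_count, read_count = 1L)]
  out <- data.table::rbindlist(list(
    winner[, .(barcode, sample_id, cell_barcode, umi, read_count, reads_supporting)],
    if (nrow(no_umi)) no_umi[, .(barcode, sample_id, cell_barcode, umi, read_count,
                                 reads_supporting = read_count)]),
    use.names = TRUE)
  out[]
}

#' Pre-filtering parameters
#'
#' @param min_umi_barcode_count optional positive integer; (cell, UMI, barcode)
#'   combinations with lower read support are dropped (applied before UMI
#'   collapsing).
#' @param min_relative_abundance optional fraction in \[0, 1\]; barcodes whose
#'   total count over the entire dataset falls below this fraction of the grand
#'   total are dropped.
#' @param stage when the relative-abundance rule runs relative to error
#'   correction; `"before_correction"` (default) or `"after_correction"`.
#' @return a validated list of class `prefilter_params`.
#' @export
prefilter_params <- function(min_umi_barcode_count = NULL,
                             min_relative_abundance = NULL,
                             stage = c("before_correction", "after_correction")) {
  if (!is.null(min_umi_barcode_count))
    stopifnot(min_umi_barcode_count >= 1)
  if (!is.null(min_relative_abundance))
    stopifnot(min_relative_abundance >= 0, min_relative_abundance <= 1)
  structure(list(min_umi_barcode_count = min_umi_barcode_count,
                 min_relative_abundance = min_relative_abundance,
                 stage = match.arg(stage)),
            class = "prefilter_params")
}

#' Count-based pre-filtering of tag observations
#'
#' Two optional, independent rules: (a) drop (cell, UMI, barcode) combinations
#' whose read support is below `min_umi_barcode_count`; (b) drop barcodes whose
#' total count across the entire pooled dataset, divided by the grand total, is
#' below `min_relative_abundance`. With both parameters absent the input is
#' returned unchanged. The operation is idempotent.
#'
#' @param observations a tag observation `data.table`.
#' @param params a [prefilter_params()] object.
#' @param apply_relative whether to apply the relative-abundance rule in this
#'   call (the pipeline may defer it until after error correction).
#' @return filtered observations.
#' @export
prefilter <- function(observations, params, apply_relative = TRUE) {
  stopifnot(inherits(params, "prefilter_params"))
  obs <- data.table::as.data.table(observations)
  if (nrow(obs) == 0) return(obs)
  if (!is.null(params$min_umi_barcode_count)) {
    support <- obs[, .(combo_support = sum(read_count)),
                   by = .(sample_id, cell_barcode, umi, barcode)]
    obs <- merge(obs, support, by = c("sample_id", "cell_barcode", "umi", "barcode"),
                 sort = FALSE)
    obs <- obs[combo_support >= params$min_umi_barcode_count]
    obs[, combo_support := NULL]
  }
  if (apply_relative && !is.null(params$min_relative_abundance)) {
    totals <- obs[, .(total = sum(read_count)), by = barcode]
    grand <- sum(totals$total)
    keep <- totals$barcode[totals$total / grand >= params$min_relative_abundance]
    obs <- obs[barcode %in% keep]
  }
  obs[]
}
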