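# YAML-driven entry points: validated run configuration, extraction pipeline
# orchestration, and simulation driver. The exec/tagtrace script wraps these as
# `extract --config run.yaml` and `simulate --config sim.yaml`.

extract_schema <- list(
  mode = c("reference_based", "reference_free"),
  input = list(
    fastq = NULL,  # map sample_id -> one or two paths
    bam = list(path = NULL, contig_mode = NULL, cell_tag = NULL, umi_tag = NULL,
               sample_id = NULL)),
  whitelist = NULL,
  qc = list(phred_threshold = NULL, min_fraction = NULL),
  tolerance = NULL,
  pattern = list(flank5 = NULL, flank3 = NULL, mask = NULL,
                 min_length = NULL, max_length = NULL),
  reference = NULL,
  correction = list(distance_threshold = NULL, metric = NULL, ratio = NULL),
  prefilter = list(min_umi_barcode_count = NULL, min_relative_abundance = NULL,
                   stage = NULL),
  modality = c("bulk", "single_cell", "spatial"),
  scan_mate = c("both", "1", "2"),
  reverse_complement = NULL,
  output_dir = NULL,
  threads = NULL,
  seed = NULL)

simulate_schema <- list(
  n_barcodes = NULL, barcode_length = NULL, min_hamming = NULL,
  flank5 = NULL, flank3 = NULL,
  distribution = list(type = NULL, mean = NULL, sd = NULL, exponent = NULL),
  reads_per_barcode = NULL, total_reads = NULL,
  chimeras_per_barcode = NULL, chimera_relative_abundance = NULL,
  mode = c("empirical", "controlled"), error_rate = NULL,
  n_samples = NULL, seed = NULL, gzip = NULL, output_dir = NULL)

# Recursive unknown-key check against a schema skeleton (catches typos).
check_keys <- function(cfg, schema, path = "") {
  if (!is.list(cfg)) return(invisible())
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop(sprintf("unknown configuration key '%s%s'", path, unknown[1]), call. = FALSE)
  for (k in names(cfg)) {
    # 'fastq' maps arbitrary sample ids; skip its children
    if (k == "fastq") next
    if (is.list(schema[[k]]) && is.list(cfg[[k]]))
      check_keys(cfg[[k]], schema[[k]], paste0(path, k, "."))
  }
  invisible()
}

require_key <- function(cfg, key) {
  if (is.null(cfg[[key]]))
    stop(sprintf("missing required configuration key '%s'", key), call. = FALSE)
  cfg[[key]]
}

#' Parse and validate a YAML run configuration
#'
#' Fills defaults (tolerance 0, correction threshold 0, QC Q20 at 75% of bases),
#' rejects unknown keys with the offending key path, and enforces mode/spec
#' consistency (a reference path for reference-based runs, a pattern with at
#' least one flank for reference-free runs; exactly one of `input.fastq` /
#' `input.bam`). The resolved configuration is echoed to the run log.
#'
#' @param path YAML file.
#' @param kind `"extract"` or `"simulate"`.
#' @return a validated configuration list of class `run_config` (extract) or a
#'   [simulation_config()] (simulate).
#' @export
parse_config <- function(path, kind = c("extract", "simulate")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (kind == "simulate") {
    check_keys(cfg, simulate_schema)
    dist <- cfg$distribution %||% list()
    sim <- simulation_config(
      n_barcodes = cfg$n_barcodes %||% 500L,
      barcode_length = cfg$barcode_length %||% 60L,
      min_hamming = cfg$min_hamming %||% 6L,
      flank5 = cfg$flank5 %||% DEFAULT_FLANK5,
      flank3 = cfg$flank3 %||% DEFAULT_FLANK3,
      distribution = dist$type %||% "uniform",
      mean = dist$mean %||% 100, sd = dist$sd %||% 20,
      exponent = dist$exponent %||% 1,
      reads_per_barcode = cfg$reads_per_barcode %||% 200L,
      total_reads = cfg$total_reads,
      chimeras_per_barcode = cfg$chimeras_per_barcode %||% 0L,
      chimera_relative_abundance = cfg$chimera_relative_abundance %||% 0.1,
      mode = cfg$mode %||% "empirical",
      error_rate = cfg$error_rate %||% 0.001,
      n_samples = cfg$n_samples %||% 4L,
      seed = cfg$seed %||% 1L,
      gzip = cfg$gzip %||% FALSE)
    attr(sim, "output_dir") <- cfg$output_dir %||% "."
    return(sim)
  }
  check_keys(cfg, extract_schema)
  mode <- match.arg(require_key(cfg, "mode"), c("reference_based", "reference_free"))
  input <- require_key(cfg, "input")
  has_fastq <- !is.null(input$fastq)
  has_bam <- !is.null(input$bam)
  if (has_fastq == has_bam)
    stop("exactly one of input.fastq / input.bam must be given", call. = FALSE)
  if (mode == "reference_based" && is.null(cfg$reference))
    stop("reference_based mode requires 'reference'", call. = FALSE)
  if (mode == "reference_free" && is.null(cfg$pattern))
    stop("reference_free mode requires 'pattern'", call. = FALSE)
  qc <- cfg$qc %||% list()
  corr <- cfg$correction %||% list()
  pf <- cfg$prefilter %||% list()
  out <- list(
    mode = mode,
    input = input,
    whitelist = cfg$whitelist,
    qc = qc_params(qc$phred_threshold %||% 20L, qc$min_fraction %||% 0.75),
    tolerance = as.integer(cfg$tolerance %||% 0L),
    pattern = if (mode == "reference_free")
      barcode_pattern(cfg$pattern$flank5, cfg$pattern$flank3, cfg$pattern$mask,
                      cfg$pattern$min_length, cfg$pattern$max_length),
    reference = cfg$reference,
    correction = correction_params(corr$distance_threshold %||% 0L,
                                   corr$metric %||% "auto", corr$ratio),
    prefilter = prefilter_params(pf$min_umi_barcode_count,
                                 pf$min_relative_abundance,
                                 pf$stage %||% "before_correction"),
    modality = match.arg(cfg$modality %||% "bulk", c("bulk", "single_cell", "spatial")),
    scan_mate = as.character(cfg$scan_mate %||% "both"),
    reverse_complement = isTRUE(cfg$reverse_complement),
    output_dir = cfg$output_dir %||% ".",
    threads = as.integer(cfg$threads %||% 1L),
    seed = as.integer(cfg$seed %||% 1L))
  class(out) <- "run_config"
  log_stage("parse_config", "mode=%s modality=%s tolerance=%d K=%d input=%s",
            out$mode, out$modality, out$tolerance,
            out$correction$distance_threshold,
            if (has_fastq) "fastq" else "bam")
  out
}

load_config_reads <- function(config) {
  if (!is.null(config$input$fastq)) {
    streams <- lapply(names(config$input$fastq), function(sid) {
      read_fastq(unlist(config$input$fastq[[sid]]), sample_id = sid)
    })
    reads <- data.table::rbindlist(streams)
    if (config$scan_mate %in% c("1", "2") && nrow(reads))
      reads <- reads[is.na(mate) | mate == as.integer(config$scan_mate)]
    reads
  } else {
    b <- config$input$bam
    read_bam(require_key(b, "path"),
             contig_mode = b$contig_mode %||% "all",
             sample_id = b$sample_id %||% "sample_1",
             cell_tag = b$cell_tag %||% "CB",
             umi_tag = b$umi_tag %||% "UB")
  }
}

#' Run the extraction pipeline from a validated configuration
#'
#' Orchestrates input -> QC/whitelist filtering -> extraction -> (absolute
#' prefilter, UMI collapsing) -> error correction -> relative-abundance
#' prefilter (at its configured stage) -> count matrix, and writes CSV + H5AD
#' outputs plus the correction summary.
#'
#' @param config a `run_config` from [parse_config()] (or an equivalent list).
#' @param write whether to write output files (default TRUE).
#' @return invisibly, a list with `matrix`, `correction`, `observations`,
#'   `files`.
#' @export
run_extract <- function(config, write = TRUE) {
  set.seed(config$seed)
  reads <- load_config_reads(config)
  whitelist <- if (!is.null(config$whitelist)) load_whitelist(config$whitelist)
  reads <- filter_reads(reads, config$qc, whitelist)
  spec <- if (config$mode == "reference_based") load_references(config$reference)
          else config$pattern
  obs <- extract_tags(reads, config$mode, spec, config$tolerance,
                      scan_revcomp = config$reverse_complement)
  obs <- prefilter(obs, config$prefilter, apply_relative = FALSE)
  if (any(!is.na(obs$umi))) obs <- collapse_umis(obs)
  pre_stage <- config$prefilter$stage == "before_correction"
  if (pre_stage) obs <- prefilter(obs, config$prefilter, apply_relative = TRUE)
  tal <- tally_observations(obs)
  correction <- correct_barcodes(tal, config$correction)
  # propagate cluster roots to per-cell observations, then the deferred filter
  if (nrow(obs)) obs[, barcode := correction$assignment[barcode]]
  if (!pre_stage) {
    obs <- prefilter(obs, config$prefilter, apply_relative = TRUE)
    keep <- unique(obs$barcode)
    correction$tallies <- correction$tallies[barcode %in% keep]
  }
  mat <- build_count_matrix(if (config$modality == "bulk") correction$tallies else obs,
                            config$modality,
                            params = list(mode = config$mode,
                                          tolerance = config$tolerance,
                                          distance_threshold =
                                            config$correction$distance_threshold,
                                          seed = config$seed))
  files <- character(0)
  if (write) {
    files <- write_outputs(mat, config$output_dir)
    write_correction_summary(correction,
                             file.path(config$output_dir, "correction"))
  }
  log_stage("run_extract", "done: %d row(s) x %d barcode(s)",
            nrow(mat$counts), ncol(mat$counts))
  invisible(list(matrix = mat, correction = correction, observations = obs,
                 files = files))
}

#' Run the simulation workflow from a validated configuration
#'
#' @param config a [simulation_config()], e.g. from
#'   `parse_config(path, "simulate")`.
#' @param out_dir output directory (defaults to the config's `output_dir`).
#' @return invisibly, the [synthesize_reads()] result.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  out_dir <- out_dir %||% attr(config, "output_dir") %||% "."
  invisible(synthesize_reads(config, out_dir))
}
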