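# Count-matrix construction, clone assignment from combinatorial tag sets, and
# CSV/H5AD output.

#' Build a count matrix from corrected tag observations
#'
#' Bulk modality: counts summed per (sample, barcode), one row per sample.
#' Single-cell/spatial: one row per (sample, cell/spot), one retained molecule
#' (or read, when no UMI was present) per count.
#'
#' @param observations corrected tag observations (or per-sample tallies with a
#'   `count` column for bulk data).
#' @param modality `"bulk"`, `"single_cell"`, or `"spatial"`.
#' @param params optional named list of run parameters stored with the matrix.
#' @return an object of class `tag_count_matrix`: list with `counts` (integer
#'   matrix, rows = samples or sample/cell pairs, columns = barcodes),
#'   `row_info` (`data.table` describing rows), `modality`, `params`.
#' @export
build_count_matrix <- function(observations,
                               modality = c("bulk", "single_cell", "spatial"),
                               params = list()) {
  modality <- match.arg(modality)
  obs <- data.table::as.data.table(observations)
  if (!"count" %in% names(obs) && "read_count" %in% names(obs))
    data.table::setnames(obs, "read_count", "count")
  if (nrow(obs) == 0) {
    warning("no observations: returning an empty count matrix", call. = FALSE)
    return(structure(list(counts = matrix(0L, 0, 0),
                          row_info = data.table::data.table(sample_id = character(0)),
                          modality = modality, params = params),
                     class = "tag_count_matrix"))
  }
  if (modality == "bulk") {
    agg <- obs[, .(count = sum(count)), by = .(sample_id, barcode)]
    wide <- data.table::dcast(agg, sample_id ~ barcode, value.var = "count", fill = 0L)
    row_info <- wide[, .(sample_id)]
    counts <- as.matrix(wide[, -1, drop = FALSE])
    rownames(counts) <- row_info$sample_id
  } else {
    if (all(is.na(obs$cell_barcode)))
      stop(sprintf("%s modality requires cell/spot barcodes, but none are present",
                   modality), call. = FALSE)
    obs <- obs[!is.na(cell_barcode)]
    agg <- obs[, .(count = sum(count)), by = .(sample_id, cell_barcode, barcode)]
    wide <- data.table::dcast(agg, sample_id + cell_barcode ~ barcode,
                              value.var = "count", fill = 0L)
    row_info <- wide[, .(sample_id, cell_barcode)]
    counts <- as.matrix(wide[, -(1:2), drop = FALSE])
    rownames(counts) <- paste(row_info$sample_id, row_info$cell_barcode, sep = ",")
  }
  storage.mode(counts) <- "integer"
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  structure(list(counts = counts, row_info = row_info, modality = modality,
                 params = params),
            class = "tag_count_matrix")
}

#' @export
print.tag_count_matrix <- function(x, ...) {
  cat(sprintf("<tag_count_matrix> %s: %d row(s) x %d barcode(s), %d total counts\n",
              x$modality, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Assign cells to clones by combinatorial tag similarity
#'
#' Per matrix row, the detected tag set D contains the barcodes with count at or
#' above `presence_threshold`. Similarity with each clone's expected tag set E
#' is Jaccard, `|D n E| / |D u E|` (or `|D n E| / |E|` with
#' `method = "overlap"`). The best-scoring clone is assigned iff its similarity
#' reaches `min_similarity`; ties between clones leave the cell unassigned.
#' Only presence/absence matters, never count magnitudes.
#'
#' @param cell_matrix a `tag_count_matrix` (single-cell or spatial).
#' @param clones named list: clone id -> character vector of expected tag names.
#' @param min_similarity assignment cutoff (default 0.75).
#' @param method `"jaccard"` (default) or `"overlap"` (over the expected set).
#' @param presence_threshold minimum count for a tag to be called present.
#' @return a `data.table` with one row per matrix row: row label, `clone_id`
#'   (`"unassigned"` when no clone qualifies) and `similarity` of the best match.
#' @export
assign_clones <- function(cell_matrix, clones, min_similarity = 0.75,
                          method = c("jaccard", "overlap"),
                          presence_threshold = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(cell_matrix, "tag_count_matrix"))
  if (length(clones) == 0) stop("empty clone list", call. = FALSE)
  if (is.null(names(clones)) || any(!nzchar(names(clones))) ||
      anyDuplicated(names(clones)))
    stop("clones must be a uniquely named list of tag sets", call. = FALSE)
  if (any(lengths(clones) == 0)) stop("every clone needs at least one tag", call. = FALSE)
  counts <- cell_matrix$counts
  known <- unique(unlist(clones))
  extra <- setdiff(colnames(counts), known)
  if (length(extra))
    warning("matrix columns not present in any clone definition are ignored: ",
            paste(head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "", call. = FALSE)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    D <- colnames(counts)[counts[i, ] >= presence_threshold]
    sims <- vapply(clones, function(E) {
      inter <- length(intersect(D, E))
      denom <- if (method == "jaccard") length(union(D, E)) else length(E)
      if (denom == 0) 0 else inter / denom
    }, numeric(1))
    best <- max(sims)
    winners <- names(sims)[sims == best]
    assigned <- length(winners) == 1L && best >= min_similarity
    list(clone_id = if (assigned) winners else "unassigned", similarity = best)
  })
  data.table::data.table(
    cell = rownames(counts),
    clone_id = vapply(res, `[[`, character(1), "clone_id"),
    similarity = vapply(res, `[[`, numeric(1), "similarity"))
}

#' Write a count matrix to CSV and H5AD
#'
#' The CSV carries the row labels in the leading column(s) and one column per
#' barcode. The H5AD file follows the AnnData convention (observations = rows,
#' variables = barcodes, run parameters in `uns`; the sample id is stored as a
#' per-observation annotation) and is produced through the system's `python`
#' with the `anndata` package; both files contain identical counts.
#'
#' @param matrix a `tag_count_matrix`.
#' @param out_dir output directory (created if needed).
#' @param basename file name stem (default `"counts"`).
#' @param formats subset of `c("csv", "h5ad")`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(matrix, out_dir, basename = "counts",
                          formats = c("csv", "h5ad")) {
  stopifnot(inherits(matrix, "tag_count_matrix"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  out <- character(0)
  csv_path <- file.path(out_dir, paste0(basename, ".csv"))
  df <- cbind(matrix$row_info, data.table::as.data.table(matrix$counts))
  if ("csv" %in% formats) {
    data.table::fwrite(df, csv_path)
    out["csv"] <- csv_path
  }
  if ("h5ad" %in% formats) {
    h5_path <- file.path(out_dir, paste0(basename, ".h5ad"))
    tmp_csv <- if ("csv" %in% formats) csv_path else {
      t <- tempfile(fileext = ".csv"); data.table::fwrite(df, t); t
    }
    write_h5ad_via_python(tmp_csv, h5_path, matrix)
    out["h5ad"] <- h5_path
  }
  invisible(out)
}

n_label_cols <- function(matrix) if (matrix$modality == "bulk") 1L else 2L

write_h5ad_via_python <- function(csv_path, h5_path, matrix) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stop("H5AD export requires a python interpreter with the anndata package ",
         "on the PATH; CSV output is unaffected", call. = FALSE)
  script <- system.file("python", "h5ad_io.py", package = "tagtrace")
  meta <- tempfile(fileext = ".json")
  jsonlite::write_json(list(modality = matrix$modality,
                            params = matrix$params,
                            n_label_cols = n_label_cols(matrix)),
                       meta, auto_unbox = TRUE, null = "null")
  status <- system2(py, c(script, "write", shQuote(csv_path), shQuote(h5_path),
                          shQuote(meta)), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0)
    stop("H5AD export failed:\n", paste(status, collapse = "\n"), call. = FALSE)
  invisible(h5_path)
}

#' Read a counts CSV back into a `tag_count_matrix`
#'
#' @param path CSV written by [write_outputs()].
#' @param modality the modality it was written with.
#' @return a `tag_count_matrix`.
#' @export
read_counts_csv <- function(path, modality = c("bulk", "single_cell", "spatial")) {
  modality <- match.arg(modality)
  df <- data.table::fread(path)
  nlab <- if (modality == "bulk") 1L else 2L
  row_info <- df[, seq_len(nlab), with = FALSE]
  counts <- as.matrix(df[, -seq_len(nlab), with = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- if (nlab == 1L) row_info[[1]]
                      else paste(row_info[[1]], row_info[[2]], sep = ",")
  structure(list(counts = counts, row_info = row_info, modality = modality,
                 params = list()),
            class = "tag_count_matrix")
}

#' Read counts back from an H5AD file (via python/anndata)
#'
#' Used mainly to verify CSV/H5AD consistency.
#'
#' @param path H5AD file.
#' @return a `data.table` with the row annotations and barcode count columns.
#' @export
read_h5ad_counts <- function(path) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("reading H5AD requires python with anndata", call. = FALSE)
  script <- system.file("python", "h5ad_io.py", package = "tagtrace")
  tmp <- tempfile(fileext = ".csv")
  status <- system2(py, c(script, "read", shQuote(path), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0)
    stop("H5AD read failed:\n", paste(status, collapse = "\n"), call. = FALSE)
  data.table::fread(tmp)
}
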