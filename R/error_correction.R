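# Two-stage sequencing-error correction: n-gram fingerprint pre-clustering
# (pigeonhole principle) followed by count-ordered forest refinement, applied
# globally across the dataset with per-sample count correction.

#' Error-correction parameters
#'
#' @param distance_threshold K, the maximum distance at which a barcode may be
#'   merged into a higher-count one. `K = 0` disables correction.
#' @param metric `"auto"` (Hamming when all barcodes have equal length,
#'   Levenshtein otherwise), `"hamming"`, or `"levenshtein"`.
#' @param ratio optional barcode ratio >= 1: a barcode is merged into a root only
#'   if the root's global count is at least `ratio` times the barcode's.
#' @return a list of class `correction_params`.
#' @export
correction_params <- function(distance_threshold = 0L,
                              metric = c("auto", "hamming", "levenshtein"),
                              ratio = NULL) {
  stopifnot(distance_threshold >= 0)
  if (!is.null(ratio)) stopifnot(ratio >= 1)
  structure(list(distance_threshold = as.integer(distance_threshold),
                 metric = match.arg(metric), ratio = ratio),
            class = "correction_params")
}

#' Hamming distance between DNA strings
#'
#' Vectorized over pairs; arguments of length one are recycled. Unequal string
#' lengths are an error.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
hamming_distance <- function(a, b) hamming_cpp(a, b)

#' Levenshtein distance between strings
#'
#' Vectorized over pairs; arguments of length one are recycled.
#'
#' @param a,b character vectors.
#' @return integer vector of edit distances.
#' @export
levenshtein_distance <- function(a, b) levenshtein_cpp(a, b)

tag_distance <- function(a, b, metric) {
  switch(metric,
         hamming = hamming_cpp(a, b),
         levenshtein = levenshtein_cpp(a, b),
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Fingerprint length for a given barcode length and distance threshold
#'
#' To tolerate up to K mismatches a barcode is split into K + 1 disjoint
#' fingerprints of length `n = floor(L / (K + 1))`: K mismatches cannot touch
#' all K + 1 segments, so two barcodes within distance K always share one
#' fingerprint intact.
#'
#' @param L barcode length (must be at least K + 1).
#' @param K distance threshold.
#' @return integer fingerprint length, >= 1.
#' @export
fingerprint_length <- function(L, K) {
  stopifnot(L >= 1, K >= 0)
  if (L < K + 1)
    stop(sprintf("no valid fingerprint: barcode length %d < K + 1 = %d", L, K + 1),
         call. = FALSE)
  as.integer(L %/% (K + 1))
}

#' Split a barcode into its K + 1 fingerprints
#'
#' Non-overlapping substrings of length `n` at offsets `0, n, 2n, ..., K*n`;
#' trailing bases beyond `(K + 1) * n` are ignored.
#'
#' @param barcode DNA string (vectorized).
#' @param n fingerprint length from [fingerprint_length()].
#' @param K distance threshold.
#' @return for a single barcode, a character vector of K + 1 fingerprints; for a
#'   vector input, a matrix with K + 1 columns.
#' @export
fingerprints <- function(barcode, n, K) {
  starts <- (0:K) * n + 1L
  m <- vapply(starts, function(s) substr(barcode, s, s + n - 1L),
              character(length(barcode)))
  if (length(barcode) == 1L) as.character(m) else matrix(m, nrow = length(barcode))
}

#' Pre-cluster barcodes by shared fingerprints
#'
#' Partitions the barcodes into the connected components of the relation "share
#' at least one fingerprint" (transitive closure). For equal-length barcode sets
#' fingerprints are offset-tagged chunks (chunk index is part of the key); for
#' variable-length sets all sliding n-grams are used instead, with n computed
#' from the minimum length. By the pigeonhole principle two equal-length
#' barcodes within Hamming distance K are never separated.
#'
#' @param barcodes character vector of distinct barcodes.
#' @param K distance threshold.
#' @return a list of character vectors partitioning `barcodes` (singletons
#'   allowed).
#' @export
precluster <- function(barcodes, K) {
  nb <- length(barcodes)
  if (nb == 0) return(list())
  if (K == 0) return(as.list(barcodes))
  lens <- nchar(barcodes)
  fixed_len <- length(unique(lens)) == 1L
  if (fixed_len) {
    n <- fingerprint_length(lens[1], K)
    fp <- fingerprints(barcodes, n, K)           # nb x (K+1)
    keys <- paste0(rep(seq_len(K + 1L), each = nb), ":", as.vector(fp))
    item <- rep(seq_len(nb), times = K + 1L)
  } else {
    n <- fingerprint_length(min(lens), K)
    starts_max <- lens - n + 1L
    item <- rep(seq_len(nb), times = starts_max)
    pos <- unlist(lapply(starts_max, seq_len), use.names = FALSE)
    keys <- substr(barcodes[item], pos, pos + n - 1L)
  }
  comp <- union_by_key(nb, item, keys)
  unname(split(barcodes, comp))
}

# Union-find over items grouped by key: items sharing a key end up in one
# component. Returns a component id per item (ids renumbered by first member).
union_by_key <- function(nb, item, keys) {
  parent <- seq_len(nb)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(keys, method = "radix")
  k <- keys[ord]
  it <- item[ord]
  same <- which(k[-1] == k[-length(k)])
  for (j in same) {
    a <- find(it[j])
    b <- find(it[j + 1L])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(nb), find, integer(1))
  match(roots, unique(roots))
}

#' Refine one pre-cluster into a forest of single-level trees
#'
#' Barcodes are processed in descending global count order (ties broken
#' lexicographically). The first becomes a root. Each subsequent barcode is
#' compared against all existing roots: if its distance to the nearest root is
#' at most K — nearest-root ties broken by higher root count, then
#' lexicographically — and the ratio gate passes (no ratio set, or
#' `root_count >= ratio * barcode_count`), it is attached as a child of that
#' root; otherwise it starts a new root. Children never become attachment
#' targets.
#'
#' @param barcodes character vector (one pre-cluster).
#' @param counts global total counts aligned with `barcodes`.
#' @param params a [correction_params()] object.
#' @return a list with `assignment` (named character: barcode -> root) and
#'   `trees` (list of `list(root, children)`).
#' @export
forest_refine <- function(barcodes, counts, params) {
  stopifnot(inherits(params, "correction_params"), length(barcodes) == length(counts))
  K <- params$distance_threshold
  metric <- params$metric
  if (metric == "auto")
    metric <- if (length(unique(nchar(barcodes))) == 1L) "hamming" else "levenshtein"
  ord <- order(-counts, barcodes, method = "radix")
  bc <- barcodes[ord]
  ct <- counts[ord]
  nb <- length(bc)
  root_of <- character(nb)
  roots <- character(0)
  root_counts <- numeric(0)
  for (i in seq_len(nb)) {
    if (length(roots) == 0) {
      roots <- bc[i]; root_counts <- ct[i]; root_of[i] <- bc[i]
      next
    }
    d <- tag_distance(bc[i], roots, metric)
    eligible <- which(d <= K)
    if (length(eligible) == 0) {
      roots <- c(roots, bc[i]); root_counts <- c(root_counts, ct[i])
      root_of[i] <- bc[i]
      next
    }
    # nearest root; ties by higher count then lexicographic
    e <- eligible[order(d[eligible], -root_counts[eligible], roots[eligible],
                        method = "radix")]
    nearest <- e[1]
    gate <- is.null(params$ratio) || root_counts[nearest] >= params$ratio * ct[i]
    if (gate) {
      root_of[i] <- roots[nearest]
    } else {
      roots <- c(roots, bc[i]); root_counts <- c(root_counts, ct[i])
      root_of[i] <- bc[i]
    }
  }
  assignment <- stats::setNames(root_of, bc)
  trees <- lapply(roots, function(r) {
    list(root = r, children = setdiff(names(assignment)[assignment == r], r))
  })
  list(assignment = assignment, trees = trees)
}

#' Correct sequencing errors in barcode tallies
#'
#' Runs fingerprint pre-clustering over all distinct barcodes, then forest
#' refinement within every pre-cluster (pre-clusters are independent, so the
#' result does not depend on their processing order). Clustering uses global
#' (dataset-wide) counts; count correction is applied per sample: within each
#' tree, every sample's counts for the children are added to the root, and the
#' children disappear from the output. `K = 0` returns the input unchanged.
#'
#' @param tallies a `data.table`/data.frame with columns `barcode`, `sample_id`,
#'   `count` (one row per barcode x sample).
#' @param params a [correction_params()] object.
#' @return a list with `tallies` (corrected, same long format), `assignment`
#'   (named character: barcode -> root) and `trees`.
#' @export
correct_barcodes <- function(tallies, params) {
  stopifnot(inherits(params, "correction_params"))
  tl <- data.table::as.data.table(tallies)[, .(count = sum(count)),
                                           by = .(barcode, sample_id)]
  data.table::setorder(tl, barcode, sample_id)
  bcs <- sort(unique(tl$barcode))
  if (params$distance_threshold == 0L || length(bcs) <= 1L) {
    assignment <- stats::setNames(bcs, bcs)
    return(list(tallies = tl[],
                assignment = assignment,
                trees = lapply(bcs, function(b) list(root = b, children = character(0)))))
  }
  totals <- tl[, .(total = sum(count)), by = barcode]
  total_of <- stats::setNames(totals$total, totals$barcode)
  sets <- precluster(bcs, params$distance_threshold)
  refined <- lapply(sets, function(s) forest_refine(s, unname(total_of[s]), params))
  assignment <- unlist(lapply(refined, `[[`, "assignment"))
  trees <- do.call(c, lapply(refined, `[[`, "trees"))
  tl[, root := assignment[barcode]]
  corrected <- tl[, .(count = sum(count)), by = .(barcode = root, sample_id)]
  data.table::setorder(corrected, barcode, sample_id)
  list(tallies = corrected[], assignment = assignment, trees = trees)
}

#' Aggregate tag observations into per-sample barcode tallies
#'
#' @param observations a tag observation `data.table`.
#' @return a `data.table` with columns `barcode`, `sample_id`, `count`.
#' @export
tally_observations <- function(observations) {
  obs <- data.table::as.data.table(observations)
  if (nrow(obs) == 0)
    return(data.table::data.table(barcode = character(0), sample_id = character(0),
                                  count = integer(0)))
  obs[, .(count = sum(read_count)), by = .(barcode, sample_id)]
}

#' Write a correction summary to CSV
#'
#' Two files: `<prefix>_clusters.csv` (barcode, root) and
#' `<prefix>_counts.csv` (corrected per-sample tallies).
#'
#' @param correction result of [correct_barcodes()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_correction_summary <- function(correction, prefix) {
  f1 <- paste0(prefix, "_clusters.csv")
  f2 <- paste0(prefix, "_counts.csv")
  data.table::fwrite(data.table::data.table(barcode = names(correction$assignment),
                                            root = unname(correction$assignment)), f1)
  data.table::fwrite(correction$tallies, f2)
  invisible(c(f1, f2))
}
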