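# Locating the barcode within each read: reference-based matching against known
# sequences (exact multi-pattern search at tolerance 0, semi-global edit-tolerant
# alignment otherwise) and reference-free extraction from flanks/mask/length.

#' Reference-free barcode search specification
#'
#' Describes the structural context of a barcode: conserved flanking sequence on
#' the 5' and/or 3' side, an optional masked pattern over `{A,C,G,T,N}` (N marks
#' free positions), and an optional inclusive length interval. At least one
#' flank must be given.
#'
#' @param flank5,flank3 optional DNA strings (at least one required).
#' @param mask optional pattern over ACGTN constraining the barcode itself.
#' @param min_length,max_length optional inclusive length bounds.
#' @return a list of class `barcode_pattern`.
#' @export
barcode_pattern <- function(flank5 = NULL, flank3 = NULL, mask = NULL,
                            min_length = NULL, max_length = NULL) {
  if (is.null(flank5) && is.null(flank3))
    stop("at least one of flank5/flank3 must be provided", call. = FALSE)
  for (f in list(flank5, flank3)) if (!is.null(f)) assert_dna(toupper(f), "flank", allow_n = FALSE)
  if (!is.null(mask)) {
    mask <- toupper(mask)
    if (!grepl("^[ACGTN]+$", mask))
      stop("invalid mask characters (allowed: A,C,G,T,N)", call. = FALSE)
  }
  if (!is.null(min_length) && !is.null(max_length) && min_length > max_length)
    stop("min_length must be <= max_length", call. = FALSE)
  if (!is.null(mask)) {
    ml <- nchar(mask)
    if ((!is.null(min_length) && ml < min_length) ||
        (!is.null(max_length) && ml > max_length))
      stop("mask length outside the declared length range", call. = FALSE)
  }
  structure(list(flank5 = if (!is.null(flank5)) toupper(flank5),
                 flank3 = if (!is.null(flank3)) toupper(flank3),
                 mask = mask,
                 min_length = min_length, max_length = max_length),
            class = "barcode_pattern")
}

# ---------------------------------------------------------------------------
# Reference-based matching

# Per-read exact hits of every reference, as a list of reference indices.
exact_hit_list <- function(seqs, refs) {
  if (length(seqs) == 0) return(list())
  widths <- nchar(refs$sequence)
  subj <- Biostrings::DNAStringSet(seqs)
  if (length(unique(widths)) == 1L && !any(grepl("N", refs$sequence, fixed = TRUE))) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(refs$sequence))
    return(Biostrings::vwhichPDict(pd, subj))
  }
  # variable-width or N-containing references: per-reference scan
  hits <- vector("list", length(seqs))
  for (k in seq_len(nrow(refs))) {
    cnt <- Biostrings::vcountPattern(refs$sequence[k], subj, fixed = TRUE)
    idx <- which(cnt > 0)
    for (i in idx) hits[[i]] <- c(hits[[i]], k)
  }
  lapply(hits, function(h) h %||% integer(0))
}

# Pigeonhole candidate generation for tolerant matching: each reference is split
# into tol+1 disjoint constant-width chunks; <= tol edits leave at least one
# chunk intact, so it must occur exactly in the read.
tolerant_candidates <- function(seqs, refs, tol) {
  nref <- nrow(refs)
  all_cand <- function() rep(list(seq_len(nref)), length(seqs))
  if (any(grepl("N", refs$sequence, fixed = TRUE))) return(all_cand())
  n <- min(nchar(refs$sequence)) %/% (tol + 1L)
  if (n < 4L) return(all_cand())  # chunks too unspecific to prune
  starts <- (0:tol) * n + 1L
  chunk_seq <- unlist(lapply(starts, function(s) substr(refs$sequence, s, s + n - 1L)))
  chunk_ref <- rep(seq_len(nref), times = tol + 1L)
  uniq <- unique(chunk_seq)
  ref_of_chunk <- split(chunk_ref, factor(chunk_seq, levels = uniq))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
  hits <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(seqs))
  lapply(hits, function(h) {
    if (length(h) == 0) integer(0)
    else unique(unlist(ref_of_chunk[h], use.names = FALSE))
  })
}

#' Match reads against a reference set
#'
#' Vectorized matching of each read sequence against every reference. With
#' `tolerance = 0` the leftmost exact occurrence of any reference is reported;
#' with `tolerance >= 1` each reference is aligned semi-globally (gaps free at
#' both read ends) and the reference with the unique smallest edit distance
#' `<= tolerance` wins. Reads hit by two or more references (or two references
#' tied at the minimum distance) are flagged ambiguous.
#'
#' @param seqs character vector of read sequences.
#' @param refs reference set from [load_references()].
#' @param tolerance maximum edit distance (0 = exact).
#' @return a `data.table` with one row per read: `status`
#'   (`hit`/`none`/`ambiguous`), `ref` (reference name), `position` (1-based
#'   leftmost start, exact mode only), `distance` (tolerant mode only).
#' @export
match_references <- function(seqs, refs, tolerance = 0L) {
  stopifnot(tolerance >= 0)
  n <- length(seqs)
  out <- data.table::data.table(status = rep("none", n), ref = NA_character_,
                                position = NA_integer_, distance = NA_integer_)
  if (n == 0) return(out)
  if (tolerance == 0) {
    hits <- exact_hit_list(seqs, refs)
    nh <- lengths(hits)
    out[nh >= 2L, status := "ambiguous"]
    one <- which(nh == 1L)
    if (length(one)) {
      ridx <- unlist(hits[one])
      pos <- vapply(seq_along(one), function(j) {
        regexpr(refs$sequence[ridx[j]], seqs[one[j]], fixed = TRUE)[1]
      }, integer(1))
      out[one, `:=`(status = "hit", ref = refs$name[ridx], position = pos)]
    }
    return(out[])
  }
  cand <- tolerant_candidates(seqs, refs, as.integer(tolerance))
  m <- best_reference_match_cpp(seqs, refs$sequence, cand, as.integer(tolerance))
  hit <- m[, 1] > 0
  amb <- m[, 3] == 1
  out[amb, status := "ambiguous"]
  out[hit, `:=`(status = "hit", ref = refs$name[m[hit, 1]], distance = m[hit, 2])]
  out[]
}

#' Exact single-read reference match
#'
#' Convenience wrapper around [match_references()] for one read at tolerance 0.
#'
#' @param sequence one read sequence.
#' @param refs reference set.
#' @return `list(name, position)` for a unique hit, or `NULL` (no hit, or an
#'   ambiguous read matched by several references).
#' @export
match_reference_exact <- function(sequence, refs) {
  res <- match_references(sequence, refs, tolerance = 0L)
  if (res$status[1] != "hit") return(NULL)
  list(name = res$ref[1], position = res$position[1])
}

#' Edit-tolerant single-read reference match
#'
#' Semi-global alignment of every reference against the read (gaps free at both
#' read ends); the reference with the unique minimum edit distance within the
#' budget wins. Tolerance 0 is rejected — use [match_reference_exact()].
#'
#' @param sequence one read sequence.
#' @param refs reference set.
#' @param max_mismatches edit-distance budget, >= 1.
#' @return `list(name, distance)` or `NULL` (no hit within budget, or tie).
#' @export
match_reference_tolerant <- function(sequence, refs, max_mismatches) {
  if (max_mismatches < 1)
    stop("max_mismatches must be >= 1; use match_reference_exact() for exact matching",
         call. = FALSE)
  res <- match_references(sequence, refs, tolerance = max_mismatches)
  if (res$status[1] != "hit") return(NULL)
  list(name = res$ref[1], distance = res$distance[1])
}

# ---------------------------------------------------------------------------
# Reference-free matching

#' Compile a reference-free pattern into a matcher
#'
#' With tolerance 0 the flanks must occur verbatim (leftmost occurrence; the 3'
#' flank is searched after the 5' one). With tolerance >= 1 each flank is
#' located by semi-global alignment with up to `tolerance` edits per flank;
#' among equal-distance placements the innermost one (closest to the barcode) is
#' taken, and exact placement is tried first. The barcode is the read interval
#' strictly between the flank alignments; candidates then pass the mask, length
#' and N checks (an N is only accepted where the mask has an N).
#'
#' @param pattern a [barcode_pattern()].
#' @param tolerance per-flank edit budget, >= 0.
#' @return a function `(seqs) -> data.table(barcode, reason)`; `barcode` is `NA`
#'   where extraction failed and `reason` says why.
#' @export
compile_pattern <- function(pattern, tolerance = 0L) {
  stopifnot(inherits(pattern, "barcode_pattern"), tolerance >= 0)
  tol <- as.integer(tolerance)
  p <- pattern
  function(seqs) {
    n <- length(seqs)
    barcode <- rep(NA_character_, n)
    reason <- rep(NA_character_, n)
    if (n == 0) return(data.table::data.table(barcode = barcode, reason = reason))
    len <- nchar(seqs)
    bc_start <- rep(1L, n)       # first barcode base
    bc_end <- len                # last barcode base
    ok <- rep(TRUE, n)

    if (!is.null(p$flank5)) {
      w5 <- nchar(p$flank5)
      s5 <- regexpr(p$flank5, seqs, fixed = TRUE)
      e5 <- ifelse(s5 > 0, s5 + w5 - 1L, -1L)
      d5 <- ifelse(s5 > 0, 0L, -1L)
      if (tol >= 1) {
        miss <- which(s5 < 0)
        if (length(miss)) {
          loc <- locate_flank5_cpp(p$flank5, seqs[miss], tol)
          d5[miss] <- loc[, 1]
          e5[miss] <- loc[, 2]
        }
      }
      found5 <- d5 >= 0
      reason[ok & !found5] <- "no_flank5"
      ok <- ok & found5
      bc_start <- e5 + 1L
    }
    if (!is.null(p$flank3)) {
      w3 <- nchar(p$flank3)
      idx <- which(ok)
      if (length(idx)) {
        region <- substr(seqs[idx], bc_start[idx], len[idx])
        s3r <- regexpr(p$flank3, region, fixed = TRUE)
        d3 <- ifelse(s3r > 0, 0L, -1L)
        s3 <- as.integer(s3r)
        if (tol >= 1) {
          missr <- which(s3r < 0)
          if (length(missr)) {
            loc <- locate_flank3_cpp(p$flank3, region[missr], tol)
            d3[missr] <- loc[, 1]
            s3[missr] <- loc[, 2]
          }
        }
        found3 <- d3 >= 0
        reason[idx[!found3]] <- "no_flank3"
        ok[idx] <- found3
        # absolute position of the base before the 3' flank
        bc_end[idx] <- bc_start[idx] + s3 - 2L
      } else {
        ok <- ok & FALSE
      }
    }
    idx <- which(ok)
    if (length(idx)) {
      inverted <- bc_end[idx] < bc_start[idx] - 1L
      reason[idx[inverted]] <- "flank_overlap"
      ok[idx[inverted]] <- FALSE
    }
    idx <- which(ok)
    if (length(idx)) {
      cand <- substr(seqs[idx], bc_start[idx], bc_end[idx])
      clen <- nchar(cand)
      bad_len <- rep(FALSE, length(idx))
      if (!is.null(p$min_length)) bad_len <- bad_len | clen < p$min_length
      if (!is.null(p$max_length)) bad_len <- bad_len | clen > p$max_length
      reason[idx[bad_len]] <- "bad_length"
      keep <- !bad_len
      if (!is.null(p$mask)) {
        okm <- mask_ok(cand, p$mask)
        reason[idx[keep & !okm]] <- "mask_mismatch"
        keep <- keep & okm
      } else {
        hasN <- grepl("N", cand, fixed = TRUE)
        reason[idx[keep & hasN]] <- "n_in_barcode"
        keep <- keep & !hasN
      }
      barcode[idx[keep]] <- cand[keep]
    }
    data.table::data.table(barcode = barcode, reason = reason)
  }
}

# Positional mask check: candidate must have the mask's length; fixed letters
# must match exactly, N positions accept any base (including N).
mask_ok <- function(cand, mask) {
  ml <- nchar(mask)
  ok <- nchar(cand) == ml
  mask_chars <- strsplit(mask, "")[[1]]
  for (i in which(mask_chars != "N")) {
    ok <- ok & substr(cand, i, i) == mask_chars[i]
  }
  ok
}

# ---------------------------------------------------------------------------
# Extraction driver

#' Extract tag observations from a read stream
#'
#' Applies the configured matcher to every read; each successful match yields one
#' tag observation inheriting the read's sample/cell/UMI provenance (at most one
#' observation per read). Optionally also scans the reverse complement of reads
#' that had no forward hit. In reference-based mode the observed barcode is the
#' matched reference sequence (its name is kept in `ref_name`).
#'
#' @param reads a read stream.
#' @param mode `"reference_based"` or `"reference_free"`.
#' @param spec a reference set ([load_references()]) or a [barcode_pattern()],
#'   matching `mode`.
#' @param tolerance edit-distance budget (0 = exact matching).
#' @param scan_revcomp also scan the reverse complement (default off: amplicon
#'   FASTQ is oriented).
#' @return a tag observation `data.table` (`barcode`, `sample_id`,
#'   `cell_barcode`, `umi`, `read_count = 1`, and `ref_name` in reference-based
#'   mode) with a [drop_log()] attribute.
#' @export
extract_tags <- function(reads, mode = c("reference_based", "reference_free"),
                         spec, tolerance = 0L, scan_revcomp = FALSE) {
  mode <- match.arg(mode)
  if (nrow(reads) == 0) return(set_drop_log(empty_observations(), integer(0)))
  seqs <- reads$sequence

  run_match <- function(s) {
    if (mode == "reference_based") {
      res <- match_references(s, spec, tolerance)
      data.table::data.table(
        barcode = ifelse(res$status == "hit",
                         spec$sequence[match(res$ref, spec$name)], NA_character_),
        ref_name = res$ref,
        reason = data.table::fcase(res$status == "hit", NA_character_,
                                   res$status == "ambiguous", "ambiguous",
                                   default = "no_match"))
    } else {
      matcher <- compile_pattern(spec, tolerance)
      res <- matcher(s)
      res$ref_name <- NA_character_
      res
    }
  }

  res <- run_match(seqs)
  if (scan_revcomp) {
    miss <- which(is.na(res$barcode))
    if (length(miss)) {
      res_rc <- run_match(reverse_complement(seqs[miss]))
      got <- !is.na(res_rc$barcode)
      res[miss[got], `:=`(barcode = res_rc$barcode[got],
                          ref_name = res_rc$ref_name[got],
                          reason = NA_character_)]
    }
  }

  hit <- !is.na(res$barcode)
  drops <- table(res$reason[!hit])
  drops <- stats::setNames(as.integer(drops), names(drops))
  obs <- data.table::data.table(
    barcode = res$barcode[hit],
    sample_id = reads$sample_id[hit],
    cell_barcode = reads$cell_barcode[hit],
    umi = reads$umi[hit],
    read_count = 1L)
  if (mode == "reference_based") obs$ref_name <- res$ref_name[hit]
  log_stage("extract_tags", "%d reads in, %d observations (%s)",
            nrow(reads), nrow(obs),
            if (length(drops)) paste(names(drops), drops, sep = "=", collapse = ", ")
            else "no drops")
  set_drop_log(obs, drops)
}
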