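#' Label map constructor
#'
#' A label map is the fundamental object of optical genome mapping: an ordered
#' list of fluorescent label positions (bp) along one DNA entity — a reference
#' chromosome, a clone haplotype, an assembled contig or a single imaged
#' molecule.
#'
#' @param map_id identifier (coerced to character).
#' @param length_bp total length of the entity in bp (> 0).
#' @param positions numeric vector of label positions, strictly increasing,
#'   all in `(0, length_bp]`.
#' @param channels integer vector of label channel ids (recycled).
#' @return object of class `label_map`.
#' @export
label_map <- function(map_id, length_bp, positions = numeric(),
                      channels = 1L) {
  length_bp <- as.numeric(length_bp)
  positions <- as.numeric(positions)
  if (!is.finite(length_bp) || length_bp <= 0) {
    stop("length_bp must be a positive number")
  }
  if (length(positions)) {
    if (any(!is.finite(positions))) stop("positions must be finite")
    if (any(diff(positions) <= 0)) {
      stop("positions must be strictly increasing")
    }
    if (positions[1L] <= 0 || positions[length(positions)] > length_bp) {
      stop("positions must lie in (0, length_bp]")
    }
  }
  channels <- rep_len(as.integer(channels), length(positions))
  structure(
    list(map_id = as.character(map_id), length_bp = length_bp,
         positions = positions, channels = channels),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %.0f bp, %d labels\n",
              x$map_id, x$length_bp, length(x$positions)))
  invisible(x)
}

#' @export
length.label_map <- function(x) length(x$positions)

#' Labeling motif specification
#'
#' Describes one labeling chemistry: the IUPAC recognition sequence and where
#' the dye ends up relative to the motif's 5' start. With `label_offset = o`,
#' a forward-strand match starting at 1-based position `s` places a label at
#' `s + o + 1`; a reverse-strand match ending at `e` places it at `e - o - 1`
#' (the mirrored coordinate). Nicking enzymes such as Nt.BspQI (GCTCTTC, nick
#' one base 3' of the site) correspond to `label_offset = nchar(motif) - 1`.
#'
#' @param recognition_sequence IUPAC DNA string, non-empty.
#' @param label_offset integer bp from motif 5' start to the label, >= 0.
#' @param channel label color channel id.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(recognition_sequence, label_offset = 0L,
                       channel = 1L) {
  recognition_sequence <- toupper(as.character(recognition_sequence))
  if (!nzchar(recognition_sequence)) stop("recognition sequence is empty")
  iupac <- strsplit("ACGTNRYSWKMBDHV", "")[[1L]]
  if (!all(strsplit(recognition_sequence, "")[[1L]] %in% iupac)) {
    stop("recognition sequence contains non-IUPAC characters")
  }
  label_offset <- as.integer(label_offset)
  if (is.na(label_offset) || label_offset < 0) {
    stop("label_offset must be a non-negative integer")
  }
  structure(
    list(recognition_sequence = recognition_sequence,
         label_offset = label_offset, channel = as.integer(channel)),
    class = "motif_spec"
  )
}

#' Alignment record constructor
#'
#' One aligned segment of a molecule or contig against a reference map.
#' `site_pairs` is a two-column matrix of (reference site index, query site
#' index), ordered by increasing reference index; query indices increase for
#' orientation `+` and decrease for `-`.
#'
#' @param query_id,ref_id identifiers.
#' @param orientation `"+"` or `"-"`.
#' @param query_start_bp,query_end_bp,ref_start_bp,ref_end_bp coordinate
#'   ranges of the aligned segment (1-based bp).
#' @param site_pairs two-column numeric matrix `(ref_site, query_site)`.
#' @param confidence non-negative alignment confidence.
#' @param validate set `FALSE` to skip invariant checks (internal use).
#' @return object of class `alignment_record`.
#' @export
alignment_record <- function(query_id, ref_id, orientation,
                             query_start_bp, query_end_bp,
                             ref_start_bp, ref_end_bp,
                             site_pairs, confidence = 0,
                             validate = TRUE) {
  site_pairs <- matrix(as.integer(site_pairs), ncol = 2,
                       dimnames = list(NULL, c("ref_site", "query_site")))
  rec <- structure(
    list(query_id = as.character(query_id), ref_id = as.character(ref_id),
         orientation = orientation,
         query_start_bp = as.numeric(query_start_bp),
         query_end_bp = as.numeric(query_end_bp),
         ref_start_bp = as.numeric(ref_start_bp),
         ref_end_bp = as.numeric(ref_end_bp),
         site_pairs = site_pairs, confidence = as.numeric(confidence)),
    class = "alignment_record"
  )
  if (validate) validate_alignment_record(rec)
  rec
}

validate_alignment_record <- function(rec) {
  sp <- rec$site_pairs
  if (nrow(sp) < 2L) stop("alignment needs at least 2 site pairs")
  if (!rec$orientation %in% c("+", "-")) stop("orientation must be '+' or '-'")
  if (any(diff(sp[, 1L]) <= 0)) {
    stop("reference site indices must be strictly increasing")
  }
  dq <- diff(sp[, 2L])
  if (rec$orientation == "+" && any(dq <= 0)) {
    stop("query site indices must be strictly increasing for orientation '+'")
  }
  if (rec$orientation == "-" && any(dq >= 0)) {
    stop("query site indices must be strictly decreasing for orientation '-'")
  }
  if (rec$confidence < 0) stop("confidence must be >= 0")
  invisible(rec)
}

#' @export
print.alignment_record <- function(x, ...) {
  cat(sprintf("<alignment> %s -> %s [%s] ref %.0f-%.0f, %d matched sites\n",
              x$query_id, x$ref_id, x$orientation,
              x$ref_start_bp, x$ref_end_bp, nrow(x$site_pairs)))
  invisible(x)
}

#' Site pairs in ascending query order
#'
#' Orientation-normalization helper: returns the `site_pairs` matrix of a
#' record reordered so that query site indices ascend, regardless of
#' orientation (for `-` records the reference indices then descend).
#'
#' @param rec an [alignment_record()].
#' @return two-column matrix `(ref_site, query_site)`.
#' @export
site_pairs_query_ascending <- function(rec) {
  sp <- rec$site_pairs
  if (rec$orientation == "-") sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
  sp
}

#' Group alignment records into split-alignment sets
#'
#' Alignments sharing a query id are grouped and ordered by query coordinate;
#' the complement of their query spans gives the unaligned intervals. A
#' split-aligned molecule (several segments) is the raw signal of the complex
#' SV pipeline.
#'
#' @param records list of [alignment_record()].
#' @param query_lengths named numeric vector of query lengths in bp
#'   (names = query ids); needed to close the last unaligned interval. If a
#'   query id is missing its length is taken as the max aligned coordinate.
#' @param slack_bp segments may overlap on the query by at most this much.
#' @return named list of `split_alignment_set` objects, each with elements
#'   `query_id`, `segments` (ordered by query start) and `unaligned_intervals`
#'   (two-column matrix, 0-based half-open bp).
#' @export
split_alignment_sets <- function(records, query_lengths = NULL,
                                 slack_bp = 10000) {
  ids <- vapply(records, function(r) r$query_id, character(1))
  out <- lapply(split(records, ids), function(segs) {
    qs <- vapply(segs, function(r) min(r$query_start_bp, r$query_end_bp),
                 numeric(1))
    qe <- vapply(segs, function(r) max(r$query_start_bp, r$query_end_bp),
                 numeric(1))
    o <- order(qs, qe)
    segs <- segs[o]; qs <- qs[o]; qe <- qe[o]
    if (length(segs) > 1L) {
      ov <- qe[-length(qe)] - qs[-1L]
      if (any(ov > slack_bp)) {
        warning(sprintf(
          "query %s: segments overlap by up to %.0f bp (> slack %.0f)",
          segs[[1L]]$query_id, max(ov), slack_bp))
      }
    }
    qlen <- if (!is.null(query_lengths) &&
                segs[[1L]]$query_id %in% names(query_lengths)) {
      as.numeric(query_lengths[[segs[[1L]]$query_id]])
    } else max(qe)
    un <- unaligned_complement(qs, qe, qlen)
    structure(list(query_id = segs[[1L]]$query_id, segments = segs,
                   unaligned_intervals = un),
              class = "split_alignment_set")
  })
  out
}

# complement of the union of [qs, qe) within [0, qlen)
unaligned_complement <- function(qs, qe, qlen) {
  o <- order(qs)
  qs <- qs[o]; qe <- qe[o]
  merged_s <- numeric(); merged_e <- numeric()
  for (i in seq_along(qs)) {
    if (length(merged_s) && qs[i] <= merged_e[length(merged_e)]) {
      merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], qe[i])
    } else {
      merged_s <- c(merged_s, qs[i]); merged_e <- c(merged_e, qe[i])
    }
  }
  starts <- c(0, merged_e)
  ends <- c(merged_s, qlen)
  keep <- ends - starts > 1e-9
  cbind(start = starts[keep], end = ends[keep])
}
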