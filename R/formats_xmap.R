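XMAP_COLS <- c("XmapEntryID", "QryContigID", "RefContigID", "QryStartPos",
               "QryEndPos", "RefStartPos", "RefEndPos", "Orientation",
               "Confidence", "HitEnum", "QryLen", "RefLen", "LabelChannel",
               "Alignment")

#' Read an XMAP alignment file
#'
#' Parses map-to-map alignments; the `Alignment` string
#' `"(refSite,qrySite)(...)..."` becomes the record's `site_pairs` matrix in
#' file order. Several rows sharing a `QryContigID` are separate records here;
#' group them with [split_alignment_sets()] downstream. If reference or query
#' maps are supplied, site indices are validated against them.
#'
#' @param path XMAP file path.
#' @param ref_maps,query_maps optional lists of [label_map()] for index
#'   validation.
#' @return list of [alignment_record()].
#' @export
read_xmap <- function(path, ref_maps = NULL, query_maps = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#h", lines, value = TRUE)
  cols <- if (length(hdr)) {
    strsplit(sub("^#h[ \t]*", "", hdr[1L]), "\t", fixed = TRUE)[[1L]]
  } else XMAP_COLS
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(list())
  nsites <- function(maps) {
    stats::setNames(vapply(maps, function(m) length(m$positions), integer(1)),
                    vapply(maps, function(m) m$map_id, character(1)))
  }
  ref_n <- if (!is.null(ref_maps)) nsites(ref_maps)
  qry_n <- if (!is.null(query_maps)) nsites(query_maps)
  lapply(seq_along(body), function(k) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
    v <- function(name) {
      j <- match(name, cols)
      if (is.na(j) || j > length(f)) NA_character_ else f[j]
    }
    sp <- parse_alignment_string(v("Alignment"))
    rec <- alignment_record(
      query_id = v("QryContigID"), ref_id = v("RefContigID"),
      orientation = v("Orientation"),
      query_start_bp = as.numeric(v("QryStartPos")),
      query_end_bp = as.numeric(v("QryEndPos")),
      ref_start_bp = as.numeric(v("RefStartPos")),
      ref_end_bp = as.numeric(v("RefEndPos")),
      site_pairs = sp, confidence = as.numeric(v("Confidence"))
    )
    if (!is.null(ref_n) && rec$ref_id %in% names(ref_n) &&
        max(sp[, 1L]) > ref_n[[rec$ref_id]]) {
      stop(sprintf("XMAP validation error: ref site index %d > %d sites on %s",
                   max(sp[, 1L]), ref_n[[rec$ref_id]], rec$ref_id))
    }
    if (!is.null(qry_n) && rec$query_id %in% names(qry_n) &&
        max(sp[, 2L]) > qry_n[[rec$query_id]]) {
      stop(sprintf("XMAP validation error: query site index %d > %d sites on %s",
                   max(sp[, 2L]), qry_n[[rec$query_id]], rec$query_id))
    }
    rec
  })
}

#' Parse an XMAP alignment string
#'
#' @param s string of the form `"(1,1)(2,2)(4,3)"`.
#' @return two-column integer matrix `(ref_site, query_site)` in string order.
#' @export
parse_alignment_string <- function(s) {
  if (is.na(s) || !grepl("^(\\([0-9]+,[0-9]+\\))+$", s)) {
    stop(sprintf("malformed alignment string: '%s'", s))
  }
  m <- regmatches(s, gregexpr("[0-9]+", s))[[1L]]
  v <- as.integer(m)
  matrix(v, ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("ref_site", "query_site")))
}

#' Write alignment records to an XMAP file
#'
#' @param records list of [alignment_record()].
#' @param path output path.
#' @param ref_lengths,query_lengths optional named numeric vectors used to
#'   fill the RefLen/QryLen columns (0 when unknown).
#' @export
write_xmap <- function(records, path, ref_lengths = NULL,
                       query_lengths = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# XMAP File Version:\t0.2",
    paste0("#h ", paste(XMAP_COLS, collapse = "\t"))
  ), con)
  getlen <- function(tbl, id) {
    if (!is.null(tbl) && id %in% names(tbl)) as.numeric(tbl[[id]]) else 0
  }
  for (k in seq_along(records)) {
    r <- records[[k]]
    aln <- paste(sprintf("(%d,%d)", r$site_pairs[, 1L], r$site_pairs[, 2L]),
                 collapse = "")
    writeLines(paste(c(
      k, r$query_id, r$ref_id,
      sprintf("%.1f", r$query_start_bp), sprintf("%.1f", r$query_end_bp),
      sprintf("%.1f", r$ref_start_bp), sprintf("%.1f", r$ref_end_bp),
      r$orientation, sprintf("%.2f", r$confidence), paste0(nrow(r$site_pairs), "M"),
      sprintf("%.1f", getlen(query_lengths, r$query_id)),
      sprintf("%.1f", getlen(ref_lengths, r$ref_id)),
      "1", aln), collapse = "\t"), con)
  }
  invisible(path)
}
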