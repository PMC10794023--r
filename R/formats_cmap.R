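CMAP_COLS <- c("CMapId", "ContigLength", "NumSites", "SiteID",
               "LabelChannel", "Position", "StdDev", "Coverage", "Occurrence")

#' Read a CMAP consensus/reference map file
#'
#' Tab-separated rows `(CMapId, ContigLength, NumSites, SiteID, LabelChannel,
#' Position, StdDev, Coverage, Occurrence, ...)`; the conventional final row
#' per map (LabelChannel 0, Position = ContigLength) is treated as the length
#' sentinel, not a label. Columns beyond the standard nine are preserved as
#' opaque strings in `attr(map, "extra_cols")` and written back by
#' [write_cmap()].
#'
#' @param path CMAP file path.
#' @return list of [label_map()], one per CMapId, in file order.
#' @export
read_cmap <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#h", lines, value = TRUE)
  cols <- if (length(hdr)) {
    strsplit(sub("^#h[ \t]*", "", hdr[1L]), "\t", fixed = TRUE)[[1L]]
  } else CMAP_COLS
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(list())
  f <- strsplit(body, "\t", fixed = TRUE)
  n <- lengths(f)
  if (any(n < 6L)) {
    stop(sprintf("CMAP parse error: row with %d fields (need >= 6)", min(n)))
  }
  get <- function(name, i) vapply(f, `[`, character(1), i)
  idx <- function(name) {
    j <- match(name, cols)
    if (is.na(j)) stop(sprintf("CMAP missing column %s", name))
    j
  }
  id <- get("CMapId", idx("CMapId"))
  len <- as.numeric(get("ContigLength", idx("ContigLength")))
  chan <- as.integer(get("LabelChannel", idx("LabelChannel")))
  pos <- as.numeric(get("Position", idx("Position")))
  n_extra <- max(lengths(f)) - length(CMAP_COLS)
  extras <- if (n_extra > 0) {
    do.call(cbind, lapply(seq_len(n_extra) + length(CMAP_COLS), function(j)
      vapply(f, function(x) if (length(x) >= j) x[j] else "", character(1))))
  } else NULL
  out <- list()
  for (this_id in unique(id)) {
    sel <- which(id == this_id)
    lab <- sel[chan[sel] != 0L]
    o <- order(pos[lab])
    lab <- lab[o]
    m <- label_map(this_id, len[sel[1L]], pos[lab], chan[lab])
    if (!is.null(extras)) {
      attr(m, "extra_cols") <- extras[lab, , drop = FALSE]
      attr(m, "extra_names") <- if (length(cols) > length(CMAP_COLS)) {
        cols[-seq_along(CMAP_COLS)]
      } else paste0("X", seq_len(ncol(extras)))
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Write label maps to a CMAP file
#'
#' Emits the standard nine columns (positions printed with one decimal) plus
#' any opaque extra columns carried by [read_cmap()], and the LabelChannel-0
#' length sentinel row per map.
#'
#' @param maps list of [label_map()].
#' @param path output path.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  extra_names <- unique(unlist(lapply(maps, attr, "extra_names")))
  writeLines(c(
    "# CMAP File Version:\t0.1",
    paste0("#h ", paste(c(CMAP_COLS, extra_names), collapse = "\t")),
    paste0("#f ", paste(rep("float", length(CMAP_COLS) + length(extra_names)),
                        collapse = "\t"))
  ), con)
  for (m in maps) {
    ns <- length(m$positions)
    ex <- attr(m, "extra_cols")
    for (i in seq_len(ns)) {
      row <- c(m$map_id, sprintf("%.1f", m$length_bp), ns, i,
               m$channels[i], sprintf("%.1f", m$positions[i]), "0.0", "1", "1")
      if (!is.null(ex)) row <- c(row, ex[i, ])
      writeLines(paste(row, collapse = "\t"), con)
    }
    row <- c(m$map_id, sprintf("%.1f", m$length_bp), ns, ns + 1L, 0L,
             sprintf("%.1f", m$length_bp), "0.0", "1", "0")
    if (!is.null(ex)) row <- c(row, rep("", ncol(ex)))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
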