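#' Read a BNX molecule file
#'
#' Parses BNX v1.2/v1.3: header lines starting `#`, then per-molecule blocks
#' of a `0` metadata line (molecule id, length) followed by one label line per
#' channel (`1`, `2`, ...) whose last value is the molecule-length sentinel,
#' and optional `QX` quality lines (ignored — per-label quality is unused
#' here). The trailing sentinel is dropped from the label positions.
#'
#' Molecules with non-monotone label positions are rejected with a warning and
#' parsing continues; molecules shorter than `min_length_bp` are retained but
#' flagged (`attr(map, "short")`).
#'
#' @param path BNX file path.
#' @param min_length_bp flag molecules shorter than this (default from
#'   [om_config()]).
#' @return list of [label_map()], one per molecule.
#' @export
read_bnx <- function(path, min_length_bp = om_config()$bnx$min_molecule_length) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  out <- list()
  cur_id <- NULL; cur_len <- NA_real_
  cur_pos <- numeric(); cur_chan <- integer()
  bad <- FALSE
  flush <- function() {
    if (is.null(cur_id) || bad) return()
    o <- order(cur_pos) # channels are separate sorted lines; interleave
    pos <- cur_pos[o]; chan <- cur_chan[o]
    if (length(pos) && any(diff(pos) <= 0)) {
      # collapse exact cross-channel duplicates, keep first channel
      keep <- c(TRUE, diff(pos) > 0)
      pos <- pos[keep]; chan <- chan[keep]
    }
    m <- label_map(cur_id, cur_len, pos, chan)
    attr(m, "short") <- cur_len < min_length_bp
    out[[length(out) + 1L]] <<- m
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    tag <- f[1L]
    if (tag == "0") {
      flush()
      cur_id <- f[2L]
      cur_len <- as.numeric(f[3L])
      cur_pos <- numeric(); cur_chan <- integer(); bad <- FALSE
    } else if (grepl("^[0-9]+$", tag)) {
      if (is.null(cur_id)) {
        stop(sprintf("BNX parse error at line %d: label line before any '0' line", i))
      }
      pos <- as.numeric(f[-1L])
      # drop the molecule-end sentinel (last value equal to molecule length)
      if (length(pos) && abs(pos[length(pos)] - cur_len) <= 0.11) {
        pos <- pos[-length(pos)]
      }
      if (length(pos) && any(diff(pos) <= 0)) {
        warning(sprintf(
          "BNX line %d: non-monotone label positions; molecule %s rejected",
          i, cur_id))
        bad <- TRUE
      } else {
        cur_pos <- c(cur_pos, pos)
        cur_chan <- c(cur_chan, rep.int(as.integer(tag), length(pos)))
      }
    } else if (startsWith(tag, "QX")) {
      next
    } else {
      stop(sprintf("BNX parse error at line %d: unrecognized tag '%s'", i, tag))
    }
  }
  flush()
  out
}

#' Write molecules to a BNX file
#'
#' Output is re-readable by [read_bnx()] with positions preserved to 0.1 bp
#' (the format prints one decimal). Each label line ends with the
#' molecule-length sentinel; a label-free molecule gets a sentinel-only line.
#'
#' @param molecules list of [label_map()].
#' @param path output path.
#' @param version BNX dialect version string to stamp in the header.
#' @export
write_bnx <- function(molecules, path, version = "1.3") {
  channels <- sort(unique(unlist(lapply(molecules, function(m)
    if (length(m$positions)) unique(m$channels) else 1L))))
  if (!length(channels)) channels <- 1L
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# BNX File Version:\t%s", version),
    sprintf("# Label Channels:\t%d", length(channels)),
    "#0h\tLabelChannel\tMoleculeID\tLength",
    "#0f\tint\tint\tfloat"
  ), con)
  for (m in molecules) {
    writeLines(sprintf("0\t%s\t%.1f", m$map_id, m$length_bp), con)
    for (ch in channels) {
      pos <- m$positions[m$channels == ch]
      writeLines(paste(c(as.character(ch), sprintf("%.1f", c(pos, m$length_bp))),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
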