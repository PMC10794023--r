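#' In-silico digestion of a DNA sequence into a label map
#'
#' Finds every occurrence of each recognition motif on both strands of the
#' sequence (IUPAC codes in the motif are honored) and places a label per
#' match: `start + label_offset + 1` for forward matches, `end - label_offset
#' - 1` for reverse-complement matches (all coordinates 1-based). Labels from
#' overlapping or two-strand matches that fall within `collapse_bp` of each
#' other on the same channel — e.g. the two strands of a palindromic site,
#' which label ~1 bp apart and are unresolvable optically — are merged to
#' their midpoint.
#'
#' @param sequence DNA string or `Biostrings::DNAString`; must be non-empty.
#' @param motifs a [motif_spec()] or list of them.
#' @param map_id identifier for the resulting map.
#' @param collapse_bp merge distance for sub-resolution label pairs.
#' @return a [label_map()] of length `nchar(sequence)`.
#' @export
in_silico_digest <- function(sequence, motifs, map_id = "digest",
                             collapse_bp = om_config()$digest$collapse_bp) {
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  subject <- if (inherits(sequence, "DNAString")) sequence else {
    if (!nzchar(as.character(sequence))) {
      stop("empty sequence: a label map must have length > 0")
    }
    Biostrings::DNAString(as.character(sequence))
  }
  L <- length(subject)
  if (L == 0L) stop("empty sequence: a label map must have length > 0")
  pos <- numeric(); chan <- integer()
  for (m in motifs) {
    pat <- Biostrings::DNAString(m$recognition_sequence)
    fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    p_f <- Biostrings::start(fwd) + m$label_offset + 1
    rcp <- Biostrings::reverseComplement(pat)
    p_r <- numeric(0)
    if (as.character(rcp) != as.character(pat)) {
      rev <- Biostrings::matchPattern(rcp, subject, fixed = "subject")
      p_r <- Biostrings::end(rev) - m$label_offset - 1
    } else {
      # palindrome: the same match labels both strands, mirrored
      p_r <- Biostrings::end(fwd) - m$label_offset - 1
    }
    p <- c(p_f, p_r)
    p <- p[p > 0 & p <= L]
    pos <- c(pos, p)
    chan <- c(chan, rep.int(m$channel, length(p)))
  }
  if (!length(pos)) return(label_map(map_id, L))
  out_pos <- numeric(); out_chan <- integer()
  for (ch in sort(unique(chan))) {
    p <- sort(pos[chan == ch])
    grp <- cumsum(c(1, diff(p) > collapse_bp))
    p <- as.numeric(tapply(p, grp, mean))
    out_pos <- c(out_pos, p)
    out_chan <- c(out_chan, rep.int(ch, length(p)))
  }
  o <- order(out_pos)
  out_pos <- out_pos[o]; out_chan <- out_chan[o]
  # cross-channel exact ties cannot be represented; nudge is not meaningful,
  # drop the later channel's duplicate
  keep <- c(TRUE, diff(out_pos) > 0)
  label_map(map_id, L, out_pos[keep], out_chan[keep])
}
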