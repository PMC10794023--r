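#' Apply SVs to a reference genome in label space
#'
#' Produces one haplotype's label maps by editing the reference label
#' coordinates: deletions drop the labels in their span and shift downstream
#' positions left; insertions splice in the event's own label pattern and
#' shift right; inversions mirror label positions within the span (and flip
#' strand); duplications splice a copy of the span's labels immediately after
#' it; translocations cut the span out of its chromosome and splice it into
#' the destination. Events must be non-overlapping on the haplotype.
#'
#' Alongside the maps, a liftover table maps every output label to its source
#' reference label (`src_chrom`, `src_pos`, `src_site`, `strand`) or marks it
#' `novel` (inserted material); duplicated copies are flagged `dup_copy`.
#'
#' @param genome named list of reference [label_map()].
#' @param svs list of [sv_event()] to apply (any order).
#' @return list with `maps` (named list of [label_map()]) and `liftover`
#'   (data.table: chrom, pos, src_chrom, src_pos, src_site, strand, novel,
#'   dup_copy).
#' @export
apply_svs_to_genome <- function(genome, svs) {
  chroms <- names(genome)
  lens <- vapply(genome, function(m) m$length_bp, numeric(1))
  # --- validate spans and overlaps -------------------------------------
  iv <- lapply(stats::setNames(nm = chroms), function(ch) matrix(numeric(), 0, 2))
  for (e in svs) {
    if (!e$ref_id %in% chroms) stop(sprintf("unknown chromosome %s", e$ref_id))
    hi <- if (e$sv_type == "insertion") e$start_bp + 1 else e$end_bp
    if (hi > lens[[e$ref_id]] || e$start_bp < 0) {
      stop(sprintf("SV %s span exceeds map %s", e$sv_id, e$ref_id))
    }
    iv[[e$ref_id]] <- rbind(iv[[e$ref_id]], c(e$start_bp, hi))
    if (grepl("^translocation", e$sv_type)) {
      if (!e$dest_ref_id %in% chroms) {
        stop(sprintf("unknown destination chromosome %s", e$dest_ref_id))
      }
      if (e$dest_bp > lens[[e$dest_ref_id]]) {
        stop(sprintf("SV %s destination exceeds map", e$sv_id))
      }
      iv[[e$dest_ref_id]] <- rbind(iv[[e$dest_ref_id]], c(e$dest_bp, e$dest_bp + 1))
    }
  }
  for (ch in chroms) {
    m <- iv[[ch]]
    if (nrow(m) > 1L) {
      o <- order(m[, 1L]); m <- m[o, , drop = FALSE]
      if (any(m[-nrow(m), 2L] > m[-1L, 1L])) {
        stop(sprintf("overlapping SVs on %s", ch))
      }
    }
  }
  # --- per-chromosome edit lists ---------------------------------------
  base <- lapply(stats::setNames(nm = chroms), function(ch) {
    m <- genome[[ch]]
    data.table::data.table(
      pos0 = m$positions, src_chrom = ch, src_pos = m$positions,
      src_site = seq_along(m$positions), strand = "+",
      novel = FALSE, dup_copy = FALSE)
  })
  dels <- lapply(stats::setNames(nm = chroms), function(ch) matrix(numeric(), 0, 2))
  invs <- dels
  inss <- lapply(stats::setNames(nm = chroms), function(ch) list())
  add_ins <- function(ch, p, size, content) {
    inss[[ch]][[length(inss[[ch]]) + 1L]] <<- list(p = p, size = size,
                                                   content = content)
  }
  for (e in svs) {
    ch <- e$ref_id
    if (e$sv_type == "deletion") {
      dels[[ch]] <- rbind(dels[[ch]], c(e$start_bp, e$end_bp))
    } else if (e$sv_type == "insertion") {
      off <- e$novel_offsets
      if (is.null(off)) off <- generate_novel_offsets(e$size_bp)
      content <- data.table::data.table(
        offset = as.numeric(off), src_chrom = NA_character_,
        src_pos = NA_real_, src_site = NA_integer_, strand = "+",
        novel = TRUE, dup_copy = FALSE)
      add_ins(ch, e$start_bp, e$size_bp, content)
    } else if (e$sv_type == "inversion") {
      invs[[ch]] <- rbind(invs[[ch]], c(e$start_bp, e$end_bp))
    } else if (e$sv_type == "duplication") {
      span <- base[[ch]][pos0 >= e$start_bp & pos0 < e$end_bp]
      content <- data.table::data.table(
        offset = span$pos0 - e$start_bp, src_chrom = span$src_chrom,
        src_pos = span$src_pos, src_site = span$src_site, strand = "+",
        novel = FALSE, dup_copy = TRUE)
      add_ins(ch, e$end_bp, e$end_bp - e$start_bp, content)
    } else { # translocations
      span <- base[[ch]][pos0 >= e$start_bp & pos0 < e$end_bp]
      content <- data.table::data.table(
        offset = span$pos0 - e$start_bp, src_chrom = span$src_chrom,
        src_pos = span$src_pos, src_site = span$src_site, strand = "+",
        novel = FALSE, dup_copy = FALSE)
      dels[[ch]] <- rbind(dels[[ch]], c(e$start_bp, e$end_bp))
      add_ins(e$dest_ref_id, e$dest_bp, e$end_bp - e$start_bp, content)
    }
  }
  # --- materialize ------------------------------------------------------
  maps <- list(); lift <- list()
  for (ch in chroms) {
    rows <- data.table::copy(base[[ch]])
    dl <- dels[[ch]]
    for (k in seq_len(nrow(dl))) {
      rows <- rows[!(pos0 >= dl[k, 1L] & pos0 < dl[k, 2L])]
    }
    im <- invs[[ch]]
    for (k in seq_len(nrow(im))) {
      s <- im[k, 1L]; e_ <- im[k, 2L]
      sel <- rows$pos0 >= s & rows$pos0 < e_
      rows[sel, `:=`(pos0 = s + e_ - pos0,
                     strand = ifelse(strand == "+", "-", "+"))]
    }
    shift_at <- function(x, inclusive_ins = FALSE) {
      s <- numeric(length(x))
      for (k in seq_len(nrow(dl))) s <- s - ifelse(x >= dl[k, 2L], dl[k, 2L] - dl[k, 1L], 0)
      for (e_ins in inss[[ch]]) {
        hit <- if (inclusive_ins) x >= e_ins$p else x > e_ins$p
        s <- s + ifelse(hit, e_ins$size, 0)
      }
      s
    }
    rows[, pos := pos0 + shift_at(pos0)]
    extra <- list()
    for (e_ins in inss[[ch]]) {
      if (!nrow(e_ins$content)) next
      # shift at the insertion point counts deletions up to p and other
      # insertions strictly left of p
      sh <- -sum(apply(dl, 1L, function(d) if (e_ins$p >= d[2L]) d[2L] - d[1L] else 0))
      for (o_ins in inss[[ch]]) {
        if (o_ins$p < e_ins$p) sh <- sh + o_ins$size
      }
      ct <- data.table::copy(e_ins$content)
      ct[, pos := e_ins$p + sh + offset]
      extra[[length(extra) + 1L]] <- ct[, .(pos, src_chrom, src_pos, src_site,
                                            strand, novel, dup_copy)]
    }
    out <- rows[, .(pos, src_chrom, src_pos, src_site, strand, novel, dup_copy)]
    if (length(extra)) out <- data.table::rbindlist(c(list(out), extra))
    data.table::setorder(out, pos)
    out <- out[c(TRUE, diff(out$pos) > 1e-9)]  # collapse coincident labels
    newlen <- lens[[ch]] -
      sum(apply(dl, 1L, function(d) d[2L] - d[1L])) +
      sum(vapply(inss[[ch]], function(z) z$size, numeric(1)))
    maps[[ch]] <- label_map(ch, newlen, out$pos)
    out[, chrom := ch]
    lift[[ch]] <- out
  }
  list(maps = maps,
       liftover = data.table::rbindlist(lift)[, .(chrom, pos, src_chrom,
                                                  src_pos, src_site, strand,
                                                  novel, dup_copy)])
}
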