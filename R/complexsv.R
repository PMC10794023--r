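BP_TYPES <- c("inversion_bp", "dup_bp", "tra_intra_bp", "tra_inter_bp",
              "large_del_bp", "large_ins_bp")

# inner-boundary reference coordinate of a segment, on the side facing the
# junction ("right" side of the left segment, "left" side of the right one)
inner_ref_coord <- function(seg, role) {
  if (role == "left") {
    if (seg$orientation == "+") max(seg$ref_start_bp, seg$ref_end_bp)
    else min(seg$ref_start_bp, seg$ref_end_bp)
  } else {
    if (seg$orientation == "+") min(seg$ref_start_bp, seg$ref_end_bp)
    else max(seg$ref_start_bp, seg$ref_end_bp)
  }
}

# which way the aligned segment extends from its junction locus:
# "L" = covers coordinates below the locus, "R" = above
segment_side <- function(role, orientation) {
  if (role == "left") { if (orientation == "+") "L" else "R" }
  else { if (orientation == "+") "R" else "L" }
}

#' Build the junction between two query-adjacent aligned segments
#'
#' @param left,right [alignment_record()]s adjacent on the query (left first).
#' @param slack_bp maximum tolerated overlap of the two segments on the query.
#' @return a list of class `junction` (`ref_gap_bp` is signed along the
#'   reference between the inner boundaries), or `NULL` when the segments
#'   overlap on the query by more than `slack_bp` (junction rejected).
#' @export
make_junction <- function(left, right, slack_bp = 10000) {
  q_left_hi <- max(left$query_start_bp, left$query_end_bp)
  q_right_lo <- min(right$query_start_bp, right$query_end_bp)
  if (q_left_hi - q_right_lo > slack_bp) return(NULL)
  r_l <- inner_ref_coord(left, "left")
  r_r <- inner_ref_coord(right, "right")
  structure(list(
    molecule_id = left$query_id, left_segment = left, right_segment = right,
    same_ref = left$ref_id == right$ref_id,
    orientation_pattern = paste0(left$orientation, right$orientation),
    query_gap_bp = q_right_lo - q_left_hi,
    ref_gap_bp = r_r - r_l,
    locus_left = list(ref_id = left$ref_id, pos = r_l,
                      side = segment_side("left", left$orientation)),
    locus_right = list(ref_id = right$ref_id, pos = r_r,
                       side = segment_side("right", right$orientation))
  ), class = "junction")
}

#' Classify a split-alignment junction into a break-point call
#'
#' Decision rules, in order: different chromosomes give an inter-chromosomal
#' translocation break point; an orientation flip on the same chromosome
#' gives an inversion break point; same orientation with the two reference
#' spans overlapping by at least `dup_min_overlap_labels` matched sites gives
#' a duplication break point; a right segment mapping entirely left of the
#' left segment gives an intra-chromosomal translocation; otherwise the
#' reference/query gap discrepancy decides — above `indel_handoff_bp` it is a
#' junction-scale indel (`large_del_bp`/`large_ins_bp`), and a deficit beyond
#' `tra_intra_min_bp` an intra-chromosomal translocation. Small
#' discrepancies are not break points (they belong to the indel pipeline).
#'
#' @param junction a [make_junction()] result.
#' @param config an [om_config()] list (uses the `complexsv` group).
#' @param source evidence source tag (`"split"`, `"realign"`, `"contig"`).
#' @return one-row data.table (`bp_type`, canonically ordered loci
#'   `ref_a`/`pos_a`/`side_a`, `ref_b`/`pos_b`/`side_b`, `pattern`,
#'   `molecule_id`, `source`, `full_span`) or `NULL` when the junction is no
#'   break point.
#' @export
classify_junction <- function(junction, config = om_config(),
                              source = "split") {
  if (is.null(junction)) return(NULL)
  cc <- config$complexsv
  j <- junction
  bp_type <- NULL
  if (!j$same_ref) {
    bp_type <- "tra_inter_bp"
  } else if (j$orientation_pattern %in% c("+-", "-+")) {
    bp_type <- "inversion_bp"
  } else {
    # same chromosome, same orientation; for '--' junctions the molecule is
    # read in reverse, so collinear means the reference gap runs negative —
    # flip its sign before reasoning about order and discrepancy
    l <- j$left_segment; r <- j$right_segment
    l_sites <- range(l$site_pairs[, 1L]); r_sites <- range(r$site_pairs[, 1L])
    ov <- min(l_sites[2L], r_sites[2L]) - max(l_sites[1L], r_sites[1L]) + 1L
    ref_gap <- if (j$orientation_pattern == "--") -j$ref_gap_bp else j$ref_gap_bp
    disc <- ref_gap - j$query_gap_bp
    if (ov >= cc$dup_min_overlap_labels) {
      bp_type <- "dup_bp"
    } else if (ref_gap < 0) {
      bp_type <- "tra_intra_bp"      # re-ordered segments
    } else if (disc > cc$indel_handoff_bp) {
      bp_type <- if (disc < cc$tra_intra_min_bp) "large_del_bp" else "tra_intra_bp"
    } else if (-disc > cc$indel_handoff_bp) {
      bp_type <- "large_ins_bp"
    } else {
      return(NULL)
    }
  }
  a <- j$locus_left; b <- j$locus_right
  swap <- (b$ref_id < a$ref_id) || (b$ref_id == a$ref_id && b$pos < a$pos)
  if (swap) { tmp <- a; a <- b; b <- tmp }
  # a tandem-dup junction measures the full unit length even where the unit
  # has no labels: molecule distance across the junction minus the (negative)
  # reference gap
  event_size <- if (bp_type == "dup_bp") {
    j$query_gap_bp - j$ref_gap_bp
  } else NA_real_
  data.table::data.table(
    bp_type = bp_type, ref_a = a$ref_id, pos_a = a$pos, side_a = a$side,
    ref_b = b$ref_id, pos_b = b$pos, side_b = b$side,
    pattern = j$orientation_pattern, molecule_id = j$molecule_id,
    source = source, full_span = FALSE, event_size_bp = event_size)
}

#' Call break points from split-aligned molecules
#'
#' Classifies every adjacent junction of every split-alignment set. A
#' molecule aligned A-B-A' (two flanking collinear segments around a foreign
#' or inverted middle) yields two paired break points and has its calls
#' flagged `full_span` — such molecules witness the entire event. A
#' duplication junction is flagged `full_span` when the flanking segments
#' extend past both ends of the duplicated unit by `full_span_flank_bp`.
#'
#' @param split_sets list from [split_alignment_sets()].
#' @param config an [om_config()] list.
#' @param source evidence source tag stamped on the calls.
#' @return data.table of break-point calls (zero rows if none).
#' @export
call_from_split_sets <- function(split_sets, config = om_config(),
                                 source = "split") {
  cc <- config$complexsv
  out <- list()
  for (ss in split_sets) {
    segs <- ss$segments
    if (length(segs) < 2L) next
    calls <- vector("list", length(segs) - 1L)
    for (i in seq_len(length(segs) - 1L)) {
      jn <- make_junction(segs[[i]], segs[[i + 1L]],
                          slack_bp = cc$query_overlap_slack_bp)
      calls[[i]] <- classify_junction(jn, config, source = source)
    }
    # A-B-A' pattern: flanking segments collinear on one chromosome
    for (i in seq_len(max(length(segs) - 2L, 0L))) {
      a <- segs[[i]]; b <- segs[[i + 2L]]
      if (is.null(calls[[i]]) || is.null(calls[[i + 1L]])) next
      if (a$ref_id == b$ref_id && a$orientation == b$orientation &&
          inner_ref_coord(b, "right") >= inner_ref_coord(a, "left") - cc$merge_window_bp) {
        calls[[i]][, full_span := TRUE]
        calls[[i + 1L]][, full_span := TRUE]
      }
    }
    for (i in seq_along(calls)) {
      if (is.null(calls[[i]])) next
      if (calls[[i]]$bp_type == "dup_bp") {
        l <- segs[[i]]; r <- segs[[i + 1L]]
        unit_lo <- calls[[i]]$pos_a; unit_hi <- calls[[i]]$pos_b
        covers <- min(l$ref_start_bp, l$ref_end_bp) <=
          unit_lo - cc$full_span_flank_bp &&
          max(r$ref_start_bp, r$ref_end_bp) >= unit_hi + cc$full_span_flank_bp
        if (covers) calls[[i]][, full_span := TRUE]
      }
    }
    out <- c(out, Filter(Negate(is.null), calls))
  }
  if (!length(out)) return(empty_bp_calls())
  data.table::rbindlist(out)
}

empty_bp_calls <- function() {
  data.table::data.table(
    bp_type = character(), ref_a = character(), pos_a = numeric(),
    side_a = character(), ref_b = character(), pos_b = numeric(),
    side_b = character(), pattern = character(), molecule_id = character(),
    source = character(), full_span = logical(), event_size_bp = numeric())
}

#' Call break points from contig alignments
#'
#' Contigs assembled from molecules carry very long-range information
#' (needed e.g. for translocations). The junction logic is identical to
#' molecules; support is counted once per contig and the source is marked
#' `"contig"` so consolidation can weight it appropriately (cancer
#' assemblies carry more errors, so an uncorroborated contig never promotes
#' a call to complete on its own).
#'
#' @param contig_split_sets list from [split_alignment_sets()] over the
#'   contig-to-reference alignments.
#' @param config an [om_config()] list.
#' @return data.table of break-point calls with `source = "contig"`.
#' @export
call_from_contigs <- function(contig_split_sets, config = om_config()) {
  call_from_split_sets(contig_split_sets, config, source = "contig")
}

# single-linkage 1-D chaining of break-point calls of one (type, refs, sides)
cluster_bp_group <- function(g, window) {
  data.table::setorder(g, pos_a, pos_b)
  grp <- integer(nrow(g)); gid <- 0L
  for (i in seq_len(nrow(g))) {
    if (i == 1L || g$pos_a[i] - g$pos_a[i - 1L] > window ||
        abs(g$pos_b[i] - g$pos_b[i - 1L]) > window) gid <- gid + 1L
    grp[i] <- gid
  }
  g[, cl := grp]
  g
}

weighted_median <- function(x, w) {
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Consolidate break-point calls into complex SV calls
#'
#' Break points of the same type, locus pair and segment sides within
#' `merge_window_bp` are clustered; each cluster's refined position is the
#' support-weighted median. Molecule support counts 1 per molecule; a contig
#' corroborated by at least one molecule counts as `min_bp_support`
#' molecules, an uncorroborated contig counts 1 and caps its call at partial
#' status. Clusters with support below `min_bp_support` are dropped.
#' Complementary clusters are then paired into events: the two boundary
#' junctions of an inversion (`+-` with `-+`), and the two junctions of a
#' translocation (loci adjacent on the anchor chromosome). An event is
#' `complete` when all its break points are present and mutually consistent,
#' or when full-span molecules witness it; otherwise `partial`. A lone
#' duplication junction without full-span evidence is likewise `partial`.
#'
#' Junction-scale indel break points (`large_del_bp`, `large_ins_bp`) are
#' routed to the indel namespace: they are returned in the `handoff`
#' attribute, not as complex SV calls.
#'
#' @param bp_calls data.table of break-point calls
#'   ([call_from_split_sets()], [call_from_contigs()], re-alignment
#'   evidence).
#' @param config an [om_config()] list.
#' @return data.table of complex SV calls: `call_id`, `sv_type`, `ref_id`,
#'   `start_bp`, `end_bp`, `size_bp`, `ref_id2`, `pos2_bp`, `status`,
#'   `support`, `full_span_support`, `confidence`. Attribute `"handoff"`
#'   holds the large-indel break-point clusters.
#' @export
consolidate_breakpoints <- function(bp_calls, config = om_config()) {
  cc <- config$complexsv
  empty <- data.table::data.table(
    call_id = character(), sv_type = character(), ref_id = character(),
    start_bp = numeric(), end_bp = numeric(), size_bp = numeric(),
    ref_id2 = character(), pos2_bp = numeric(), status = character(),
    support = numeric(), full_span_support = integer(), confidence = numeric())
  if (is.null(bp_calls) || !nrow(bp_calls)) {
    data.table::setattr(empty, "handoff", empty_bp_calls())
    return(empty)
  }
  bp <- data.table::copy(data.table::as.data.table(bp_calls))
  if (!"event_size_bp" %in% names(bp)) bp[, event_size_bp := NA_real_]
  handoff <- bp[bp_type %in% c("large_del_bp", "large_ins_bp")]
  bp <- bp[!bp_type %in% c("large_del_bp", "large_ins_bp")]
  if (!nrow(bp)) {
    data.table::setattr(empty, "handoff", handoff)
    return(empty)
  }
  bp[, key := paste(bp_type, ref_a, ref_b, side_a, side_b, pattern,
                    sep = "|")]
  pieces <- lapply(split(bp, by = "key"), cluster_bp_group,
                   window = cc$merge_window_bp)
  bp <- data.table::rbindlist(pieces)
  bp[, cl_id := paste(key, cl, sep = "#")]
  clusters <- bp[, {
    mol_w <- rep(1, .N)
    is_contig <- source == "contig"
    corroborated <- any(!is_contig)
    mol_w[is_contig] <- if (corroborated) cc$min_bp_support else 1
    .(bp_type = bp_type[1L], ref_a = ref_a[1L], ref_b = ref_b[1L],
      side_a = side_a[1L], side_b = side_b[1L], pattern = pattern[1L],
      pos_a = weighted_median(pos_a, mol_w),
      pos_b = weighted_median(pos_b, mol_w),
      support = sum(mol_w),
      n_molecules = sum(!is_contig),
      full_span_support = sum(full_span & !is_contig),
      contig_only = all(is_contig),
      event_size = stats::median(event_size_bp, na.rm = TRUE))
  }, by = cl_id]
  # contig-only clusters survive (as partial calls); molecule clusters need
  # min_bp_support or full-span witnesses
  clusters <- clusters[support >= cc$min_bp_support | full_span_support > 0 |
                         contig_only]
  if (!nrow(clusters)) {
    data.table::setattr(empty, "handoff", handoff)
    return(empty)
  }
  calls <- list(); used <- character()
  add_call <- function(sv_type, ref_id, start_bp, end_bp, ref_id2 = NA_character_,
                       pos2_bp = NA_real_, status, support, fss, contig_only) {
    if (contig_only) status <- "partial"
    calls[[length(calls) + 1L]] <<- data.table::data.table(
      sv_type = sv_type, ref_id = ref_id, start_bp = start_bp,
      end_bp = end_bp, size_bp = end_bp - start_bp, ref_id2 = ref_id2,
      pos2_bp = pos2_bp, status = status, support = support,
      full_span_support = as.integer(fss),
      confidence = support / (support + cc$min_bp_support))
  }
  # --- inversions: pair the +- and -+ boundary clusters ------------------
  inv <- clusters[bp_type == "inversion_bp"]
  if (nrow(inv)) {
    inv_a <- inv[pattern == "+-"]; inv_b <- inv[pattern == "-+"]
    taken_b <- rep(FALSE, nrow(inv_b))
    for (i in seq_len(nrow(inv_a))) {
      d <- abs(inv_b$pos_a - inv_a$pos_a[i]) + abs(inv_b$pos_b - inv_a$pos_b[i])
      d[taken_b | inv_b$ref_a != inv_a$ref_a[i]] <- Inf
      jbest <- which.min(d)
      if (length(jbest) && is.finite(d[jbest]) &&
          d[jbest] <= 4 * cc$merge_window_bp) {
        taken_b[jbest] <- TRUE
        # the +- junction brackets the span from outside-left/inside-right,
        # the -+ junction from inside-left/outside-right: average the two
        s <- mean(c(inv_a$pos_a[i], inv_b$pos_a[jbest]))
        e <- mean(c(inv_a$pos_b[i], inv_b$pos_b[jbest]))
        add_call("inversion", inv_a$ref_a[i], s, e, status = "complete",
                 support = inv_a$support[i] + inv_b$support[jbest],
                 fss = inv_a$full_span_support[i] + inv_b$full_span_support[jbest],
                 contig_only = inv_a$contig_only[i] && inv_b$contig_only[jbest])
      } else {
        st <- if (inv_a$full_span_support[i] > 0) "complete" else "partial"
        add_call("inversion", inv_a$ref_a[i], inv_a$pos_a[i], inv_a$pos_b[i],
                 status = st, support = inv_a$support[i],
                 fss = inv_a$full_span_support[i],
                 contig_only = inv_a$contig_only[i])
      }
    }
    for (j in which(!taken_b)) {
      st <- if (inv_b$full_span_support[j] > 0) "complete" else "partial"
      add_call("inversion", inv_b$ref_a[j], inv_b$pos_a[j], inv_b$pos_b[j],
               status = st, support = inv_b$support[j],
               fss = inv_b$full_span_support[j],
               contig_only = inv_b$contig_only[j])
    }
  }
  # --- duplications: one junction defines the unit ----------------------
  # [pos_a, pos_b] is the label-covered part of the unit; the junction-
  # measured unit size is centered on it (minimax placement of the
  # label-free remainder)
  dup <- clusters[bp_type == "dup_bp"]
  for (i in seq_len(nrow(dup))) {
    st <- if (dup$full_span_support[i] > 0) "complete" else "partial"
    covered <- dup$pos_b[i] - dup$pos_a[i]
    size <- dup$event_size[i]
    if (is.finite(size) && size > covered) {
      mid <- (dup$pos_a[i] + dup$pos_b[i]) / 2
      s <- mid - size / 2; e <- mid + size / 2
    } else {
      s <- dup$pos_a[i]; e <- dup$pos_b[i]
    }
    add_call("duplication", dup$ref_a[i], s, e,
             status = st, support = dup$support[i],
             fss = dup$full_span_support[i], contig_only = dup$contig_only[i])
  }
  # --- translocations: pair the two junctions around the insertion point -
  for (ty in c("tra_inter_bp", "tra_intra_bp")) {
    tra <- clusters[bp_type == ty]
    if (!nrow(tra)) next
    sv_ty <- if (ty == "tra_inter_bp") "translocation_inter" else
      "translocation_intra"
    taken <- rep(FALSE, nrow(tra))
    for (i in seq_len(nrow(tra))) {
      if (taken[i]) next
      paired <- FALSE
      for (j in seq_len(nrow(tra))) {
        if (j == i || taken[j]) next
        if (tra$ref_a[i] != tra$ref_a[j] || tra$ref_b[i] != tra$ref_b[j]) next
        # the two junctions of one event differ in segment sides and are
        # adjacent on the anchor chromosome (where the material lands); the
        # other chromosome carries the moved span
        if (tra$side_a[i] == tra$side_a[j] && tra$side_b[i] == tra$side_b[j]) next
        da <- abs(tra$pos_a[i] - tra$pos_a[j])
        db <- abs(tra$pos_b[i] - tra$pos_b[j])
        if (min(da, db) > 4 * cc$merge_window_bp) next
        # on the moved-span chromosome the two segments point inward (side R
        # at the lower locus, L at the higher); on the anchor chromosome they
        # point outward around the insertion point
        inward <- function(p1, s1, p2, s2) {
          (p1 <= p2 && s1 == "R" && s2 == "L") ||
            (p2 < p1 && s2 == "R" && s1 == "L")
        }
        in_a <- inward(tra$pos_a[i], tra$side_a[i], tra$pos_a[j], tra$side_a[j])
        in_b <- inward(tra$pos_b[i], tra$side_b[i], tra$pos_b[j], tra$side_b[j])
        span_on_a <- if (in_a != in_b) in_a else da >= db
        taken[i] <- taken[j] <- TRUE
        if (span_on_a) { # span on the a-side chromosome, anchor on b
          span <- range(c(tra$pos_a[i], tra$pos_a[j]))
          add_call(sv_ty, tra$ref_a[i], span[1L], span[2L],
                   ref_id2 = tra$ref_b[i],
                   pos2_bp = mean(c(tra$pos_b[i], tra$pos_b[j])),
                   status = "complete",
                   support = tra$support[i] + tra$support[j],
                   fss = tra$full_span_support[i] + tra$full_span_support[j],
                   contig_only = tra$contig_only[i] && tra$contig_only[j])
        } else {
          span <- range(c(tra$pos_b[i], tra$pos_b[j]))
          add_call(sv_ty, tra$ref_b[i], span[1L], span[2L],
                   ref_id2 = tra$ref_a[i],
                   pos2_bp = mean(c(tra$pos_a[i], tra$pos_a[j])),
                   status = "complete",
                   support = tra$support[i] + tra$support[j],
                   fss = tra$full_span_support[i] + tra$full_span_support[j],
                   contig_only = tra$contig_only[i] && tra$contig_only[j])
        }
        paired <- TRUE
        break
      }
      if (!paired) {
        taken[i] <- TRUE
        st <- if (tra$full_span_support[i] > 0) "complete" else "partial"
        add_call(sv_ty, tra$ref_a[i], tra$pos_a[i], tra$pos_a[i],
                 ref_id2 = tra$ref_b[i], pos2_bp = tra$pos_b[i],
                 status = st, support = tra$support[i],
                 fss = tra$full_span_support[i],
                 contig_only = tra$contig_only[i])
      }
    }
  }
  out <- if (length(calls)) data.table::rbindlist(calls) else empty
  if (nrow(out)) {
    data.table::setorder(out, ref_id, start_bp)
    out[, call_id := sprintf("complex_%d", .I)]
    data.table::setcolorder(out, "call_id")
  }
  data.table::setattr(out, "handoff", handoff)
  out[]
}

#' Merge, annotate and de-duplicate the two pipelines' outputs
#'
#' Produces the unified annotated call set: an insertion whose enclosing
#' region overlaps a duplication of compatible size (within a relative
#' `dedup_size_tol` of the duplicated unit) is redundant — the duplication
#' explains it — so the duplication is reported and the insertion is
#' suppressed with a cross-reference. Every call carries a
#' `complete`/`partial` break-point completeness status (cluster-based indel
#' calls are anchored on both sides, hence complete). If gene intervals are
#' supplied, overlapping gene names (half-open interval overlap) are
#' attached.
#'
#' @param complex_calls [consolidate_breakpoints()] output.
#' @param indel_calls final indel calls ([postprocess_calls()] output).
#' @param gene_intervals optional data.frame `(chrom, start, end, name)`.
#' @param config an [om_config()] list.
#' @return unified data.table: `call_id`, `pipeline`, `sv_type`, `ref_id`,
#'   `start_bp`, `end_bp`, `size_bp`, `zygosity`, `allele_fraction`,
#'   `support`, `status`, `confidence`, `genes`, `cross_ref`.
#' @export
annotate_and_deduplicate <- function(complex_calls, indel_calls,
                                     gene_intervals = NULL,
                                     config = om_config()) {
  cc <- config$complexsv
  ind <- if (!is.null(indel_calls) && nrow(indel_calls)) {
    data.table::data.table(
      call_id = indel_calls$call_id, pipeline = "indel",
      sv_type = indel_calls$sv_type, ref_id = indel_calls$ref_id,
      start_bp = indel_calls$start_bp, end_bp = indel_calls$end_bp,
      size_bp = indel_calls$size_bp, zygosity = indel_calls$zygosity,
      allele_fraction = indel_calls$allele_fraction,
      support = as.numeric(indel_calls$support), status = "complete",
      confidence = indel_calls$confidence, cross_ref = NA_character_)
  } else NULL
  cpx <- if (!is.null(complex_calls) && nrow(complex_calls)) {
    data.table::data.table(
      call_id = complex_calls$call_id, pipeline = "complex",
      sv_type = complex_calls$sv_type, ref_id = complex_calls$ref_id,
      start_bp = complex_calls$start_bp, end_bp = complex_calls$end_bp,
      size_bp = complex_calls$size_bp, zygosity = NA_character_,
      allele_fraction = NA_real_, support = as.numeric(complex_calls$support),
      status = complex_calls$status, confidence = complex_calls$confidence,
      cross_ref = NA_character_)
  } else NULL
  # insertion subsumed by an overlapping, size-compatible duplication
  if (!is.null(ind) && !is.null(cpx)) {
    dups <- cpx[sv_type == "duplication"]
    drop_ids <- character()
    for (i in seq_len(nrow(dups))) {
      unit <- dups$size_bp[i]
      hit <- ind[sv_type == "insertion" & ref_id == dups$ref_id[i] &
                   start_bp <= dups$end_bp[i] & end_bp >= dups$start_bp[i] &
                   abs(size_bp - unit) <= cc$dedup_size_tol * unit]
      if (nrow(hit)) {
        drop_ids <- c(drop_ids, hit$call_id)
        cpx[call_id == dups$call_id[i],
            cross_ref := paste(hit$call_id, collapse = ",")]
      }
    }
    if (length(drop_ids)) ind <- ind[!call_id %in% drop_ids]
  }
  out <- data.table::rbindlist(Filter(Negate(is.null), list(ind, cpx)),
                               fill = TRUE)
  if (!nrow(out)) {
    out <- data.table::data.table(
      call_id = character(), pipeline = character(), sv_type = character(),
      ref_id = character(), start_bp = numeric(), end_bp = numeric(),
      size_bp = numeric(), zygosity = character(),
      allele_fraction = numeric(), support = numeric(), status = character(),
      confidence = numeric(), cross_ref = character())
  }
  out[, genes := NA_character_]
  if (!is.null(gene_intervals) && nrow(out)) {
    gi <- data.table::as.data.table(gene_intervals)
    for (ch in unique(out$ref_id)) {
      g <- gi[chrom == ch]
      if (!nrow(g)) next
      idx <- which(out$ref_id == ch)
      qr <- IRanges::IRanges(start = as.integer(floor(out$start_bp[idx])),
                             end = as.integer(ceiling(out$end_bp[idx])))
      sr <- IRanges::IRanges(start = as.integer(g$start),
                             end = as.integer(g$end) - 1L) # half-open
      hits <- IRanges::findOverlaps(qr, sr)
      if (length(hits)) {
        byq <- split(g$name[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
        for (q in names(byq)) {
          out$genes[idx[as.integer(q)]] <- paste(unique(byq[[q]]),
                                                 collapse = ",")
        }
      }
    }
  }
  data.table::setorder(out, ref_id, start_bp)
  out[]
}
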