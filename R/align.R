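#' Scoring parameters for the fit aligner
#'
#' The fit aligner maximizes, over monotone matchings of query labels onto
#' reference-window labels,
#' \deqn{\sum_{pairs} [match\_reward - sizing\_error\_scale \cdot
#'   (obs-exp)^2 / (exp \cdot 1000)] - skip\ penalties,}
#' where `obs`/`exp` are the query/reference distances between consecutive
#' matched labels and each unmatched internal label costs its side's skip
#' penalty. At most `band_max_skips` consecutive labels may be skipped per
#' side. Defaults are calibrated so a noise-free sub-map of >= 5 labels
#' always clears `min_segment_score` (5 x match_reward = 15 > 8) while a
#' random placement's sizing penalties are strongly negative.
#'
#' @param match_reward score per matched label pair.
#' @param missed_ref_label_penalty cost per skipped reference label.
#' @param false_molecule_label_penalty cost per skipped query label.
#' @param sizing_error_scale converts squared normalized distance discrepancy
#'   (per kb of expected distance) into penalty.
#' @param min_segment_score alignments scoring below this are rejected.
#' @param band_max_skips maximum consecutive unmatched labels per side.
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(match_reward = 3, missed_ref_label_penalty = 1,
                           false_molecule_label_penalty = 1,
                           sizing_error_scale = 10, min_segment_score = 8,
                           band_max_skips = 3L) {
  stopifnot(missed_ref_label_penalty >= 0, false_molecule_label_penalty >= 0,
            sizing_error_scale >= 0, band_max_skips >= 0)
  structure(list(match_reward = match_reward,
                 missed_ref_label_penalty = missed_ref_label_penalty,
                 false_molecule_label_penalty = false_molecule_label_penalty,
                 sizing_error_scale = sizing_error_scale,
                 min_segment_score = min_segment_score,
                 band_max_skips = as.integer(band_max_skips)),
            class = "scoring_params")
}

# DP over one orientation; returns list(score, pairs, skips) or NULL.
# S tracks the best matching ending at a cell with >= 1 pairs (a single pair
# scores match_reward), S2 the best with >= 2 pairs — kept separate so the
# constrained (>= 2 pairs) optimum is representable even when it scores below
# a lone match. Tie order everywhere: score, then fewer skips, then leftmost
# first reference site.
fit_align_dp <- function(q, r, params) {
  m <- length(q); n <- length(r)
  if (m < 2L || n < 2L) return(NULL)
  band <- params$band_max_skips
  lex_better <- function(sc1, k1, f1, sc2, k2, f2) {
    sc1 > sc2 + 1e-12 ||
      (abs(sc1 - sc2) <= 1e-12 && (k1 < k2 || (k1 == k2 && f1 < f2)))
  }
  S <- matrix(params$match_reward, n, m); K <- matrix(0L, n, m)
  Fi <- matrix(rep(seq_len(n), m), n, m)
  S2 <- matrix(-Inf, n, m); K2 <- matrix(0L, n, m); F2 <- matrix(0L, n, m)
  P2i <- matrix(0L, n, m); P2j <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      i0 <- max(1L, i - band - 1L); j0 <- max(1L, j - band - 1L)
      for (ip in i0:(i - 1L)) {
        if (ip < 1L || ip >= i) next
        exp_d <- r[i] - r[ip]
        if (exp_d <= 0) next
        for (jp in j0:(j - 1L)) {
          if (jp < 1L || jp >= j) next
          pen <- params$sizing_error_scale * (q[j] - q[jp] - exp_d)^2 / (exp_d * 1000) +
            (i - ip - 1L) * params$missed_ref_label_penalty +
            (j - jp - 1L) * params$false_molecule_label_penalty
          sc <- S[ip, jp] + params$match_reward - pen
          sk <- K[ip, jp] + (i - ip - 1L) + (j - jp - 1L)
          if (lex_better(sc, sk, Fi[ip, jp], S2[i, j], K2[i, j], F2[i, j])) {
            S2[i, j] <- sc; K2[i, j] <- sk; F2[i, j] <- Fi[ip, jp]
            P2i[i, j] <- ip; P2j[i, j] <- jp
          }
        }
      }
      if (lex_better(S2[i, j], K2[i, j], F2[i, j], S[i, j], K[i, j], Fi[i, j])) {
        S[i, j] <- S2[i, j]; K[i, j] <- K2[i, j]; Fi[i, j] <- F2[i, j]
      }
    }
  }
  best <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!is.finite(S2[i, j])) next
    if (is.null(best) ||
        lex_better(S2[i, j], K2[i, j], F2[i, j],
                   best$score, best$skips, best$first)) {
      best <- list(score = S2[i, j], i = i, j = j, skips = K2[i, j],
                   first = F2[i, j])
    }
  }
  if (is.null(best)) return(NULL)
  pairs <- matrix(0L, 0L, 2L)
  i <- best$i; j <- best$j; via2 <- TRUE
  while (TRUE) {
    pairs <- rbind(c(i, j), pairs)
    if (!via2) break
    ii <- P2i[i, j]; jj <- P2j[i, j]
    if (ii == 0L) break
    # did the predecessor's S come from its own S2 (chain continues) or from
    # its single-pair seed (chain ends there)? Mirrors the forward update.
    via2 <- is.finite(S2[ii, jj]) &&
      lex_better(S2[ii, jj], K2[ii, jj], F2[ii, jj],
                 params$match_reward, 0L, ii)
    i <- ii; j <- jj
  }
  list(score = best$score, pairs = pairs, skips = best$skips)
}

#' Fit-align a query label map into a reference window
#'
#' Dynamic-programming alignment of an entire (partial) molecule label map
#' against a window of reference labels, used for targeted re-alignment of
#' unaligned molecule parts and for aligning simulated molecules. See
#' [scoring_params()] for the objective. Ties are broken toward fewer skipped
#' labels, then the leftmost reference start, making the result deterministic.
#'
#' @param query_labels numeric label positions of the query (molecule
#'   coordinates, ascending).
#' @param ref_window_labels numeric label positions of the reference window
#'   (reference coordinates, ascending).
#' @param params a [scoring_params()].
#' @param try_both_orientations also score the reflected query and keep the
#'   better orientation (ties prefer `+`).
#' @return an [alignment_record()] (site indices are positions within the two
#'   input vectors; confidence = score), or `NULL` if fewer than 2 query
#'   labels or the best score is below `min_segment_score`.
#' @export
fit_align <- function(query_labels, ref_window_labels,
                      params = scoring_params(),
                      try_both_orientations = TRUE) {
  q <- as.numeric(query_labels); r <- as.numeric(ref_window_labels)
  if (length(q) < 2L || length(r) < 2L) return(NULL)
  fwd <- fit_align_dp(q, r, params)
  rev_res <- NULL
  if (try_both_orientations) {
    qr <- (max(q) + min(q)) - rev(q)  # reflect, keep ascending
    rev_res <- fit_align_dp(qr, r, params)
  }
  use_rev <- !is.null(rev_res) &&
    (is.null(fwd) || rev_res$score > fwd$score + 1e-12)
  res <- if (use_rev) rev_res else fwd
  if (is.null(res) || res$score < params$min_segment_score) return(NULL)
  m <- length(q)
  if (use_rev) {
    qry_idx <- m + 1L - res$pairs[, 2L]  # map reflected index back
    orientation <- "-"
  } else {
    qry_idx <- res$pairs[, 2L]
    orientation <- "+"
  }
  ref_idx <- res$pairs[, 1L]
  rec <- alignment_record(
    query_id = "query", ref_id = "ref", orientation = orientation,
    query_start_bp = q[qry_idx[1L]], query_end_bp = q[qry_idx[length(qry_idx)]],
    ref_start_bp = r[ref_idx[1L]], ref_end_bp = r[ref_idx[length(ref_idx)]],
    site_pairs = cbind(ref_idx, qry_idx), confidence = max(res$score, 0)
  )
  attr(rec, "score") <- res$score # raw DP score (can be < 0 below thresholds)
  rec
}

#' Rescue tandem duplications by re-aligning unaligned molecule parts
#'
#' If the part of a molecule that the aligner left unaligned can itself be
#' aligned to the same reference region as an adjacent aligned segment, the
#' molecule likely carries a second tandem copy of that region. For each
#' unaligned interval with at least `realign_min_labels` labels adjacent to an
#' aligned segment, the unaligned labels are fit-aligned into the adjacent
#' segment's reference span (plus `realign_flank_bp` flank); an alignment that
#' clears `realign_min_score` and overlaps the segment's reference range
#' yields duplication evidence.
#'
#' @param split_set a `split_alignment_set` (see [split_alignment_sets()]).
#' @param molecule the molecule's [label_map()].
#' @param ref_map the reference [label_map()] the segments align to.
#' @param config an [om_config()] list.
#' @return `NULL`, or a list per evidence with `ref_id`, `unit_start`,
#'   `unit_end` (the overlapped reference interval = duplicated unit),
#'   `molecule_id` and `score`.
#' @export
detect_tandem_dup_by_realign <- function(split_set, molecule, ref_map,
                                         config = om_config()) {
  pa <- config$align
  params <- scoring_params(
    match_reward = pa$match_reward,
    missed_ref_label_penalty = pa$missed_ref_label_penalty,
    false_molecule_label_penalty = pa$false_molecule_label_penalty,
    sizing_error_scale = pa$sizing_error_scale,
    min_segment_score = pa$realign_min_score,
    band_max_skips = pa$band_max_skips
  )
  matched_q <- sort(unique(unlist(lapply(split_set$segments, function(s)
    s$site_pairs[, 2L]))))
  evidence <- list()
  un <- split_set$unaligned_intervals
  for (k in seq_len(nrow(un))) {
    in_iv <- which(molecule$positions > un[k, 1L] &
                     molecule$positions <= un[k, 2L])
    in_iv <- setdiff(in_iv, matched_q)
    if (length(in_iv) < pa$realign_min_labels) next
    qpos <- molecule$positions[in_iv]
    # adjacent segments: those whose query span touches this interval
    for (seg in split_set$segments) {
      if (seg$ref_id != ref_map$map_id) next
      qlo <- min(seg$query_start_bp, seg$query_end_bp)
      qhi <- max(seg$query_start_bp, seg$query_end_bp)
      adjacent <- (abs(qlo - un[k, 2L]) < 1e-6 || abs(qhi - un[k, 1L]) < 1e-6 ||
                     (qhi >= un[k, 1L] - 1e-6 && qlo <= un[k, 2L] + 1e-6))
      if (!adjacent) next
      rlo <- min(seg$ref_start_bp, seg$ref_end_bp) - pa$realign_flank_bp
      rhi <- max(seg$ref_start_bp, seg$ref_end_bp) + pa$realign_flank_bp
      widx <- which(ref_map$positions >= rlo & ref_map$positions <= rhi)
      if (length(widx) < 2L) next
      aln <- fit_align(qpos, ref_map$positions[widx], params)
      if (is.null(aln)) next
      a_lo <- min(aln$ref_start_bp, aln$ref_end_bp)
      a_hi <- max(aln$ref_start_bp, aln$ref_end_bp)
      s_lo <- min(seg$ref_start_bp, seg$ref_end_bp)
      s_hi <- max(seg$ref_start_bp, seg$ref_end_bp)
      ov_lo <- max(a_lo, s_lo); ov_hi <- min(a_hi, s_hi)
      if (ov_hi > ov_lo) {
        evidence[[length(evidence) + 1L]] <- list(
          ref_id = ref_map$map_id, unit_start = ov_lo, unit_end = ov_hi,
          molecule_id = molecule$map_id, score = aln$confidence)
      }
    }
  }
  if (!length(evidence)) NULL else evidence
}
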