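#' Truth-matching criteria
#'
#' How calls are matched against simulator truth. Indels are label-resolution
#' calls: the reported enclosing (anchor-to-anchor) region localizes the
#' event, so an indel matches when one interval contains the other within
#' `breakpoint_tolerance_bp` slack and the sizes are compatible (within 30%
#' or `2 kb`, whichever is larger). Span types (inversion, duplication) match
#' by reciprocal overlap of at least `min_reciprocal_overlap`. Translocations
#' match by both break points within tolerance, ignoring span. All rules are
#' symmetric in calls and truth.
#'
#' @param breakpoint_tolerance_bp slack in bp (default 10 kb).
#' @param min_reciprocal_overlap reciprocal overlap for span types, in (0,1].
#' @param require_type_match require equal SV type.
#' @param require_zygosity_match additionally require equal zygosity
#'   (zygosity-aware evaluation mode).
#' @return list of class `match_criteria`.
#' @export
match_criteria <- function(breakpoint_tolerance_bp = 10000,
                           min_reciprocal_overlap = 0.5,
                           require_type_match = TRUE,
                           require_zygosity_match = FALSE) {
  stopifnot(breakpoint_tolerance_bp >= 0, min_reciprocal_overlap > 0,
            min_reciprocal_overlap <= 1)
  structure(list(breakpoint_tolerance_bp = breakpoint_tolerance_bp,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 require_type_match = require_type_match,
                 require_zygosity_match = require_zygosity_match),
            class = "match_criteria")
}

match_pair_ok <- function(type, cs, ce, csz, ts, te, tsz, crit) {
  tol <- crit$breakpoint_tolerance_bp
  if (type %in% c("insertion", "deletion")) {
    contained <- (ts >= cs - tol && te <= ce + tol) ||
      (cs >= ts - tol && ce <= te + tol)
    size_ok <- abs(csz - tsz) <= max(0.3 * max(csz, tsz), 2000)
    contained && size_ok
  } else if (type %in% c("inversion", "duplication")) {
    ov <- min(ce, te) - max(cs, ts)
    ov > 0 && ov / max(ce - cs, te - ts) >= crit$min_reciprocal_overlap
  } else { # translocations: both break points, span ignored
    abs(cs - ts) <= tol && abs(ce - te) <= tol
  }
}

#' Match SV calls against truth
#'
#' Greedy one-to-one bipartite matching by ascending break-point (midpoint)
#' distance: candidate pairs must be on the same chromosome, pass the
#' type-specific rule in [match_criteria()], match in type (when required)
#' and zygosity (when required). Greedy matching is deterministic; on small
#' instances it coincides with the optimal assignment (property-tested).
#'
#' @param calls data.table with columns `call_id`, `sv_type`, `ref_id`,
#'   `start_bp`, `end_bp`, `size_bp` and optionally `zygosity`.
#' @param truth data.table from [truth_table()] (columns `sv_id`, `sv_type`,
#'   `ref_id`, `start_bp`, `end_bp`, `size_bp`, `zygosity`).
#' @param criteria a [match_criteria()].
#' @return list: `tp` (data.table call_id/sv_id pairs), `fp` (call ids),
#'   `fn` (truth sv ids).
#' @export
match_calls <- function(calls, truth, criteria = match_criteria()) {
  calls <- data.table::as.data.table(calls)
  truth <- data.table::as.data.table(truth)
  nc <- nrow(calls); nt <- nrow(truth)
  if (nc == 0L || nt == 0L) {
    return(list(tp = data.table::data.table(call_id = character(),
                                            sv_id = character()),
                fp = if (nc) calls$call_id else character(),
                fn = if (nt) truth$sv_id else character()))
  }
  pairs <- list()
  for (i in seq_len(nc)) {
    for (j in seq_len(nt)) {
      if (calls$ref_id[i] != truth$ref_id[j]) next
      if (criteria$require_type_match &&
          calls$sv_type[i] != truth$sv_type[j]) next
      if (criteria$require_zygosity_match) {
        cz <- if ("zygosity" %in% names(calls)) calls$zygosity[i] else NA
        if (is.na(cz) || cz != truth$zygosity[j]) next
      }
      ty <- truth$sv_type[j]
      if (!match_pair_ok(ty, calls$start_bp[i], calls$end_bp[i],
                         calls$size_bp[i], truth$start_bp[j],
                         truth$end_bp[j], truth$size_bp[j], criteria)) next
      d <- abs((calls$start_bp[i] + calls$end_bp[i]) / 2 -
                 (truth$start_bp[j] + truth$end_bp[j]) / 2)
      pairs[[length(pairs) + 1L]] <- c(i = i, j = j, d = d)
    }
  }
  used_c <- logical(nc); used_t <- logical(nt)
  tp <- list()
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, "d"], pm[, "i"], pm[, "j"]), , drop = FALSE]
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, "i"]; j <- pm[k, "j"]
      if (used_c[i] || used_t[j]) next
      used_c[i] <- used_t[j] <- TRUE
      tp[[length(tp) + 1L]] <- data.table::data.table(
        call_id = calls$call_id[i], sv_id = truth$sv_id[j])
    }
  }
  list(tp = if (length(tp)) data.table::rbindlist(tp) else
    data.table::data.table(call_id = character(), sv_id = character()),
    fp = calls$call_id[!used_c], fn = truth$sv_id[!used_t])
}

#' Precision, recall and F1 from match counts
#'
#' Precision is the fraction of calls that are true, recall the fraction of
#' true SVs that are called. Undefined ratios (zero denominators) are
#' reported as `NA` — never as 0 by convention.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a call set against truth
#'
#' @param calls,truth,criteria as in [match_calls()].
#' @return list: `overall` (precision/recall/F1 + counts), `per_type`
#'   (data.table by sv_type), `matching` (the [match_calls()] result).
#' @export
evaluate_calls <- function(calls, truth, criteria = match_criteria()) {
  m <- match_calls(calls, truth, criteria)
  tp <- nrow(m$tp); fp <- length(m$fp); fn <- length(m$fn)
  overall <- c(precision_recall_f1(tp, fp, fn),
               list(tp = tp, fp = fp, fn = fn))
  truth <- data.table::as.data.table(truth)
  per_type <- truth[, {
    ids <- sv_id
    tpk <- sum(m$tp$sv_id %in% ids)
    fnk <- sum(m$fn %in% ids)
    calls_k <- data.table::as.data.table(calls)[sv_type == .BY$sv_type]
    fpk <- sum(m$fp %in% calls_k$call_id)
    pr <- precision_recall_f1(tpk, fpk, fnk)
    .(tp = tpk, fp = fpk, fn = fnk, precision = pr$precision,
      recall = pr$recall, f1 = pr$f1)
  }, by = sv_type]
  list(overall = overall, per_type = per_type, matching = m)
}

#' Stratify recall by clone of origin
#'
#' SVs introduced at different stages of the simulated evolution (germline,
#' trunk, sub-clones) have different expected support; this reports the
#' matching outcome per origin clone. Empty strata give `NA` metrics.
#'
#' @param matching a [match_calls()] result.
#' @param truth the truth table used for matching (with `origin_clone`).
#' @return data.table: `origin_clone`, `n`, `tp`, `fn`, `recall`.
#' @export
stratify_by_stage <- function(matching, truth) {
  truth <- data.table::as.data.table(truth)
  truth[, {
    tpk <- sum(matching$tp$sv_id %in% sv_id)
    fnk <- sum(matching$fn %in% sv_id)
    .(n = .N, tp = tpk, fn = fnk,
      recall = if (tpk + fnk > 0) tpk / (tpk + fnk) else NA_real_)
  }, by = origin_clone]
}
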