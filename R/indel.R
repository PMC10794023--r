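#' Normalize a molecule alignment for incomplete linearization
#'
#' Each molecule is stretched by an unknown per-molecule factor (incomplete
#' linearization in the nano-channel). The factor is estimated as the median
#' of per-interval observed/expected distance ratios over the aligned
#' intervals — the median makes it robust to a minority of intervals that are
#' genuinely abnormal (indels) — and all molecule distances are divided by
#' it, so the median residual ratio is exactly 1.
#'
#' @param alignment an [alignment_record()] with >= 3 site pairs.
#' @param molecule the molecule's [label_map()].
#' @param ref_map the reference [label_map()].
#' @return list: `alignment` (unchanged), `scale_factor`, `intervals` — a
#'   data.table of consecutive matched-site intervals with columns
#'   `ref_left_site`, `ref_right_site`, `observed_bp` (normalized),
#'   `expected_bp`, `ratio` — and `flagged` (TRUE when < 2 intervals made
#'   normalization impossible and distances were passed through raw).
#' @export
normalize_alignment <- function(alignment, molecule, ref_map) {
  sp <- alignment$site_pairs
  qpos <- molecule$positions[sp[, 2L]]
  rpos <- ref_map$positions[sp[, 1L]]
  obs <- abs(diff(qpos))
  expd <- diff(rpos)
  flagged <- length(obs) < 2L
  scale <- if (flagged) 1 else stats::median(obs / expd)
  if (!is.finite(scale) || scale <= 0) { scale <- 1; flagged <- TRUE }
  data.table::data.table(
    ref_left_site = sp[-nrow(sp), 1L], ref_right_site = sp[-1L, 1L],
    observed_bp = obs / scale, expected_bp = expd,
    ratio = (obs / scale) / expd
  ) -> intervals
  list(alignment = alignment, scale_factor = scale, intervals = intervals,
       flagged = flagged)
}

is_abnormal <- function(observed, expected, cfg) {
  abs(observed - expected) > pmax(cfg$abs_threshold_bp,
                                  cfg$rel_threshold * expected)
}

#' Arbitrate abnormal label pairs across molecules
#'
#' The cross-molecule arbitration step: an interval whose normalized
#' observed distance deviates from the reference by more than
#' `max(abs_threshold_bp, rel_threshold * expected)` is abnormal. Abnormal
#' intervals at the same reference site pair are mutually reinforcing when at
#' least `min_support` molecules deviate with the same sign and consistent
#' magnitude (within `magnitude_tolerance_bp` of their median): these become
#' indel candidates. An abnormal observation unsupported by any other
#' molecule while >= `min_normal` molecules are normal there is treated as an
#' alignment/sizing error and corrected to the consensus (median) distance.
#' A molecule whose alignment has more than `max_abnormal_frac` abnormal
#' intervals that are not part of any candidate group is considered
#' mis-aligned and discarded entirely.
#'
#' @param pair_table data.table of per-molecule intervals: `molecule_id`,
#'   `ref_id`, `ref_left_site`, `ref_right_site`, `observed_bp`,
#'   `expected_bp` (build from [normalize_alignment()] results).
#' @param config an [om_config()] list (uses the `indel` group).
#' @return the table with added columns `abnormal`, `verdict`
#'   (`normal`/`candidate`/`corrected`/`alignment_discarded`/`deferred`) and
#'   `corrected_bp` (consensus value for corrected rows, otherwise
#'   `observed_bp`).
#' @export
arbitrate_abnormal_pairs <- function(pair_table, config = om_config()) {
  cfg <- config$indel
  pt <- data.table::as.data.table(pair_table)
  pt[, abnormal := is_abnormal(observed_bp, expected_bp, cfg)]
  pt[, deviation := observed_bp - expected_bp]
  pt[, verdict := "normal"]
  pt[, corrected_bp := observed_bp]
  pt[, `:=`(n_at = .N, n_abn = sum(abnormal)),
     by = .(ref_id, ref_left_site, ref_right_site)]
  # low-coverage loci: defer all verdicts
  pt[n_at < cfg$min_coverage, verdict := "deferred"]
  grp <- pt[verdict != "deferred" & abnormal,
            .(molecule_id, ref_id, ref_left_site, ref_right_site, deviation)]
  if (nrow(grp)) {
    grp[, sign_dev := sign(deviation)]
    grp[, med_dev := stats::median(deviation), by = .(ref_id, ref_left_site,
                                                      ref_right_site, sign_dev)]
    grp[, consistent := abs(deviation - med_dev) <= cfg$magnitude_tolerance_bp]
    grp[, n_consistent := sum(consistent), by = .(ref_id, ref_left_site,
                                                  ref_right_site, sign_dev)]
    grp[, is_candidate := consistent & n_consistent >= cfg$min_support]
    pt[grp, on = .(molecule_id, ref_id, ref_left_site, ref_right_site),
       `:=`(is_candidate = i.is_candidate, n_consistent = i.n_consistent)]
  }
  if (!"is_candidate" %in% names(pt)) pt[, is_candidate := FALSE]
  if (!"n_consistent" %in% names(pt)) pt[, n_consistent := 0L]
  pt[is.na(is_candidate), is_candidate := FALSE]
  pt[is.na(n_consistent), n_consistent := 0L]
  pt[verdict != "deferred" & abnormal & is_candidate, verdict := "candidate"]
  # isolated abnormal pair among enough normal molecules -> corrected
  pt[, n_normal := sum(!abnormal), by = .(ref_id, ref_left_site, ref_right_site)]
  iso <- pt$verdict != "deferred" & pt$abnormal & !pt$is_candidate &
    pt$n_abn == 1L & pt$n_normal >= cfg$min_normal
  if (any(iso)) {
    pt[, consensus_bp := stats::median(observed_bp[!abnormal]),
       by = .(ref_id, ref_left_site, ref_right_site)]
    pt[iso, `:=`(verdict = "corrected", corrected_bp = consensus_bp)]
    pt[, consensus_bp := NULL]
  }
  # molecules dominated by unexplained abnormality -> alignment discarded
  mol <- pt[verdict != "deferred",
            .(frac_bad = mean(abnormal & !is_candidate)), by = molecule_id]
  bad <- mol[frac_bad > cfg$max_abnormal_frac, molecule_id]
  if (length(bad)) pt[molecule_id %in% bad, verdict := "alignment_discarded"]
  pt[]
}

#' Group candidate pairs into candidate indel regions
#'
#' Overlapping candidate reference intervals (in site-index space) are merged
#' by interval union into candidate regions; each candidate pair belongs to
#' exactly one region. The region's anchors are then pulled outward to the
#' nearest flanking sites at which at least `anchor_min_frac` of the
#' molecules spanning the region have a matched label, so that molecules
#' missing the labels nearest the break points still contribute a spanning
#' (anchor-to-anchor) observation.
#'
#' @param pair_table arbitration output ([arbitrate_abnormal_pairs()]); rows
#'   with verdict `alignment_discarded` are ignored.
#' @param config an [om_config()] list.
#' @return data.table of regions: `region_id`, `ref_id`, `anchor_left_site`,
#'   `anchor_right_site`, `n_member_pairs`.
#' @export
build_candidate_regions <- function(pair_table, config = om_config()) {
  cfg <- config$indel
  pt <- data.table::as.data.table(pair_table)
  cand <- pt[verdict == "candidate"]
  if (!nrow(cand)) {
    return(data.table::data.table(region_id = integer(), ref_id = character(),
                                  anchor_left_site = integer(),
                                  anchor_right_site = integer(),
                                  n_member_pairs = integer()))
  }
  usable <- pt[verdict != "alignment_discarded"]
  regions <- list()
  for (rid in unique(cand$ref_id)) {
    cc <- cand[ref_id == rid]
    ivs <- unique(cc[, .(ref_left_site, ref_right_site)])
    data.table::setorder(ivs, ref_left_site, ref_right_site)
    # interval union in site space (shared endpoint sites count as overlap)
    grp <- integer(nrow(ivs)); g <- 0L; hi <- -Inf
    for (i in seq_len(nrow(ivs))) {
      if (ivs$ref_left_site[i] > hi) { g <- g + 1L; hi <- ivs$ref_right_site[i] }
      grp[i] <- g
      hi <- max(hi, ivs$ref_right_site[i])
    }
    ivs[, grp := grp]
    mol_sites <- usable[ref_id == rid,
                        .(lo = min(ref_left_site), hi = max(ref_right_site)),
                        by = molecule_id]
    site_cov <- usable[ref_id == rid]
    for (gg in unique(grp)) {
      span <- ivs[grp == gg]
      left <- min(span$ref_left_site); right <- max(span$ref_right_site)
      spanning <- mol_sites[lo <= left & hi >= right]
      n_span <- nrow(spanning)
      # pull anchors outward until enough spanning molecules match the site
      matched_frac <- function(site) {
        if (n_span == 0L) return(1)
        has <- site_cov[molecule_id %in% spanning$molecule_id &
                          (ref_left_site == site | ref_right_site == site),
                        data.table::uniqueN(molecule_id)]
        has / n_span
      }
      aleft <- left
      while (aleft > 1L && matched_frac(aleft) < cfg$anchor_min_frac) {
        aleft <- aleft - 1L
      }
      aright <- right
      max_site <- max(site_cov$ref_right_site)
      while (aright < max_site && matched_frac(aright) < cfg$anchor_min_frac) {
        aright <- aright + 1L
      }
      regions[[length(regions) + 1L]] <- data.table::data.table(
        ref_id = rid, anchor_left_site = aleft, anchor_right_site = aright,
        n_member_pairs = nrow(cc[ref_left_site >= left & ref_right_site <= right]))
    }
  }
  out <- data.table::rbindlist(regions)
  data.table::setorder(out, ref_id, anchor_left_site)
  out[, region_id := .I]
  out[]
}

#' Spanning inter-anchor observations for a region
#'
#' Computes, for every molecule whose (non-discarded) alignment matches both
#' anchor sites, the normalized distance between the anchors — including
#' molecules whose inner labels are unmatched.
#'
#' @param region one row of [build_candidate_regions()] output.
#' @param norm_alignments list of [normalize_alignment()] results, with the
#'   molecule id stored in `alignment$query_id`.
#' @param ref_map reference [label_map()] of the region's chromosome.
#' @param discarded character vector of molecule ids to exclude.
#' @return data.table: `molecule_id`, `observed_bp`, `confidence`;
#'   `expected_bp` in attribute `"expected_bp"`.
#' @export
region_spanning_observations <- function(region, norm_alignments, ref_map,
                                         discarded = character()) {
  aL <- region$anchor_left_site; aR <- region$anchor_right_site
  rows <- list()
  for (na in norm_alignments) {
    al <- na$alignment
    if (al$ref_id != region$ref_id) next
    if (al$query_id %in% discarded) next
    sp <- al$site_pairs
    iL <- match(aL, sp[, 1L]); iR <- match(aR, sp[, 1L])
    if (is.na(iL) || is.na(iR)) next
    obs <- abs(na$molecule_positions[sp[iR, 2L]] -
                 na$molecule_positions[sp[iL, 2L]]) / na$scale_factor
    rows[[length(rows) + 1L]] <- data.table::data.table(
      molecule_id = al$query_id, observed_bp = obs,
      confidence = al$confidence)
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else {
    data.table::data.table(molecule_id = character(), observed_bp = numeric(),
                           confidence = numeric())
  }
  data.table::setattr(out, "expected_bp",
                      ref_map$positions[aR] - ref_map$positions[aL])
  out
}

#' Cluster inter-anchor distances
#'
#' One-dimensional model-based clustering of the pooled spanning distances
#' with no prior on cluster proportions (the fraction of SV-supporting
#' molecules is unknown in a cancer mixture). Gaussian clusters in one
#' dimension are contiguous in sorted order, so the search enumerates all
#' ordered partitions of the sorted values into k in {1,2,3} blocks,
#' scoring each by a BIC-penalized Gaussian log-likelihood
#' (`sum_c -n_c/2 (log(2 pi sigma_c^2) + 1) - k log(n)`, sd floored at
#' `sigma_floor_bp`) and keeping only partitions whose blocks have at least
#' `min_cluster_size` members and whose adjacent means are at least
#' `min_separation_bp` apart; infeasible splits are effectively merged.
#' Ties break toward fewer clusters, then the earlier split.
#'
#' @param observations numeric vector of spanning distances (bp).
#' @param config an [om_config()] list.
#' @return list of class `distance_clustering`: `clusters` (data.table:
#'   `mean_bp`, `sd_bp`, `n`, and `members` list of observation indices),
#'   `chosen_k`, `criterion_values` (named by k), `assignment` (cluster index
#'   per observation).
#' @export
cluster_distances <- function(observations, config = om_config()) {
  cfg <- config$indel
  x <- as.numeric(observations)
  n <- length(x)
  if (n == 0L) stop("no observations to cluster")
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  block <- function(i, j) { # stats of xs[i..j]
    m <- j - i + 1L
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    mu <- s / m
    var <- max(s2 / m - mu^2, 0)
    sd <- max(sqrt(var), cfg$sigma_floor_bp)
    ll <- -m / 2 * (log(2 * pi * sd^2) + 1)
    list(mu = mu, sd = sd, n = m, ll = ll)
  }
  score_partition <- function(cuts) { # cuts: last index of each block but the final
    bounds <- c(0L, cuts, n)
    k <- length(bounds) - 1L
    blocks <- vector("list", k)
    for (b in seq_len(k)) {
      i <- bounds[b] + 1L; j <- bounds[b + 1L]
      if (j - i + 1L < cfg$min_cluster_size && k > 1L) return(NULL)
      blocks[[b]] <- block(i, j)
    }
    mus <- vapply(blocks, `[[`, numeric(1), "mu")
    if (k > 1L && any(diff(mus) < cfg$min_separation_bp)) return(NULL)
    ll <- sum(vapply(blocks, `[[`, numeric(1), "ll"))
    list(crit = ll - k * log(n), blocks = blocks, cuts = cuts)
  }
  best <- score_partition(integer(0))
  crit_values <- c(`1` = best$crit)
  best_k <- 1L
  if (n >= 2L * cfg$min_cluster_size) {
    bk2 <- NULL
    for (c1 in seq_len(n - 1L)) {
      p <- score_partition(c1)
      if (!is.null(p) && (is.null(bk2) || p$crit > bk2$crit + 1e-9)) bk2 <- p
    }
    if (!is.null(bk2)) {
      crit_values <- c(crit_values, `2` = bk2$crit)
      if (bk2$crit > best$crit + 1e-9) { best <- bk2; best_k <- 2L }
    }
  }
  if (n >= 3L * cfg$min_cluster_size) {
    bk3 <- NULL
    for (c1 in seq_len(n - 2L)) {
      for (c2 in seq.int(c1 + 1L, n - 1L)) {
        p <- score_partition(c(c1, c2))
        if (!is.null(p) && (is.null(bk3) || p$crit > bk3$crit + 1e-9)) bk3 <- p
      }
    }
    if (!is.null(bk3)) {
      crit_values <- c(crit_values, `3` = bk3$crit)
      if (bk3$crit > best$crit + 1e-9) { best <- bk3; best_k <- 3L }
    }
  }
  bounds <- c(0L, best$cuts, n)
  assignment_sorted <- rep(seq_len(best_k), diff(bounds))
  assignment <- integer(n)
  assignment[o] <- assignment_sorted
  clusters <- data.table::data.table(
    mean_bp = vapply(best$blocks, `[[`, numeric(1), "mu"),
    sd_bp = vapply(best$blocks, `[[`, numeric(1), "sd"),
    n = vapply(best$blocks, `[[`, numeric(1), "n"))
  clusters[, members := lapply(seq_len(best_k), function(b) which(assignment == b))]
  structure(list(clusters = clusters, chosen_k = best_k,
                 criterion_values = crit_values, assignment = assignment),
            class = "distance_clustering")
}

#' Call an indel from a region's distance clustering
#'
#' A cluster is a variant allele when its mean differs from the expected
#' inter-anchor distance by at least `min_indel_size`; larger means are
#' insertions, smaller are deletions. Zygosity follows the cluster structure:
#' a variant cluster alongside a reference-like cluster is heterozygous; a
#' single all-molecule variant cluster is homozygous (labeled `unknown` below
#' `hom_af_threshold` support — in a cancer mixture a shifted minority
#' cluster with no reference companion cannot be phased); two variant
#' clusters with no reference-like cluster are a variant-only diploid (hom);
#' three clusters are multi-allelic. The allele fraction is always reported
#' from cluster sizes — never assumed from zygosity.
#'
#' @param region one row of [build_candidate_regions()] output.
#' @param clustering a [cluster_distances()] result for the region.
#' @param expected_bp expected inter-anchor distance on the reference.
#' @param config an [om_config()] list.
#' @param mean_confidence mean alignment confidence of supporting molecules
#'   (carried into the call for scoring).
#' @return data.table of calls (possibly several for multi-allelic regions;
#'   zero rows when no variant cluster), columns: `sv_type`, `zygosity`,
#'   `ref_id`, `anchor_left_site`, `anchor_right_site`, `size_bp`,
#'   `support`, `total`, `allele_fraction`, `separation`, `mean_confidence`.
#' @export
call_indel <- function(region, clustering, expected_bp, config = om_config(),
                       mean_confidence = 0) {
  cfg <- config$indel
  cl <- data.table::copy(clustering$clusters)
  # clusters whose means differ by less than the minimum callable indel size
  # cannot represent distinct alleles: collapse them (guards against sizing-
  # noise tail splits inflating multi-allelic labels)
  repeat {
    if (nrow(cl) < 2L) break
    gaps <- diff(cl$mean_bp)
    k <- which(gaps < cfg$min_indel_size)
    if (!length(k)) break
    i <- k[1L]
    n2 <- cl$n[i] + cl$n[i + 1L]
    mu <- (cl$mean_bp[i] * cl$n[i] + cl$mean_bp[i + 1L] * cl$n[i + 1L]) / n2
    sd2 <- sqrt((cl$n[i] * cl$sd_bp[i]^2 + cl$n[i + 1L] * cl$sd_bp[i + 1L]^2) / n2)
    cl <- rbind(
      if (i > 1L) cl[seq_len(i - 1L)],
      data.table::data.table(mean_bp = mu, sd_bp = sd2, n = n2,
                             members = list(sort(unlist(cl$members[i:(i + 1L)])))),
      if (i + 1L < nrow(cl)) cl[seq.int(i + 2L, nrow(cl))])
  }
  total <- sum(cl$n)
  variant <- abs(cl$mean_bp - expected_bp) >= cfg$min_indel_size
  if (!any(variant)) {
    return(data.table::data.table())
  }
  k <- nrow(cl); has_ref <- any(!variant)
  vc <- sum(variant)
  zyg <- if (vc == 1L && has_ref) "het"
  else if (vc == 1L && !has_ref) {
    if (cl$n[variant] / total >= cfg$hom_af_threshold) "hom" else "unknown"
  } else if (!has_ref && vc == 2L) "hom"
  else "multi-allelic"
  pooled_sd <- sqrt(stats::weighted.mean(cl$sd_bp^2, cl$n))
  rows <- lapply(which(variant), function(b) {
    sep <- if (k == 1L) Inf else {
      min(abs(cl$mean_bp[b] - cl$mean_bp[-b])) / max(pooled_sd, 1)
    }
    data.table::data.table(
      sv_type = if (cl$mean_bp[b] > expected_bp) "insertion" else "deletion",
      zygosity = zyg, ref_id = region$ref_id,
      anchor_left_site = region$anchor_left_site,
      anchor_right_site = region$anchor_right_site,
      size_bp = abs(cl$mean_bp[b] - expected_bp),
      support = cl$n[b], total = total,
      allele_fraction = cl$n[b] / total,
      separation = sep, mean_confidence = mean_confidence)
  })
  data.table::rbindlist(rows)
}

#' Post-process raw indel calls into the final scored set
#'
#' Calls of the same type whose enclosing regions reciprocally overlap by at
#' least `merge_overlap_frac` are merged (support-weighted consensus span and
#' size; supports summed); each call then receives a confidence in `[0,1]`
#' from a logistic model over interpretable features — log2 support, allele
#' fraction, cluster separation in pooled-sd units (capped at 10), mean
#' alignment confidence of the supporting molecules, and local coverage
#' relative to the genome median — and calls below `report_threshold` are
#' dropped. Weights live in the configuration and can be re-fit on a labeled
#' truth set with standard logistic regression; the defaults are hand-set so
#' that single-molecule calls fall below the threshold.
#'
#' @param calls data.table of raw calls with region coordinates in bp
#'   (`start_bp`, `end_bp` = anchor positions).
#' @param config an [om_config()] list.
#' @return the filtered, scored calls, ordered by (ref_id, start_bp), with
#'   `confidence` and `call_id` columns.
#' @export
postprocess_calls <- function(calls, config = om_config()) {
  cfg <- config$indel
  if (!nrow(calls)) {
    calls[, `:=`(confidence = numeric(0), call_id = character(0))]
    return(calls[])
  }
  ct <- data.table::copy(calls)
  data.table::setorder(ct, ref_id, sv_type, start_bp)
  # merge reciprocal-overlap duplicates of the same type (greedy chain)
  grp <- integer(nrow(ct)); g <- 0L
  for (i in seq_len(nrow(ct))) {
    if (i == 1L || ct$ref_id[i] != ct$ref_id[i - 1L] ||
        ct$sv_type[i] != ct$sv_type[i - 1L]) {
      g <- g + 1L; grp[i] <- g; next
    }
    a <- c(ct$start_bp[i - 1L], ct$end_bp[i - 1L])
    b <- c(ct$start_bp[i], ct$end_bp[i])
    ov <- min(a[2L], b[2L]) - max(a[1L], b[1L])
    ro <- ov / max(a[2L] - a[1L], b[2L] - b[1L])
    if (ov > 0 && ro >= cfg$merge_overlap_frac) grp[i] <- g
    else { g <- g + 1L; grp[i] <- g }
  }
  ct[, mrg_grp := grp]
  merged <- ct[, .(
    ref_id = ref_id[1L], sv_type = sv_type[1L],
    zygosity = zygosity[which.max(support)],
    start_bp = stats::weighted.mean(start_bp, support),
    end_bp = stats::weighted.mean(end_bp, support),
    size_bp = stats::weighted.mean(size_bp, support),
    support = sum(support), total = max(total),
    allele_fraction = sum(support) / max(total),
    separation = max(separation),
    mean_confidence = stats::weighted.mean(mean_confidence, support)
  ), by = mrg_grp][, mrg_grp := NULL]
  med_cov <- stats::median(merged$total)
  w <- cfg$confidence_weights
  eta <- w[["intercept"]] +
    w[["log2_support"]] * log2(pmax(merged$support, 1)) +
    w[["allele_fraction"]] * merged$allele_fraction +
    w[["separation"]] * pmin(merged$separation, 10) +
    w[["aln_confidence"]] * merged$mean_confidence +
    w[["rel_coverage"]] * merged$total / max(med_cov, 1)
  merged[, confidence := stats::plogis(eta)]
  merged <- merged[confidence >= cfg$report_threshold]
  data.table::setorder(merged, ref_id, start_bp)
  merged[, call_id := sprintf("indel_%d", .I)]
  merged[]
}

#' Run the full indel pipeline
#'
#' The four steps in sequence: (1) per-molecule normalization of inter-label
#' distances and cross-molecule arbitration of abnormal pairs; (2) merging of
#' mutually reinforcing candidate pairs into candidate regions with pooled
#' inter-anchor distances; (3) constrained 1-D clustering of each region's
#' distances and initial typing; (4) redundancy removal and confidence
#' scoring.
#'
#' @param alignments list of [alignment_record()] (one or more per molecule;
#'   only records with >= 3 site pairs enter normalization).
#' @param molecules list of molecule [label_map()] (ids must match
#'   `query_id`s).
#' @param ref_genome named list of reference [label_map()].
#' @param config an [om_config()] list.
#' @return list: `calls` (final scored calls), `regions`, `pair_table`
#'   (arbitration verdicts), `stats` (per-step counts).
#' @export
call_indels <- function(alignments, molecules, ref_genome,
                        config = om_config()) {
  cfg <- config$indel
  mol_by_id <- stats::setNames(molecules,
                               vapply(molecules, function(m) m$map_id,
                                      character(1)))
  norm <- list(); pair_rows <- list()
  for (al in alignments) {
    if (nrow(al$site_pairs) < 3L) next
    mol <- mol_by_id[[al$query_id]]
    ref <- ref_genome[[al$ref_id]]
    if (is.null(mol) || is.null(ref)) next
    na <- normalize_alignment(al, mol, ref)
    na$molecule_positions <- mol$positions
    norm[[length(norm) + 1L]] <- na
    iv <- na$intervals
    iv[, `:=`(molecule_id = al$query_id, ref_id = al$ref_id)]
    pair_rows[[length(pair_rows) + 1L]] <- iv
  }
  if (!length(pair_rows)) {
    return(list(calls = data.table::data.table(), regions = NULL,
                pair_table = NULL,
                stats = list(n_alignments = length(alignments), n_used = 0)))
  }
  pair_table <- data.table::rbindlist(pair_rows)
  pair_table <- arbitrate_abnormal_pairs(pair_table, config)
  discarded <- unique(pair_table[verdict == "alignment_discarded", molecule_id])
  regions <- build_candidate_regions(pair_table, config)
  calls <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i]
    ref <- ref_genome[[region$ref_id]]
    obs <- region_spanning_observations(region, norm, ref, discarded)
    if (nrow(obs) < cfg$min_coverage) next
    clustering <- cluster_distances(obs$observed_bp, config)
    expd <- attr(obs, "expected_bp")
    # restrict support counting / confidence to the variant cluster members
    cl_calls <- call_indel(region, clustering, expd, config,
                           mean_confidence = mean(obs$confidence))
    if (!nrow(cl_calls)) next
    cl_calls[, `:=`(start_bp = ref$positions[region$anchor_left_site],
                    end_bp = ref$positions[region$anchor_right_site],
                    region_id = region$region_id)]
    calls[[length(calls) + 1L]] <- cl_calls
  }
  raw <- if (length(calls)) data.table::rbindlist(calls) else
    data.table::data.table(ref_id = character(), sv_type = character(),
                           zygosity = character(), start_bp = numeric(),
                           end_bp = numeric(), size_bp = numeric(),
                           support = integer(), total = integer(),
                           allele_fraction = numeric(),
                           separation = numeric(),
                           mean_confidence = numeric())
  final <- postprocess_calls(raw, config)
  list(calls = final, regions = regions, pair_table = pair_table,
       stats = list(n_alignments = length(alignments), n_used = length(norm),
                    n_discarded = length(discarded),
                    n_corrected = sum(pair_table$verdict == "corrected"),
                    n_candidate_pairs = sum(pair_table$verdict == "candidate"),
                    n_regions = nrow(regions), n_raw_calls = nrow(raw),
                    n_final_calls = nrow(final)))
}
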