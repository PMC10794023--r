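#' Default pipeline configuration
#'
#' Returns the full configuration tree used by the simulator, the aligner and
#' both calling pipelines. Every threshold the pipelines use lives here so a
#' run is fully described by one object. Pass overrides as a nested list;
#' unnamed defaults are kept.
#'
#' Key groups:
#' \describe{
#'   \item{digest}{`collapse_bp`: labels closer than this are merged to their
#'     midpoint (sub-resolution; two strands of a palindromic site label ~1 bp
#'     apart).}
#'   \item{align}{fit-aligner scoring (see [scoring_params()]).}
#'   \item{indel}{arbitration thresholds, clustering constraints, call-time
#'     minima and confidence-model weights for the indel pipeline.}
#'   \item{complexsv}{junction classification and break-point consolidation
#'     thresholds.}
#'   \item{evaluate}{default truth-matching criteria.}
#'   \item{simulate}{noise model and scenario defaults.}
#' }
#'
#' @param ... named overrides, e.g. `om_config(indel = list(min_support = 5))`.
#' @return nested list of configuration values.
#' @export
om_config <- function(...) {
  defaults <- list(
    digest = list(
      collapse_bp = 1.5
    ),
    bnx = list(
      min_molecule_length = 50000
    ),
    align = list(
      match_reward = 3,
      missed_ref_label_penalty = 1,
      false_molecule_label_penalty = 1,
      sizing_error_scale = 10,
      min_segment_score = 8,
      band_max_skips = 3,
      # tandem-dup rescue
      realign_min_labels = 4,
      realign_flank_bp = 50000,
      realign_min_score = 8
    ),
    indel = list(
      abs_threshold_bp = 1500,
      rel_threshold = 0.05,
      magnitude_tolerance_bp = 2000,
      min_support = 3,
      min_normal = 3,
      max_abnormal_frac = 0.5,
      min_coverage = 8,
      anchor_min_frac = 0.5,
      max_region_bp = 300000,
      min_cluster_size = 3,
      min_separation_bp = 1500,
      sigma_floor_bp = 150,
      min_indel_size = 2000,
      hom_af_threshold = 0.85,
      merge_overlap_frac = 0.5,
      report_threshold = 0.5,
      confidence_weights = c(
        intercept = -2.5,
        log2_support = 1.5,
        allele_fraction = 1.0,
        separation = 0.1,
        aln_confidence = 0.02,
        rel_coverage = 0.2
      )
    ),
    complexsv = list(
      indel_handoff_bp = 50000,
      tra_intra_min_bp = 1e6,
      dup_min_overlap_labels = 2,
      query_overlap_slack_bp = 10000,
      merge_window_bp = 30000,
      min_bp_support = 3,
      full_span_flank_bp = 10000,
      dedup_size_tol = 0.5
    ),
    evaluate = list(
      breakpoint_tolerance_bp = 10000,
      min_reciprocal_overlap = 0.5,
      require_type_match = TRUE,
      require_zygosity_match = FALSE
    ),
    simulate = list(
      label_density_per_100kb = 16, # DLE-1-like; Nt.BspQI-like would be ~10
      noise = list(
        sizing_sd_per_kb = 100,     # bp of sd per sqrt(kb) of true distance
        stretch_range = c(0.95, 1.05),
        label_miss_prob = 0.1,
        false_label_rate = 1,       # expected false labels per 100 kb
        length_meanlog = log(2e5),
        length_sdlog = 0.35,
        min_molecule_length = 1e5,
        reverse_prob = 0,
        chimera_rate = 0
      ),
      coverage = 100,
      svs_per_stage = 50,
      indel_size_range = c(2000, 200000), # log-uniform
      seed = 1L
    )
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  merge_cfg(defaults, overrides)
}

# recursive modifyList that refuses unknown keys (catches typos in configs)
merge_cfg <- function(base, override) {
  if (length(override) == 0L) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "")) {
    stop("configuration overrides must be named")
  }
  for (nm in nms) {
    if (!nm %in% names(base)) {
      stop(sprintf("unknown configuration key: '%s'", nm))
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_cfg(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
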