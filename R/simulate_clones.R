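#' Cancer clone evolution graph
#'
#' The benchmark's four-population design: normal cells (`sample1`,
#' carrying germline SVs), trunk cancer cells (`sample2`, inheriting
#' `sample1`'s SVs plus private somatic ones) and two sub-clones (`sample3`,
#' `sample4`) inheriting the trunk's SVs plus their own. A configurable
#' fraction of trunk SVs may be lost in each sub-clone (default 0), matching
#' "most" rather than "all" inheritance.
#'
#' @param germline,trunk,subclone1,subclone2 lists of [sv_event()] private to
#'   each stage. Events should carry the matching `origin_clone` tag
#'   (`sample1` ... `sample4`); it is stamped if missing.
#' @param trunk_loss_frac fraction of trunk SVs each sub-clone loses.
#' @param seed RNG seed for the loss draw.
#' @return object of class `clone_graph` with `clones`: a named list of
#'   `list(parent, private, lost)`.
#' @export
clone_graph <- function(germline = list(), trunk = list(),
                        subclone1 = list(), subclone2 = list(),
                        trunk_loss_frac = 0, seed = 1L) {
  stamp <- function(evs, clone) lapply(evs, function(e) {
    e$origin_clone <- clone; e
  })
  germline <- stamp(germline, "sample1")
  trunk <- stamp(trunk, "sample2")
  subclone1 <- stamp(subclone1, "sample3")
  subclone2 <- stamp(subclone2, "sample4")
  lose <- function(evs) {
    if (trunk_loss_frac <= 0 || !length(evs)) return(character())
    set.seed(seed)
    ids <- vapply(evs, function(e) e$sv_id, character(1))
    sample(ids, size = floor(trunk_loss_frac * length(ids)))
  }
  structure(list(clones = list(
    sample1 = list(parent = NA_character_, private = germline,
                   lost = character()),
    sample2 = list(parent = "sample1", private = trunk, lost = character()),
    sample3 = list(parent = "sample2", private = subclone1,
                   lost = lose(trunk)),
    sample4 = list(parent = "sample2", private = subclone2,
                   lost = lose(trunk))
  )), class = "clone_graph")
}

#' Per-clone SV sets along the evolution graph
#'
#' @param graph a [clone_graph()].
#' @return named list: for each clone, the list of [sv_event()] it carries
#'   (inherited along the parent path minus losses, plus private).
#' @export
clone_sv_sets <- function(graph) {
  out <- list()
  resolve <- function(clone) {
    if (!is.null(out[[clone]])) return(out[[clone]])
    node <- graph$clones[[clone]]
    inherited <- if (is.na(node$parent)) list() else resolve(node$parent)
    if (length(node$lost)) {
      inherited <- Filter(function(e) !e$sv_id %in% node$lost, inherited)
    }
    res <- c(inherited, node$private)
    out[[clone]] <<- res
    res
  }
  for (clone in names(graph$clones)) resolve(clone)
  out[names(graph$clones)]
}

#' Build diploid clone genomes from a clone graph
#'
#' Heterozygous events are placed on their assigned haplotype, homozygous
#' events on both; inheritance is implicit in [clone_sv_sets()] so a trunk SV
#' appears identically (same haplotype, same inserted label pattern) in both
#' sub-clones.
#'
#' @param ref_genome named list of reference [label_map()].
#' @param graph a [clone_graph()].
#' @return named list: per clone, `list(hap1, hap2)` where each haplotype is
#'   the result of [apply_svs_to_genome()].
#' @export
build_clone_genomes <- function(ref_genome, graph) {
  sets <- clone_sv_sets(graph)
  lapply(sets, function(svs) {
    on_hap <- function(h) Filter(function(e)
      e$zygosity == "hom" || e$haplotype == h, svs)
    list(hap1 = apply_svs_to_genome(ref_genome, on_hap(1L)),
         hap2 = apply_svs_to_genome(ref_genome, on_hap(2L)))
  })
}

#' Cell mixture specification
#'
#' @param proportions named numeric vector, clone -> fraction; must be
#'   non-negative and sum to 1 (within 1e-9).
#' @param chrom_dosage optional data.frame `(clone, chrom, multiplier)` of
#'   per-chromosome copy multipliers (whole-arm aneuploidy); affects both
#'   molecule sampling weights and expected support fractions.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(proportions, chrom_dosage = NULL) {
  if (is.null(names(proportions)) || any(names(proportions) == "")) {
    stop("proportions must be a named vector")
  }
  if (any(proportions < 0)) stop("proportions must be >= 0")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (sum(proportions) <= 0) stop("mixture has zero mass")
  structure(list(proportions = proportions, chrom_dosage = chrom_dosage),
            class = "mixture_spec")
}

#' Benchmark mixture presets
#'
#' `sample5`: high tumor content (70% cancer cells: trunk 30%, each sub-clone
#' 20%). `sample6`: low tumor content, one sub-clone (normal 70%, trunk 15%,
#' sub-clone1 15%). `sample7`: low tumor content, two sub-clones (normal 70%,
#' trunk 10%, each sub-clone 10%).
#'
#' @param name `"sample5"`, `"sample6"` or `"sample7"`.
#' @return a [mixture_spec()].
#' @export
mixture_preset <- function(name = c("sample5", "sample6", "sample7")) {
  name <- match.arg(name)
  p <- switch(name,
    sample5 = c(sample1 = 0.30, sample2 = 0.30, sample3 = 0.20, sample4 = 0.20),
    sample6 = c(sample1 = 0.70, sample2 = 0.15, sample3 = 0.15),
    sample7 = c(sample1 = 0.70, sample2 = 0.10, sample3 = 0.10, sample4 = 0.10))
  mixture_spec(p)
}

dosage_multiplier <- function(mixture, clone, chrom) {
  cd <- mixture$chrom_dosage
  if (is.null(cd)) return(1)
  hit <- cd$clone == clone & cd$chrom == chrom
  if (any(hit)) cd$multiplier[which(hit)[1L]] else 1
}

#' Ground-truth table for a clone graph under a mixture
#'
#' For every distinct SV in the graph, computes the expected fraction of
#' molecules at its locus that support the SV allele:
#' \deqn{f = \frac{\sum_c \pi_c m_c d_c / 2}{\sum_c \pi_c m_c}}
#' where \eqn{\pi_c} is the clone fraction, \eqn{m_c} its local copy
#' multiplier and \eqn{d_c \in \{0,1,2\}} the number of haplotypes of clone
#' \eqn{c} carrying the SV.
#'
#' @param graph a [clone_graph()].
#' @param mixture a [mixture_spec()]; clones absent from it have fraction 0.
#' @return data.table with one row per SV: sv_id, sv_type, ref_id, start_bp,
#'   end_bp, size_bp, dest_ref_id, dest_bp, zygosity, origin_clone,
#'   expected_support_fraction.
#' @export
truth_table <- function(graph, mixture) {
  sets <- clone_sv_sets(graph)
  all_svs <- list()
  for (clone in names(sets)) for (e in sets[[clone]]) {
    if (is.null(all_svs[[e$sv_id]])) all_svs[[e$sv_id]] <- e
  }
  carriers <- lapply(sets, function(evs)
    vapply(evs, function(e) e$sv_id, character(1)))
  pi_c <- mixture$proportions
  rows <- lapply(all_svs, function(e) {
    num <- 0; den <- 0
    for (clone in names(graph$clones)) {
      p <- if (clone %in% names(pi_c)) pi_c[[clone]] else 0
      if (p <= 0) next
      m <- dosage_multiplier(mixture, clone, e$ref_id)
      d <- if (e$sv_id %in% carriers[[clone]]) {
        if (e$zygosity == "hom") 2 else 1
      } else 0
      num <- num + p * m * d / 2
      den <- den + p * m
    }
    data.table::data.table(
      sv_id = e$sv_id, sv_type = e$sv_type, ref_id = e$ref_id,
      start_bp = e$start_bp, end_bp = e$end_bp, size_bp = e$size_bp,
      dest_ref_id = e$dest_ref_id, dest_bp = e$dest_bp,
      zygosity = e$zygosity, origin_clone = e$origin_clone,
      expected_support_fraction = if (den > 0) num / den else 0)
  })
  data.table::rbindlist(rows)
}
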