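#' Random reference genome in label space
#'
#' Generates a toy diploid reference as a set of chromosome label maps with
#' labels laid down as a homogeneous Poisson process at the requested density.
#' The default 16 labels / 100 kb emulates the DLE-1 chemistry; ~10/100 kb
#' would emulate Nt.BspQI.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of each chromosome (scalar or vector).
#' @param density_per_100kb expected labels per 100 kb.
#' @param seed RNG seed.
#' @return named list of [label_map()] (`chr1`, `chr2`, ...).
#' @export
random_reference_genome <- function(n_chrom = 2, chrom_length_bp = 5e6,
                                    density_per_100kb = 16, seed = 1L) {
  set.seed(seed)
  chrom_length_bp <- rep_len(as.numeric(chrom_length_bp), n_chrom)
  out <- list()
  for (i in seq_len(n_chrom)) {
    L <- chrom_length_bp[i]
    n <- stats::rpois(1L, L / 1e5 * density_per_100kb)
    pos <- sort(stats::runif(n, min = 1, max = L))
    pos <- pos[c(TRUE, diff(pos) > 1)]  # sub-bp collisions are unphysical
    out[[paste0("chr", i)]] <- label_map(paste0("chr", i), L, pos)
  }
  out
}

#' Structural variant event
#'
#' One simulated SV on the reference. Span types (`deletion`, `inversion`,
#' `duplication`, translocations) use `[start_bp, end_bp)`; an `insertion` is
#' a point event (`end_bp == start_bp`) of length `size_bp` whose inserted
#' material carries its own label pattern (`novel_offsets`, generated at the
#' ambient density when not given) so that its size is measurable from the
#' inter-anchor distance. Translocations cut `[start_bp, end_bp)` out of
#' `ref_id` and splice it into `dest_ref_id` at `dest_bp`.
#'
#' @param sv_type one of `insertion`, `deletion`, `inversion`, `duplication`,
#'   `translocation_intra`, `translocation_inter`.
#' @param ref_id chromosome of the event.
#' @param start_bp,end_bp reference span (see above).
#' @param size_bp event size; for span types defaults to `end_bp - start_bp`.
#' @param dest_ref_id,dest_bp destination for translocations.
#' @param zygosity `"het"` or `"hom"`.
#' @param origin_clone clone in which the event first arises.
#' @param haplotype 1 or 2; haplotype carrying a het event (hom uses both).
#' @param novel_offsets label offsets within inserted material (insertions).
#' @param sv_id identifier; autogenerated if missing.
#' @return list of class `sv_event`.
#' @export
sv_event <- function(sv_type, ref_id, start_bp, end_bp = start_bp,
                     size_bp = NULL, dest_ref_id = NA_character_,
                     dest_bp = NA_real_, zygosity = "het",
                     origin_clone = "clone1", haplotype = 1L,
                     novel_offsets = NULL, sv_id = NULL) {
  types <- c("insertion", "deletion", "inversion", "duplication",
             "translocation_intra", "translocation_inter")
  sv_type <- match.arg(sv_type, types)
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (sv_type == "insertion") {
    if (end_bp != start_bp) stop("insertion must have end_bp == start_bp")
    if (is.null(size_bp) || size_bp <= 0) stop("insertion needs size_bp > 0")
  } else {
    if (start_bp >= end_bp) stop("span types need start_bp < end_bp")
    if (is.null(size_bp)) size_bp <- end_bp - start_bp
  }
  if (grepl("^translocation", sv_type)) {
    if (is.na(dest_bp)) stop("translocation needs a destination")
    if (sv_type == "translocation_inter" &&
        (is.na(dest_ref_id) || dest_ref_id == ref_id)) {
      stop("translocation_inter needs a different destination chromosome")
    }
    if (sv_type == "translocation_intra") {
      if (!is.na(dest_ref_id) && dest_ref_id != ref_id) {
        stop("translocation_intra destination must be the same chromosome")
      }
      dest_ref_id <- ref_id
      if (dest_bp >= start_bp && dest_bp <= end_bp) {
        stop("translocation destination inside excised span")
      }
    }
  }
  if (!zygosity %in% c("het", "hom")) stop("zygosity must be het or hom")
  if (is.null(sv_id)) {
    sv_id <- sprintf("%s_%s_%d", sv_type, ref_id, round(start_bp))
  }
  structure(list(sv_id = sv_id, sv_type = sv_type, ref_id = as.character(ref_id),
                 start_bp = start_bp, end_bp = end_bp,
                 size_bp = as.numeric(size_bp),
                 dest_ref_id = as.character(dest_ref_id),
                 dest_bp = as.numeric(dest_bp),
                 zygosity = zygosity, origin_clone = origin_clone,
                 haplotype = as.integer(haplotype),
                 novel_offsets = novel_offsets),
            class = "sv_event")
}

# ambient-density label offsets for inserted material
generate_novel_offsets <- function(size_bp, density_per_100kb = 16) {
  n <- stats::rpois(1L, size_bp / 1e5 * density_per_100kb)
  sort(stats::runif(n, min = 1, max = size_bp - 1))
}

#' Random non-overlapping SV set
#'
#' Draws `n` SVs of the given types with log-uniform sizes, rejecting
#' placements that overlap (with a guard gap) previously placed events on the
#' same chromosome, including events in `avoid` (e.g. an ancestor clone's
#' SVs, so a child's private events never collide with inherited ones).
#'
#' @param genome reference genome (list of [label_map()]).
#' @param n number of events.
#' @param types SV types to draw from (uniformly).
#' @param size_range log-uniform size range in bp.
#' @param zygosity_probs probability of `c(het, hom)`.
#' @param origin_clone clone tag stamped on the events.
#' @param avoid list of `sv_event` whose loci must not be touched.
#' @param guard_bp minimum gap between events.
#' @param density_per_100kb ambient density for inserted label patterns.
#' @return list of [sv_event()].
#' @export
random_sv_set <- function(genome, n, types = c("insertion", "deletion"),
                          size_range = c(2000, 200000),
                          zygosity_probs = c(het = 0.5, hom = 0.5),
                          origin_clone = "clone1", avoid = list(),
                          guard_bp = 50000, density_per_100kb = 16) {
  chroms <- names(genome)
  lens <- vapply(genome, function(m) m$length_bp, numeric(1))
  occupied <- lapply(stats::setNames(nm = chroms), function(ch) {
    evs <- Filter(function(e) e$ref_id == ch || identical(e$dest_ref_id, ch),
                  avoid)
    if (!length(evs)) return(matrix(numeric(), 0, 2))
    do.call(rbind, lapply(evs, function(e) {
      rbind(if (e$ref_id == ch) c(e$start_bp, max(e$end_bp, e$start_bp + 1)),
            if (identical(e$dest_ref_id, ch)) c(e$dest_bp, e$dest_bp + 1))
    }))
  })
  overlaps <- function(ch, s, e) {
    occ <- occupied[[ch]]
    nrow(occ) > 0 && any(s - guard_bp < occ[, 2L] & e + guard_bp > occ[, 1L])
  }
  claim <- function(ch, s, e) {
    occupied[[ch]] <<- rbind(occupied[[ch]], c(s, e))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in 1:200) {
      ty <- sample(types, 1L)
      size <- exp(stats::runif(1, log(size_range[1]), log(size_range[2])))
      ch <- sample(chroms, 1L, prob = lens)
      L <- lens[[ch]]
      zy <- sample(names(zygosity_probs), 1L, prob = zygosity_probs)
      hap <- sample(1:2, 1L)
      ev <- NULL
      if (ty == "insertion") {
        p <- stats::runif(1, guard_bp, L - guard_bp)
        if (!overlaps(ch, p, p + 1)) {
          ev <- sv_event("insertion", ch, p, p, size_bp = size, zygosity = zy,
                         origin_clone = origin_clone, haplotype = hap,
                         novel_offsets = generate_novel_offsets(size, density_per_100kb))
          claim(ch, p, p + 1)
        }
      } else if (ty %in% c("deletion", "inversion", "duplication")) {
        s <- stats::runif(1, guard_bp, L - size - guard_bp)
        if (!overlaps(ch, s, s + size)) {
          ev <- sv_event(ty, ch, s, s + size, zygosity = zy,
                         origin_clone = origin_clone, haplotype = hap)
          claim(ch, s, s + size)
        }
      } else { # translocations
        s <- stats::runif(1, guard_bp, L - size - guard_bp)
        if (ty == "translocation_inter" && length(chroms) > 1L) {
          dch <- sample(setdiff(chroms, ch), 1L)
        } else {
          ty <- "translocation_intra"; dch <- ch
        }
        dL <- lens[[dch]]
        d <- stats::runif(1, guard_bp, dL - guard_bp)
        if (ty == "translocation_intra" && abs(d - s) < size + 2e6) next
        if (!overlaps(ch, s, s + size) && !overlaps(dch, d, d + 1)) {
          ev <- sv_event(ty, ch, s, s + size, dest_ref_id = dch, dest_bp = d,
                         zygosity = zy, origin_clone = origin_clone,
                         haplotype = hap)
          claim(ch, s, s + size); claim(dch, d, d + 1)
        }
      }
      if (!is.null(ev)) { out[[i]] <- ev; break }
    }
    if (is.null(out[[i]])) stop("could not place SV after 200 attempts")
  }
  out
}
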