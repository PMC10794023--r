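#' Molecule noise model
#'
#' Parametric noise applied to sampled molecules, in this order: per-interval
#' Gaussian sizing error with sd `sizing_sd_per_kb * sqrt(d / 1 kb)` (sizing
#' noise grows with the square root of the true distance), label dropout with
#' probability `label_miss_prob`, false labels as a Poisson process at
#' `false_label_rate` per 100 kb, and a per-molecule multiplicative stretch
#' drawn uniformly from `stretch_range` (incomplete linearization). Molecule
#' lengths are lognormal with a hard minimum.
#'
#' @param sizing_sd_per_kb bp of sizing sd per sqrt(kb) of true distance.
#' @param stretch_range length-2 numeric, per-molecule scale factor range.
#' @param label_miss_prob per-label dropout probability in `[0,1]`.
#' @param false_label_rate expected false labels per 100 kb.
#' @param length_meanlog,length_sdlog lognormal molecule-length parameters.
#' @param min_molecule_length hard minimum molecule length (bp).
#' @param reverse_prob probability a molecule is read in reverse orientation.
#' @param chimera_rate reserved (default 0; chimeras are not modeled).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(sizing_sd_per_kb = 100, stretch_range = c(0.95, 1.05),
                        label_miss_prob = 0.1, false_label_rate = 1,
                        length_meanlog = log(2e5), length_sdlog = 0.35,
                        min_molecule_length = 1e5, reverse_prob = 0,
                        chimera_rate = 0) {
  stopifnot(sizing_sd_per_kb >= 0, label_miss_prob >= 0, label_miss_prob <= 1,
            false_label_rate >= 0, length(stretch_range) == 2,
            stretch_range[1] <= stretch_range[2], reverse_prob >= 0,
            reverse_prob <= 1)
  structure(list(sizing_sd_per_kb = sizing_sd_per_kb,
                 stretch_range = stretch_range,
                 label_miss_prob = label_miss_prob,
                 false_label_rate = false_label_rate,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 min_molecule_length = min_molecule_length,
                 reverse_prob = reverse_prob, chimera_rate = chimera_rate),
            class = "noise_model")
}

#' Noise-free limit of the noise model
#'
#' Convenience constructor for control experiments: no sizing error, no
#' dropout, no false labels, stretch fixed at 1.
#'
#' @param ... overrides forwarded to [noise_model()].
#' @export
noise_free <- function(...) {
  noise_model(sizing_sd_per_kb = 0, stretch_range = c(1, 1),
              label_miss_prob = 0, false_label_rate = 0, ...)
}

# split one haplotype window's labels into collinear true-alignment segments;
# a run breaks when chromosome or strand changes, ref order reverses, or the
# ref jump is wildly inconsistent with the query gap (an aligner would never
# bridge such a gap within one segment)
segment_true_alignment <- function(mol_id, pos, src_chrom, src_site, strand,
                                   ref_genome, max_gap_disc_bp = 1e6) {
  ok <- !is.na(src_site)
  if (sum(ok) < 2L) return(list())
  idx <- which(ok)
  ref_pos_of <- function(k) ref_genome[[src_chrom[k]]]$positions[src_site[k]]
  segs <- list(); cur <- idx[1L]
  for (k in idx[-1L]) {
    prev <- cur[length(cur)]
    same <- src_chrom[k] == src_chrom[prev] && strand[k] == strand[prev]
    coll <- same && ((strand[k] == "+" && src_site[k] > src_site[prev]) ||
                       (strand[k] == "-" && src_site[k] < src_site[prev]))
    if (coll) {
      disc <- abs(abs(ref_pos_of(k) - ref_pos_of(prev)) - (pos[k] - pos[prev]))
      if (disc > max_gap_disc_bp) coll <- FALSE
    }
    if (coll) cur <- c(cur, k) else { segs[[length(segs) + 1L]] <- cur; cur <- k }
  }
  segs[[length(segs) + 1L]] <- cur
  segs <- Filter(function(s) length(s) >= 2L, segs)
  lapply(segs, function(s) {
    ch <- src_chrom[s[1L]]
    ref <- ref_genome[[ch]]
    ori <- strand[s[1L]]
    sp <- cbind(ref_site = src_site[s], query_site = s)
    if (ori == "-") sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
    rs <- ref$positions[sp[1L, 1L]]; re <- ref$positions[sp[nrow(sp), 1L]]
    qs <- pos[sp[1L, 2L]]; qe <- pos[sp[nrow(sp), 2L]]
    alignment_record(mol_id, ch, ori, qs, qe, rs, re, sp,
                     confidence = nrow(sp), validate = FALSE)
  })
}

#' Sample noisy molecules from a clone mixture
#'
#' Draws molecules clone-proportionally until the target fold-coverage of the
#' reference genome is reached. Each molecule picks a random haplotype and a
#' uniform start on a chromosome (weighted by length and any aneuploidy
#' dosage), gets a lognormal length, and passes through the [noise_model()].
#' For every molecule the noise-free correspondence of its surviving true
#' labels to reference sites is emitted as one or more (split) alignment
#' records; molecules whose source crosses an SV junction naturally yield
#' split alignments.
#'
#' @param clone_genomes output of [build_clone_genomes()].
#' @param mixture a [mixture_spec()]; clones must exist in `clone_genomes`.
#' @param noise a [noise_model()].
#' @param ref_genome the reference genome the truth alignments refer to.
#' @param coverage target fold-coverage of the reference genome.
#' @param seed RNG seed (full determinism contract: same seed, same output).
#' @return list with `molecules` (list of [label_map()]), `alignments`
#'   (list of [alignment_record()], >= 0 per molecule), `meta` (data.table:
#'   molecule_id, clone, hap, chrom, start, length, stretch) and `coverage`
#'   (data.table of per-molecule source reference spans: molecule_id,
#'   src_chrom, lo, hi).
#' @export
sample_molecules <- function(clone_genomes, mixture, noise, ref_genome,
                             coverage = 100, seed = 1L) {
  set.seed(seed)
  clones <- names(mixture$proportions)
  if (!all(clones %in% names(clone_genomes))) {
    stop("mixture names clones absent from clone_genomes")
  }
  pi_c <- mixture$proportions
  if (sum(pi_c) <= 0) stop("mixture has zero mass")
  glen <- sum(vapply(ref_genome, function(m) m$length_bp, numeric(1)))
  target <- coverage * glen
  # chromosome pick weights per (clone, hap)
  chrom_w <- list()
  for (cl in clones) for (h in 1:2) {
    maps <- clone_genomes[[cl]][[paste0("hap", h)]]$maps
    w <- vapply(names(maps), function(ch)
      maps[[ch]]$length_bp * dosage_multiplier(mixture, cl, ch), numeric(1))
    chrom_w[[paste0(cl, ".", h)]] <- w
  }
  molecules <- list(); alignments <- list(); meta <- list(); covr <- list()
  total <- 0; mid <- 0L
  while (total < target) {
    n_batch <- max(100L, ceiling((target - total) / exp(noise$length_meanlog)))
    cl_b <- sample(clones, n_batch, replace = TRUE, prob = pi_c)
    hap_b <- sample(1:2, n_batch, replace = TRUE)
    len_b <- pmax(noise$min_molecule_length,
                  stats::rlnorm(n_batch, noise$length_meanlog, noise$length_sdlog))
    stretch_b <- stats::runif(n_batch, noise$stretch_range[1],
                              noise$stretch_range[2])
    for (b in seq_len(n_batch)) {
      if (total >= target) break
      cl <- cl_b[b]; h <- hap_b[b]
      key <- paste0(cl, ".", h)
      hapg <- clone_genomes[[cl]][[paste0("hap", h)]]
      w <- chrom_w[[key]]
      ch <- sample(names(w), 1L, prob = w)
      L <- hapg$maps[[ch]]$length_bp
      len <- min(len_b[b], L)
      start <- stats::runif(1, 0, L - len)
      lo <- hapg$liftover[chrom == ch]
      sel <- lo$pos > start & lo$pos <= start + len
      pos <- lo$pos[sel] - start
      src_chrom <- lo$src_chrom[sel]; src_pos <- lo$src_pos[sel]
      src_site <- lo$src_site[sel]; strand <- lo$strand[sel]
      mid <- mid + 1L
      mol_id <- as.character(mid)
      # --- noise -------------------------------------------------------
      keep <- if (noise$label_miss_prob > 0) {
        stats::runif(length(pos)) >= noise$label_miss_prob
      } else rep(TRUE, length(pos))
      pos <- pos[keep]; src_chrom <- src_chrom[keep]; src_pos <- src_pos[keep]
      src_site <- src_site[keep]; strand <- strand[keep]
      if (noise$sizing_sd_per_kb > 0 && length(pos)) {
        gaps <- diff(c(0, pos))
        gaps <- gaps + stats::rnorm(length(gaps), 0,
                                    noise$sizing_sd_per_kb * sqrt(gaps / 1000))
        gaps <- pmax(gaps, 1)  # keep ordering
        pos <- cumsum(gaps)
        pos <- pos * (len / max(len, max(pos) + 1)) # stay within molecule
      }
      n_false <- if (noise$false_label_rate > 0) {
        stats::rpois(1L, noise$false_label_rate * len / 1e5)
      } else 0L
      if (n_false > 0) {
        fpos <- stats::runif(n_false, 1, len)
        pos <- c(pos, fpos)
        src_chrom <- c(src_chrom, rep(NA_character_, n_false))
        src_pos <- c(src_pos, rep(NA_real_, n_false))
        src_site <- c(src_site, rep(NA_integer_, n_false))
        strand <- c(strand, rep(NA_character_, n_false))
      }
      o <- order(pos)
      pos <- pos[o]; src_chrom <- src_chrom[o]; src_pos <- src_pos[o]
      src_site <- src_site[o]; strand <- strand[o]
      dup <- c(FALSE, diff(pos) <= 0.1)
      if (any(dup)) {
        pos <- pos[!dup]; src_chrom <- src_chrom[!dup]
        src_pos <- src_pos[!dup]; src_site <- src_site[!dup]
        strand <- strand[!dup]
      }
      s <- stretch_b[b]
      mol_len <- len * s
      mol_pos <- pos * s
      molecules[[mid]] <- label_map(mol_id, mol_len, mol_pos)
      alns <- segment_true_alignment(mol_id, mol_pos, src_chrom, src_site,
                                     strand, ref_genome)
      if (length(alns)) alignments <- c(alignments, alns)
      meta[[mid]] <- data.table::data.table(
        molecule_id = mol_id, clone = cl, hap = h, chrom = ch,
        start = start, length = len, stretch = s)
      okc <- !is.na(src_chrom)
      if (any(okc)) {
        cv <- data.table::data.table(src_chrom = src_chrom[okc],
                                     src_pos = src_pos[okc])
        cv <- cv[, .(lo = min(src_pos), hi = max(src_pos)), by = src_chrom]
        cv[, molecule_id := mol_id]
        covr[[length(covr) + 1L]] <- cv
      }
      total <- total + len
    }
  }
  list(molecules = molecules, alignments = alignments,
       meta = data.table::rbindlist(meta),
       coverage = data.table::rbindlist(covr))
}

#' Simulate a full benchmark dataset
#'
#' Convenience wrapper: builds the clone genomes, the truth table for the
#' mixture and the noisy molecule set in one call.
#'
#' @param ref_genome named list of reference [label_map()].
#' @param graph a [clone_graph()].
#' @param mixture a [mixture_spec()].
#' @param noise a [noise_model()].
#' @param coverage target fold-coverage.
#' @param seed RNG seed.
#' @return list: `molecules`, `alignments`, `meta`, `coverage`, `truth`
#'   (see [truth_table()]), `clone_genomes`, `ref_genome`, `graph`,
#'   `mixture`.
#' @export
simulate_dataset <- function(ref_genome, graph, mixture,
                             noise = noise_model(), coverage = 100,
                             seed = 1L) {
  clone_genomes <- build_clone_genomes(ref_genome, graph)
  truth <- truth_table(graph, mixture)
  sim <- sample_molecules(clone_genomes, mixture, noise, ref_genome,
                          coverage = coverage, seed = seed)
  c(sim, list(truth = truth, clone_genomes = clone_genomes,
              ref_genome = ref_genome, graph = graph, mixture = mixture))
}

#' Empirical SV support fractions at truth loci
#'
#' For each truth record, counts molecules whose physical source spans the
#' locus and, among them, those drawn from a haplotype carrying the SV.
#'
#' @param dataset a [simulate_dataset()] result.
#' @return the truth table with `n_spanning`, `n_support` and
#'   `empirical_fraction` columns added.
#' @export
empirical_support <- function(dataset) {
  truth <- data.table::copy(dataset$truth)
  sets <- clone_sv_sets(dataset$graph)
  carrier_haps <- lapply(sets, function(evs) {
    ids <- vapply(evs, function(e) e$sv_id, character(1))
    zy <- vapply(evs, function(e) e$zygosity, character(1))
    hp <- vapply(evs, function(e) e$haplotype, integer(1))
    stats::setNames(lapply(seq_along(evs), function(i)
      if (zy[i] == "hom") 1:2 else hp[i]), ids)
  })
  meta <- dataset$meta
  cov <- dataset$coverage
  res <- truth[, {
    span <- cov[src_chrom == ref_id & lo <= start_bp & hi >= end_bp]
    mols <- meta[molecule_id %in% span$molecule_id]
    supp <- mapply(function(cl, h) {
      ch <- carrier_haps[[cl]]
      !is.null(ch) && sv_id %in% names(ch) && h %in% ch[[sv_id]]
    }, mols$clone, mols$hap)
    .(n_spanning = nrow(mols), n_support = sum(supp))
  }, by = sv_id]
  truth <- merge(truth, res, by = "sv_id", all.x = TRUE, sort = FALSE)
  truth[is.na(n_spanning), `:=`(n_spanning = 0L, n_support = 0L)]
  truth[, empirical_fraction := ifelse(n_spanning > 0,
                                       n_support / n_spanning, NA_real_)]
  truth
}

#' Datasets spanning a series of SV-supporting fractions
#'
#' Reproduces the support-fraction sweep benchmark: a two-population world
#' (an SV-free "normal" clone and a "variant" clone carrying every SV
#' homozygously) mixed so that each dataset's expected supporting fraction at
#' every SV locus equals the requested value.
#'
#' @param ref_genome named list of reference [label_map()].
#' @param svs list of [sv_event()]; zygosity is forced to `hom` and origin to
#'   the variant clone so the mixture fraction alone sets the support level.
#' @param fractions supporting fractions in `(0, 1]`.
#' @param noise a [noise_model()].
#' @param coverage target fold-coverage per dataset.
#' @param seed base RNG seed; dataset i uses `seed + i - 1`.
#' @return named list of [simulate_dataset()] results (`f0.10`, ...).
#' @export
make_support_series <- function(ref_genome, svs, fractions = seq(0.1, 0.9, 0.1),
                                noise = noise_model(), coverage = 100,
                                seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0,1]")
  svs <- lapply(svs, function(e) {
    e$zygosity <- "hom"; e$origin_clone <- "sample2"; e
  })
  out <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    graph <- clone_graph(germline = list(), trunk = svs)
    mx_p <- if (f >= 1) c(sample2 = 1.0) else c(sample1 = 1 - f, sample2 = f)
    mixture <- mixture_spec(mx_p)
    out[[sprintf("f%.2f", f)]] <- simulate_dataset(
      ref_genome, graph, mixture, noise, coverage, seed = seed + i - 1L)
  }
  out
}
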