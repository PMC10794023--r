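# Shared fixture builders (all data generated in code; no files shipped).

random_molecule_fixture <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- runif(1, 5e4, 4e5)
    k <- rpois(1, len / 1e5 * 12)
    pos <- sort(runif(k, 1, len))
    pos <- pos[c(TRUE, diff(pos) > 1)]
    label_map(sprintf("mol%d", i), len, round(pos, 1))
  })
}

random_alignment_fixture <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(3:12, 1)
    ref_sites <- sort(sample(1:200, k))
    ori <- sample(c("+", "-"), 1)
    qry <- if (ori == "+") seq_len(k) + sample(0:30, 1) else
      rev(seq_len(k) + sample(0:30, 1))
    alignment_record(
      query_id = sprintf("q%d", i), ref_id = sample(c("chr1", "chr2"), 1),
      orientation = ori,
      query_start_bp = 1000, query_end_bp = 1000 + k * 5000,
      ref_start_bp = ref_sites[1] * 6000, ref_end_bp = ref_sites[k] * 6000,
      site_pairs = cbind(ref_sites, qry), confidence = runif(1, 0, 30))
  })
}

# small world for pipeline tests: 2 x 2 Mb genome
tiny_reference <- function(seed = 3L, chrom_length = 2e6) {
  random_reference_genome(n_chrom = 2, chrom_length_bp = chrom_length,
                          density_per_100kb = 16, seed = seed)
}

# convenience: split sets with molecule lengths attached
split_sets_of <- function(dataset) {
  qlens <- stats::setNames(
    vapply(dataset$molecules, function(m) m$length_bp, numeric(1)),
    vapply(dataset$molecules, function(m) m$map_id, character(1)))
  split_alignment_sets(dataset$alignments, qlens)
}

# pure-clone, hom SV dataset used by several indel tests
indel_world <- function(n_sv = 6, noise = noise_free(), coverage = 60,
                        seed = 7L, size_range = c(3000, 20000),
                        zygosity_probs = c(het = 0, hom = 1),
                        mixture = mixture_spec(c(sample2 = 1)),
                        ref_seed = 3L) {
  ref <- tiny_reference(seed = ref_seed)
  set.seed(seed)
  svs <- random_sv_set(ref, n_sv, types = c("insertion", "deletion"),
                       size_range = size_range,
                       zygosity_probs = zygosity_probs,
                       origin_clone = "sample2")
  graph <- clone_graph(trunk = svs)
  ds <- simulate_dataset(ref, graph, mixture, noise, coverage, seed = seed)
  ds
}
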