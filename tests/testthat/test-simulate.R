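test_that("deletion shifts downstream labels by its size", {
  ref <- list(chr1 = label_map("chr1", 2e4, c(9000, 11000, 15000)))
  hap <- apply_svs_to_genome(ref, list(
    sv_event("deletion", "chr1", 10000, 13700)))
  expect_equal(hap$maps$chr1$positions, c(9000, 11300))
  expect_equal(hap$maps$chr1$length_bp, 20000 - 3700)
  # liftover: surviving labels map to their sources
  expect_equal(hap$liftover$src_pos, c(9000, 15000))
})

test_that("inversion mirrors label offsets and reverses order", {
  ref <- list(chr1 = label_map("chr1", 5e4, c(5000, 21000, 24000, 28000, 45000)))
  hap <- apply_svs_to_genome(ref, list(
    sv_event("inversion", "chr1", 20000, 30000)))
  # labels at offsets 1000, 4000, 8000 from span start -> mirrored
  expect_equal(hap$maps$chr1$positions,
               c(5000, 20000 + 2000, 20000 + 6000, 20000 + 9000, 45000))
  inside <- hap$liftover[!is.na(src_pos) & src_pos >= 20000 & src_pos < 30000]
  expect_true(all(inside$strand == "-"))
})

test_that("insertion splices its label pattern and shifts downstream", {
  ref <- list(chr1 = label_map("chr1", 5e4, c(10000, 30000)))
  hap <- apply_svs_to_genome(ref, list(
    sv_event("insertion", "chr1", 20000, 20000, size_bp = 5000,
             novel_offsets = c(1000, 3000))))
  expect_equal(hap$maps$chr1$positions, c(10000, 21000, 23000, 35000))
  expect_equal(hap$maps$chr1$length_bp, 55000)
  expect_equal(hap$liftover$novel, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("duplication splices a copy after the span; translocation cuts and pastes", {
  ref <- list(chr1 = label_map("chr1", 1e5, c(10000, 42000, 45000, 80000)),
              chr2 = label_map("chr2", 1e5, c(50000)))
  hap <- apply_svs_to_genome(ref, list(
    sv_event("duplication", "chr1", 40000, 50000)))
  expect_equal(hap$maps$chr1$positions, c(10000, 42000, 45000, 52000, 55000, 90000))
  expect_equal(sum(hap$liftover$dup_copy), 2)
  hap2 <- apply_svs_to_genome(ref, list(
    sv_event("translocation_inter", "chr1", 40000, 50000,
             dest_ref_id = "chr2", dest_bp = 20000)))
  expect_equal(hap2$maps$chr1$positions, c(10000, 70000))
  expect_equal(hap2$maps$chr1$length_bp, 90000)
  expect_equal(hap2$maps$chr2$positions, c(22000, 25000, 60000))
  expect_equal(hap2$maps$chr2$length_bp, 110000)
})

test_that("overlapping SVs and spans beyond the map are rejected", {
  ref <- list(chr1 = label_map("chr1", 1e5, c(10000, 50000)))
  expect_error(apply_svs_to_genome(ref, list(
    sv_event("deletion", "chr1", 10000, 30000),
    sv_event("inversion", "chr1", 20000, 40000))), "overlapping")
  expect_error(apply_svs_to_genome(ref, list(
    sv_event("deletion", "chr1", 90000, 120000))), "exceeds")
})

test_that("random local SV sets equal the segment-concatenation oracle", {
  set.seed(14)
  for (rep in 1:5) {
    ref1 <- label_map("chr1", 5e6, sort(runif(600, 1, 5e6)))
    ref <- list(chr1 = ref1)
    svs <- random_sv_set(ref, 50,
                         types = c("insertion", "deletion", "inversion",
                                   "duplication"),
                         size_range = c(2000, 60000), guard_bp = 10000,
                         origin_clone = "sample2")
    got <- apply_svs_to_genome(ref, svs)$maps$chr1$positions
    want <- oracle_apply_svs(ref1, svs)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("deletion-only sets conserve label counts exactly", {
  set.seed(15)
  ref1 <- label_map("chr1", 5e6, sort(runif(600, 1, 5e6)))
  ref <- list(chr1 = ref1)
  svs <- random_sv_set(ref, 20, types = "deletion",
                       size_range = c(2000, 50000), origin_clone = "sample2")
  hap <- apply_svs_to_genome(ref, svs)
  inside <- sum(vapply(svs, function(e)
    sum(ref1$positions >= e$start_bp & ref1$positions < e$end_bp), numeric(1)))
  expect_equal(length(hap$maps$chr1$positions),
               length(ref1$positions) - inside)
  # liftover is a bijection between non-novel labels and surviving ref labels
  lo <- hap$liftover[!(novel) & !(dup_copy)]
  expect_false(anyDuplicated(lo$src_site) > 0)
  expect_equal(nrow(lo), length(hap$maps$chr1$positions))
})

test_that("clone genomes follow the evolution graph (path-union oracle)", {
  set.seed(16)
  ref <- tiny_reference(seed = 5)
  g_sv <- random_sv_set(ref, 5, origin_clone = "sample1",
                        size_range = c(3000, 20000))
  t_sv <- random_sv_set(ref, 5, origin_clone = "sample2", avoid = g_sv,
                        size_range = c(3000, 20000))
  s3 <- random_sv_set(ref, 5, origin_clone = "sample3",
                      avoid = c(g_sv, t_sv), size_range = c(3000, 20000))
  s4 <- random_sv_set(ref, 5, origin_clone = "sample4",
                      avoid = c(g_sv, t_sv, s3), size_range = c(3000, 20000))
  graph <- clone_graph(g_sv, t_sv, s3, s4)
  sets <- clone_sv_sets(graph)
  ids <- function(evs) sort(vapply(evs, function(e) e$sv_id, character(1)))
  expect_equal(ids(sets$sample1), ids(g_sv))
  expect_equal(ids(sets$sample2), ids(c(g_sv, t_sv)))
  expect_equal(ids(sets$sample3), ids(c(g_sv, t_sv, s3)))
  expect_equal(ids(sets$sample4), ids(c(g_sv, t_sv, s4)))
  # a hom germline deletion lands on both haplotypes of every clone
  genomes <- build_clone_genomes(ref, clone_graph(
    germline = list(sv_event("deletion", "chr1", 1e5, 1.2e5,
                             zygosity = "hom"))))
  for (cl in names(genomes)) {
    for (h in c("hap1", "hap2")) {
      expect_equal(genomes[[cl]][[h]]$maps$chr1$length_bp,
                   ref$chr1$length_bp - 2e4)
    }
  }
  # a het trunk SV lands on exactly one haplotype of both sub-clones
  genomes2 <- build_clone_genomes(ref, clone_graph(
    trunk = list(sv_event("deletion", "chr1", 1e5, 1.2e5, zygosity = "het",
                          haplotype = 2L))))
  expect_equal(genomes2$sample3$hap1$maps$chr1$length_bp, ref$chr1$length_bp)
  expect_equal(genomes2$sample3$hap2$maps$chr1$length_bp,
               ref$chr1$length_bp - 2e4)
  expect_equal(genomes2$sample4$hap2$maps$chr1$length_bp,
               ref$chr1$length_bp - 2e4)
  expect_equal(genomes2$sample1$hap2$maps$chr1$length_bp, ref$chr1$length_bp)
})

test_that("mixture specs validate and presets match the benchmark design", {
  expect_error(mixture_spec(c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(mixture_spec(c(0.5, 0.5)), "named")
  s7 <- mixture_preset("sample7")
  expect_equal(sum(s7$proportions), 1)
  expect_equal(s7$proportions[["sample1"]], 0.7)
  expect_equal(s7$proportions[["sample4"]], 0.1)
})

test_that("expected support fractions follow clone fractions and dosage", {
  # het SV private to sub-clone 2 under the low-tumor two-sub-clone mixture:
  # 10% of cells x 1 of 2 haplotypes = 0.05
  graph <- clone_graph(subclone2 = list(
    sv_event("deletion", "chr1", 1e5, 1.1e5, zygosity = "het")))
  tt <- truth_table(graph, mixture_preset("sample7"))
  expect_equal(tt$expected_support_fraction, 0.05)
  # hom trunk SV: sample2+3+4 = 30% of cells, both haplotypes
  graph2 <- clone_graph(trunk = list(
    sv_event("deletion", "chr1", 1e5, 1.1e5, zygosity = "hom")))
  tt2 <- truth_table(graph2, mixture_preset("sample7"))
  expect_equal(tt2$expected_support_fraction, 0.30)
  # aneuploidy dosage: doubling the carrier clone's chromosome raises the
  # fraction accordingly
  mx <- mixture_spec(c(sample1 = 0.7, sample2 = 0.1, sample3 = 0.1,
                       sample4 = 0.1),
                     chrom_dosage = data.frame(clone = "sample2",
                                               chrom = "chr1",
                                               multiplier = 2))
  tt3 <- truth_table(graph2, mx)
  expect_equal(tt3$expected_support_fraction,
               (0.1 * 2 + 0.1 + 0.1) / (0.7 + 0.1 * 2 + 0.1 + 0.1))
})

test_that("noise-free single-clone hom SV gives support fraction 1", {
  ds <- indel_world(n_sv = 2, coverage = 30, seed = 11)
  es <- empirical_support(ds)
  expect_true(all(es$n_spanning > 0))
  expect_equal(es$empirical_fraction, rep(1, nrow(es)))
})

test_that("same seed gives byte-identical outputs (determinism contract)", {
  ds1 <- indel_world(n_sv = 2, coverage = 10, seed = 5)
  ds2 <- indel_world(n_sv = 2, coverage = 10, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".bnx")
  f2 <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(ds1$molecules, f1)
  write_bnx(ds2$molecules, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(ds1$truth, ds2$truth)
})

test_that("sampled coverage is within 5% of the request", {
  ds <- indel_world(n_sv = 1, coverage = 25, seed = 6)
  glen <- sum(vapply(ds$ref_genome, function(m) m$length_bp, numeric(1)))
  got <- sum(ds$meta$length) / glen
  expect_lt(abs(got - 25) / 25, 0.05)
})

test_that("molecule noise behaves as configured", {
  nm <- noise_model(sizing_sd_per_kb = 150, label_miss_prob = 0.25,
                    false_label_rate = 2)
  ds <- indel_world(n_sv = 1, noise = nm, coverage = 30, seed = 12)
  # dropout: matched label count per molecule is ~75% of the source labels
  n_lab <- sum(vapply(ds$molecules, function(m) length(m$positions), numeric(1)))
  ds0 <- indel_world(n_sv = 1, noise = noise_free(), coverage = 30, seed = 12)
  n_lab0 <- sum(vapply(ds0$molecules, function(m) length(m$positions), numeric(1)))
  # miss 25% of true labels, add 2/100kb false ones (~12.5% of label mass)
  expect_lt(n_lab, n_lab0)
  expect_error(noise_model(label_miss_prob = 1.5))
  expect_error(mixture_spec(c(sample1 = -0.1, sample2 = 1.1)))
})

test_that("support series hits the requested fractions empirically", {
  ref <- tiny_reference(seed = 21)
  set.seed(22)
  svs <- random_sv_set(ref, 4, types = c("insertion", "deletion"),
                       size_range = c(4000, 20000), origin_clone = "sample2")
  series <- make_support_series(ref, svs, fractions = c(0.2, 0.6),
                                noise = noise_free(), coverage = 60,
                                seed = 31)
  expect_named(series, c("f0.20", "f0.60"))
  for (nm in names(series)) {
    f <- series[[nm]]$truth$expected_support_fraction[1]
    es <- empirical_support(series[[nm]])
    ok <- es[n_spanning >= 20]
    expect_gt(nrow(ok), 0)
    # 4 sd: molecule sampling is length-biased (a deletion carrier spans the
    # collapsed junction more easily than a reference molecule spans the full
    # span), which drifts the spanning fraction ~1 sd on top of binomial noise
    band <- 4 * sqrt(f * (1 - f) / ok$n_spanning)
    expect_true(all(abs(ok$empirical_fraction - f) <= band + 1e-9))
  }
  # identical SV coordinates across the series
  expect_equal(series[[1]]$truth$start_bp, series[[2]]$truth$start_bp)
  expect_error(make_support_series(ref, svs, fractions = c(0, 0.5)))
})
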