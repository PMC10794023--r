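ref_map_10 <- function() label_map("chr1", 1.2e5, seq(10000, 110000, 10000))

aln_for <- function(mol_pos, mol_id = "m1", sites = seq_along(mol_pos)) {
  alignment_record(mol_id, "chr1", "+", mol_pos[1], mol_pos[length(mol_pos)],
                   10000 * sites[1], 10000 * sites[length(sites)],
                   site_pairs = cbind(sites, seq_along(mol_pos)),
                   confidence = 10)
}

test_that("uniform stretch is inverted exactly by normalization", {
  ref <- ref_map_10()
  mol_pos <- ref$positions * 1.04
  mol <- label_map("m1", 1.3e5, mol_pos)
  na <- normalize_alignment(aln_for(mol_pos), mol, ref)
  expect_equal(na$scale_factor, 1.04, tolerance = 1e-9)
  expect_equal(na$intervals$ratio, rep(1, 10), tolerance = 1e-9)
  expect_false(na$flagged)
})

test_that("median scale estimate resists one inserted interval", {
  ref <- ref_map_10()
  # 5 kb insertion between sites 5 and 6, molecule otherwise exact
  mol_pos <- ref$positions
  mol_pos[6:11] <- mol_pos[6:11] + 5000
  mol <- label_map("m1", 1.3e5, mol_pos)
  na <- normalize_alignment(aln_for(mol_pos), mol, ref)
  expect_equal(na$scale_factor, 1, tolerance = 1e-9)
  expect_equal(na$intervals$observed_bp[5], 15000)
  expect_gt(na$intervals$ratio[5], 1.4)
})

test_that("stretch factors recover at the analytic precision bound", {
  # analytic oracle: a per-interval ratio has variance sigma^2 d / d^2 with
  # sigma(d) = 100 sqrt(d/1kb), i.e. 10/d; the median of ~equal-variance
  # ratios over a molecule with total aligned length D then has
  # sd ~ 1.253 sqrt(10/D). The estimator must attain this within 25%.
  set.seed(41)
  ref <- label_map("chr1", 1.2e6, sort(runif(190, 1, 1.2e6)))
  errs <- numeric(0); total_d <- numeric(0)
  for (i in 1:200) {
    s <- runif(1, 0.95, 1.05)
    k0 <- sample(1:80, 1)
    sites <- k0:(k0 + 100)
    d <- diff(ref$positions[sites])
    d_noisy <- pmax(d + rnorm(length(d), 0, 100 * sqrt(d / 1000)), 1) * s
    mol_pos <- cumsum(c(1000, d_noisy))
    mol <- label_map("m", max(mol_pos) + 1000, mol_pos)
    al <- alignment_record("m", "chr1", "+", mol_pos[1], max(mol_pos),
                           ref$positions[sites[1]], ref$positions[max(sites)],
                           site_pairs = cbind(sites, seq_along(sites)))
    na <- normalize_alignment(al, mol, ref)
    errs <- c(errs, (na$scale_factor - s) / s)
    total_d <- c(total_d, sum(d))
  }
  theory <- 1.253 * sqrt(10 / mean(total_d))
  expect_lt(sqrt(mean(errs^2)), 1.25 * theory)
  expect_lt(sqrt(mean(errs^2)), 0.0075)  # < 0.75% for ~600 kb molecules
})

test_that("fewer than 2 intervals passes through flagged", {
  ref <- ref_map_10()
  mol <- label_map("m1", 5e4, c(1000, 11000))
  al <- alignment_record("m1", "chr1", "+", 1000, 11000, 10000, 20000,
                         site_pairs = cbind(1:2, 1:2))
  na <- normalize_alignment(al, mol, ref)
  expect_true(na$flagged)
  expect_equal(na$scale_factor, 1)
})

make_pair_table <- function(devs_by_mol, expected = 10000) {
  # devs_by_mol: list molecule -> numeric vector of deviations per interval
  rows <- lapply(names(devs_by_mol), function(mid) {
    dv <- devs_by_mol[[mid]]
    data.table::data.table(
      molecule_id = mid, ref_id = "chr1",
      ref_left_site = seq_along(dv), ref_right_site = seq_along(dv) + 1L,
      observed_bp = expected + dv, expected_bp = expected)
  })
  data.table::rbindlist(rows)
}

test_that("mutually reinforcing deviations become candidates", {
  devs <- c(lapply(stats::setNames(nm = paste0("v", 1:4)), function(x)
    c(0, 3000, 0, 0, 0, 0, 0, 0, 0)),
    lapply(stats::setNames(nm = paste0("n", 1:6)), function(x) rep(0, 9)))
  pt <- arbitrate_abnormal_pairs(make_pair_table(devs))
  cand <- pt[verdict == "candidate"]
  expect_equal(sort(unique(cand$molecule_id)), paste0("v", 1:4))
  expect_true(all(cand$ref_left_site == 2))
})

test_that("an isolated abnormal pair is corrected to the consensus", {
  devs <- c(list(x = c(0, -2000, 0, 0, 0, 0, 0, 0, 0)),
            lapply(stats::setNames(nm = paste0("n", 1:9)), function(i) rep(0, 9)))
  pt <- arbitrate_abnormal_pairs(make_pair_table(devs))
  fixed <- pt[molecule_id == "x" & ref_left_site == 2]
  expect_equal(fixed$verdict, "corrected")
  expect_equal(fixed$corrected_bp, 10000)
  expect_true(all(pt[molecule_id != "x", verdict] == "normal"))
})

test_that("alignments dominated by inconsistent abnormality are discarded", {
  set.seed(5)
  devs <- c(list(bad = c(3000, -4000, 2500, -2600, 5000, -2100, 2900, 0, 0)),
            lapply(stats::setNames(nm = paste0("n", 1:9)), function(i) rep(0, 9)))
  pt <- arbitrate_abnormal_pairs(make_pair_table(devs))
  expect_true(all(pt[molecule_id == "bad", verdict] == "alignment_discarded"))
})

test_that("low-coverage loci defer all verdicts", {
  devs <- list(a = c(0, 3000), b = c(0, 3000), c = c(0, 2900))
  pt <- arbitrate_abnormal_pairs(make_pair_table(devs))
  expect_true(all(pt$verdict == "deferred"))
})

test_that("arbitration matches a direct rule evaluation on random tables", {
  set.seed(43)
  cfg <- om_config()$indel
  for (rep in 1:20) {
    n_mol <- sample(8:14, 1); n_iv <- sample(4:8, 1)
    devs <- lapply(stats::setNames(nm = sprintf("m%02d", seq_len(n_mol))),
                   function(x) {
                     d <- rep(0, n_iv)
                     k <- sample(0:2, 1)
                     if (k > 0) {
                       at <- sample(n_iv, k)
                       d[at] <- sample(c(-1, 1), k, TRUE) * runif(k, 2000, 4000)
                     }
                     d
                   })
    pt <- arbitrate_abnormal_pairs(make_pair_table(devs))
    # oracle: recompute the abnormal flag and candidate rule independently
    for (r in seq_len(nrow(pt))) {
      row <- pt[r]
      dev <- row$observed_bp - row$expected_bp
      abn <- abs(dev) > max(cfg$abs_threshold_bp,
                            cfg$rel_threshold * row$expected_bp)
      expect_equal(row$abnormal, abn)
      if (!abn) expect_true(row$verdict %in% c("normal", "alignment_discarded"))
    }
    # every candidate group has >= min_support same-sign members
    cand <- pt[verdict == "candidate"]
    if (nrow(cand)) {
      grp <- cand[, .(n = .N), by = .(ref_left_site, sign(observed_bp - expected_bp))]
      expect_true(all(grp$n >= cfg$min_support))
    }
  }
})

test_that("overlapping candidate pairs merge into one region (union-find oracle)", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    lefts <- sample(1:30, n, replace = TRUE)
    rights <- lefts + sample(1:4, n, replace = TRUE)
    # fabricate an arbitration table where each interval is a candidate with
    # enough molecules, plus spanning molecules matching every site
    rows <- list()
    for (i in seq_len(n)) for (m in 1:3) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        molecule_id = sprintf("m%d_%d", i, m), ref_id = "chr1",
        ref_left_site = lefts[i], ref_right_site = rights[i],
        observed_bp = 10000 * (rights[i] - lefts[i]) + 3000,
        expected_bp = 10000 * (rights[i] - lefts[i]),
        abnormal = TRUE, verdict = "candidate")
    }
    pt <- data.table::rbindlist(rows)
    pt[, corrected_bp := observed_bp]
    regions <- build_candidate_regions(pt, om_config(
      indel = list(anchor_min_frac = 0)))
    want_groups <- length(unique(oracle_region_partition(lefts, rights)))
    expect_equal(nrow(regions), want_groups)
    # redundancy contract: every candidate interval is inside exactly 1 region
    for (i in seq_len(n)) {
      hits <- regions[anchor_left_site <= lefts[i] &
                        anchor_right_site >= rights[i]]
      expect_gte(nrow(hits), 1)
    }
  }
})

test_that("molecules missing inner labels still contribute spanning distances", {
  ref <- ref_map_10()
  # molecule A matched at sites 3..6; molecule B misses site 4 and 5
  molA <- label_map("A", 1.2e5, ref$positions[3:6] - 20000)
  alA <- alignment_record("A", "chr1", "+", molA$positions[1],
                          molA$positions[4], ref$positions[3],
                          ref$positions[6],
                          site_pairs = cbind(3:6, 1:4), confidence = 9)
  molB <- label_map("B", 1.2e5, ref$positions[c(3, 6)] - 20000 + c(0, 2500))
  alB <- alignment_record("B", "chr1", "+", molB$positions[1],
                          molB$positions[2], ref$positions[3],
                          ref$positions[6],
                          site_pairs = cbind(c(3, 6), 1:2), confidence = 9)
  nas <- lapply(list(list(alA, molA), list(alB, molB)), function(z) {
    na <- normalize_alignment(z[[1]], z[[2]], ref)
    na$molecule_positions <- z[[2]]$positions
    na
  })
  region <- data.table::data.table(region_id = 1L, ref_id = "chr1",
                                   anchor_left_site = 3L,
                                   anchor_right_site = 6L)
  obs <- region_spanning_observations(region, nas, ref)
  expect_equal(nrow(obs), 2)
  expect_equal(attr(obs, "expected_bp"), 30000)
  expect_equal(sort(obs$molecule_id), c("A", "B"))
})

test_that("a single tight cluster stays one cluster", {
  set.seed(46)
  x <- rnorm(20, 30000, 500)
  cl <- cluster_distances(x)
  expect_equal(cl$chosen_k, 1L)
  expect_equal(cl$clusters$mean_bp, mean(x), tolerance = 1e-6)
})

test_that("a 15% minority cluster is found with its exact members", {
  set.seed(47)
  x <- c(rnorm(17, 30000, 400), rnorm(3, 35000, 400))
  cl <- cluster_distances(x)
  expect_equal(cl$chosen_k, 2L)
  expect_equal(cl$clusters$n, c(17, 3))
  expect_equal(which(cl$assignment == 2L), 18:20)
})

test_that("identical observations collapse to one zero-variance cluster", {
  cl <- cluster_distances(rep(25000, 12))
  expect_equal(cl$chosen_k, 1L)
  expect_equal(cl$clusters$sd_bp, om_config()$indel$sigma_floor_bp)
})

test_that("clustering equals the exhaustive split oracle on small instances", {
  set.seed(48)
  cfg <- om_config()$indel
  for (rep in 1:40) {
    n <- sample(6:12, 1)
    k_true <- sample(1:3, 1)
    centers <- 30000 + cumsum(c(0, runif(2, 2000, 9000)))[seq_len(k_true)]
    x <- rnorm(n, sample(centers, n, replace = TRUE), 400)
    got <- cluster_distances(x)
    want <- oracle_cluster(x, cfg)
    crit_got <- max(got$criterion_values[as.character(got$chosen_k)])
    expect_equal(got$chosen_k, want$k)
    expect_equal(unname(crit_got), want$crit, tolerance = 1e-6)
  }
})

region_row <- function() data.table::data.table(
  region_id = 1L, ref_id = "chr1", anchor_left_site = 3L,
  anchor_right_site = 6L)

clustering_of <- function(means, sds, ns) {
  structure(list(
    clusters = data.table::data.table(mean_bp = means, sd_bp = sds, n = ns),
    chosen_k = length(means), criterion_values = c(`1` = 0),
    assignment = rep(seq_along(means), ns)), class = "distance_clustering")
}

test_that("cluster patterns map to type and zygosity as designed", {
  # two clusters, one reference-like: het insertion of ~2.6 kb
  cl <- clustering_of(c(30012, 32598), c(300, 300), c(30, 27))
  call <- call_indel(region_row(), cl, 30000)
  expect_equal(call$sv_type, "insertion")
  expect_equal(call$zygosity, "het")
  expect_equal(call$size_bp, 2598)
  expect_equal(call$allele_fraction, 27 / 57)
  # single shifted cluster with every molecule: hom deletion of ~10 kb
  cl2 <- clustering_of(19980, 300, 40)
  call2 <- call_indel(region_row(), cl2, 30000)
  expect_equal(call2$sv_type, "deletion")
  expect_equal(call2$zygosity, "hom")
  expect_equal(call2$size_bp, 10020)
  # support / total reported as printed: 12/109 = 11%
  cl3 <- clustering_of(c(30000, 35200), c(300, 300), c(97, 12))
  call3 <- call_indel(region_row(), cl3, 30000)
  expect_equal(call3$support, 12)
  expect_equal(call3$total, 109)
  expect_equal(round(call3$allele_fraction, 2), 0.11)
  # no variant cluster -> no call
  expect_equal(nrow(call_indel(region_row(), clustering_of(30100, 300, 20),
                               30000)), 0)
  # minority shifted cluster without reference companion -> zygosity unknown
  cl4 <- clustering_of(36000, 300, 9)
  call4 <- call_indel(region_row(), cl4, 30000)
  expect_equal(call4$zygosity, "hom") # af = 1 within the spanning set
  # three clusters incl. reference: multi-allelic
  cl5 <- clustering_of(c(26000, 30000, 35000), c(300, 300, 300), c(10, 10, 10))
  call5 <- call_indel(region_row(), cl5, 30000)
  expect_equal(nrow(call5), 2)
  expect_true(all(call5$zygosity == "multi-allelic"))
})

test_that("postprocessing merges duplicate calls and filters weak ones", {
  calls <- data.table::data.table(
    ref_id = "chr1", sv_type = "deletion", zygosity = "het",
    start_bp = c(100000, 104000), end_bp = c(140000, 141000),
    size_bp = c(5000, 5200), support = c(10, 6), total = c(20, 18),
    allele_fraction = c(0.5, 0.33), separation = c(8, 7),
    mean_confidence = c(12, 11))
  out <- postprocess_calls(calls)
  expect_equal(nrow(out), 1)
  expect_equal(out$support, 16)
  expect_equal(out$size_bp, (5000 * 10 + 5200 * 6) / 16)
  # a lone supporting molecule cannot clear the report threshold
  weak <- data.table::data.table(
    ref_id = "chr1", sv_type = "insertion", zygosity = "het",
    start_bp = 5e5, end_bp = 5.2e5, size_bp = 4000, support = 1, total = 30,
    allele_fraction = 1 / 30, separation = 3, mean_confidence = 10)
  expect_equal(nrow(postprocess_calls(weak)), 0)
})

test_that("the four-step pipeline calls a planted low-fraction indel", {
  # 15%-support regime: the fraction the flexible clustering must handle
  ds <- indel_world(n_sv = 4, noise = noise_model(), coverage = 80,
                    seed = 19, size_range = c(5000, 5000),
                    mixture = mixture_spec(c(sample1 = 0.85, sample2 = 0.15)))
  res <- call_indels(ds$alignments, ds$molecules, ds$ref_genome)
  ev <- evaluate_calls(res$calls, ds$truth)
  expect_gte(ev$overall$recall, 0.75)
  expect_gte(ev$overall$precision, 0.75)
})

test_that("an SV-free genome yields at most 1 false call per 10 Mb", {
  ref <- random_reference_genome(n_chrom = 2, chrom_length_bp = 5e6,
                                 density_per_100kb = 16, seed = 71)
  ds <- simulate_dataset(ref, clone_graph(), mixture_spec(c(sample1 = 1)),
                         noise_model(), coverage = 60, seed = 72)
  res <- call_indels(ds$alignments, ds$molecules, ref)
  expect_lte(nrow(res$calls), 1)
})
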