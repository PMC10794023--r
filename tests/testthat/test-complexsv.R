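# junction fixture: two segments with controllable geometry
seg_at <- function(ref_id, ref_lo, ref_hi, ori, q_lo, q_hi, sites,
                   mol = "m1") {
  qs <- if (ori == "+") c(q_lo, q_hi) else c(q_hi, q_lo)
  alignment_record(mol, ref_id, ori, qs[1], qs[2], ref_lo, ref_hi,
                   site_pairs = cbind(sites,
                                      if (ori == "+") seq_along(sites)
                                      else rev(seq_along(sites))),
                   confidence = 10)
}

test_that("junction classification follows the hand-written truth table", {
  cfg <- om_config()
  classify <- function(left, right) {
    j <- make_junction(left, right,
                       slack_bp = cfg$complexsv$query_overlap_slack_bp)
    out <- classify_junction(j, cfg)
    if (is.null(out)) NA_character_ else out$bp_type
  }
  L <- seg_at("chr21", 1e6, 1.2e6, "+", 0, 2e5, 10:14)
  # different chromosome -> inter-chromosomal translocation break point
  expect_equal(classify(L, seg_at("chr13", 5e6, 5.2e6, "+", 2.1e5, 4e5, 50:54)),
               "tra_inter_bp")
  # orientation flip, same chromosome, abutting -> inversion break point
  expect_equal(classify(L, seg_at("chr21", 1.2e6, 1.4e6, "-", 2.1e5, 4e5, 15:19)),
               "inversion_bp")
  expect_equal(classify(L, seg_at("chr21", 1.2e6, 1.4e6, "+", 2.1e5, 4e5, 15:19)),
               NA_character_) # collinear, no gap discrepancy -> none
  # ref overlap >= 2 labels, same orientation -> duplication break point
  expect_equal(classify(L, seg_at("chr21", 1.05e6, 1.3e6, "+", 2.1e5, 4e5, 11:16)),
               "dup_bp")
  # re-ordered segments -> intra-chromosomal translocation
  expect_equal(classify(L, seg_at("chr21", 2e5, 4e5, "+", 2.1e5, 4e5, 2:4)),
               "tra_intra_bp")
  # collinear with large ref-gap deficit: junction-scale deletion, then
  # intra-translocation once the discrepancy exceeds its floor
  expect_equal(classify(L, seg_at("chr21", 1.3e6, 1.5e6, "+", 2.1e5, 4e5, 20:24)),
               "large_del_bp")   # disc = 100 kb - 10 kb = 90 kb
  expect_equal(classify(L, seg_at("chr21", 2.5e6, 2.7e6, "+", 2.1e5, 4e5, 30:34)),
               "tra_intra_bp")   # disc = 1.3 Mb - 10 kb > 1 Mb
  # query gap far exceeding ref gap -> junction-scale insertion
  expect_equal(classify(L, seg_at("chr21", 1.21e6, 1.4e6, "+", 3e5, 5e5, 15:19)),
               "large_ins_bp")   # query gap 100 kb vs ref gap 10 kb
  # '-' segments on the same chromosome, collinear for '-' reading -> none
  A <- seg_at("chr21", 1.2e6, 1.4e6, "-", 0, 2e5, 15:19)
  B <- seg_at("chr21", 1e6, 1.19e6, "-", 2.1e5, 4e5, 10:14)
  expect_equal(classify(A, B), NA_character_)
  # query-overlapping segments beyond slack -> junction rejected
  expect_null(make_junction(L, seg_at("chr21", 1.2e6, 1.4e6, "+", 1e5, 3e5,
                                      15:19), slack_bp = 10000))
})

test_that("canonical locus ordering puts the lower chromosome/position first", {
  L <- seg_at("chr21", 1e6, 1.2e6, "+", 0, 2e5, 10:14)
  R <- seg_at("chr13", 5e6, 5.2e6, "+", 2.1e5, 4e5, 50:54)
  bp <- classify_junction(make_junction(L, R))
  expect_equal(bp$ref_a, "chr13")
  expect_equal(bp$ref_b, "chr21")
  expect_lte(bp$pos_a, bp$pos_b + 1e9) # ordering by (ref, pos) is canonical
})

test_that("single-segment molecules yield no break-point calls", {
  ss <- split_alignment_sets(list(seg_at("chr1", 1e6, 1.2e6, "+", 0, 2e5,
                                         10:14)))
  expect_equal(nrow(call_from_split_sets(ss)), 0)
})

test_that("an A-B-A' molecule yields two paired, full-span break points", {
  segs <- list(
    seg_at("chr21", 1e6, 1.2e6, "+", 0, 2e5, 10:14),
    seg_at("chr13", 5e6, 5.1e6, "+", 2.05e5, 3.05e5, 50:54),
    seg_at("chr21", 1.201e6, 1.4e6, "+", 3.1e5, 5e5, 15:19))
  ss <- split_alignment_sets(segs, c(m1 = 5e5))
  bp <- call_from_split_sets(ss)
  expect_equal(nrow(bp), 2)
  expect_true(all(bp$bp_type == "tra_inter_bp"))
  expect_true(all(bp$full_span))
})

test_that("contig calls mirror molecule calls with contig source", {
  segs <- list(
    seg_at("chr16", 1e6, 2e6, "+", 0, 1e6, 10:19, mol = "ctg1"),
    seg_at("chr6", 8e6, 9e6, "+", 1.01e6, 2e6, 80:89, mol = "ctg1"))
  ss <- split_alignment_sets(segs, c(ctg1 = 2e6))
  bp <- call_from_contigs(ss)
  expect_equal(bp$bp_type, "tra_inter_bp")
  expect_equal(bp$source, "contig")
  # a collinear full-length contig gives nothing
  one <- split_alignment_sets(list(seg_at("chr16", 1e6, 2e6, "+", 0, 1e6,
                                          10:19, mol = "ctg2")))
  expect_equal(nrow(call_from_contigs(one)), 0)
})

test_that("an uncorroborated contig call stays partial; corroborated promotes", {
  bp_contig <- data.table::data.table(
    bp_type = "dup_bp", ref_a = "chr1", pos_a = 1e6, side_a = "L",
    ref_b = "chr1", pos_b = 1.1e6, side_b = "R", pattern = "++",
    molecule_id = "ctg1", source = "contig", full_span = TRUE)
  out <- consolidate_breakpoints(bp_contig)
  expect_equal(out$status, "partial")
  # with one corroborating molecule the contig weighs min_bp_support
  bp_mol <- data.table::copy(bp_contig)[, `:=`(molecule_id = "m9",
                                               source = "split")]
  out2 <- consolidate_breakpoints(rbind(bp_contig, bp_mol))
  expect_equal(out2$status, "complete")
  expect_gte(out2$support, om_config()$complexsv$min_bp_support + 1)
})

test_that("lone dup cluster without full-span evidence is partial", {
  bp <- data.table::rbindlist(lapply(1:4, function(i) data.table::data.table(
    bp_type = "dup_bp", ref_a = "chr1", pos_a = 1e6 + i * 100, side_a = "L",
    ref_b = "chr1", pos_b = 1.1e6 + i * 100, side_b = "R", pattern = "++",
    molecule_id = sprintf("m%d", i), source = "split", full_span = FALSE)))
  out <- consolidate_breakpoints(bp)
  expect_equal(out$sv_type, "duplication")
  expect_equal(out$status, "partial")
})

test_that("jittered break points cluster to the true loci (1-D oracle)", {
  set.seed(55)
  true_loci <- c(1e6, 2e6, 3.2e6, 4.1e6, 4.9e6)
  rows <- list()
  for (i in seq_along(true_loci)) {
    for (k in 1:20) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        bp_type = "inversion_bp", ref_a = "chr1",
        pos_a = true_loci[i] + rnorm(1, 0, 3000), side_a = "L",
        ref_b = "chr1", pos_b = true_loci[i] + 5e4 + rnorm(1, 0, 3000),
        side_b = "L", pattern = "+-", molecule_id = sprintf("m%d_%d", i, k),
        source = "split", full_span = FALSE)
    }
  }
  bp <- data.table::rbindlist(rows)
  out <- consolidate_breakpoints(bp)
  expect_equal(nrow(out), 5)
  # refined positions are within a few kb of the true loci
  expect_true(all(abs(sort(out$start_bp) - true_loci) < 6000))
  # oracle: single-linkage gaps > merge window over sorted positions
  gaps <- diff(sort(bp$pos_a))
  expect_equal(sum(gaps > om_config()$complexsv$merge_window_bp) + 1L, 5L)
})

test_that("inversion boundary pairs promote to one complete inversion", {
  rows <- lapply(1:6, function(k) data.table::data.table(
    bp_type = "inversion_bp", ref_a = "chr1",
    pos_a = 1e6 + rnorm(1, 0, 1000), side_a = "L",
    ref_b = "chr1", pos_b = 1.05e6 + rnorm(1, 0, 1000), side_b = "L",
    pattern = if (k <= 3) "+-" else "-+",
    molecule_id = sprintf("m%d", k), source = "split", full_span = FALSE))
  set.seed(56)
  out <- consolidate_breakpoints(data.table::rbindlist(rows))
  expect_equal(nrow(out), 1)
  expect_equal(out$sv_type, "inversion")
  expect_equal(out$status, "complete")
})

test_that("break-point refinement error shrinks with support", {
  set.seed(57)
  errs <- vapply(c(2, 5, 10, 20), function(n_sup) {
    med <- replicate(40, {
      bp <- data.table::rbindlist(lapply(1:n_sup, function(k)
        data.table::data.table(
          bp_type = "dup_bp", ref_a = "chr1",
          pos_a = 1e6 + rnorm(1, 0, 5000), side_a = "L", ref_b = "chr1",
          pos_b = 1.2e6 + rnorm(1, 0, 5000), side_b = "R", pattern = "++",
          molecule_id = sprintf("m%d", k), source = "split",
          full_span = TRUE)))
      out <- consolidate_breakpoints(bp)
      abs(out$start_bp - 1e6)
    })
    median(med)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))  # monotone non-increasing in support
})

test_that("insertions subsumed by size-compatible duplications are suppressed", {
  cpx <- data.table::data.table(
    call_id = "complex_1", sv_type = "duplication", ref_id = "chr1",
    start_bp = 1e6, end_bp = 1.004e6, size_bp = 4000,
    ref_id2 = NA_character_, pos2_bp = NA_real_, status = "complete",
    support = 12, full_span_support = 5L, confidence = 0.8)
  ind <- data.table::data.table(
    call_id = c("indel_1", "indel_2"), sv_type = "insertion",
    ref_id = "chr1", start_bp = c(0.995e6, 1.8e6), end_bp = c(1.01e6, 1.82e6),
    size_bp = c(4100, 3000), zygosity = "het", allele_fraction = 0.4,
    support = 9L, total = 20L, separation = 5, mean_confidence = 10,
    confidence = 0.9)
  out <- annotate_and_deduplicate(cpx, ind)
  # the overlapping, size-compatible insertion is replaced by the duplication
  expect_false("indel_1" %in% out$call_id)
  expect_true("indel_2" %in% out$call_id)   # unrelated insertion unchanged
  expect_equal(out[call_id == "complex_1", cross_ref], "indel_1")
  expect_true(all(out$status %in% c("complete", "partial")))
})

test_that("gene annotation attaches overlapping gene names", {
  ind <- data.table::data.table(
    call_id = "indel_1", sv_type = "deletion", ref_id = "chr8",
    start_bp = 2e6, end_bp = 2.1e6, size_bp = 3700, zygosity = "het",
    allele_fraction = 0.49, support = 56L, total = 114L, separation = 9,
    mean_confidence = 10, confidence = 0.95)
  genes <- data.frame(chrom = c("chr8", "chr8"), start = c(2.05e6, 5e6),
                      end = c(2.4e6, 5.1e6), name = c("CSMD1", "OTHER"))
  out <- annotate_and_deduplicate(NULL, ind, gene_intervals = genes)
  expect_equal(out$genes, "CSMD1")
})
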