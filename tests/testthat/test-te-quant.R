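two_family_loci <- function() {
  te_fixture(
    rep("chr1", 4), start = c(0, 5000, 20000, 25000),
    end = c(1000, 6000, 21000, 26000),
    family = c("A", "A", "B", "B")
  )
}

test_that("exclusive-family read assignment follows the all-alignments rule", {
  te <- two_family_loci()
  all_a <- aln_fixture(rep("r1", 3), "chr1", c(100, 300, 5100), hit_count = 3)
  expect_equal(assign_read_family(all_a, te), "A")
  mixed <- aln_fixture(rep("r2", 2), "chr1", c(100, 20100), hit_count = 2)
  expect_true(is.na(assign_read_family(mixed, te)))
  outside <- aln_fixture(rep("r3", 2), "chr1", c(100, 10000), hit_count = 2)
  expect_true(is.na(assign_read_family(outside, te)))
  # an alignment counts as inside only when >= half the read overlaps
  edge_in <- aln_fixture("r4", "chr1", 950) # 50 of 100 bp inside locus A
  expect_equal(assign_read_family(edge_in, te), "A")
  edge_out <- aln_fixture("r5", "chr1", 951) # 49 bp inside
  expect_true(is.na(assign_read_family(edge_out, te)))
  expect_error(assign_read_family(dplyr::bind_rows(all_a, mixed), te),
               "single read_id")
})

test_that("family counting gives one count per read and exact CPM arithmetic", {
  te <- two_family_loci()
  aln <- dplyr::bind_rows(
    aln_fixture(sprintf("u%02d", 1:10), "chr1", rep(100, 10)),
    aln_fixture(rep("m1", 4), "chr1", c(100, 300, 5100, 5300), hit_count = 4)
  )
  fc <- family_counts(aln, te, total_mappable_reads = 1e6)
  # 10 unique reads + 1 four-alignment read, all exclusively in family A
  expect_equal(fc$counts$count[fc$counts$family == "A"], 11)
  expect_equal(fc$counts$cpm[fc$counts$family == "A"], 11)
  expect_equal(fc$counts$log2_cpm1[fc$counts$family == "A"], log2(12))
  expect_equal(fc$counts$count[fc$counts$family == "B"], 0)
  expect_equal(fc$n_assigned, 11)
  expect_error(family_counts(aln, te, 0), "positive")
})

test_that("family counting matches the exhaustive oracle on simulated reads", {
  made <- make_annotation(31, loci_per_family = 15, n_genes = 0, chrom_len = 3e5)
  aln <- simulate_alignments(made$annotation, made$truth, n_reads = 1000,
                             multimap_rate = 0.5, seed = 32)
  aln <- dplyr::select(aln, -true_family, -true_locus_id)
  te <- made$annotation$te_loci
  oracle <- oracle_assign_family(aln, te)
  got <- retroreg:::read_family_table(aln, te)
  merged <- dplyr::left_join(oracle, got, by = "read_id", suffix = c("_o", "_g"))
  expect_identical(merged$family_g, merged$family_o)
  fc <- family_counts(aln, te, total_mappable_reads = 1e6)
  oracle_counts <- table(oracle$family[!is.na(oracle$family)])
  for (f in names(oracle_counts)) {
    expect_equal(fc$counts$count[fc$counts$family == f],
                 as.numeric(oracle_counts[[f]]))
  }
  # conservation: total family counts never exceed the number of reads
  expect_lte(sum(fc$counts$count), dplyr::n_distinct(aln$read_id))
})

test_that("EM matches the analytic two-locus fixed point", {
  te <- te_fixture(c("chr1", "chr1"), c(0, 10000), c(1000, 11000), family = "A")
  build <- function(u_a, u_b, m) {
    dplyr::bind_rows(
      if (u_a > 0) aln_fixture(sprintf("ua%d", 1:u_a), "chr1", 100),
      if (u_b > 0) aln_fixture(sprintf("ub%d", 1:u_b), "chr1", 10100),
      if (m > 0) dplyr::bind_rows(lapply(1:m, function(i) {
        aln_fixture(rep(sprintf("m%d", i), 2), "chr1", c(200, 10200), hit_count = 2)
      }))
    )
  }
  # the quoted case: u_A = 30, u_B = 10, m = 20 -> 45 / 15
  em <- em_locus_quant(build(30, 10, 20), te)
  expect_equal(sort(em$counts$em_total, decreasing = TRUE), c(45, 15),
               tolerance = 1e-6)
  # all evidence at A: u_A = 5, u_B = 0, 10 shared -> 15 / 0
  em0 <- em_locus_quant(build(5, 0, 10), te)
  expect_equal(sort(em0$counts$em_total, decreasing = TRUE), c(15, 0),
               tolerance = 1e-6)
  # random (u_A, u_B, m) against the closed-form allocation a = u_A + m * a / (a + b)
  withr::local_seed(44)
  for (i in 1:5) {
    u <- sample(1:40, 2)
    m <- sample(1:30, 1)
    em <- em_locus_quant(build(u[1], u[2], m), te)
    tot <- sum(u) + m
    expect_equal(unname(em$counts$em_total),
                 c(u[1] + m * u[1] / sum(u), u[2] + m * u[2] / sum(u)),
                 tolerance = 1e-6)
    expect_equal(sum(em$counts$em_total), tot, tolerance = 1e-6)
  }
})

test_that("EM respects unique evidence, conserves reads, and increases likelihood", {
  te <- te_fixture(c("chr1", "chr1", "chr1"), c(0, 10000, 20000),
                   c(1000, 11000, 21000), family = "A")
  aln <- dplyr::bind_rows(
    aln_fixture(sprintf("u%d", 1:12), "chr1", rep(c(100, 10100, 20100), 4)),
    dplyr::bind_rows(lapply(1:9, function(i) {
      aln_fixture(rep(sprintf("m%d", i), 3), "chr1", c(200, 10200, 20200),
                  hit_count = 3)
    }))
  )
  em <- em_locus_quant(aln, te)
  expect_true(em$converged)
  expect_true(all(em$counts$em_total >= em$counts$unique - 1e-9))
  expect_equal(sum(em$counts$em_total), em$n_assigned, tolerance = 1e-6)
  expect_true(all(diff(em$loglik) >= -1e-9))
  # no multi-mappers: EM equals unique counts immediately
  uniq_only <- aln_fixture(sprintf("u%d", 1:6), "chr1", rep(c(100, 10100), 3))
  em_u <- em_locus_quant(uniq_only, te)
  expect_equal(em_u$counts$em_total, em_u$counts$unique)
  # alignments outside every locus are dropped with a message
  with_stray <- dplyr::bind_rows(uniq_only, aln_fixture("s1", "chr1", 5000))
  expect_message(em_s <- em_locus_quant(with_stray, te), "dropped 1")
  expect_equal(em_s$n_assigned, 6)
})

test_that("EM recovers planted locus proportions from heavy multi-mapping", {
  made <- make_annotation(11, n_families = 1, loci_per_family = 10, n_genes = 0)
  aln <- simulate_alignments(made$annotation, made$truth, n_reads = 20000,
                             multimap_rate = 0.4, seed = 12)
  em <- em_locus_quant(aln, made$annotation$te_loci)
  truth_p <- made$truth$locus_proportions[["LTR5_Hs"]]
  expect_lt(max(abs(em$theta[names(truth_p)] - truth_p)), 0.02)
})

test_that("family expression summary gives mean and population sd of log2 CPM", {
  te <- two_family_loci()
  mk <- function(count_a) {
    aln <- aln_fixture(sprintf("r%d", seq_len(count_a)), "chr1", rep(100, count_a))
    family_counts(aln, te, total_mappable_reads = 1e6)
  }
  s1 <- mk(3); s2 <- mk(15)
  out <- summarize_family_expression(list(s1, s2))
  v <- c(s1$counts$log2_cpm1[1], s2$counts$log2_cpm1[1])
  expect_equal(out$mean_log2_cpm1[out$family == "A"], mean(v))
  expect_equal(out$sd_log2_cpm1[out$family == "A"],
               sqrt(mean((v - mean(v))^2)))
  identical_out <- summarize_family_expression(list(s1, s1))
  expect_equal(identical_out$sd_log2_cpm1, c(0, 0))
  expect_error(summarize_family_expression(list(s1)), "at least 2")
  # 10 random samples against a direct two-pass computation
  withr::local_seed(55)
  samples <- lapply(1:10, function(i) mk(sample(1:50, 1)))
  out10 <- summarize_family_expression(samples)
  vals <- vapply(samples, function(s) s$counts$log2_cpm1[s$counts$family == "A"],
                 numeric(1))
  expect_equal(out10$mean_log2_cpm1[out10$family == "A"], mean(vals))
  expect_equal(out10$sd_log2_cpm1[out10$family == "A"],
               sqrt(sum((vals - mean(vals))^2) / 10))
})
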