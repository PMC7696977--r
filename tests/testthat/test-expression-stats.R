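test_that("BH adjustment reproduces the hand step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "finite")
  withr::local_seed(111)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("DEG thresholding applies strict alpha and inclusive fold-change bounds", {
  rec <- tibble::tibble(
    gene_id = c("up_clear", "lfc_boundary", "p_fail", "down_clear", "lfc_small"),
    log2fc = c(1.2, 1.0, 3.0, -2.0, 0.5),
    pvalue = c(1e-4, 1e-4, 0.9, 1e-4, 1e-4),
    padj = c(0.04, 0.04, 0.9, 0.04, 0.04)
  )
  out <- deg_filter(rec)
  expect_setequal(out$up$gene_id, c("up_clear", "lfc_boundary"))
  expect_equal(out$down$gene_id, "down_clear")
  strict <- deg_filter(rec, lfc_inclusive = FALSE)
  expect_setequal(strict$up$gene_id, "up_clear")
  # padj computed from pvalue when absent
  no_padj <- dplyr::select(rec, -padj)
  out2 <- deg_filter(no_padj)
  expect_equal(out2$records$padj, bh_adjust(rec$pvalue))
  # random table against a direct threshold oracle
  withr::local_seed(112)
  tab <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                        log2fc = rnorm(300, 0, 1.2),
                        pvalue = runif(300)^2)
  got <- deg_filter(tab)
  q <- oracle_bh(tab$pvalue)
  keep <- q < 0.05 & abs(tab$log2fc) >= 1
  expect_setequal(c(got$up$gene_id, got$down$gene_id), tab$gene_id[keep])
})

test_that("planted DE simulation keeps the empirical FDR under control", {
  withr::local_seed(113)
  fdrs <- vapply(1:40, function(i) {
    sim <- simulate_de_table(n_genes = 1000, n_true = 100, lfc = 2,
                             seed = sample.int(1e6, 1))
    out <- deg_filter(sim$records)
    called <- c(out$up$gene_id, out$down$gene_id)
    if (length(called) == 0) return(0)
    mean(!called %in% sim$truth$true_deg_ids)
  }, numeric(1))
  expect_lte(mean(fdrs), 0.10)
})

test_that("set overlap tests match the hand chi-square and the hypergeometric oracle", {
  universe <- sprintf("g%03d", 1:200)
  res <- set_overlap_test(universe[1:100], universe[c(1:30, 101:110)], universe,
                          method = "chi2")
  expect_equal(unname(res$table), matrix(c(30, 70, 10, 90), 2, byrow = TRUE))
  expect_equal(res$statistic, 12.5, tolerance = 1e-9)
  expect_equal(res$p, pchisq(12.5, 1, lower.tail = FALSE), tolerance = 1e-9)
  # empty second set: no association, p 1
  expect_equal(set_overlap_test(universe[1:50], character(0), universe,
                                method = "chi2")$p, 1)
  expect_error(set_overlap_test("x", "x", character(0)), "non-empty")
  expect_error(set_overlap_test("not_in_universe", universe[1], universe),
               "subset")
  # Fisher p equals exact hypergeometric enumeration; transpose-invariant
  withr::local_seed(114)
  for (i in 1:50) {
    n <- sample(20:120, 1)
    u <- sprintf("u%03d", seq_len(n))
    a <- sample(u, sample.int(n, 1))
    b <- sample(u, sample.int(n, 1))
    f <- set_overlap_test(a, b, u, method = "fisher")
    expect_equal(f$p, oracle_fisher(f$table), tolerance = 1e-10)
    f_t <- set_overlap_test(b, a, u, method = "fisher")
    expect_equal(f_t$p, f$p, tolerance = 1e-12)
  }
})

test_that("Spearman correlation is rank-based with the asymptotic t p-value", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(spearman_corr(x, x * 3 + 1)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  withr::local_seed(115)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- sample(1:10, n, replace = TRUE) # ties exercised
    b <- a + rnorm(n, 0, 3)
    got <- spearman_corr(a, b)
    expect_equal(got$rho, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    # invariant under strictly monotone transforms
    expect_equal(spearman_corr(exp(a), b)$rho, got$rho)
  }
  expect_warning(out <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(out$constant_input)
  expect_error(spearman_corr(1:3, 1:3), "at least 4")
})

test_that("enhancer candidates require all three criteria and the inclusive 10 kb boundary", {
  te <- te_fixture(rep("chr1", 3), c(50000, 90000, 130000),
                   c(50500, 90500, 130500), family = "LTR5_Hs")
  bound <- te$locus_id[1:2]
  genes <- tibble::tibble(
    gene_id = c("hit", "boundary_hit", "too_far", "not_up", "not_reciprocal",
                "unbound_locus"),
    chrom = "chr1",
    strand = "+",
    tss = c(52000, 60500, 101000, 53000, 54000, 131000)
  )
  # boundary_hit TSS 60500: distance to locus end base 50499 is 10001 -> out;
  # to 50500-width locus... use distance to locus 1 edge: 60500 - 50499 = 10001.
  # Make it exactly 10 000 instead:
  genes$tss[2] <- 60499
  de_states <- tibble::tibble(
    gene_id = genes$gene_id,
    log2fc = c(-2, -2, -2, -2, +2, -2),
    pvalue = c(1e-8, 1e-8, 1e-8, 1e-8, 1e-8, 1e-8)
  )
  de_treatment <- tibble::tibble(
    gene_id = genes$gene_id,
    log2fc = c(2, 2, 2, 0.1, 2, 2),
    pvalue = c(1e-8, 1e-8, 1e-8, 1e-8, 1e-8, 1e-8)
  )
  out <- enhancer_candidates(genes, te, bound, de_treatment, de_states)
  expect_setequal(out$gene_id, c("hit", "boundary_hit"))
  expect_equal(out$distance_bp[out$gene_id == "boundary_hit"], 10000)
  expect_true(all(out$reciprocal_response & out$upregulated_with_treatment &
                    out$tf_bound))
  # one bp further: excluded
  genes$tss[2] <- 60500
  out2 <- enhancer_candidates(genes, te, bound, de_treatment, de_states)
  expect_equal(out2$gene_id, "hit")
  # reciprocal direction flag flips the state requirement
  out_up <- enhancer_candidates(genes, te, bound, de_treatment, de_states,
                                reciprocal_sign = "up")
  expect_equal(out_up$gene_id, "not_reciprocal")
})

test_that("planted synthetic integration fixture yields exactly the planted genes", {
  made <- make_annotation(116)
  pair <- simulate_de_pair(made$annotation, made$truth, seed = 117)
  out <- enhancer_candidates(made$annotation$genes, made$annotation$te_loci,
                             made$truth$bound_locus_ids,
                             pair$de_treatment, pair$de_states)
  expect_setequal(out$gene_id, pair$truth$planted_candidate_genes)
  expect_gt(length(pair$truth$planted_candidate_genes), 0)
})

test_that("comparative-CT fold changes double per cycle and average replicates first", {
  ctrl <- qpcr_measurement("ctrl", target_ct = c(24, 24.2, 23.8),
                           reference_ct = c(18, 18.1, 17.9))
  expect_equal(ddct_fold_change(ctrl, ctrl), 1.0)
  case1 <- qpcr_measurement("case", target_ct = c(23, 23.2, 22.8),
                            reference_ct = c(18, 18.1, 17.9))
  expect_equal(ddct_fold_change(case1, ctrl), 2.0)
  # hand computation on an uneven replicate table
  case2 <- qpcr_measurement("case2", target_ct = c(25.1, 24.7),
                            reference_ct = c(18.4, 18.0))
  dct_case <- mean(c(25.1, 24.7)) - mean(c(18.4, 18.0))
  dct_ctrl <- mean(c(24, 24.2, 23.8)) - mean(c(18, 18.1, 17.9))
  expect_equal(ddct_fold_change(case2, ctrl), 2^-(dct_case - dct_ctrl))
  expect_error(qpcr_measurement("bad", numeric(0), 18), "positive")
})
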