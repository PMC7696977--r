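test_that("BED6 and rmsk repeat annotations load with 0-based half-open coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t1068\tLTR5_Hs\t0\t+", bed)
  loci <- load_repeat_annotation(bed)
  expect_equal(loci$family, "LTR5_Hs")
  expect_equal(loci$length_bp, 968)
  expect_equal(loci$locus_id, "chr1:100-1068:LTR5_Hs")

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(load_repeat_annotation(empty)), 0)

  rmsk <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily",
    "chr1\t100\t1068\t+\tLTR5_Hs\tLTR\tERVK",
    "chr1\t5000\t5400\tC\tAluY\tSINE\tAlu",
    "chr2\t10\t900\t-\tL1HS\tLINE\tL1"
  ), rmsk)
  loci <- load_repeat_annotation(rmsk)
  # hand parse of the same fixture
  expect_equal(loci$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(loci$start, c(100, 5000, 10))
  expect_equal(loci$end, c(1068, 5400, 900))
  expect_equal(loci$strand, c("+", "-", "-"))
  expect_equal(loci$family, c("LTR5_Hs", "AluY", "L1HS"))
  expect_equal(loci$class_name, c("LTR", "SINE", "LINE"))
})

test_that("malformed annotation lines raise parse errors naming the line", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tA\t0\t+", "chr1\tnot_a_number\t300\tB"), bed)
  expect_error(load_repeat_annotation(bed), "line 2")
  short <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100", short)
  expect_error(load_repeat_annotation(short), "line 1")
})

test_that("GTF gene models convert coordinates and locate the strand-aware TSS", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1000\t1200\t.\t+\t.\tgene_id "gplus"; transcript_id "gplus.t1";',
    'chr1\tsrc\texon\t1500\t1800\t.\t+\t.\tgene_id "gplus"; transcript_id "gplus.t1";',
    'chr1\tsrc\texon\t1000\t1200\t.\t-\t.\tgene_id "gminus"; transcript_id "gminus.t1";',
    'chr1\tsrc\texon\t1500\t1800\t.\t-\t.\tgene_id "gminus"; transcript_id "gminus.t1";'
  ), gtf)
  gm <- load_gene_models(gtf)
  expect_equal(gm$genes$tss[gm$genes$gene_id == "gplus"], 999)
  expect_equal(gm$genes$tss[gm$genes$gene_id == "gminus"], 1799)
  # 1-based inclusive [1000, 1200] becomes 0-based half-open [999, 1200)
  expect_equal(min(gm$features$start), 999)
  expect_equal(max(gm$features$end), 1800)
})

test_that("gene models round-trip through GTF", {
  made <- make_annotation(5, n_genes = 20, chrom_len = 3e5, loci_per_family = 5)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(made$annotation$genes, gtf)
  back <- load_gene_models(gtf)
  orig <- made$annotation$genes
  expect_equal(dplyr::arrange(back$genes, gene_id),
               dplyr::arrange(orig$genes, gene_id))
  expect_equal(
    dplyr::arrange(back$features, gene_id, start),
    dplyr::arrange(orig$features, gene_id, start)[names(back$features)]
  )
})

test_that("TE loci round-trip through BED6", {
  made <- make_annotation(6, loci_per_family = 10, n_genes = 0)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed6(made$annotation$te_loci, bed)
  back <- load_repeat_annotation(bed)
  orig <- made$annotation$te_loci
  cols <- c("chrom", "start", "end", "strand", "family", "locus_id", "length_bp")
  expect_equal(dplyr::arrange(back[cols], locus_id),
               dplyr::arrange(orig[cols], locus_id))
})

test_that("locus filtering removes exonic/UTR overlaps and the inclusive 1 kb TSS vicinity", {
  genes <- gene_models_fixture(
    genes = tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000),
    features = tibble::tibble(gene_id = "g1", chrom = "chr1",
                              start = 10000, end = 10500, type = "exon")
  )
  te <- te_fixture(
    rep("chr1", 5),
    start = c(10100, 9600, 8500, 7999, 11501),
    end = c(10200, 9800, 9000, 8500, 12000),
    family = c("inside_exon", "near_tss", "edge_1000", "edge_1001", "downstream_far")
  )
  # edge_1000: locus end 9000 -> nearest base 8999, distance 10000-8999 = 1001
  # -> kept; near_tss at 200 bp -> removed; start 11501 is 1501 bp past the TSS
  surv <- filter_te_loci(te, genes, tss_exclusion_bp = 1000)
  expect_setequal(surv$family, c("edge_1000", "edge_1001", "downstream_far"))
  # boundary: a locus whose nearest edge is exactly 1000 bp away is removed
  exact <- te_fixture("chr1", 11000, 11200, family = "exact")
  expect_equal(nrow(filter_te_loci(exact, genes, 1000)), 0)
  exact_up <- te_fixture("chr1", 8500, 9001, family = "exact_up") # edge 9000, distance 1000
  expect_equal(nrow(filter_te_loci(exact_up, genes, 1000)), 0)
  expect_error(filter_te_loci(te, genes, -1), "non-negative")
})

test_that("locus filtering matches the all-pairs oracle and is order-invariant", {
  withr::local_seed(101)
  te <- random_intervals(200, max_pos = 50000, max_width = 800)
  te <- retroreg:::make_te_loci(te$chrom, te$start, te$end, te$strand,
                                family = sprintf("F%03d", seq_len(200)))
  gstart <- floor(runif(20, 0, 50000))
  genes <- gene_models_fixture(
    genes = tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                           chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                           strand = sample(c("+", "-"), 20, replace = TRUE),
                           tss = gstart),
    features = tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                              chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                              start = gstart, end = gstart + 500, type = "exon")
  )
  surv <- filter_te_loci(te, genes, 1000)
  expect_equal(surv$locus_id, oracle_filter(te, genes, 1000)$locus_id)
  perm <- sample.int(nrow(te))
  surv_perm <- filter_te_loci(te[perm, ], genes, 1000)
  expect_setequal(surv_perm$locus_id, surv$locus_id)
})

test_that("interval merging follows the strict <50 bp gap rule", {
  two <- genomic_intervals("chr1", c(100, 249), c(200, 300))
  expect_equal(nrow(merge_intervals(two, 50)), 1) # gap 49 merges
  expect_equal(merge_intervals(two, 50)$end, 300)
  two50 <- genomic_intervals("chr1", c(100, 250), c(200, 300))
  expect_equal(nrow(merge_intervals(two50, 50)), 2) # gap exactly 50 does not
  expect_equal(nrow(merge_intervals(two[0, ], 50)), 0)
})

test_that("interval merging matches the quadratic oracle and is idempotent", {
  withr::local_seed(202)
  for (gap in c(0, 1, 50)) {
    x <- random_intervals(120, max_pos = 3000, max_width = 80)
    got <- merge_intervals(x, gap)
    expect_equal(as.data.frame(got), as.data.frame(oracle_merge(x, gap)))
    expect_equal(merge_intervals(got, gap), got) # idempotent
    gaps <- got |>
      dplyr::group_by(chrom) |>
      dplyr::summarise(g = list(start[-1] - end[-dplyr::n()]), .groups = "drop")
    expect_true(all(unlist(gaps$g) >= gap))
  }
})

test_that("overlap fraction is relative to the first interval", {
  a <- genomic_intervals("chr1", 0, 200)
  b <- genomic_intervals("chr1", 100, 400)
  expect_equal(overlap_fraction(a, b), 0.5)
  expect_equal(overlap_fraction(b, a), 100 / 300)
  expect_equal(overlap_fraction(a, genomic_intervals("chr1", 300, 400)), 0)
  expect_equal(overlap_fraction(a, genomic_intervals("chr2", 0, 200)), 0)
  inner <- genomic_intervals("chr1", 50, 150)
  expect_equal(overlap_fraction(inner, a), 1.0)
  # symmetry: fraction(a,b) * len(a) == fraction(b,a) * len(b)
  withr::local_seed(303)
  x <- random_intervals(50, chroms = "chr1", max_pos = 1000, max_width = 300)
  y <- random_intervals(50, chroms = "chr1", max_pos = 1000, max_width = 300)
  expect_equal(overlap_fraction(x, y) * (x$end - x$start),
               overlap_fraction(y, x) * (y$end - y$start))
})
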