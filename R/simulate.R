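#' Seeded synthetic genome annotation with planted truth
#'
#' Generates a small multi-chromosome repeat annotation (several TE families,
#' one of them the LTR5_Hs-like target family, with solo-LTR-sized loci of
#' 300-1000 bp), gene models with exons and TSSs, and a truth bundle holding
#' every planted parameter downstream generators and recovery tests use.
#' Loci are mutually non-overlapping, as are genes; loci may fall inside
#' genes by chance, which is what the TSS/exon filtering step is for. All
#' generators in this module are pure functions of their parameters and
#' seed: the global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n_chroms number of chromosomes (default 3).
#' @param chrom_len length of each chromosome in bp (default 1e6).
#' @param n_families number of TE families (default 4; the first is named
#'   `LTR5_Hs`).
#' @param loci_per_family loci per family (default 50).
#' @param n_genes number of genes (default 100).
#' @param enrichment_fold planted peak-rate fold for the target family
#'   (default 3).
#' @param bump_height,bump_sd planted Gaussian signal bump at target-family
#'   anchors: peak height (track value units, default 1) and sd in bp
#'   (default 200).
#' @param motif_p_bound,motif_p_unbound planted E-box presence probability in
#'   bound (default 0.5) and unbound (default 0.1) target-family loci.
#' @param bound_frac fraction of target-family loci marked factor-bound
#'   (default 0.5).
#' @return list with `annotation` (list of class `annotation_set`: `te_loci`,
#'   `genes`, `chrom_sizes`) and `truth` (list of class `truth_bundle`).
#' @export
make_annotation <- function(seed, n_chroms = 3, chrom_len = 1e6, n_families = 4,
                            loci_per_family = 50, n_genes = 100,
                            enrichment_fold = 3, bump_height = 1, bump_sd = 200,
                            motif_p_bound = 0.5, motif_p_unbound = 0.1,
                            bound_frac = 0.5) {
  if (n_chroms < 1 || chrom_len < 1 || n_families < 1 || loci_per_family < 1 ||
      n_genes < 0) {
    abort("annotation parameters must be positive")
  }
  n_loci <- n_families * loci_per_family
  if (ceiling(n_loci / n_chroms) * 1000 > chrom_len) {
    abort("infeasible packing: requested locus bp exceeds chromosome length")
  }
  withr::with_seed(seed, {
    chroms <- sprintf("chr%d", seq_len(n_chroms))
    chrom_sizes <- setNames(rep(chrom_len, n_chroms), chroms)
    families <- c("LTR5_Hs",
                  c("LTR13", "MER41B", "L1PA2", "AluYb8", "THE1B",
                    "MLT1A", "LTR7")[seq_len(max(0, n_families - 1))])

    loci <- place_intervals(
      n = n_loci,
      widths = function(n) round(runif(n, 300, 1000)),
      chroms = chroms, chrom_len = chrom_len
    )
    loci$strand <- sample(c("+", "-"), n_loci, replace = TRUE)
    loci$family <- rep(families, each = loci_per_family)[sample.int(n_loci)]
    te_loci <- make_te_loci(loci$chrom, loci$start, loci$end, loci$strand,
                            loci$family, class_name = "LTR")

    genes <- if (n_genes > 0) {
      spans <- place_intervals(
        n = n_genes,
        widths = function(n) round(runif(n, 2000, 8000)),
        chroms = chroms, chrom_len = chrom_len
      )
      spans$gene_id <- sprintf("gene_%03d", seq_len(n_genes))
      spans$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      feats <- purrr::pmap_dfr(spans, function(chrom, start, end, gene_id, strand) {
        n_exons <- sample(2:4, 1)
        # exon boundaries inside the span; first/last exon pinned to the ends
        cuts <- sort(sample(seq(start + 200, end - 200, by = 50),
                            2 * (n_exons - 1)))
        starts <- c(start, cuts[seq(2, length(cuts), by = 2)])
        ends <- c(cuts[seq(1, length(cuts), by = 2)], end)
        tibble(gene_id = gene_id, chrom = chrom, start = starts, ends = ends,
               type = "exon")
      })
      names(feats)[names(feats) == "ends"] <- "end"
      structure(list(
        genes = tibble(gene_id = spans$gene_id, chrom = spans$chrom,
                       strand = spans$strand,
                       tss = ifelse(spans$strand == "+", spans$start, spans$end - 1)),
        features = feats
      ), class = "gene_models")
    } else {
      structure(list(genes = tibble(gene_id = character(), chrom = character(),
                                    strand = character(), tss = numeric()),
                     features = tibble(gene_id = character(), chrom = character(),
                                       start = numeric(), end = numeric(),
                                       type = character())),
                class = "gene_models")
    }

    family_proportions <- local({
      w <- rgamma(n_families, shape = 5)
      setNames(w / sum(w), families)
    })
    locus_proportions <- lapply(setNames(families, families), function(f) {
      ids <- te_loci$locus_id[te_loci$family == f]
      w <- rgamma(length(ids), shape = 5)
      setNames(w / sum(w), ids)
    })
    target_ids <- te_loci$locus_id[te_loci$family == "LTR5_Hs"]
    bound_locus_ids <- sort(sample(target_ids, round(bound_frac * length(target_ids))))

    truth <- structure(list(
      seed = seed,
      families = families,
      family_proportions = family_proportions,
      locus_proportions = locus_proportions,
      enriched_family = "LTR5_Hs",
      enrichment_fold = enrichment_fold,
      motif_presence_probs = c(bound = motif_p_bound, unbound = motif_p_unbound),
      bound_locus_ids = bound_locus_ids,
      profile_bump = list(center_offset = 0, height = bump_height, sd = bump_sd),
      multimap_cross_family_prob = 0.1,
      true_deg_ids = character(),
      planted_lfc = NA_real_,
      planted_candidate_genes = character()
    ), class = "truth_bundle")

    list(
      annotation = structure(list(te_loci = te_loci, genes = genes,
                                  chrom_sizes = chrom_sizes),
                             class = "annotation_set"),
      truth = truth
    )
  })
}

# place n non-overlapping intervals of the given widths uniformly over the
# chromosomes, by rejection sampling (deterministic under the caller's seed)
place_intervals <- function(n, widths, chroms, chrom_len, max_tries = 10000) {
  w <- widths(n)
  chrom <- sample(chroms, n, replace = TRUE)
  out <- tibble(chrom = chrom, start = NA_real_, end = NA_real_)
  occupied <- lapply(setNames(chroms, chroms), function(c) IRanges::IRanges())
  for (i in seq_len(n)) {
    ci <- chrom[[i]]
    for (try in seq_len(max_tries)) {
      s <- floor(runif(1, 0, chrom_len - w[[i]]))
      cand <- IRanges::IRanges(start = s + 1, end = s + w[[i]])
      if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0L) {
        occupied[[ci]] <- c(occupied[[ci]], cand)
        out$start[[i]] <- s
        out$end[[i]] <- s + w[[i]]
        break
      }
    }
    if (is.na(out$start[[i]])) abort("could not place non-overlapping intervals")
  }
  out
}

#' Simulate multi-mapping read alignments with planted family abundances
#'
#' Each read's true source family and locus are drawn from the truth
#' bundle's planted proportions, the primary alignment is placed uniformly
#' inside the source locus, and with probability `multimap_rate` the read is
#' reported at 1-3 additional positions inside other loci (cross-family with
#' probability `truth$multimap_cross_family_prob`, otherwise same-family).
#' `hit_count` (the SAM `NH` value) counts all reported alignments of the
#' read.
#'
#' @param annotation an `annotation_set`.
#' @param truth its `truth_bundle`.
#' @param n_reads number of reads (default 50000).
#' @param read_len read length in bp (default 100).
#' @param multimap_rate probability a read is multi-mapped (default 0.4).
#' @param seed integer seed.
#' @return alignment tibble (see [read_alignments()]) plus a `true_family`
#'   and `true_locus_id` column per record for recovery tests.
#' @export
simulate_alignments <- function(annotation, truth, n_reads = 50000,
                                read_len = 100, multimap_rate = 0.4, seed) {
  if (multimap_rate < 0 || multimap_rate > 1) abort("multimap_rate must be in [0, 1]")
  te <- annotation$te_loci
  withr::with_seed(seed, {
    fam <- sample(truth$families, n_reads, replace = TRUE,
                  prob = truth$family_proportions[truth$families])
    locus_id <- vapply(fam, function(f) {
      p <- truth$locus_proportions[[f]]
      sample(names(p), 1, prob = p)
    }, character(1))
    li <- match(locus_id, te$locus_id)
    pos <- floor(runif(n_reads, te$start[li],
                       pmax(te$start[li] + 1, te$end[li] - read_len)))
    is_multi <- runif(n_reads) < multimap_rate
    k_extra <- ifelse(is_multi, sample(1:3, n_reads, replace = TRUE), 0L)
    read_id <- sprintf("read_%06d", seq_len(n_reads))

    primary <- tibble(
      read_id = read_id, chrom = te$chrom[li], start = pos,
      end = pos + read_len, strand = "+",
      mapq = ifelse(is_multi, 1, 255), hit_count = 1L + k_extra,
      true_family = fam, true_locus_id = locus_id
    )
    extras <- NULL
    if (any(k_extra > 0)) {
      ridx <- rep(which(k_extra > 0), times = k_extra[k_extra > 0])
      cross <- runif(length(ridx)) < truth$multimap_cross_family_prob
      extra_locus <- vapply(seq_along(ridx), function(j) {
        i <- ridx[[j]]
        pool <- if (cross[[j]] && dplyr::n_distinct(te$family) > 1L) {
          te$locus_id[te$family != fam[[i]]]
        } else {
          setdiff(te$locus_id[te$family == fam[[i]]], locus_id[[i]])
        }
        if (length(pool) == 0L) locus_id[[i]] else sample(pool, 1)
      }, character(1))
      ei <- match(extra_locus, te$locus_id)
      epos <- floor(runif(length(ridx), te$start[ei],
                          pmax(te$start[ei] + 1, te$end[ei] - read_len)))
      extras <- tibble(
        read_id = read_id[ridx], chrom = te$chrom[ei], start = epos,
        end = epos + read_len, strand = "+",
        mapq = 1, hit_count = 1L + k_extra[ridx],
        true_family = fam[ridx], true_locus_id = locus_id[ridx]
      )
    }
    dplyr::bind_rows(primary, extras) |> dplyr::arrange(.data$read_id)
  })
}

# sum values of overlapping segments into a disjoint segment table
combine_segments <- function(segments) {
  gr <- GenomicRanges::GRanges(segments$chrom,
                               IRanges::IRanges(segments$start + 1, segments$end))
  dis <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dis, gr)
  val <- rowsum(segments$value[S4Vectors::subjectHits(hits)],
                group = S4Vectors::queryHits(hits))
  idx <- as.integer(rownames(val))
  tibble(chrom = as.character(GenomicRanges::seqnames(dis))[idx],
         start = GenomicRanges::start(dis)[idx] - 1,
         end = as.numeric(GenomicRanges::end(dis))[idx],
         value = unname(val[, 1L])) |>
    dplyr::filter(.data$value != 0) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Simulate a signal track with planted bumps at target-family anchors
#'
#' Flat background (plus optional per-tile Gaussian noise, clamped at zero)
#' over every chromosome, with a Gaussian-shaped bump of the truth bundle's
#' height and sd centered at the strand-aware 5' anchor of each
#' enriched-family locus. Bumps are laid down at 1-bp resolution over
#' +/- 4 sd, so their discrete mass matches the analytic Gaussian integral
#' closely.
#'
#' @param annotation an `annotation_set`.
#' @param truth its `truth_bundle` (uses `profile_bump`, `enriched_family`).
#' @param library_size total tags for CPM normalization (default 1e6).
#' @param background flat per-bp background value (default 0.01).
#' @param noise_sd sd of additive per-100bp-tile noise (default 0: none).
#' @param seed integer seed.
#' @return a [signal_track()].
#' @export
simulate_track <- function(annotation, truth, library_size = 1e6,
                           background = 0.01, noise_sd = 0, seed) {
  te <- annotation$te_loci
  bump <- truth$profile_bump
  withr::with_seed(seed, {
    tiles <- purrr::imap_dfr(as.list(annotation$chrom_sizes), function(len, chrom) {
      starts <- seq(0, len - 1, by = 100)
      tibble(chrom = chrom, start = starts, end = pmin(starts + 100, len))
    })
    tiles$value <- pmax(0, background + if (noise_sd > 0) {
      rnorm(nrow(tiles), 0, noise_sd)
    } else 0)

    segs <- tiles
    if (bump$height > 0) {
      anchors <- te |>
        dplyr::filter(.data$family == truth$enriched_family) |>
        dplyr::mutate(anchor = ifelse(.data$strand == "-", .data$end, .data$start) +
                        bump$center_offset)
      half <- ceiling(4 * bump$sd)
      offsets <- seq(-half, half - 1)
      gauss <- bump$height * exp(-(offsets + 0.5)^2 / (2 * bump$sd^2))
      bumps <- tibble(
        chrom = rep(anchors$chrom, each = length(offsets)),
        start = rep(anchors$anchor, each = length(offsets)) + offsets,
        value = rep(gauss, times = nrow(anchors))
      ) |>
        dplyr::filter(.data$start >= 0) |>
        dplyr::mutate(end = .data$start + 1)
      segs <- dplyr::bind_rows(tiles, bumps)
    }
    signal_track(combine_segments(segs), library_size = library_size)
  })
}

#' Simulate peaks over TE loci with a planted family enrichment
#'
#' Each peak's host locus is drawn with probability proportional to locus
#' span, multiplied by the truth bundle's `enrichment_fold` for the enriched
#' family (`fold = 1` gives a uniform placement over TE base pairs — the
#' calibration null). The peak center is uniform inside the host locus, so
#' every peak overlaps its locus by at least half its width; the summit is
#' the peak center.
#'
#' @param annotation an `annotation_set`.
#' @param truth its `truth_bundle`.
#' @param n_peaks number of peaks (default 400).
#' @param fold planted rate multiplier for the enriched family (default:
#'   `truth$enrichment_fold`).
#' @param width_range peak width range in bp (default 150-300).
#' @param seed integer seed.
#' @return peak tibble (see [read_peaks()]).
#' @export
simulate_peaks <- function(annotation, truth, n_peaks = 400,
                           fold = truth$enrichment_fold,
                           width_range = c(150, 300), seed) {
  te <- annotation$te_loci
  withr::with_seed(seed, {
    w <- (te$end - te$start) *
      ifelse(te$family == truth$enriched_family, fold, 1)
    li <- sample.int(nrow(te), n_peaks, replace = TRUE, prob = w / sum(w))
    width <- round(runif(n_peaks, width_range[[1L]], width_range[[2L]]))
    center <- floor(runif(n_peaks, te$start[li], te$end[li]))
    start <- pmax(0, center - floor(width / 2))
    tibble(
      chrom = te$chrom[li], start = start, end = start + width,
      name = sprintf("peak_%04d", seq_len(n_peaks)), score = 100,
      summit_offset = center - start
    ) |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::mutate(name = sprintf("peak_%04d", dplyr::row_number()))
  })
}

#' Simulate a genome sequence with planted E-boxes
#'
#' Chromosomes are i.i.d. uniform A/C/G/T. An E-box 6-mer (`CACGTG` or
#' `CATGTG`, chosen at random) is written at the center of each bound
#' target-family locus with probability `p_bound`, and of each unbound
#' target-family locus with probability `p_unbound` (both from the truth
#' bundle).
#'
#' @param annotation an `annotation_set`.
#' @param truth its `truth_bundle`.
#' @param seed integer seed.
#' @return named [Biostrings::DNAStringSet], one sequence per chromosome.
#' @export
simulate_sequences <- function(annotation, truth, seed) {
  withr::with_seed(seed, {
    chroms <- lapply(as.list(annotation$chrom_sizes), function(len) {
      sample(c("A", "C", "G", "T"), len, replace = TRUE)
    })
    te <- annotation$te_loci[annotation$te_loci$family == truth$enriched_family, ]
    bound <- te$locus_id %in% truth$bound_locus_ids
    p <- ifelse(bound, truth$motif_presence_probs[["bound"]],
                truth$motif_presence_probs[["unbound"]])
    plant <- runif(nrow(te)) < p
    motif <- sample(EBOX_FORWARD, nrow(te), replace = TRUE)
    for (i in which(plant)) {
      center <- floor((te$start[[i]] + te$end[[i]]) / 2)
      at <- (center - 3):(center + 2) + 1 # 1-based
      chroms[[te$chrom[[i]]]][at] <- strsplit(motif[[i]], "")[[1L]]
    }
    Biostrings::DNAStringSet(vapply(chroms, paste0, character(1), collapse = ""))
  })
}

#' Simulate a differential-expression table with planted true positives
#'
#' Null genes receive `p ~ Uniform(0, 1)` and `log2fc ~ Normal(0, 0.2)`;
#' planted true genes receive `p ~ Beta(0.01, 1)` (heavily concentrated near
#' zero) and `log2fc = +/- lfc`.
#'
#' @param n_genes total genes (default 1000).
#' @param n_true planted true DEGs (default 100).
#' @param lfc planted absolute log2 fold change (default 2).
#' @param seed integer seed.
#' @param gene_ids optional ids (default `gene_0001`...); planted genes are a
#'   random subset.
#' @param planted_sign `"both"` (random, default), `"up"`, or `"down"`.
#' @return list with `records` (DE tibble) and `truth` (list:
#'   `true_deg_ids`, `planted_lfc`).
#' @export
simulate_de_table <- function(n_genes = 1000, n_true = 100, lfc = 2, seed,
                              gene_ids = sprintf("gene_%04d", seq_len(n_genes)),
                              planted_sign = c("both", "up", "down")) {
  planted_sign <- match.arg(planted_sign)
  stopifnot(n_true <= n_genes, length(gene_ids) == n_genes)
  withr::with_seed(seed, {
    true_idx <- sample.int(n_genes, n_true)
    p <- runif(n_genes)
    l2fc <- rnorm(n_genes, 0, 0.2)
    if (n_true > 0) {
      p[true_idx] <- rbeta(n_true, 0.01, 1)
      sign <- switch(planted_sign,
                     both = sample(c(-1, 1), n_true, replace = TRUE),
                     up = 1, down = -1)
      l2fc[true_idx] <- sign * lfc
    }
    list(
      records = tibble(gene_id = gene_ids, log2fc = l2fc, pvalue = p,
                       mean_expr = 2^rnorm(n_genes, 5, 2)),
      truth = list(true_deg_ids = sort(gene_ids[true_idx]), planted_lfc = lfc)
    )
  })
}

#' Simulate the treatment/state DE-table pair with planted enhancer targets
#'
#' Builds two DE tables over the annotation's genes: a state contrast (the
#' planted candidate genes are significantly down) and a treatment contrast
#' (the same genes significantly up). Candidates are drawn from the genes
#' whose TSS lies within `neighborhood_bp` of a bound target-family locus,
#' so that [enhancer_candidates()] on these inputs must return exactly the
#' planted set; near-miss decoys (each failing exactly one criterion) are
#' planted too.
#'
#' @param annotation an `annotation_set`.
#' @param truth its `truth_bundle`.
#' @param n_candidates planted qualifying genes (default 3; reduced when the
#'   geometry offers fewer eligible genes).
#' @param neighborhood_bp TSS neighborhood used for eligibility (default
#'   10000).
#' @param planted_lfc planted absolute log2 fold change (default 2).
#' @param seed integer seed.
#' @return list with `de_treatment`, `de_states` (DE tibbles) and `truth`
#'   (the input truth with `planted_candidate_genes` filled in).
#' @export
simulate_de_pair <- function(annotation, truth, n_candidates = 3,
                             neighborhood_bp = 10000, planted_lfc = 2, seed) {
  gtab <- annotation$genes$genes
  te <- annotation$te_loci
  bound <- te[te$family == truth$enriched_family &
                te$locus_id %in% truth$bound_locus_ids, ]
  eligible <- gtab |>
    dplyr::left_join(bound, by = "chrom", suffix = c("", ".locus"),
                     relationship = "many-to-many") |>
    dplyr::mutate(d = tss_locus_distance(.data$tss, .data$start, .data$end)) |>
    dplyr::filter(!is.na(.data$d), .data$d <= neighborhood_bp) |>
    dplyr::distinct(.data$gene_id) |>
    dplyr::pull("gene_id")
  withr::with_seed(seed, {
    n_cand <- min(n_candidates, length(eligible))
    planted <- sort(sample(eligible, n_cand))
    n_genes <- nrow(gtab)
    base <- function() {
      tibble(gene_id = gtab$gene_id,
             log2fc = rnorm(n_genes, 0, 0.2),
             pvalue = runif(n_genes))
    }
    de_states <- base()
    de_treatment <- base()
    plant <- function(de, ids, lfc) {
      i <- match(ids, de$gene_id)
      de$log2fc[i] <- lfc
      de$pvalue[i] <- 1e-9
      de
    }
    de_states <- plant(de_states, planted, -planted_lfc)
    de_treatment <- plant(de_treatment, planted, planted_lfc)
    # decoys: significant in only one contrast, or in both but far from any
    # bound locus — each must fail exactly one of the three criteria
    near_pool <- setdiff(eligible, planted)
    near_pool <- near_pool[sample.int(length(near_pool))]
    far <- setdiff(gtab$gene_id, c(eligible, planted))
    decoys <- list(
      states_only = near_pool[seq_len(min(1, length(near_pool)))],
      treatment_only = near_pool[1 + seq_len(min(1, max(0, length(near_pool) - 1)))],
      both_but_far = far[sample.int(length(far))][seq_len(min(1, length(far)))]
    )
    de_states <- plant(de_states, c(decoys$states_only, decoys$both_but_far),
                       -planted_lfc)
    de_treatment <- plant(de_treatment, c(decoys$treatment_only, decoys$both_but_far),
                          planted_lfc)
    truth$planted_candidate_genes <- planted
    truth$decoy_genes <- decoys
    list(de_treatment = de_treatment, de_states = de_states, truth = truth)
  })
}

#' Write every synthetic input the pipeline consumes
#'
#' Generates the full fixture set in the exact dialects the readers consume
#' (BED6 repeats, GTF genes, chrom.sizes, SAM alignments, bedGraph track,
#' narrowPeak peaks, FASTA genome, DE TSVs) plus the truth bundle as a JSON
#' sidecar, so every I/O path is exercised end to end.
#'
#' @param seed integer seed; sub-generators derive their own seeds from it.
#' @param outdir output directory (created).
#' @param n_reads,multimap_rate,n_peaks,noise_sd,... forwarded to the
#'   generators; annotation parameters via `...` go to [make_annotation()].
#' @return invisibly, a list with the in-memory objects (`annotation`,
#'   `truth`, `alignments`, `track`, `peaks`, `genome`, `de_treatment`,
#'   `de_states`) and `paths` (named file paths).
#' @export
simulate_all <- function(seed, outdir, n_reads = 50000, multimap_rate = 0.4,
                         n_peaks = 400, noise_sd = 0.02, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  made <- make_annotation(seed, ...)
  ann <- made$annotation
  truth <- made$truth
  aln <- simulate_alignments(ann, truth, n_reads = n_reads,
                             multimap_rate = multimap_rate, seed = seed + 1)
  track <- simulate_track(ann, truth, noise_sd = noise_sd, seed = seed + 2)
  peaks <- simulate_peaks(ann, truth, n_peaks = n_peaks, seed = seed + 3)
  genome <- simulate_sequences(ann, truth, seed = seed + 4)
  pair <- simulate_de_pair(ann, truth, seed = seed + 5)
  truth <- pair$truth

  paths <- list(
    repeats = file.path(outdir, "repeats.bed"),
    genes = file.path(outdir, "genes.gtf"),
    chrom_sizes = file.path(outdir, "genome.chrom.sizes"),
    alignments = file.path(outdir, "alignments.sam"),
    track = file.path(outdir, "signal.bedgraph"),
    peaks = file.path(outdir, "peaks.narrowPeak"),
    genome = file.path(outdir, "genome.fa"),
    de_treatment = file.path(outdir, "de_treatment.tsv"),
    de_states = file.path(outdir, "de_states.tsv"),
    bound_loci = file.path(outdir, "bound_loci.txt"),
    universe = file.path(outdir, "universe.txt"),
    truth = file.path(outdir, "truth.json")
  )
  write_bed6(ann$te_loci, paths$repeats)
  write_gtf(ann$genes, paths$genes)
  write_chrom_sizes(ann$chrom_sizes, paths$chrom_sizes)
  write_sam(dplyr::select(aln, -"true_family", -"true_locus_id"),
            ann$chrom_sizes, paths$alignments)
  write_bedgraph(track, paths$track)
  write_narrowpeak(peaks, paths$peaks)
  Biostrings::writeXStringSet(genome, paths$genome)
  readr::write_tsv(pair$de_treatment, paths$de_treatment)
  readr::write_tsv(pair$de_states, paths$de_states)
  writeLines(truth$bound_locus_ids, paths$bound_loci)
  writeLines(ann$genes$genes$gene_id, paths$universe)
  # named vectors become JSON objects, not bare arrays, so names survive
  as_json_tree <- function(x) {
    if (is.list(x)) lapply(x, as_json_tree)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(as_json_tree(unclass(truth)), paths$truth,
                       auto_unbox = TRUE, digits = NA)

  invisible(list(annotation = ann, truth = truth, alignments = aln,
                 track = track, peaks = peaks, genome = genome,
                 de_treatment = pair$de_treatment, de_states = pair$de_states,
                 paths = paths))
}
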