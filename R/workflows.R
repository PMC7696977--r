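#' Run configuration for the three analysis workflows
#'
#' All stage parameters default to the pipeline's canonical values: 1 kb TSS
#' exclusion, 50 bp peak merging, 50% peak overlap, 5 kb flanks with 100 bp
#' bins, 25 bp motif flanks, alpha 0.05, `|log2fc| >= 1`, 10 kb enhancer
#' neighborhood, and a 5-peak reporting floor. Unknown parameter or input
#' names are rejected; the effective config is echoed verbatim into the
#' output directory of every run.
#'
#' @param inputs named list of input file paths (see the workflow runners for
#'   which each needs).
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest.
#' @param ... parameter overrides (must name existing defaults).
#' @return list of class `run_config`.
#' @export
run_config <- function(inputs = list(), outdir, seed = 1L, ...) {
  params <- list(
    tss_exclusion_bp = 1000,
    merge_gap_bp = 50,
    min_frac = 0.5,
    flank_bp = 5000,
    bin_bp = 100,
    motif_flank_bp = 25,
    alpha = 0.05,
    min_abs_lfc = 1,
    neighborhood_bp = 10000,
    min_peaks = 5,
    read_overlap_frac = 0.5,
    em_tol = 1e-8,
    em_max_iter = 1000,
    enrichment_model = "span",
    overlap_method = "chi2",
    target_family = "LTR5_Hs",
    reciprocal_sign = "down",
    library_size = 1e6,
    total_mappable_reads = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) {
    abort(sprintf("unknown config parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  params[names(overrides)] <- overrides
  known_inputs <- c("repeats", "genes", "chrom_sizes", "alignments", "track",
                    "peaks", "genome", "de_treatment", "de_states",
                    "bound_loci", "universe")
  unknown <- setdiff(names(inputs), known_inputs)
  if (length(unknown)) {
    abort(sprintf("unknown config input(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(list(inputs = inputs, params = params, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

require_inputs <- function(config, needed) {
  missing <- setdiff(needed, names(config$inputs))
  if (length(missing)) {
    abort(sprintf("config is missing required input(s): %s",
                  paste(missing, collapse = ", ")))
  }
  absent <- needed[!file.exists(unlist(config$inputs[needed]))]
  if (length(absent)) {
    abort(sprintf("input file(s) not found: %s",
                  paste(unlist(config$inputs[absent]), collapse = ", ")))
  }
}

start_run <- function(config, workflow) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(workflow = workflow, inputs = config$inputs, params = config$params,
         seed = config$seed),
    file.path(config$outdir, sprintf("%s_config.json", workflow)),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}

finish_run <- function(config, workflow, outputs, timings) {
  manifest <- list(
    workflow = workflow,
    inputs = lapply(config$inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    params = config$params,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("retroreg")),
    outputs = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    stage_seconds = timings
  )
  path <- file.path(config$outdir, sprintf("%s_manifest.json", workflow))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest
}

load_filtered_loci <- function(config) {
  te <- load_repeat_annotation(config$inputs$repeats)
  genes <- load_gene_models(config$inputs$genes)
  list(genes = genes,
       loci = filter_te_loci(te, genes, config$params$tss_exclusion_bp))
}

#' TE expression workflow: filter loci, family CPM, EM locus counts
#'
#' `filter-loci -> quant-family -> quant-locus` over one alignment set.
#' Needs inputs `repeats`, `genes`, `alignments`; `total_mappable_reads`
#' must be set in the parameters (it is a property of the full library, not
#' of the TE-restricted alignments).
#'
#' @param config a [run_config()].
#' @return list with `filtered_loci`, `family_counts`, `locus_counts`,
#'   `manifest`.
#' @export
run_expression_workflow <- function(config) {
  require_inputs(config, c("repeats", "genes", "alignments"))
  p <- config$params
  if (is.null(p$total_mappable_reads)) {
    abort("total_mappable_reads must be set in the config parameters")
  }
  start_run(config, "expression")
  t0 <- proc.time()[["elapsed"]]
  flt <- load_filtered_loci(config)
  aln <- read_alignments(config$inputs$alignments)
  t1 <- proc.time()[["elapsed"]]
  fam <- family_counts(aln, flt$loci, p$total_mappable_reads,
                       read_overlap_frac = p$read_overlap_frac)
  t2 <- proc.time()[["elapsed"]]
  target <- flt$loci[flt$loci$family == p$target_family, ]
  loc <- em_locus_quant(aln, target, read_overlap_frac = p$read_overlap_frac,
                        tol = p$em_tol, max_iter = p$em_max_iter)
  t3 <- proc.time()[["elapsed"]]

  out <- c(
    filtered_loci = file.path(config$outdir, "filtered_loci.bed"),
    family_counts = file.path(config$outdir, "family_counts.tsv"),
    locus_counts = file.path(config$outdir, "locus_counts.tsv")
  )
  write_bed6(flt$loci, out[["filtered_loci"]])
  readr::write_tsv(fam$counts, out[["family_counts"]])
  readr::write_tsv(loc$counts, out[["locus_counts"]])
  manifest <- finish_run(config, "expression", as.list(out),
                         list(load = t1 - t0, family = t2 - t1, locus = t3 - t2))
  list(filtered_loci = flt$loci, family_counts = fam, locus_counts = loc,
       manifest = manifest)
}

#' Regulatory workflow: metaprofile, peak enrichment, motif test
#'
#' `profile -> peak-enrich -> motif-test` over one shared filtered locus
#' set. Needs inputs `repeats`, `genes`, `track`, `peaks`, `genome`. Peaks
#' are merged (`merge_gap_bp`) before assignment; the profile is built over
#' the filtered target-family loci; the E-box presence test compares
#' fixed-width center windows ([locus_center_windows()]) of peak-bound
#' versus unbound target-family loci, so presence is not confounded by
#' locus length.
#' An empty peak file yields empty enrichment and motif tables with a
#' warning, not an error.
#'
#' @param config a [run_config()].
#' @return list with `profile`, `assignment`, `enrichment`, `motif_test`,
#'   `manifest`.
#' @export
run_regulatory_workflow <- function(config) {
  require_inputs(config, c("repeats", "genes", "track", "peaks", "genome"))
  p <- config$params
  start_run(config, "regulatory")
  t0 <- proc.time()[["elapsed"]]
  flt <- load_filtered_loci(config)
  target <- flt$loci[flt$loci$family == p$target_family, ]
  track <- read_bedgraph(config$inputs$track, library_size = p$library_size)
  peaks <- read_peaks(config$inputs$peaks)
  t1 <- proc.time()[["elapsed"]]

  profile <- build_profile(track, target, flank_bp = p$flank_bp, bin_bp = p$bin_bp)
  t2 <- proc.time()[["elapsed"]]

  out <- c(
    profile = file.path(config$outdir, "profile_target_family.tsv"),
    enrichment = file.path(config$outdir, "family_enrichment.tsv"),
    motif = file.path(config$outdir, "motif_presence.tsv")
  )
  write_profile_tsv(profile, out[["profile"]])

  if (nrow(peaks) == 0L) {
    warn("no peaks supplied: enrichment and motif tables are empty")
    enrichment <- tibble(family = character(), observed = numeric(),
                         expected = numeric(), chi2 = numeric(), p = numeric(),
                         padj = numeric(), low_expected = logical(),
                         reported = logical())
    assignment <- assign_peaks_to_te(peaks, flt$loci, min_frac = p$min_frac)
    motif <- NULL
    readr::write_tsv(enrichment, out[["enrichment"]])
    readr::write_tsv(tibble(group = character(), with_motif = numeric(),
                            without_motif = numeric()), out[["motif"]])
  } else {
    merged <- merge_intervals(peaks, max_gap_bp = p$merge_gap_bp)
    merged$name <- sprintf("merged_peak_%d", seq_len(nrow(merged)))
    merged$summit_offset <- NA_real_
    assignment <- assign_peaks_to_te(merged, flt$loci, min_frac = p$min_frac)
    expected <- expected_family_peaks(assignment, flt$loci,
                                      model = p$enrichment_model)
    enrichment <- family_enrichment_test(assignment$family_counts, expected) |>
      reporting_filter(min_peaks = p$min_peaks)
    readr::write_tsv(enrichment, out[["enrichment"]])

    genome <- read_genome(config$inputs$genome)
    bound_ids <- assignment$assignments$locus_id[assignment$assignments$family ==
                                                   p$target_family]
    windows <- locus_center_windows(target, flank_bp = p$motif_flank_bp)
    bound_loci <- windows[windows$locus_id %in% bound_ids, ]
    unbound_loci <- windows[!windows$locus_id %in% bound_ids, ]
    motif <- if (nrow(bound_loci) > 0L && nrow(unbound_loci) > 0L) {
      motif_presence_test(extract_sequences(genome, bound_loci),
                          extract_sequences(genome, unbound_loci))
    } else {
      warn("bound/unbound split is degenerate: motif test skipped")
      NULL
    }
    motif_tab <- if (is.null(motif)) {
      tibble(group = character(), with_motif = numeric(), without_motif = numeric())
    } else {
      tibble(group = rownames(motif$table),
             with_motif = motif$table[, 1L], without_motif = motif$table[, 2L],
             chi2 = motif$chi2, p = motif$p)
    }
    readr::write_tsv(motif_tab, out[["motif"]])
  }
  t3 <- proc.time()[["elapsed"]]
  manifest <- finish_run(config, "regulatory", as.list(out),
                         list(load = t1 - t0, profile = t2 - t1,
                              enrichment_motif = t3 - t2))
  list(profile = profile, assignment = assignment, enrichment = enrichment,
       motif_test = motif, manifest = manifest)
}

#' Integration workflow: DEG lists, overlap test, enhancer candidates
#'
#' Thresholds the treatment and state DE tables, tests the overlap of their
#' DEG sets over an explicitly supplied universe (no silent default), and
#' calls LTR-neighborhood enhancer-candidate genes. Needs inputs `repeats`,
#' `genes`, `de_treatment`, `de_states`, `bound_loci`, `universe`.
#'
#' @param config a [run_config()].
#' @return list with `deg_treatment`, `deg_states`, `overlap`, `candidates`,
#'   `manifest`.
#' @export
run_integration_workflow <- function(config) {
  require_inputs(config, c("repeats", "genes", "de_treatment", "de_states",
                           "bound_loci", "universe"))
  p <- config$params
  start_run(config, "integration")
  t0 <- proc.time()[["elapsed"]]
  te <- load_repeat_annotation(config$inputs$repeats)
  genes <- load_gene_models(config$inputs$genes)
  de_treatment <- read_de_table(config$inputs$de_treatment)
  de_states <- read_de_table(config$inputs$de_states)
  bound_ids <- read_gene_list(config$inputs$bound_loci)
  universe <- read_gene_list(config$inputs$universe)
  t1 <- proc.time()[["elapsed"]]

  deg_t <- deg_filter(de_treatment, alpha = p$alpha, min_abs_lfc = p$min_abs_lfc)
  deg_s <- deg_filter(de_states, alpha = p$alpha, min_abs_lfc = p$min_abs_lfc)
  degs_t <- c(deg_t$up$gene_id, deg_t$down$gene_id)
  degs_s <- c(deg_s$up$gene_id, deg_s$down$gene_id)
  overlap <- set_overlap_test(intersect(degs_t, universe),
                              intersect(degs_s, universe),
                              universe, method = p$overlap_method)
  candidates <- enhancer_candidates(
    genes, te, bound_ids, de_treatment, de_states,
    neighborhood_bp = p$neighborhood_bp, target_family = p$target_family,
    reciprocal_sign = p$reciprocal_sign, alpha = p$alpha,
    min_abs_lfc = p$min_abs_lfc
  )
  t2 <- proc.time()[["elapsed"]]

  out <- c(
    deg_treatment = file.path(config$outdir, "deg_treatment.tsv"),
    deg_states = file.path(config$outdir, "deg_states.tsv"),
    overlap = file.path(config$outdir, "overlap_test.tsv"),
    candidates = file.path(config$outdir, "enhancer_candidates.tsv")
  )
  readr::write_tsv(dplyr::bind_rows(up = deg_t$up, down = deg_t$down,
                                    .id = "direction"), out[["deg_treatment"]])
  readr::write_tsv(dplyr::bind_rows(up = deg_s$up, down = deg_s$down,
                                    .id = "direction"), out[["deg_states"]])
  readr::write_tsv(tibble(
    method = overlap$method, statistic = overlap$statistic, p = overlap$p,
    n_overlap = length(overlap$overlap),
    n_a = sum(overlap$table[1, ]), n_b = sum(overlap$table[, 1]),
    universe = sum(overlap$table)
  ), out[["overlap"]])
  readr::write_tsv(candidates, out[["candidates"]])
  manifest <- finish_run(config, "integration", as.list(out),
                         list(load = t1 - t0, analyses = t2 - t1))
  list(deg_treatment = deg_t, deg_states = deg_s, overlap = overlap,
       candidates = candidates, manifest = manifest)
}
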