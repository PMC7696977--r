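# Read-locus overlap rule: an alignment "maps within" a TE locus when at
# least read_overlap_frac (default 50%) of the read lies inside the locus.
# The same rule feeds family-level exclusive counting and the locus-level EM.

# all (alignment row, locus row) pairs satisfying the overlap rule
alignment_locus_hits <- function(alignments, te_loci, read_overlap_frac = 0.5) {
  if (read_overlap_frac <= 0 || read_overlap_frac > 1) {
    abort("read_overlap_frac must be in (0, 1]")
  }
  if (nrow(alignments) == 0L || nrow(te_loci) == 0L) {
    return(tibble(aln = integer(), locus = integer()))
  }
  hits <- find_overlaps0(as_granges0(alignments), as_granges0(te_loci))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(alignments$end[q], te_loci$end[s]) - pmax(alignments$start[q], te_loci$start[s])
  keep <- ov >= read_overlap_frac * (alignments$end[q] - alignments$start[q])
  tibble(aln = q[keep], locus = s[keep])
}

# per-read exclusive family assignment for an alignment table
read_family_table <- function(alignments, te_loci, read_overlap_frac = 0.5) {
  alignments$.aln <- seq_len(nrow(alignments))
  hits <- alignment_locus_hits(alignments, te_loci, read_overlap_frac)
  hits$family <- te_loci$family[hits$locus]
  hits$read_id <- alignments$read_id[hits$aln]
  per_read <- alignments |>
    dplyr::count(.data$read_id, name = "n_aln")
  hit_stats <- hits |>
    dplyr::distinct(.data$read_id, .data$aln, .data$family) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      n_aln_hit = dplyr::n_distinct(.data$aln),
      n_fam = dplyr::n_distinct(.data$family),
      family = .data$family[1L],
      .groups = "drop"
    )
  per_read |>
    dplyr::left_join(hit_stats, by = "read_id") |>
    dplyr::mutate(family = dplyr::if_else(
      !is.na(.data$n_fam) & .data$n_fam == 1L & .data$n_aln_hit == .data$n_aln,
      .data$family, NA_character_
    )) |>
    dplyr::select("read_id", "family")
}

#' Exclusive-family assignment of one read
#'
#' A multi-mapping read is informative at the family level only when every
#' one of its reported alignments falls within loci of one and the same
#' repeat family; any alignment outside the family (or outside annotated TE
#' loci altogether) makes the read unassignable.
#'
#' @param records_of_one_read alignment tibble whose rows all share one
#'   `read_id`.
#' @param te_loci TE-locus tibble.
#' @param read_overlap_frac minimum fraction of the read inside a locus for
#'   the alignment to count as within it (default 0.5).
#' @return the family name, or `NA_character_` when the read is not
#'   family-exclusive.
#' @export
assign_read_family <- function(records_of_one_read, te_loci, read_overlap_frac = 0.5) {
  if (dplyr::n_distinct(records_of_one_read$read_id) != 1L) {
    abort("records_of_one_read must all share a single read_id")
  }
  read_family_table(records_of_one_read, te_loci, read_overlap_frac)$family[[1L]]
}

#' Family-level TE expression from alignments
#'
#' Each read contributes exactly one count to its exclusively assigned family
#' (none when unassignable), regardless of how many alignments it has.
#' Counts are normalized to CPM against the total number of reads mappable
#' anywhere on the genome — an explicit input, since it cannot be recovered
#' from a TE-restricted alignment stream — and expression is reported as
#' log2(CPM + 1).
#'
#' @param alignments alignment tibble ([read_alignments()]).
#' @param te_loci TE-locus tibble.
#' @param total_mappable_reads library size: all reads mapped anywhere on the
#'   genome.
#' @param read_overlap_frac see [assign_read_family()].
#' @return A `family_counts` object: list with `counts` (tibble `family`,
#'   `count`, `cpm`, `log2_cpm1`, one row per family present in `te_loci`),
#'   `total_mappable_reads`, `n_reads`, `n_assigned`.
#' @export
family_counts <- function(alignments, te_loci, total_mappable_reads,
                          read_overlap_frac = 0.5) {
  if (!is.numeric(total_mappable_reads) || length(total_mappable_reads) != 1L ||
      total_mappable_reads <= 0) {
    abort("total_mappable_reads must be a single positive number")
  }
  assigned <- read_family_table(alignments, te_loci, read_overlap_frac)
  if (total_mappable_reads < nrow(assigned)) {
    warn("total_mappable_reads is smaller than the number of distinct reads")
  }
  counts <- assigned |>
    dplyr::filter(!is.na(.data$family)) |>
    dplyr::count(.data$family, name = "count")
  counts <- tibble(family = sort(unique(te_loci$family))) |>
    dplyr::left_join(counts, by = "family") |>
    dplyr::mutate(
      count = dplyr::coalesce(as.numeric(.data$count), 0),
      cpm = .data$count * 1e6 / total_mappable_reads,
      log2_cpm1 = log2(.data$cpm + 1)
    )
  structure(
    list(counts = counts,
         total_mappable_reads = total_mappable_reads,
         n_reads = nrow(assigned),
         n_assigned = sum(!is.na(assigned$family))),
    class = "family_counts"
  )
}

#' Locus-level quantification by EM redistribution of multi-mappers
#'
#' Reads whose alignments fall within a single candidate locus are counted as
#' unique evidence. Reads compatible with several loci are assigned
#' fractionally: with locus abundances `theta` (initialized uniform so that
#' loci without unique reads are not zeroed at the start), the E-step gives
#' read `r` responsibility `theta_l / sum(theta_k, k in L(r))` for each
#' candidate locus `l`, and the M-step sets `theta` proportional to unique
#' counts plus fractional assignments. Unique-read evidence therefore anchors
#' the fixed point. Loci are not length-normalized: the quantity estimated is
#' a read count, reported downstream as CPM.
#'
#' @param alignments alignment tibble; alignments overlapping no provided
#'   locus are dropped (their number is reported in the result).
#' @param te_loci TE-locus tibble over which to quantify.
#' @param read_overlap_frac see [assign_read_family()].
#' @param tol stop when the largest absolute change in `theta` falls below
#'   this (default 1e-8).
#' @param max_iter iteration cap (default 1000); hitting it yields
#'   `converged = FALSE` with a warning.
#' @return A `locus_counts` object: list with `counts` (tibble `locus_id`,
#'   `unique`, `em_total`), `theta` (named abundance vector summing to 1),
#'   `loglik` (observed-data log-likelihood per iteration), `iterations`,
#'   `converged`, `n_assigned`, `n_dropped_alignments`.
#' @export
em_locus_quant <- function(alignments, te_loci, read_overlap_frac = 0.5,
                           tol = 1e-8, max_iter = 1000) {
  alignments$.aln <- seq_len(nrow(alignments))
  hits <- alignment_locus_hits(alignments, te_loci, read_overlap_frac)
  n_dropped <- dplyr::n_distinct(alignments$.aln) - dplyr::n_distinct(hits$aln)
  if (n_dropped > 0) {
    inform(sprintf("em_locus_quant: dropped %d alignment(s) overlapping no locus", n_dropped))
  }
  L <- nrow(te_loci)
  locus_ids <- te_loci$locus_id

  cand <- tibble(read_id = alignments$read_id[hits$aln], locus = hits$locus) |>
    dplyr::distinct()
  # collapse reads by candidate-set signature: EM cost scales with distinct sets
  sets <- cand |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(sig = paste(sort(.data$locus), collapse = ","), .groups = "drop") |>
    dplyr::count(.data$sig, name = "weight")
  members <- lapply(strsplit(sets$sig, ",", fixed = TRUE), as.integer)
  set_size <- lengths(members)

  unique_counts <- numeric(L)
  uni <- set_size == 1L
  if (any(uni)) {
    tab <- rowsum(sets$weight[uni], group = unlist(members[uni]))
    unique_counts[as.integer(rownames(tab))] <- tab[, 1L]
  }
  multi_members <- members[!uni]
  multi_weight <- sets$weight[!uni]
  n_assigned <- sum(sets$weight)

  theta <- rep(1 / L, L)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  n <- unique_counts
  repeat {
    iter <- iter + 1L
    frac <- numeric(L)
    ll <- sum(unique_counts[unique_counts > 0] * log(theta[unique_counts > 0]))
    for (k in seq_along(multi_members)) {
      S <- multi_members[[k]]
      th <- theta[S]
      d <- sum(th)
      if (d <= 0) {
        # degenerate: every candidate at zero abundance -> equal shares
        frac[S] <- frac[S] + multi_weight[[k]] / length(S)
        ll <- ll + multi_weight[[k]] * log(.Machine$double.xmin)
      } else {
        frac[S] <- frac[S] + multi_weight[[k]] * th / d
        ll <- ll + multi_weight[[k]] * log(d)
      }
    }
    loglik <- c(loglik, ll)
    n <- unique_counts + frac
    theta_new <- if (sum(n) > 0) n / sum(n) else rep(1 / L, L)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) warn(sprintf("EM did not converge in %d iterations", max_iter))
  structure(
    list(counts = tibble(locus_id = locus_ids,
                         unique = unique_counts,
                         em_total = n),
         theta = setNames(theta, locus_ids),
         loglik = loglik,
         iterations = iter,
         converged = converged,
         n_assigned = n_assigned,
         n_dropped_alignments = n_dropped),
    class = "locus_counts"
  )
}

#' Mean and spread of family expression across samples
#'
#' Per-family mean and population standard deviation of log2(CPM + 1) across
#' samples — the summary behind expression-versus-variability scatter plots
#' of TE families.
#'
#' @param samples list of at least two `family_counts` objects.
#' @return tibble `family`, `mean_log2_cpm1`, `sd_log2_cpm1`, `n_samples`.
#' @export
summarize_family_expression <- function(samples) {
  if (length(samples) < 2L) abort("need at least 2 samples to summarize")
  purrr::imap_dfr(samples, function(s, i) {
    dplyr::mutate(s$counts, .sample = i)
  }) |>
    tidyr::complete(.data$family, .data$.sample, fill = list(log2_cpm1 = 0)) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      mean_log2_cpm1 = mean(.data$log2_cpm1),
      sd_log2_cpm1 = sqrt(mean((.data$log2_cpm1 - mean(.data$log2_cpm1))^2)),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}
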