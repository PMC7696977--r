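#' Assign peaks to TE loci
#'
#' A peak is assigned to the locus it overlaps most, provided the overlap
#' covers at least `min_frac` of the *peak* (the query fraction, mirroring
#' `intersectBed -f` semantics). Ties are broken deterministically: smaller
#' locus start, then lexicographic locus id. Peaks are expected to be merged
#' ([merge_intervals()]) and blacklist-filtered upstream.
#'
#' @param peaks peak tibble ([read_peaks()]).
#' @param te_loci TE-locus tibble.
#' @param min_frac minimum peak-overlap fraction in `(0, 1]` (default 0.5).
#' @return A `peak_assignment` object: list with `assignments` (tibble
#'   `peak` row index, `locus_id`, `family`, `overlap_bp`, `frac` — only
#'   assigned peaks), `family_counts` (tibble `family`, `n_peaks`,
#'   `n_bound_loci`), `n_peaks`, `n_assigned`.
#' @export
assign_peaks_to_te <- function(peaks, te_loci, min_frac = 0.5) {
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac <= 0 || min_frac > 1) {
    abort("min_frac must be in (0, 1]")
  }
  assignments <- tibble(peak = integer(), locus_id = character(),
                        family = character(), overlap_bp = numeric(),
                        frac = numeric())
  if (nrow(peaks) > 0L && nrow(te_loci) > 0L) {
    hits <- find_overlaps0(as_granges0(peaks), as_granges0(te_loci))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(peaks$end[q], te_loci$end[s]) - pmax(peaks$start[q], te_loci$start[s])
    frac <- ov / (peaks$end[q] - peaks$start[q])
    cand <- tibble(peak = q, locus = s, overlap_bp = ov, frac = frac,
                   locus_start = te_loci$start[s],
                   locus_id = te_loci$locus_id[s],
                   family = te_loci$family[s]) |>
      dplyr::filter(.data$frac >= min_frac)
    assignments <- cand |>
      dplyr::arrange(.data$peak, dplyr::desc(.data$overlap_bp),
                     .data$locus_start, .data$locus_id) |>
      dplyr::distinct(.data$peak, .keep_all = TRUE) |>
      dplyr::select("peak", "locus_id", "family", "overlap_bp", "frac")
  }
  fam <- assignments |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_peaks = dplyr::n(),
                     n_bound_loci = dplyr::n_distinct(.data$locus_id),
                     .groups = "drop")
  fam <- tibble(family = sort(unique(te_loci$family))) |>
    dplyr::left_join(fam, by = "family") |>
    dplyr::mutate(n_peaks = dplyr::coalesce(as.numeric(.data$n_peaks), 0),
                  n_bound_loci = dplyr::coalesce(as.numeric(.data$n_bound_loci), 0))
  structure(
    list(assignments = assignments, family_counts = fam,
         n_peaks = nrow(peaks), n_assigned = nrow(assignments)),
    class = "peak_assignment"
  )
}

#' Expected per-family peak counts under a genomic null
#'
#' The null distributes the assigned peaks over families in proportion either
#' to the total base pairs each family occupies (`"span"`) or to its number
#' of loci (`"count"`). Families with zero weight are excluded (with a
#' message) since no expectation can be formed for them.
#'
#' @param assignment a `peak_assignment` (or the number of assigned peaks).
#' @param te_loci TE-locus tibble.
#' @param model `"span"` or `"count"`.
#' @return tibble `family`, `weight`, `expected`.
#' @export
expected_family_peaks <- function(assignment, te_loci, model = c("span", "count")) {
  model <- match.arg(model)
  n_assigned <- if (inherits(assignment, "peak_assignment")) {
    assignment$n_assigned
  } else {
    as.numeric(assignment)
  }
  w <- te_loci |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      weight = if (model == "span") sum(.data$end - .data$start) else dplyr::n(),
      .groups = "drop"
    )
  zero <- w$weight <= 0
  if (any(zero)) {
    inform(sprintf("expected_family_peaks: excluding %d zero-%s family(ies)",
                   sum(zero), model))
    w <- w[!zero, ]
  }
  dplyr::mutate(w, expected = n_assigned * .data$weight / sum(.data$weight)) |>
    dplyr::arrange(.data$family)
}

#' Per-family chi-square enrichment of peak counts
#'
#' For each family, a 1-df goodness-of-fit chi-square on the two-cell
#' partition (peaks in the family vs. all other assigned peaks) against its
#' expected share, without continuity correction; p is the upper tail.
#' Benjamini-Hochberg adjusted p-values are added across families. Families
#' whose expected cell (either side) is below 5 are flagged `low_expected`
#' but still computed.
#'
#' @param observed named vector or tibble (`family`, `n_peaks`) of observed
#'   per-family peak counts, e.g. `assign_peaks_to_te()$family_counts`.
#' @param expected tibble from [expected_family_peaks()].
#' @return An enrichment tibble: `family`, `observed`, `expected`, `chi2`,
#'   `p`, `padj`, `low_expected`, `reported` (all `TRUE` until
#'   [reporting_filter()] is applied).
#' @export
family_enrichment_test <- function(observed, expected) {
  obs <- if (is.data.frame(observed)) {
    setNames(observed$n_peaks, observed$family)
  } else {
    observed
  }
  res <- expected |>
    dplyr::mutate(observed = dplyr::coalesce(as.numeric(obs[.data$family]), 0))
  n_total <- sum(res$observed)
  if (any(res$expected <= 0)) abort("expected counts must be positive")
  res <- res |>
    dplyr::mutate(
      chi2 = (.data$observed - .data$expected)^2 / .data$expected +
        ((n_total - .data$observed) - (n_total - .data$expected))^2 /
          (n_total - .data$expected),
      p = pchisq(.data$chi2, df = 1, lower.tail = FALSE),
      padj = stats::p.adjust(.data$p, method = "BH"),
      low_expected = .data$expected < 5 | (n_total - .data$expected) < 5,
      reported = TRUE
    ) |>
    dplyr::select("family", "observed", "expected", "chi2", "p", "padj",
                  "low_expected", "reported")
  res
}

#' Keep only families supported by enough peaks
#'
#' Marks `reported = TRUE` only for families with at least `min_peaks`
#' observed peaks (boundary inclusive: 5 peaks are enough at the default).
#'
#' @param results enrichment tibble from [family_enrichment_test()].
#' @param min_peaks minimum observed peak count (default 5).
#' @return the tibble with `reported` updated.
#' @export
reporting_filter <- function(results, min_peaks = 5) {
  dplyr::mutate(results, reported = .data$observed >= min_peaks)
}
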