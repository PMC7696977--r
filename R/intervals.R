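#' Genomic intervals
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval covers bases `start .. end - 1` and its width is `end - start`.
#' Formats that use other conventions (GTF, SAM) are converted at I/O time.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("%s table must have chrom/start/end columns", what))
  }
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    abort(sprintf("%s coordinates must be finite", what))
  }
  if (any(x$start < 0)) abort(sprintf("%s start must be >= 0", what))
  if (any(x$end <= x$start)) {
    abort(sprintf("%s must satisfy start < end (half-open, width > 0)", what))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    abort(sprintf("%s strand must be one of '+', '-', '.'", what))
  }
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Overlap between two intervals as a fraction of the first
#'
#' Returns `(overlap bp) / width(a)`, the fraction semantics used when
#' intersecting peaks with repeat annotation ("50% overlap"). Vectorized over
#' paired rows of `a` and `b`; intervals on different chromosomes overlap by 0.
#'
#' @param a,b interval tibbles with the same number of rows (or one of them a
#'   single row, which is recycled).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  stopifnot(nrow(a) == nrow(b))
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  ov / interval_width(a)
}

#' Merge nearby intervals
#'
#' Per chromosome, sorts by start and merges any two intervals whose gap
#' (start of the later minus end of the earlier) is strictly less than
#' `max_gap_bp`; overlapping or bookended intervals always merge. This is the
#' "merge peaks closer than 50 bp" step. Strand is ignored and dropped.
#'
#' @param intervals interval tibble.
#' @param max_gap_bp merge when gap `< max_gap_bp` (strict); 50 by default.
#' @return tibble of disjoint intervals sorted by (chrom, start), with all
#'   pairwise gaps `>= max_gap_bp`.
#' @export
merge_intervals <- function(intervals, max_gap_bp = 50) {
  if (max_gap_bp < 0) abort("max_gap_bp must be >= 0")
  if (nrow(intervals) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  validate_intervals(intervals)
  intervals |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      # a new run starts where the gap to the furthest end so far is >= max_gap_bp
      run = cumsum(c(TRUE, (.data$start[-1] - cummax(.data$end)[-dplyr::n()]) >= max_gap_bp))
    ) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
}

# findOverlaps without the "no sequence levels in common" warning (a query
# on a chromosome absent from the subject is a legitimate zero-hit case here)
find_overlaps0 <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject,
                                               ignore.strand = TRUE))
}

# GRanges bridge: internal 0-based half-open <-> 1-based closed
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand
  )
}
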