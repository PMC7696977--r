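EBOX_FORWARD <- c("CACGTG", "CATGTG")

#' Summit-centered windows around peaks
#'
#' Builds `[summit - flank_bp, summit + flank_bp + 1)` windows (51 bp at the
#' default flank of 25, including the summit base). When a peak carries no
#' summit, the peak midpoint (floor) is used. Window starts clipped at
#' position 0 are clamped (with a message).
#'
#' @param peaks peak tibble ([read_peaks()]); `summit_offset` is relative to
#'   the peak start.
#' @param flank_bp bases on either side of the summit (default 25).
#' @return interval tibble `chrom`, `start`, `end`, `strand` with one window
#'   per peak.
#' @export
summit_windows <- function(peaks, flank_bp = 25) {
  if (flank_bp < 0) abort("flank_bp must be >= 0")
  summit <- ifelse(is.na(peaks$summit_offset),
                   floor((peaks$start + peaks$end) / 2),
                   peaks$start + peaks$summit_offset)
  start <- summit - flank_bp
  if (any(start < 0)) {
    inform(sprintf("summit_windows: clamped %d window(s) at position 0", sum(start < 0)))
    start <- pmax(start, 0)
  }
  tibble(chrom = peaks$chrom, start = start, end = summit + flank_bp + 1,
         strand = ".")
}

#' Motif windows at locus centers
#'
#' Fixed-width windows (`2 * flank_bp + 1`) centered on each locus midpoint,
#' carrying the locus id. Scanning equal-width windows instead of whole loci
#' keeps the per-sequence background motif rate independent of locus length,
#' so a bound/unbound presence contrast is not confounded by length.
#'
#' @param te_loci TE-locus tibble.
#' @param flank_bp bases on either side of the center (default 25).
#' @return interval tibble with `locus_id` preserved.
#' @export
locus_center_windows <- function(te_loci, flank_bp = 25) {
  center <- floor((te_loci$start + te_loci$end) / 2)
  tibble(chrom = te_loci$chrom, start = pmax(0, center - flank_bp),
         end = center + flank_bp + 1, strand = ".",
         locus_id = te_loci$locus_id)
}

#' Scan a sequence for the canonical E-box motif
#'
#' Finds every occurrence of the E-box `CA(C/T)GTG` on both strands,
#' reporting positions on the forward sequence. `CACGTG` is its own reverse
#' complement, so a palindromic match is reported once per position (strand
#' `+`); a reverse-strand `CATGTG` appears on the forward sequence as
#' `CACATG`. `N` bases never match.
#'
#' @param seq a character string, `DNAString`, or named length-1
#'   `DNAStringSet`.
#' @param id sequence id for the hit table (defaults to the sequence's name
#'   or `"seq"`).
#' @return hit tibble: `seq_id`, `position` (0-based on the forward
#'   sequence), `strand`, `motif` (the E-box variant matched).
#' @export
scan_ebox <- function(seq, id = NULL) {
  if (inherits(seq, "DNAStringSet")) {
    if (is.null(id)) id <- names(seq)[[1L]] %||% "seq"
    seq <- seq[[1L]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  if (is.null(id)) id <- "seq"
  hit_rows <- function(pattern, strand, motif) {
    m <- Biostrings::matchPattern(pattern, seq, fixed = TRUE)
    if (length(m) == 0L) return(NULL)
    tibble(seq_id = id, position = BiocGenerics::start(m) - 1,
           strand = strand, motif = motif)
  }
  out <- dplyr::bind_rows(
    hit_rows("CACGTG", "+", "CACGTG"), # palindromic: one hit per position
    hit_rows("CATGTG", "+", "CATGTG"),
    hit_rows("CACATG", "-", "CATGTG")
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(seq_id = character(), position = numeric(),
                  strand = character(), motif = character()))
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Scan many sequences for E-box hits
#' @param seqs named `DNAStringSet` or character vector.
#' @return hit tibble as in [scan_ebox()], all sequences combined.
#' @export
scan_ebox_set <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  ids <- names(seqs) %||% sprintf("seq_%d", seq_along(seqs))
  purrr::map2_dfr(seq_along(seqs), ids, function(i, id) scan_ebox(seqs[[i]], id = id))
}

#' E-box presence in bound versus unbound loci
#'
#' Presence is binary per sequence (at least one E-box hit anywhere in the
#' record, on either strand). The bound/unbound contrast is a 2x2 chi-square
#' without continuity correction, 1 df, upper-tail p. Per-sequence hit
#' counts are returned for diagnostics.
#'
#' @param bound,unbound `DNAStringSet` (or character) sequence sets; both
#'   must be non-empty.
#' @return A `motif_presence` object: list with `table` (2x2 integer matrix,
#'   rows bound/unbound, columns with_motif/without_motif), `chi2`, `p`,
#'   `hits` (tibble `group`, `seq_id`, `n_hits`, `present`).
#' @export
motif_presence_test <- function(bound, unbound) {
  if (length(bound) == 0L || length(unbound) == 0L) {
    abort("both bound and unbound groups must be non-empty")
  }
  presence <- function(seqs, group) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
    ids <- names(seqs) %||% sprintf("%s_%d", group, seq_along(seqs))
    hits <- scan_ebox_set(setNames(seqs, ids))
    tibble(group = group, seq_id = ids) |>
      dplyr::left_join(dplyr::count(hits, .data$seq_id, name = "n_hits"),
                       by = "seq_id") |>
      dplyr::mutate(n_hits = dplyr::coalesce(as.numeric(.data$n_hits), 0),
                    present = .data$n_hits > 0)
  }
  hits <- dplyr::bind_rows(presence(bound, "bound"), presence(unbound, "unbound"))
  tab <- matrix(
    c(sum(hits$present[hits$group == "bound"]),
      sum(!hits$present[hits$group == "bound"]),
      sum(hits$present[hits$group == "unbound"]),
      sum(!hits$present[hits$group == "unbound"])),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("bound", "unbound"), c("with_motif", "without_motif"))
  )
  ct <- chisq_2x2(tab)
  structure(list(table = tab, chi2 = ct$chi2, p = ct$p, hits = hits),
            class = "motif_presence")
}

# 2x2 Pearson chi-square, no continuity correction, 1 df upper tail.
# Degenerate margins (an all-zero row or column) carry no information: chi2 0, p 1.
chisq_2x2 <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p = 1))
  }
  n <- sum(tab)
  chi2 <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (prod(rowSums(tab)) * prod(colSums(tab)))
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
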