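#' Filter TE loci against genic features
#'
#' Removes any TE locus that overlaps an exon or UTR by at least 1 bp, or
#' whose nearest edge lies within `tss_exclusion_bp` of a transcription start
#' site (boundary inclusive: a locus exactly `tss_exclusion_bp` away is
#' removed; a locus covering the TSS is at distance 0). This is the step that
#' restricts repeat quantification to intergenic copies, so that TE signal is
#' not confounded by overlapping gene transcription.
#'
#' @param te_loci TE-locus tibble ([load_repeat_annotation()]).
#' @param genes a `gene_models` object ([load_gene_models()]).
#' @param tss_exclusion_bp exclusion radius around each TSS, in bp (default
#'   1000).
#' @return the surviving loci, in input order.
#' @export
filter_te_loci <- function(te_loci, genes, tss_exclusion_bp = 1000) {
  if (!is.numeric(tss_exclusion_bp) || length(tss_exclusion_bp) != 1L ||
      tss_exclusion_bp < 0) {
    abort("tss_exclusion_bp must be a single non-negative number")
  }
  if (nrow(te_loci) == 0L) return(te_loci)
  drop <- rep(FALSE, nrow(te_loci))
  loci_gr <- as_granges0(te_loci)

  feats <- genes$features
  if (nrow(feats) > 0L) {
    hits <- find_overlaps0(loci_gr, as_granges0(feats))
    drop[unique(S4Vectors::queryHits(hits))] <- TRUE
  }

  gtab <- genes$genes
  if (nrow(gtab) > 0L) {
    # a TSS base t excludes the locus [s, e) iff t lies in [s - d, e + d)
    expanded <- tibble(chrom = te_loci$chrom,
                       start = pmax(0, te_loci$start - tss_exclusion_bp),
                       end = te_loci$end + tss_exclusion_bp)
    tss <- tibble(chrom = gtab$chrom, start = gtab$tss, end = gtab$tss + 1)
    hits <- find_overlaps0(as_granges0(expanded), as_granges0(tss))
    drop[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  te_loci[!drop, ]
}
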