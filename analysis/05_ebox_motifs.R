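#!/usr/bin/env Rscript
# E-box presence in bound versus unbound target-family loci.
#
# Scans fixed 51-bp center windows of LTR5_Hs-like loci for the canonical
# E-box CA(C/T)GTG on both strands and contrasts peak-bound against unbound
# loci with the 2x2 chi-square.

library(retroreg)

te <- load_repeat_annotation("results/data/repeats.bed")
genome <- read_genome("results/data/genome.fa")
bound_ids <- read_gene_list("results/data/bound_loci.txt")

target <- te[te$family == "LTR5_Hs", ]
windows <- locus_center_windows(target, flank_bp = 25)
bound <- extract_sequences(genome, windows[windows$locus_id %in% bound_ids, ])
unbound <- extract_sequences(genome, windows[!windows$locus_id %in% bound_ids, ])

res <- motif_presence_test(bound, unbound)
dir.create("results/motifs", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(res$hits, "results/motifs/ebox_presence_per_locus.tsv")
readr::write_tsv(
  tibble::tibble(group = rownames(res$table),
                 with_motif = res$table[, 1], without_motif = res$table[, 2],
                 chi2 = res$chi2, p = res$p),
  "results/motifs/ebox_presence_test.tsv"
)

print(res$table)
message(sprintf("bound presence %.2f vs unbound %.2f; chi2 = %.2f, p = %.3g",
                res$table[1, 1] / sum(res$table[1, ]),
                res$table[2, 1] / sum(res$table[2, ]), res$chi2, res$p))
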