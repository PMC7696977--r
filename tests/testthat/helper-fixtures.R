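# quick builders ------------------------------------------------------------

te_fixture <- function(chrom, start, end, strand = "+", family = "FAM") {
  retroreg:::make_te_loci(chrom, start, end, strand, family)
}

aln_fixture <- function(read_id, chrom, start, width = 100, hit_count = 1,
                        mapq = 255) {
  tibble::tibble(read_id = read_id, chrom = chrom, start = start,
                 end = start + width, strand = "+", mapq = mapq,
                 hit_count = hit_count)
}

gene_models_fixture <- function(genes, features) {
  structure(list(genes = genes, features = features), class = "gene_models")
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_width = 500) {
  start <- floor(runif(n, 0, max_pos))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + ceiling(runif(n, 1, max_width)),
    strand = sample(c("+", "-", "."), n, replace = TRUE)
  )
}

# independent oracles --------------------------------------------------------

# O(n^2) merge: repeatedly fuse any mergeable pair until a fixed point
oracle_merge <- function(intervals, max_gap_bp) {
  rows <- split(intervals[c("chrom", "start", "end")], seq_len(nrow(intervals)))
  changed <- TRUE
  while (changed && length(rows) > 1) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap < max_gap_bp) {
          rows[[i]] <- tibble::tibble(chrom = a$chrom,
                                      start = min(a$start, b$start),
                                      end = max(a$end, b$end))
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), chrom, start)
}

# brute-force locus filter: all (locus, feature) and (locus, tss) pairs
oracle_filter <- function(te, genes, d) {
  keep <- vapply(seq_len(nrow(te)), function(i) {
    s <- te$start[[i]]; e <- te$end[[i]]; c <- te$chrom[[i]]
    f <- genes$features
    for (j in seq_len(nrow(f))) {
      if (f$chrom[[j]] == c && min(e, f$end[[j]]) > max(s, f$start[[j]])) return(FALSE)
    }
    g <- genes$genes
    for (j in seq_len(nrow(g))) {
      if (g$chrom[[j]] != c) next
      t <- g$tss[[j]]
      dist <- if (t >= s && t < e) 0 else if (t < s) s - t else t - (e - 1)
      if (dist <= d) return(FALSE)
    }
    TRUE
  }, logical(1))
  te[keep, ]
}

# exhaustive (alignment x locus) family assignment, one read at a time
oracle_assign_family <- function(alignments, te_loci, frac = 0.5) {
  per_read <- split(alignments, alignments$read_id)
  out <- vapply(per_read, function(a) {
    fams_per_aln <- lapply(seq_len(nrow(a)), function(k) {
      hits <- character(0)
      for (j in seq_len(nrow(te_loci))) {
        if (a$chrom[[k]] != te_loci$chrom[[j]]) next
        ov <- min(a$end[[k]], te_loci$end[[j]]) - max(a$start[[k]], te_loci$start[[j]])
        if (ov >= frac * (a$end[[k]] - a$start[[k]])) {
          hits <- c(hits, te_loci$family[[j]])
        }
      }
      unique(hits)
    })
    if (any(lengths(fams_per_aln) == 0)) return(NA_character_)
    fams <- unique(unlist(fams_per_aln))
    if (length(fams) == 1) fams else NA_character_
  }, character(1))
  tibble::tibble(read_id = names(per_read), family = unname(out))
}

# hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# two-sided Fisher p by hypergeometric enumeration
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force E-box scan: test every 6-mer of the sequence and of its
# reverse complement; map reverse-complement hits back to forward positions
oracle_scan_ebox <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  hits <- list()
  for (pos in seq_len(max(0, n - 5))) {
    kmer <- substr(seq, pos, pos + 5)
    if (kmer %in% c("CACGTG", "CATGTG")) {
      hits[[length(hits) + 1]] <- tibble::tibble(position = pos - 1, strand = "+",
                                                 motif = kmer)
    }
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  for (pos in seq_len(max(0, n - 5))) {
    kmer <- substr(rc, pos, pos + 5)
    if (kmer == "CATGTG") { # CACGTG on the reverse strand is the same forward hit
      hits[[length(hits) + 1]] <- tibble::tibble(position = n - pos - 5, strand = "-",
                                                 motif = kmer)
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(position = numeric(), strand = character(),
                          motif = character()))
  }
  dplyr::arrange(out, position, strand)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
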