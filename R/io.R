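#' Read a repeat annotation into TE loci
#'
#' Accepts either BED6 (the `name` column holds the repeat family) or the
#' UCSC RepeatMasker table dialect (tab-separated with a header naming
#' `genoName`/`genoStart`/`genoEnd`/`strand`/`repName`/`repClass`). Both are
#' 0-based half-open already. Stable locus identifiers are assigned as
#' `chrom:start-end:family`.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"bed"`, or `"rmsk"`.
#' @return A TE-locus tibble: `chrom`, `start`, `end`, `strand`, `family`,
#'   `class_name`, `locus_id`, `length_bp`.
#' @export
load_repeat_annotation <- function(path, format = c("auto", "bed", "rmsk")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_te_loci())
  if (format == "auto") {
    format <- if (grepl("genoName", lines[[1L]])) "rmsk" else "bed"
  }
  if (format == "rmsk") parse_rmsk(lines, path) else parse_bed6(lines, path)
}

empty_te_loci <- function() {
  tibble(
    chrom = character(), start = numeric(), end = numeric(),
    strand = character(), family = character(), class_name = character(),
    locus_id = character(), length_bp = numeric()
  )
}

make_te_loci <- function(chrom, start, end, strand, family, class_name = NA_character_) {
  out <- tibble(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), strand = as.character(strand),
    family = as.character(family),
    class_name = rep_len(as.character(class_name), length(chrom))
  )
  validate_intervals(out, "TE locus")
  out$locus_id <- sprintf("%s:%d-%d:%s", out$chrom, out$start, out$end, out$family)
  if (anyDuplicated(out$locus_id)) abort("duplicate locus_id in annotation set")
  out$length_bp <- out$end - out$start
  out
}

parse_bed6 <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d in %s (need >= 4 tab-separated fields)",
                  bad[[1L]], path))
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get(2L)))
  end <- suppressWarnings(as.numeric(get(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("malformed BED line %d in %s (non-numeric coordinates)",
                                 bad[[1L]], path))
  strand <- get(6L, ".")
  strand[!strand %in% c("+", "-")] <- "."
  make_te_loci(get(1L), start, end, strand, get(4L))
}

parse_rmsk <- function(lines, path) {
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  header <- sub("^#", "", header)
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName", "repClass")
  if (!all(need %in% header)) {
    abort(sprintf("unknown repeat-annotation format in %s: expected BED6 or an rmsk header with %s",
                  path, paste(need, collapse = "/")))
  }
  body <- lines[-1L]
  if (length(body) == 0L) return(empty_te_loci())
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < length(header))
  if (length(bad)) {
    abort(sprintf("malformed rmsk line %d in %s (fewer fields than header)",
                  bad[[1L]] + 1L, path))
  }
  col <- function(name) vapply(fields, `[[`, character(1), match(name, header))
  start <- suppressWarnings(as.numeric(col("genoStart")))
  end <- suppressWarnings(as.numeric(col("genoEnd")))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("malformed rmsk line %d in %s (non-numeric coordinates)",
                                 bad[[1L]] + 1L, path))
  strand <- col("strand")
  strand[strand == "C"] <- "-" # RepeatMasker marks reverse-strand hits as C
  strand[!strand %in% c("+", "-")] <- "."
  make_te_loci(col("genoName"), start, end, strand, col("repName"), col("repClass"))
}

#' Write intervals or TE loci as BED6
#' @param x tibble with `chrom`, `start`, `end`; optional `family`/`locus_id`
#'   (name column) and `strand`.
#' @param path destination.
#' @export
write_bed6 <- function(x, path) {
  name <- if ("family" %in% names(x)) x$family else if ("locus_id" %in% names(x)) x$locus_id else "."
  strand <- if ("strand" %in% names(x)) x$strand else "."
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   name, 0L, strand)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path file with `chrom<TAB>length` rows.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = readr::cols(chrom = "c", size = "d"))
  setNames(df$size, df$chrom)
}

write_chrom_sizes <- function(sizes, path) {
  readr::write_tsv(tibble(chrom = names(sizes),
                          size = format(sizes, scientific = FALSE, trim = TRUE)),
                   path, col_names = FALSE)
  invisible(path)
}

#' Load gene models from a GTF file
#'
#' Exon (and, when present, UTR) features are read with 1-based inclusive GTF
#' coordinates and converted to the package's 0-based half-open convention.
#' The TSS of each gene is its 5'-most exon boundary on the gene's strand.
#'
#' @param path GTF file with `exon` features carrying a `gene_id` attribute.
#' @return A list of class `gene_models` with elements `genes` (tibble:
#'   `gene_id`, `chrom`, `strand`, `tss` — a 0-based base position) and
#'   `features` (tibble: `gene_id`, `chrom`, `start`, `end`, `type` in
#'   `exon`/`utr`).
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- tolower(gr$type) %in% c("exon", "utr", "five_prime_utr", "three_prime_utr",
                                  "5utr", "3utr")
  gr <- gr[keep]
  if (length(gr) == 0L) {
    return(structure(list(
      genes = tibble(gene_id = character(), chrom = character(),
                     strand = character(), tss = numeric()),
      features = tibble(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(), type = character())
    ), class = "gene_models"))
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    abort(sprintf("GTF %s: feature without a gene_id attribute", path))
  }
  feats <- tibble(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1, # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = ifelse(tolower(gr$type) == "exon", "exon", "utr")
  )
  if (!all(feats$strand %in% c("+", "-"))) {
    abort(sprintf("GTF %s: gene features must be stranded (+/-)", path))
  }
  genes <- feats |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      chrom = .data$chrom[[1L]], strand = .data$strand[[1L]],
      tss = if (.data$strand[[1L]] == "+") min(.data$start) else max(.data$end) - 1,
      .groups = "drop"
    )
  structure(list(genes = genes,
                 features = dplyr::select(feats, -"strand")),
            class = "gene_models")
}

#' Write gene models as GTF (exon features, 1-based inclusive)
#' @param models a `gene_models` object.
#' @param path destination.
#' @export
write_gtf <- function(models, path) {
  feats <- models$features
  strand <- models$genes$strand[match(feats$gene_id, models$genes$gene_id)]
  lines <- sprintf(
    "%s\tretroreg\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    feats$chrom, ifelse(feats$type == "exon", "exon", "UTR"),
    feats$start + 1, feats$end, strand, feats$gene_id, feats$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' The SAM is converted to BAM in a temporary location and read through
#' Rsamtools. The per-read hit count is taken from the `NH` tag when present,
#' otherwise inferred by grouping records on the read id.
#'
#' @param path SAM file with `@SQ` headers.
#' @return An alignment tibble: `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mapq`, `hit_count`.
#' @export
read_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "mapq", "strand"),
    tag = "NH"
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(res$qname)
  hit_count <- res$tag$NH
  out <- tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    start = as.numeric(res$pos) - 1,
    end = as.numeric(res$pos) - 1 + as.numeric(res$qwidth),
    strand = as.character(res$strand),
    mapq = as.numeric(res$mapq),
    hit_count = if (is.null(hit_count) || all(is.na(hit_count))) NA_real_ else as.numeric(hit_count)
  )
  if (anyNA(out$hit_count)) {
    tab <- table(out$read_id)
    out$hit_count <- as.numeric(tab[out$read_id])
  }
  out
}

#' Write alignments as SAM
#' @param alignments alignment tibble (see [read_alignments()]); `end - start`
#'   is written as a single match (`M`) CIGAR run.
#' @param chrom_sizes named vector of chromosome lengths for `@SQ` headers.
#' @param path destination.
#' @export
write_sam <- function(alignments, chrom_sizes, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), as.integer(chrom_sizes))
  )
  a <- alignments |>
    dplyr::group_by(.data$read_id) |>
    dplyr::mutate(.secondary = dplyr::row_number() > 1L) |>
    dplyr::ungroup()
  flag <- ifelse(a$strand == "-", 16L, 0L) + ifelse(a$.secondary, 256L, 0L)
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
    a$read_id, flag, a$chrom, as.integer(a$start) + 1L, as.integer(a$mapq),
    as.integer(a$end - a$start), as.integer(a$hit_count)
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Signal tracks (bedGraph semantics)
#'
#' A signal track is a tibble of non-overlapping per-chromosome segments with
#' a constant value each, plus the sequencing library size (total tags) used
#' for counts-per-million normalization. The library size is an explicit
#' input, never inferred from the track.
#'
#' @param segments tibble `chrom`, `start`, `end`, `value` (values >= 0).
#' @param library_size total number of tags in the library (> 0).
#' @return the segments tibble with class `signal_track` and a `library_size`
#'   attribute.
#' @export
signal_track <- function(segments, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1L || library_size <= 0) {
    abort("library_size must be a single positive number")
  }
  validate_intervals(segments, "signal segment")
  if (any(!is.finite(segments$value)) || any(segments$value < 0)) {
    abort("signal values must be finite and >= 0")
  }
  segments <- dplyr::arrange(segments, .data$chrom, .data$start)
  structure(segments, class = c("signal_track", class(tibble())),
            library_size = library_size)
}

#' Read a bedGraph file as a signal track
#' @param path bedGraph file.
#' @param library_size total tags for CPM normalization (explicit input).
#' @export
read_bedgraph <- function(path, library_size) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(
    tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1,
           end = as.numeric(GenomicRanges::end(gr)),
           value = as.numeric(gr$score)),
    library_size = library_size
  )
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`.
#' @param path destination.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   format(track$value, scientific = FALSE, trim = TRUE))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read peaks from narrowPeak or BED
#'
#' narrowPeak column 10 is the summit offset from the peak start (`-1` when
#' the caller reported none, stored as `NA`).
#'
#' @param path narrowPeak (10 columns) or BED (>= 3 columns) file.
#' @return peak tibble: `chrom`, `start`, `end`, `name`, `score`,
#'   `summit_offset` (NA when absent).
#' @export
read_peaks <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                        comment = "#")
  if (nrow(df) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), summit_offset = numeric()))
  }
  out <- tibble(
    chrom = df[[1L]],
    start = as.numeric(df[[2L]]),
    end = as.numeric(df[[3L]]),
    name = if (ncol(df) >= 4L) df[[4L]] else sprintf("peak_%d", seq_len(nrow(df))),
    score = if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5L]])) else 0,
    summit_offset = if (ncol(df) >= 10L) as.numeric(df[[10L]]) else NA_real_
  )
  out$summit_offset[!is.na(out$summit_offset) & out$summit_offset < 0] <- NA_real_
  validate_intervals(out, "peak")
  bad <- which(!is.na(out$summit_offset) & out$summit_offset >= interval_width(out))
  if (length(bad)) abort(sprintf("peak %d: summit offset outside the peak", bad[[1L]]))
  out
}

#' Write peaks as narrowPeak
#' @param peaks peak tibble (see [read_peaks()]).
#' @param path destination.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    peaks$chrom,
    format(peaks$start, scientific = FALSE, trim = TRUE),
    format(peaks$end, scientific = FALSE, trim = TRUE),
    if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%d", seq_len(nrow(peaks))),
    if ("score" %in% names(peaks)) peaks$score else 0,
    ".", 0, -1, -1,
    ifelse(is.na(peaks$summit_offset), -1,
           format(peaks$summit_offset, scientific = FALSE, trim = TRUE))
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet] (uppercased).
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Extract interval sequences from a genome
#'
#' Intervals on the `-` strand are reverse-complemented. Sequence ids default
#' to `locus_id` when present.
#'
#' @param genome a `DNAStringSet` (see [read_genome()]).
#' @param intervals interval tibble (0-based half-open).
#' @return named `DNAStringSet`, one sequence per interval row.
#' @export
extract_sequences <- function(genome, intervals) {
  validate_intervals(intervals)
  missing <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing)) abort(sprintf("chromosome %s absent from genome", missing[[1L]]))
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(intervals)), function(i) {
    s <- Biostrings::subseq(genome[[intervals$chrom[[i]]]],
                            start = intervals$start[[i]] + 1,
                            end = intervals$end[[i]])
    if ("strand" %in% names(intervals) && intervals$strand[[i]] == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    s
  }))
  names(seqs) <- if ("locus_id" %in% names(intervals)) {
    intervals$locus_id
  } else {
    sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  }
  seqs
}
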