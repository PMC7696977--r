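#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, `q_(i) = p_(i) * m / i`, enforce
#' monotonicity from the largest rank down, cap at 1, return in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a differential-expression table
#' @param path TSV with columns `gene_id`, `log2fc`, `pvalue` and optionally
#'   `padj`, `mean_expr`.
#' @return tibble of DE records.
#' @export
read_de_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"
  ))
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(df))) {
    abort(sprintf("DE table %s must have columns %s", path, paste(need, collapse = ", ")))
  }
  df
}

#' Threshold a DE table into up/down gene lists
#'
#' A gene is differentially expressed when its BH-adjusted p-value is below
#' `alpha` and `|log2 fold change| >= min_abs_lfc` (the fold-change boundary
#' is inclusive by default; set `lfc_inclusive = FALSE` for a strict
#' threshold). `padj` is computed from `pvalue` by [bh_adjust()] when absent.
#'
#' @param records DE tibble (`gene_id`, `log2fc`, `pvalue`, optional `padj`).
#' @param alpha adjusted-p cutoff (strict `<`, default 0.05).
#' @param min_abs_lfc absolute log2 fold-change threshold (default 1).
#' @param lfc_inclusive whether `|lfc|` exactly at the threshold passes.
#' @return list with `up` and `down` (tibbles split by the sign of `log2fc`)
#'   and `records` (the input with `padj` filled in).
#' @export
deg_filter <- function(records, alpha = 0.05, min_abs_lfc = 1, lfc_inclusive = TRUE) {
  if (!"padj" %in% names(records) || all(is.na(records$padj))) {
    records$padj <- bh_adjust(records$pvalue)
  }
  pass_lfc <- if (lfc_inclusive) {
    abs(records$log2fc) >= min_abs_lfc
  } else {
    abs(records$log2fc) > min_abs_lfc
  }
  keep <- records$padj < alpha & pass_lfc
  list(up = records[keep & records$log2fc > 0, ],
       down = records[keep & records$log2fc < 0, ],
       records = records)
}

#' Gene-set overlap test over a stated universe
#'
#' Builds the 2x2 table (in A / not in A) x (in B / not in B) over the given
#' universe and tests association either by Pearson chi-square (no
#' continuity correction, 1 df) or by the two-sided Fisher exact test (sum
#' of hypergeometric probabilities no larger than the observed table's).
#' The universe must be supplied explicitly — there is no defensible silent
#' default for which genes were testable.
#'
#' @param set_a,set_b character vectors of ids; must be subsets of
#'   `universe`.
#' @param universe character vector of all testable ids.
#' @param method `"chi2"` or `"fisher"`.
#' @return list with `table` (2x2), `method`, `statistic` (chi2, or the
#'   Fisher odds-ratio estimate), `p`, `overlap` (ids in both sets).
#' @export
set_overlap_test <- function(set_a, set_b, universe, method = c("chi2", "fisher")) {
  method <- match.arg(method)
  universe <- unique(universe)
  if (length(universe) == 0L) abort("universe must be non-empty")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("set_a and set_b must be subsets of the universe")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  if (method == "chi2") {
    ct <- chisq_2x2(tab)
    statistic <- ct$chi2
    p <- ct$p
  } else {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    statistic <- unname(ft$estimate)
    p <- ft$p.value
  }
  list(table = tab, method = method, statistic = statistic, p = p,
       overlap = intersect(set_a, set_b))
}

#' Spearman correlation with asymptotic t p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df, two-sided.
#'
#' @param x,y numeric vectors of equal length `>= 4`.
#' @return list with `rho`, `p`, `n`, and `constant_input` (TRUE when either
#'   vector is constant, in which case `rho` and `p` are `NA`).
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 4L) abort("need at least 4 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("spearman_corr: constant input, correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, constant_input = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n, constant_input = FALSE)
}

# distance in bp from a TSS base position to the nearest base of [start, end);
# 0 when the TSS lies inside the locus
tss_locus_distance <- function(tss, start, end) {
  ifelse(tss < start, start - tss, ifelse(tss >= end, tss - (end - 1), 0))
}

#' Call LTR-neighborhood enhancer-candidate genes
#'
#' A gene qualifies when (i) it responds in the state contrast (`de_states`)
#' in the stated reciprocal direction, (ii) it is upregulated in the
#' treatment contrast (`de_treatment`), and (iii) a TE locus of the target
#' family, bound by the factor (its id in `bound_locus_ids`), lies within
#' `neighborhood_bp` of the gene's TSS (edge-to-TSS distance, boundary
#' inclusive). Both DE conditions use [deg_filter()] thresholds.
#'
#' @param genes a `gene_models` object or a tibble with `gene_id`, `chrom`,
#'   `tss`.
#' @param te_loci TE-locus tibble.
#' @param bound_locus_ids character vector of factor-bound locus ids.
#' @param de_treatment,de_states DE tibbles (see [read_de_table()]).
#' @param neighborhood_bp TSS neighborhood radius (default 10000).
#' @param target_family repeat family whose loci count (default `"LTR5_Hs"`).
#' @param reciprocal_sign `"down"` (default) or `"up"`: required sign of the
#'   gene's fold change in `de_states`.
#' @param alpha,min_abs_lfc thresholds passed to [deg_filter()].
#' @return tibble `gene_id`, `te_locus_id` (nearest qualifying bound locus),
#'   `distance_bp`, plus the three criteria flags.
#' @export
enhancer_candidates <- function(genes, te_loci, bound_locus_ids,
                                de_treatment, de_states,
                                neighborhood_bp = 10000,
                                target_family = "LTR5_Hs",
                                reciprocal_sign = c("down", "up"),
                                alpha = 0.05, min_abs_lfc = 1) {
  reciprocal_sign <- match.arg(reciprocal_sign)
  if (neighborhood_bp < 0) abort("neighborhood_bp must be >= 0")
  gtab <- if (inherits(genes, "gene_models")) genes$genes else genes

  states <- deg_filter(de_states, alpha = alpha, min_abs_lfc = min_abs_lfc)
  reciprocal_ids <- if (reciprocal_sign == "down") {
    states$down$gene_id
  } else {
    states$up$gene_id
  }
  up_ids <- deg_filter(de_treatment, alpha = alpha, min_abs_lfc = min_abs_lfc)$up$gene_id

  loci <- te_loci |>
    dplyr::filter(.data$family == target_family,
                  .data$locus_id %in% bound_locus_ids)
  nearest <- gtab |>
    dplyr::left_join(loci, by = "chrom", suffix = c("", ".locus"),
                     relationship = "many-to-many") |>
    dplyr::mutate(distance_bp = tss_locus_distance(.data$tss, .data$start, .data$end)) |>
    dplyr::filter(!is.na(.data$distance_bp), .data$distance_bp <= neighborhood_bp) |>
    dplyr::arrange(.data$gene_id, .data$distance_bp, .data$locus_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select("gene_id", te_locus_id = "locus_id", "distance_bp")

  gtab |>
    dplyr::mutate(
      reciprocal_response = .data$gene_id %in% reciprocal_ids,
      upregulated_with_treatment = .data$gene_id %in% up_ids
    ) |>
    dplyr::left_join(nearest, by = "gene_id") |>
    dplyr::mutate(tf_bound = !is.na(.data$te_locus_id)) |>
    dplyr::filter(.data$reciprocal_response, .data$upregulated_with_treatment,
                  .data$tf_bound) |>
    dplyr::select("gene_id", "te_locus_id", "distance_bp",
                  "reciprocal_response", "upregulated_with_treatment", "tf_bound")
}

#' A qPCR measurement (replicate CT values)
#' @param sample sample label.
#' @param target_ct,reference_ct numeric replicate CT values (>= 1 each) for
#'   the target and the internal-control gene.
#' @export
qpcr_measurement <- function(sample, target_ct, reference_ct) {
  if (length(target_ct) < 1L || length(reference_ct) < 1L ||
      any(target_ct <= 0) || any(reference_ct <= 0)) {
    abort("CT replicate values must be positive and non-empty")
  }
  structure(list(sample = sample, target_ct = as.numeric(target_ct),
                 reference_ct = as.numeric(reference_ct)),
            class = "qpcr_measurement")
}

#' Comparative-CT fold change (2^-ddCT)
#'
#' Replicate CTs are averaged first; per sample `dCT = CT_target -
#' CT_reference`; `ddCT = dCT_case - dCT_control`; the relative expression of
#' case over control is `2^-ddCT` (one CT cycle ~ one doubling).
#'
#' @param case,control [qpcr_measurement()] objects.
#' @return fold change (numeric scalar).
#' @export
ddct_fold_change <- function(case, control) {
  dct <- function(m) mean(m$target_ct) - mean(m$reference_ct)
  2^-(dct(case) - dct(control))
}

#' Read a gene-set list (one id per line)
#' @param path text file.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
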