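#' Genome coverage from total sequenced bases
#'
#' @param total_bases Total sequenced bases (bp).
#' @param genome_size Genome size (bp), must be > 0.
#' @return Coverage multiple (x).
#' @export
coverage_from_reads <- function(total_bases, genome_size) {
  if (any(genome_size <= 0)) stop("`genome_size` must be > 0", call. = FALSE)
  total_bases / genome_size
}

#' Percentage of sequenced bases lost to end trimming
#'
#' Trimming `trim` bp from each end of every read removes
#' `min(2 * trim, read length)` bases per read; the loss is reported as a
#' percentage of all sequenced bases. For reads averaging 7,525 bp and a
#' 100 bp trim the analytic value is 200/7525, about 2.7%.
#'
#' @param read_lengths Integer vector of read lengths (bp).
#' @param trim Trim width per end (bp).
#' @return Percentage of bases removed.
#' @export
trim_loss_pct <- function(read_lengths, trim) {
  stopifnot(trim >= 0, all(read_lengths > 0))
  100 * sum(pmin(2 * trim, read_lengths)) / sum(read_lengths)
}

#' Per-sample coverage and heterozygosity summary
#'
#' For each sample: its coverage metadata and the percentage of
#' heterozygous calls among non-missing calls, optionally restricted to a
#' depth window (the canonical per-run comparison uses 2-5 supporting
#' reads on both platforms).
#'
#' @param m A [geno_matrix].
#' @param dp_min,dp_max Optional inclusive depth window.
#' @return A data frame: `sample`, `coverage`, `pct_het`.
#' @export
heterozygosity_table <- function(m, dp_min = 2, dp_max = 5) {
  stopifnot(inherits(m, "geno_matrix"))
  if (!is.null(dp_min) || !is.null(dp_max)) m <- filter_depth(m, dp_min, dp_max)
  pct <- vapply(seq_along(m$samples), function(i) {
    g <- m$gt[, i]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    100 * mean(g == "het")
  }, numeric(1))
  data.frame(sample = m$samples, coverage = as.numeric(m$coverage),
             pct_het = pct, stringsAsFactors = FALSE)
}

#' Coverage-heterozygosity correlation across samples
#'
#' Pearson correlation of per-sample coverage and heterozygosity
#' percentage, with the two-sided p-value from the t distribution and the
#' significance flags used in the per-run summary (0.01 and 0.02). A
#' negative correlation is the signature of random sequencing error
#' (additional depth drowns the noise); no correlation despite variable
#' coverage is the signature of systematic misalignment heterozygosity.
#'
#' @param summaries A data frame from [heterozygosity_table()] (columns
#'   `coverage` and `pct_het`), or anything of the same shape with at
#'   least 3 complete rows.
#' @return A list: `r`, `p_value`, `signif_0.01`, `signif_0.02`,
#'   `undefined` (TRUE when either vector has zero variance, in which
#'   case `r` is `NA`).
#' @export
coverage_het_correlation <- function(summaries) {
  x <- summaries$coverage
  y <- summaries$pct_het
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, signif_0.01 = FALSE,
                signif_0.02 = FALSE, undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       signif_0.01 = ct$p.value < 0.01, signif_0.02 = ct$p.value < 0.02,
       undefined = FALSE)
}

#' Nucleotide-bias discrepancy table
#'
#' Restricts to cells called homozygous in the reference platform and
#' comparable in the query, classes each cell by the doubled nucleotide
#' actually called in the reference (AA/CC/GG/TT, from the locus ref or
#' alt base), and tabulates correct vs discrepant query calls per class,
#' with a chi-square homogeneity test across the populated classes.
#'
#' @inheritParams concordance_table
#' @return A list with `table` (class, n, n_discrepant, pct_discrepant)
#'   and `test` (`statistic`, `df`, `p_value`; `NA` when fewer than two
#'   populated classes).
#' @export
nucleotide_bias_table <- function(ref, query, spec = NULL, ref_dp_min = 2) {
  tab <- concordance_table(ref, query, spec, ref_dp_min)
  cmp <- tab[tab$cls != "not_comparable" & tab$ref_gt != "het", , drop = FALSE]
  key <- locus_key(ref$panel)
  ref_base <- ref$panel$ref[match(cmp$locus, key)]
  alt_base <- ref$panel$alt[match(cmp$locus, key)]
  called <- ifelse(cmp$ref_gt == "hom_ref", ref_base, alt_base)
  disc <- cmp$cls != "concordant"
  classes <- c("A", "C", "G", "T")
  n <- vapply(classes, function(b) sum(called == b), integer(1))
  n_disc <- vapply(classes, function(b) sum(disc[called == b]), integer(1))
  out <- data.frame(
    class = paste0(classes, classes), n = n, n_discrepant = n_disc,
    pct_discrepant = ifelse(n > 0, 100 * n_disc / n, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  test <- bias_homogeneity_test(cbind(n_disc, n - n_disc))
  list(table = out, test = test)
}

#' Chi-square homogeneity test for a discrepancy count table
#'
#' Tests whether the discrepancy rate is homogeneous across nucleotide
#' classes: chi-square on the k x 2 (discrepant, correct) count table,
#' empty classes excluded.
#'
#' @param counts Matrix with one row per class and two columns
#'   (discrepant count, correct count).
#' @return A list: `statistic`, `df`, `p_value` (all `NA` when fewer than
#'   2 populated classes).
#' @export
bias_homogeneity_test <- function(counts) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) < 2 || any(colSums(counts) == 0)) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
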