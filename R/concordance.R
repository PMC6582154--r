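CONCORDANCE_CLASSES <- c("concordant", "het_ref_hom_query",
                         "hom_ref_het_query", "alt_hom", "not_comparable")

#' Classify paired genotype calls
#'
#' Vectorised classification of reference-platform vs query-platform calls
#' at the same locus/sample into exactly one of: `concordant` (identical
#' classes, het = het included), `het_ref_hom_query` (het in the reference
#' platform, homozygous in the query), `hom_ref_het_query` (homozygous in
#' the reference, het in the query), `alt_hom` (both homozygous but
#' opposite classes), `not_comparable` (either side missing).
#'
#' @param ref_gt,query_gt Character vectors of genotype classes
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`, `NA` = missing).
#' @return Character vector of class labels.
#' @export
classify_pairs <- function(ref_gt, query_gt) {
  out <- rep("not_comparable", length(ref_gt))
  cmp <- !is.na(ref_gt) & !is.na(query_gt)
  out[cmp & ref_gt == query_gt] <- "concordant"
  disc <- cmp & ref_gt != query_gt
  out[disc & ref_gt == "het"] <- "het_ref_hom_query"
  out[disc & ref_gt != "het" & query_gt == "het"] <- "hom_ref_het_query"
  out[disc & ref_gt != "het" & query_gt != "het"] <- "alt_hom"
  out
}

#' Long-format comparison table of two genotype matrices
#'
#' Applies the asymmetric platform treatment (reference platform filtered
#' to a minimum depth of `ref_dp_min`, query platform filtered by `spec`)
#' and classifies every cell.
#'
#' @param ref,query [geno_matrix] objects over the same panel and samples.
#' @param spec Optional [filter_spec()] applied to the query matrix.
#' @param ref_dp_min Minimum depth applied to the reference platform
#'   (default 2; `NULL` disables).
#' @return A data frame with columns `locus`, `sample`, `ref_gt`,
#'   `query_gt`, `query_dp`, `cls`.
#' @export
concordance_table <- function(ref, query, spec = NULL, ref_dp_min = 2) {
  stopifnot(inherits(ref, "geno_matrix"), inherits(query, "geno_matrix"))
  if (!is.null(spec)) query <- apply_filter_spec(query, spec)
  if (!identical(locus_key(ref$panel), locus_key(query$panel))) {
    common <- intersect(locus_key(ref$panel), locus_key(query$panel))
    ref <- restrict_loci(ref, common)
    query <- restrict_loci(query, common)
  }
  if (!identical(ref$samples, query$samples)) {
    stop("matrices must share samples", call. = FALSE)
  }
  if (!is.null(ref_dp_min)) ref <- filter_depth(ref, dp_min = ref_dp_min)
  L <- nrow(ref$gt); S <- ncol(ref$gt)
  data.frame(
    locus = rep(locus_key(ref$panel), S),
    sample = rep(ref$samples, each = L),
    ref_gt = as.vector(ref$gt),
    query_gt = as.vector(query$gt),
    query_dp = as.vector(query$dp),
    cls = classify_pairs(as.vector(ref$gt), as.vector(query$gt)),
    stringsAsFactors = FALSE
  )
}

summarise_cells <- function(tab) {
  cmp <- tab[tab$cls != "not_comparable", , drop = FALSE]
  n <- nrow(cmp)
  if (n == 0) {
    return(data.frame(n_comparable = 0L, pct_concordant = NA_real_,
                      pct_discrepant = NA_real_, pct_het_query = NA_real_,
                      pct_dh_adjusted = NA_real_))
  }
  n_conc <- sum(cmp$cls == "concordant")
  n_hrhq <- sum(cmp$cls == "het_ref_hom_query")
  data.frame(
    n_comparable = n,
    pct_concordant = 100 * n_conc / n,
    pct_discrepant = 100 * (n - n_conc) / n,
    pct_het_query = 100 * sum(cmp$query_gt == "het") / n,
    pct_dh_adjusted = 100 * (n_conc + n_hrhq) / n
  )
}

#' Per-sample and pooled platform accuracy
#'
#' "Accuracy" is concordance with the reference platform over the
#' comparable (both-called) cells. The report also carries the share of
#' heterozygous query calls, the DH-adjusted accuracy (discrepant cells
#' that are het in the reference but homozygous in the query counted
#' correct, the doubled-haploid argument), and the discrepancy breakdown
#' by class.
#'
#' @inheritParams concordance_table
#' @return A list with `per_sample` (one row per sample), `pooled` (one
#'   row), and `breakdown` (counts and percentage of discrepant cells per
#'   concordance class).
#' @export
per_sample_accuracy <- function(ref, query, spec = NULL, ref_dp_min = 2) {
  tab <- concordance_table(ref, query, spec, ref_dp_min)
  per <- do.call(rbind, lapply(split(tab, tab$sample), summarise_cells))
  per <- cbind(sample = rownames(per), per)
  per <- per[match(unique(tab$sample), per$sample), , drop = FALSE]
  rownames(per) <- NULL
  pooled <- summarise_cells(tab)
  disc <- tab$cls[!tab$cls %in% c("not_comparable", "concordant")]
  n_disc <- length(disc)
  breakdown <- data.frame(
    cls = c("het_ref_hom_query", "hom_ref_het_query", "alt_hom"),
    n = c(sum(disc == "het_ref_hom_query"), sum(disc == "hom_ref_het_query"),
          sum(disc == "alt_hom"))
  )
  breakdown$pct_of_discrepant <- if (n_disc > 0) 100 * breakdown$n / n_disc else NA_real_
  list(per_sample = per, pooled = pooled, breakdown = breakdown)
}

#' Doubled-haploid-adjusted accuracy
#'
#' Starting from a concordance percentage and its complementary
#' discrepancy percentage, counts the discrepant calls that are
#' heterozygous in the reference platform but homozygous in the query as
#' correct (in fully homozygous material the homozygous call is the
#' credible one) and returns the adjusted percentage:
#' `pct_concordant + pct_discrepant * het_ref_share / 100`.
#'
#' @param pct_concordant,pct_discrepant Percentages summing to 100.
#' @param het_ref_share Percentage of the discrepant calls that are het in
#'   the reference platform.
#' @return Adjusted accuracy percentage (bounded by
#'   `[pct_concordant, 100]`).
#' @export
dh_adjusted_accuracy <- function(pct_concordant, pct_discrepant, het_ref_share) {
  vals <- c(pct_concordant, pct_discrepant, het_ref_share)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    stop("all inputs must be percentages in [0, 100]", call. = FALSE)
  }
  if (abs(pct_concordant + pct_discrepant - 100) > 0.15) {
    stop("`pct_concordant` + `pct_discrepant` must equal 100", call. = FALSE)
  }
  pct_concordant + pct_discrepant * het_ref_share / 100
}

#' Per-SNP accuracy and cumulative frequency curve
#'
#' For each SNP genotyped (comparable) in at least `min_samples` samples,
#' computes the proportion of samples with a correct genotype, then the
#' cumulative percentage of SNPs whose proportion is at least `t` for each
#' threshold on the grid. The curve is monotone non-increasing in `t` and
#' reaches 100% at `t = 0`.
#'
#' @inheritParams concordance_table
#' @param min_samples Minimum comparable samples per SNP (default 7 of 9).
#' @param count_het_ref_as_correct Also count cells that are het in the
#'   reference but homozygous in the query as correct (the DH argument).
#' @param hom_only Drop heterozygous query calls before comparing.
#' @param thresholds Proportion grid (default 0, 0.1, ..., 1).
#' @return A list with `per_snp` (locus, n comparable, n correct,
#'   proportion) and `curve` (threshold, percentage of SNPs).
#' @export
per_snp_accuracy <- function(ref, query, spec = NULL, ref_dp_min = 2,
                             min_samples = 7, count_het_ref_as_correct = FALSE,
                             hom_only = FALSE,
                             thresholds = seq(0, 1, by = 0.1)) {
  if (hom_only) query <- drop_heterozygotes(query)
  tab <- concordance_table(ref, query, spec, ref_dp_min)
  cmp <- tab[tab$cls != "not_comparable", , drop = FALSE]
  ok_classes <- "concordant"
  if (count_het_ref_as_correct) ok_classes <- c(ok_classes, "het_ref_hom_query")
  n_cmp <- tapply(cmp$cls, cmp$locus, length)
  n_ok <- tapply(cmp$cls %in% ok_classes, cmp$locus, sum)
  keep <- n_cmp >= min_samples
  per_snp <- data.frame(
    locus = names(n_cmp)[keep],
    n_comparable = as.integer(n_cmp[keep]),
    n_correct = as.integer(n_ok[keep]),
    prop_correct = as.numeric(n_ok[keep] / n_cmp[keep]),
    stringsAsFactors = FALSE
  )
  rownames(per_snp) <- NULL
  curve <- data.frame(
    threshold = thresholds,
    pct_snps = vapply(thresholds, function(t) {
      if (nrow(per_snp) == 0) return(NA_real_)
      100 * mean(per_snp$prop_correct >= t - 1e-12)
    }, numeric(1))
  )
  list(per_snp = per_snp, curve = curve)
}

#' Conditional discrepancy breakdown by reference zygosity
#'
#' For cells homozygous in the reference platform: percentage with the
#' same call in the query, percentage discrepant, and the split of the
#' discrepant cells into homozygous (the other class) and heterozygous
#' query calls. For cells heterozygous in the reference: percentage het in
#' the query vs homozygous in the query.
#'
#' @inheritParams concordance_table
#' @return A list `ref_hom` / `ref_het` of percentage rows (each row sums
#'   to 100 within rounding), plus counts.
#' @export
zygosity_breakdown <- function(ref, query, spec = NULL, ref_dp_min = 2) {
  tab <- concordance_table(ref, query, spec, ref_dp_min)
  cmp <- tab[tab$cls != "not_comparable", , drop = FALSE]
  hom <- cmp[cmp$ref_gt != "het", , drop = FALSE]
  het <- cmp[cmp$ref_gt == "het", , drop = FALSE]
  n_hom <- nrow(hom); n_het <- nrow(het)
  hom_disc <- hom[hom$cls != "concordant", , drop = FALSE]
  list(
    ref_hom = data.frame(
      n = n_hom,
      pct_same = if (n_hom) 100 * sum(hom$cls == "concordant") / n_hom else NA_real_,
      pct_discrepant = if (n_hom) 100 * nrow(hom_disc) / n_hom else NA_real_,
      pct_discrepant_hom = if (nrow(hom_disc)) 100 * sum(hom_disc$query_gt != "het") / nrow(hom_disc) else NA_real_,
      pct_discrepant_het = if (nrow(hom_disc)) 100 * sum(hom_disc$query_gt == "het") / nrow(hom_disc) else NA_real_
    ),
    ref_het = data.frame(
      n = n_het,
      pct_same = if (n_het) 100 * sum(het$cls == "concordant") / n_het else NA_real_,
      pct_query_hom = if (n_het) 100 * sum(het$cls == "het_ref_hom_query") / n_het else NA_real_
    )
  )
}

## accuracy within exact query-depth strata for one comparison table
accuracy_by_depth <- function(tab) {
  cmp <- tab[tab$cls != "not_comparable", , drop = FALSE]
  dp <- cmp$query_dp
  strata <- sort(unique(dp))
  data.frame(
    dp = strata,
    n = vapply(strata, function(d) sum(dp == d), integer(1)),
    accuracy = vapply(strata, function(d) {
      100 * mean(cmp$cls[dp == d] == "concordant")
    }, numeric(1))
  )
}

## optimum = depth with maximal accuracy among sufficiently populated
## strata; ties go to the smaller depth
pick_optimal_depth <- function(acc, min_cells) {
  acc <- acc[acc$n >= min_cells, , drop = FALSE]
  if (nrow(acc) == 0) return(NA_integer_)
  as.integer(acc$dp[which.max(acc$accuracy)])
}

#' Optimal supporting-read count per sample and its coverage association
#'
#' Within each sample, accuracy is computed in each exact query-depth
#' stratum (strata with fewer than `min_cells` comparable cells are
#' excluded); the optimum is the depth with maximal accuracy (ties to the
#' smaller depth). The per-sample optima are then correlated (Pearson,
#' two-sided t test) with per-sample genome coverage. A positive
#' association indicates the depth window should track realised coverage.
#'
#' @inheritParams concordance_table
#' @param coverage Per-sample coverage; defaults to the query matrix's
#'   coverage metadata.
#' @param min_cells Minimum comparable cells for a stratum to enter the
#'   argmax (default 50).
#' @return A list with `per_sample` (sample, coverage, optimal depth),
#'   `r`, and `p_value`.
#' @export
optimal_supporting_reads <- function(ref, query, coverage = NULL,
                                     spec = NULL, ref_dp_min = 2,
                                     min_cells = 50) {
  coverage <- coverage %||% query$coverage
  tab <- concordance_table(ref, query, spec, ref_dp_min)
  opts <- vapply(query$samples, function(s) {
    acc <- accuracy_by_depth(tab[tab$sample == s, , drop = FALSE])
    pick_optimal_depth(acc, min_cells)
  }, integer(1))
  per_sample <- data.frame(sample = query$samples, coverage = as.numeric(coverage),
                           optimal_dp = as.integer(opts))
  ok <- stats::complete.cases(per_sample[c("coverage", "optimal_dp")])
  if (sum(ok) >= 3 && stats::sd(per_sample$optimal_dp[ok]) > 0 &&
      stats::sd(per_sample$coverage[ok]) > 0) {
    ct <- stats::cor.test(per_sample$coverage[ok], per_sample$optimal_dp[ok])
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  list(per_sample = per_sample, r = r, p_value = p)
}
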