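GT_LEVELS <- c("hom_ref", "het", "hom_alt")

#' Per-genotype log-likelihoods at one locus
#'
#' Independent-error model over the retained observations of a pileup.
#' With per-base error probability `e = 10^(-qual/10)`:
#' `P(b | hom X) = 1 - e` if `b = X`, else `e/3`;
#' `P(b | het) = (P(b | hom ref) + P(b | hom alt)) / 2`.
#' Observations with `qual < min_bq` are excluded; observations matching
#' neither allele enter through the error terms. An empty retained set
#' yields a zero triple (the caller must emit a missing genotype).
#'
#' @param pileup Data frame with columns `base` and `qual` (a
#'   [simulate_pileup()] row subset, or anything of the same shape).
#' @param ref,alt The two alleles of the biallelic locus.
#' @param min_bq Minimum phred base quality for inclusion (default 13,
#'   the value used throughout; 1 and 20 are the sweep alternatives).
#' @return Named numeric triple of natural-log likelihoods
#'   (`hom_ref`, `het`, `hom_alt`), plus attributes `dp`, `ad_ref`,
#'   `ad_alt` for the retained observations.
#' @export
genotype_log_likelihoods <- function(pileup, ref, alt, min_bq = 13) {
  keep <- pileup$qual >= min_bq
  base <- pileup$base[keep]
  qual <- pileup$qual[keep]
  e <- 10^(-qual / 10)
  p_rr <- ifelse(base == ref, 1 - e, e / 3)
  p_aa <- ifelse(base == alt, 1 - e, e / 3)
  ll <- c(hom_ref = sum(log(p_rr)),
          het = sum(log((p_rr + p_aa) / 2)),
          hom_alt = sum(log(p_aa)))
  structure(ll, dp = sum(keep), ad_ref = sum(base == ref),
            ad_alt = sum(base == alt))
}

## phred-scale a log-likelihood triple: round(-10*log10 L), shifted to min 0
pl_from_loglik <- function(ll) {
  pl <- round(-10 * ll / log(10))
  pl - min(pl)
}

## genotype decision from posterior scores + AD tie-breaking.
## Returns an index into GT_LEVELS or NA (missing).
decide_gt <- function(post, ad_ref, ad_alt, tol = 1e-9) {
  top <- max(post)
  tie <- which(post > top - tol)
  if (length(tie) == 1L) return(tie)
  pref <- if (ad_ref > ad_alt) c(1L, 2L, 3L) else if (ad_alt > ad_ref) c(3L, 2L, 1L) else return(NA_integer_)
  pref[pref %in% tie][1L]
}

#' Call one genotype from a log-likelihood triple
#'
#' PL values are `round(-10 log10 L)` shifted so the smallest is 0
#' (prior-free, as in VCF). The genotype is the maximum-posterior class,
#' where the posterior multiplies the heterozygote likelihood by
#' `het_prior` (1 recovers the pure maximum-likelihood call; the default
#' 0.25 down-weights heterozygotes 4:1 against each homozygote, guarding
#' against single-error heterozygote inflation at minimal depth). A
#' posterior tie between classes is resolved toward the majority allele of
#' the allelic depths; a residual tie (equal depths) is missing.
#' `dp = 0` is always missing with undefined PL.
#'
#' @param loglik Triple from [genotype_log_likelihoods()].
#' @param dp Retained observation count.
#' @param ad Integer pair `(ref count, alt count)`.
#' @param het_prior Heterozygote prior weight in `(0, 1]`.
#' @return A list with `gt` (one of `"hom_ref"`, `"het"`, `"hom_alt"` or
#'   `NA` for missing), `dp`, `ad`, `pl` (integer triple, `NULL` when
#'   `dp = 0`).
#' @export
call_genotype <- function(loglik, dp, ad, het_prior = 0.25) {
  if (dp == 0) {
    return(list(gt = NA_character_, dp = 0L, ad = c(0L, 0L), pl = NULL))
  }
  pl <- pl_from_loglik(loglik)
  post <- loglik + log(c(1, het_prior, 1))
  g <- decide_gt(post, ad[1], ad[2])
  list(gt = if (is.na(g)) NA_character_ else GT_LEVELS[g],
       dp = as.integer(dp), ad = as.integer(ad), pl = as.integer(pl))
}

#' Call genotypes for one sample over a SNP panel
#'
#' Vectorised pileup genotyping: applies the minimum base-quality gate,
#' accumulates the independent-error log-likelihoods per locus, and emits
#' GT, DP (retained observations), AD (ref/alt counts) and prior-free PL.
#' Loci without retained observations are missing. See [call_genotype()]
#' for the decision rule.
#'
#' @param pileup A [simulate_pileup()] result (columns `locus`, `base`,
#'   `qual`).
#' @param panel Panel data frame (`chrom`, `pos`, `ref`, `alt`).
#' @param min_bq Minimum phred base quality (default 13).
#' @param het_prior Heterozygote prior weight (default 0.25).
#' @return A data frame with one row per panel locus: `gt`, `dp`,
#'   `ad_ref`, `ad_alt`, `pl_hom_ref`, `pl_het`, `pl_hom_alt` (PL columns
#'   `NA` when missing).
#' @export
call_genotypes <- function(pileup, panel, min_bq = 13, het_prior = 0.25) {
  L <- nrow(panel)
  keep <- pileup$qual >= min_bq
  locus <- pileup$locus[keep]
  base <- pileup$base[keep]
  qual <- pileup$qual[keep]

  e <- 10^(-qual / 10)
  is_ref <- base == panel$ref[locus]
  is_alt <- base == panel$alt[locus]
  p_rr <- ifelse(is_ref, 1 - e, e / 3)
  p_aa <- ifelse(is_alt, 1 - e, e / 3)
  contrib <- cbind(
    ll_rr = log(p_rr),
    ll_het = log((p_rr + p_aa) / 2),
    ll_aa = log(p_aa),
    n = 1,
    ad_ref = as.numeric(is_ref),
    ad_alt = as.numeric(is_alt)
  )

  ll_rr <- ll_het <- ll_aa <- numeric(L)
  dp <- ad_ref <- ad_alt <- integer(L)
  if (length(locus)) {
    agg <- rowsum(contrib, group = locus)
    idx <- as.integer(rownames(agg))
    ll_rr[idx] <- agg[, "ll_rr"]
    ll_het[idx] <- agg[, "ll_het"]
    ll_aa[idx] <- agg[, "ll_aa"]
    dp[idx] <- as.integer(agg[, "n"])
    ad_ref[idx] <- as.integer(agg[, "ad_ref"])
    ad_alt[idx] <- as.integer(agg[, "ad_alt"])
  }

  ll <- cbind(ll_rr, ll_het, ll_aa)
  pl_raw <- round(-10 * ll / log(10))
  pl <- pl_raw - pmin(pl_raw[, 1], pl_raw[, 2], pl_raw[, 3])

  post <- ll + rep(log(c(1, het_prior, 1)), each = L)
  top <- pmax(post[, 1], post[, 2], post[, 3])
  tol <- 1e-9
  n_top <- (post[, 1] > top - tol) + (post[, 2] > top - tol) + (post[, 3] > top - tol)
  g <- max.col(post, ties.method = "first")
  amb <- which(n_top > 1L)
  for (i in amb) g[i] <- decide_gt(post[i, ], ad_ref[i], ad_alt[i], tol)

  gt <- GT_LEVELS[g]
  gt[dp == 0L] <- NA_character_
  pl[dp == 0L, ] <- NA_real_
  data.frame(
    gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
    pl_hom_ref = as.integer(pl[, 1]), pl_het = as.integer(pl[, 2]),
    pl_hom_alt = as.integer(pl[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Genotype matrix container
#'
#' A `geno_matrix` holds the calls of all samples on one platform over a
#' shared SNP panel: character matrix `gt` (`NA` = missing) plus integer
#' matrices `dp`, `ad_ref`, `ad_alt`, `pl_hom_ref`, `pl_het`,
#' `pl_hom_alt`, the `panel` data frame, `samples`, and per-sample
#' `coverage` metadata (genome-coverage multiples).
#'
#' @param calls List (one per sample) of [call_genotypes()] data frames.
#' @param panel Panel data frame.
#' @param samples Character vector of sample names.
#' @param coverage Optional numeric per-sample coverage; defaults to the
#'   mean retained depth per sample.
#' @return A list of class `geno_matrix`.
#' @export
geno_matrix_from_calls <- function(calls, panel, samples, coverage = NULL) {
  stopifnot(length(calls) == length(samples))
  grab <- function(col) {
    m <- vapply(calls, function(df) as.numeric(df[[col]]), numeric(nrow(panel)))
    dimnames(m) <- list(locus_key(panel), samples)
    m
  }
  gt <- vapply(calls, function(df) df$gt, character(nrow(panel)))
  dimnames(gt) <- list(locus_key(panel), samples)
  m <- list(
    gt = gt,
    dp = grab("dp"),
    ad_ref = grab("ad_ref"),
    ad_alt = grab("ad_alt"),
    pl_hom_ref = grab("pl_hom_ref"),
    pl_het = grab("pl_het"),
    pl_hom_alt = grab("pl_hom_alt"),
    panel = panel,
    samples = samples,
    coverage = coverage %||% vapply(calls, function(df) mean(df$dp), numeric(1))
  )
  names(m$coverage) <- samples
  structure(m, class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d loci x %d samples\n", nrow(x$gt), ncol(x$gt)))
  cat(sprintf("  missing: %.1f%%  het: %.1f%%  coverage: %s\n",
              100 * mean(is.na(x$gt)),
              100 * mean(x$gt == "het", na.rm = TRUE),
              paste(sprintf("%.1f", x$coverage), collapse = " ")))
  invisible(x)
}

## subset a geno_matrix by locus index (logical or integer)
subset_loci <- function(m, idx) {
  for (f in c("gt", "dp", "ad_ref", "ad_alt",
              "pl_hom_ref", "pl_het", "pl_hom_alt")) {
    m[[f]] <- m[[f]][idx, , drop = FALSE]
  }
  m$panel <- m$panel[idx, , drop = FALSE]
  rownames(m$panel) <- NULL
  m
}
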