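#' Reassign heterozygotes by genotype likelihood (PL)
#'
#' A heterozygous call whose PL value for het is not 0 (het is not the
#' most likely genotype) is converted to the homozygous class with the
#' smaller PL; a tie between the two homozygous PLs leaves the call
#' unconverted. Heterozygotes with `PL_het = 0` and all non-het calls are
#' untouched. Idempotent.
#'
#' @param m A [geno_matrix] (PL fields must be present on het calls).
#' @return The adjusted `geno_matrix`.
#' @export
adjust_by_pl <- function(m) {
  stopifnot(inherits(m, "geno_matrix"))
  het <- !is.na(m$gt) & m$gt == "het"
  if (!any(het)) return(m)
  if (anyNA(m$pl_het[het])) {
    stop("heterozygous call without PL values", call. = FALSE)
  }
  conv <- het & m$pl_het != 0
  to_rr <- conv & m$pl_hom_ref < m$pl_hom_alt
  to_aa <- conv & m$pl_hom_alt < m$pl_hom_ref
  m$gt[to_rr] <- "hom_ref"
  m$gt[to_aa] <- "hom_alt"
  m
}

#' Reassign heterozygotes by allelic depth (AD)
#'
#' A heterozygous call with unequal ref/alt allelic depths becomes the
#' homozygous class of the majority allele; equal depths leave the call
#' heterozygous (no tie rule is fabricated). Reads matching neither
#' allele play no part (AD is defined over ref/alt only). Idempotent.
#'
#' @param m A [geno_matrix].
#' @return The adjusted `geno_matrix`.
#' @export
adjust_by_ad <- function(m) {
  stopifnot(inherits(m, "geno_matrix"))
  het <- !is.na(m$gt) & m$gt == "het"
  m$gt[het & m$ad_ref > m$ad_alt] <- "hom_ref"
  m$gt[het & m$ad_alt > m$ad_ref] <- "hom_alt"
  m
}

#' Evaluate a heterozygote-reassignment procedure
#'
#' Tallies how many heterozygotes the adjustment converted and, when a
#' reference-platform matrix is supplied, how the converted calls fare
#' against it: concordant, discrepant-because-het-in-reference, or
#' discrepant with the alternative homozygous class.
#'
#' @param before,after The query [geno_matrix] before and after
#'   adjustment (same panel/samples).
#' @param ref Optional reference-platform [geno_matrix].
#' @param spec Optional [filter_spec()] applied (to `before`/`after`
#'   jointly, on the cells considered) before tallying — the canonical
#'   evaluation uses dp 2-5 (dp 4-6 is the deeper variant).
#' @param ref_dp_min Reference-platform depth filter (default 2).
#' @return A list of class `adjustment_outcome`: `n_het_input`,
#'   `n_converted`, `pct_converted`, and (with `ref`) `pct_concordant`,
#'   `pct_discrepant_het_ref`, `pct_discrepant_alt_hom` over the
#'   converted, reference-comparable cells.
#' @export
evaluate_adjustment <- function(before, after, ref = NULL, spec = NULL,
                                ref_dp_min = 2) {
  stopifnot(inherits(before, "geno_matrix"), inherits(after, "geno_matrix"))
  if (!is.null(spec)) {
    before <- apply_filter_spec(before, spec)
    after <- apply_filter_spec(after, spec)
  }
  het_in <- !is.na(before$gt) & before$gt == "het"
  converted <- het_in & !is.na(after$gt) & after$gt != "het"
  out <- list(
    n_het_input = sum(het_in),
    n_converted = sum(converted),
    pct_converted = if (sum(het_in)) 100 * sum(converted) / sum(het_in) else 0
  )
  if (!is.null(ref)) {
    ref_f <- if (!is.null(ref_dp_min)) filter_depth(ref, dp_min = ref_dp_min) else ref
    cells <- converted & !is.na(ref_f$gt)
    cls <- classify_pairs(ref_f$gt[cells], after$gt[cells])
    n <- length(cls)
    out$n_converted_comparable <- n
    out$pct_concordant <- if (n) 100 * sum(cls == "concordant") / n else NA_real_
    out$pct_discrepant_het_ref <- if (n) 100 * sum(cls == "het_ref_hom_query") / n else NA_real_
    out$pct_discrepant_alt_hom <- if (n) 100 * sum(cls == "alt_hom") / n else NA_real_
  }
  structure(out, class = "adjustment_outcome")
}
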