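#' Read a pre-validated SNP list
#'
#' Tab-separated with header columns `chrom`, `pos`, `ref`, `alt` (an
#' optional `dup_flag` column is carried through). Rows whose ref or alt
#' is not a single A/C/G/T base are rejected as indels; rows whose alt
#' holds several comma-separated alleles are rejected as triallelic; both
#' rejections are reported with a message and a count. Duplicate
#' `(chrom, pos)` rows and malformed rows are errors naming the offending
#' line.
#'
#' @param path Path to the TSV.
#' @return Panel data frame: `chrom`, `pos`, `ref`, `alt` (+ `dup_flag`).
#' @export
read_snp_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(df))) {
    stop("SNP list must have header columns chrom, pos, ref, alt",
         call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(df$pos))
  bad_pos <- which(is.na(pos) | pos < 1)
  if (length(bad_pos)) {
    stop("malformed pos at line ", bad_pos[1] + 1L, call. = FALSE)
  }
  df$pos <- pos
  single <- function(x) x %in% c("A", "C", "G", "T")
  triallelic <- grepl(",", df$alt, fixed = TRUE)
  indel <- (!single(df$ref) | !single(df$alt)) & !triallelic
  same <- single(df$ref) & df$ref == df$alt
  drop <- triallelic | indel | same
  if (any(drop)) {
    message(sum(triallelic), " triallelic and ", sum(indel | same),
            " indel/invalid row(s) removed")
    df <- df[!drop, , drop = FALSE]
  }
  key <- paste(df$chrom, df$pos, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate locus at line ",
         which(duplicated(key))[1] + 1L, call. = FALSE)
  }
  rownames(df) <- NULL
  keep <- intersect(c("chrom", "pos", "ref", "alt", "dup_flag"), names(df))
  df <- df[keep]
  if ("dup_flag" %in% names(df)) df$dup_flag <- as.logical(df$dup_flag)
  df
}

gt_to_vcf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")

#' Write a genotype matrix as minimal VCF 4.2
#'
#' One record per panel locus, FORMAT `GT:DP:AD:PL`, samples as columns,
#' missing genotypes as `./.` with PL `.`. The dialect round-trips
#' losslessly through [read_vcf()].
#'
#' @param m A [geno_matrix].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  stopifnot(inherits(m, "geno_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=skimgeno",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth after base-quality exclusion\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$samples), collapse = "\t")
  )
  L <- nrow(m$panel)
  cells <- matrix("", nrow = L, ncol = length(m$samples))
  for (j in seq_along(m$samples)) {
    gt <- m$gt[, j]
    gt_str <- ifelse(is.na(gt), "./.", gt_to_vcf[gt])
    pl_str <- ifelse(
      is.na(m$pl_het[, j]), ".",
      paste(m$pl_hom_ref[, j], m$pl_het[, j], m$pl_hom_alt[, j], sep = ",")
    )
    cells[, j] <- paste(
      gt_str, m$dp[, j],
      paste(m$ad_ref[, j], m$ad_alt[, j], sep = ","), pl_str,
      sep = ":"
    )
  }
  body <- paste(
    m$panel$chrom, m$panel$pos, ".", m$panel$ref, m$panel$alt, ".", "PASS",
    ".", "GT:DP:AD:PL",
    apply(cells, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

parse_gt_field <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_character_, length(gt))
  out[gt %in% c("0/0")] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% c("1/1")] <- "hom_alt"
  out
}

#' Read a VCF into a genotype matrix over a panel
#'
#' Uses `vcfR` to parse the file, then maps records onto the panel by
#' `(chrom, pos)`. Panel loci absent from the VCF are missing calls;
#' multi-allelic records are skipped with a message; phased separators
#' are accepted. FORMAT must contain GT; DP/AD/PL are read when present
#' (downstream operations that need them will find `NA`/0 otherwise).
#'
#' @param path Path to a VCF 4.2 file.
#' @param panel Panel data frame (`chrom`, `pos`, `ref`, `alt`); defaults
#'   to the loci present in the VCF.
#' @return A [geno_matrix] (coverage metadata = per-sample mean DP).
#' @export
read_vcf <- function(path, panel = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (is.null(panel)) {
    panel <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  }
  vcf_key <- paste(fix$CHROM, fix$POS, sep = ":")
  idx <- match(locus_key(panel), vcf_key)

  samples <- colnames(vcf@gt)[-1]
  L <- nrow(panel); S <- length(samples)
  pull <- function(element, as_num = TRUE) {
    x <- vcfR::extract.gt(vcf, element = element, as.numeric = as_num)
    if (is.null(x)) matrix(NA_real_, nrow(fix), S) else x
  }
  has <- function(el) any(grepl(el, vcf@gt[, "FORMAT"], fixed = TRUE))

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(NA_character_, L, S, dimnames = list(locus_key(panel), samples))
  dp <- ad_ref <- ad_alt <- matrix(0, L, S, dimnames = dimnames(gt))
  pl1 <- pl2 <- pl3 <- matrix(NA_real_, L, S, dimnames = dimnames(gt))
  ok <- !is.na(idx)
  gt[ok, ] <- apply(gt_raw[idx[ok], , drop = FALSE], 2, parse_gt_field)
  if (has("DP")) {
    dpx <- pull("DP")
    dp[ok, ] <- dpx[idx[ok], , drop = FALSE]
    dp[is.na(dp)] <- 0
  }
  if (has("AD")) {
    adx <- vcfR::extract.gt(vcf, element = "AD")
    split2 <- function(x, i) suppressWarnings(as.numeric(
      vapply(strsplit(x, ",", fixed = TRUE), function(p) {
        if (length(p) >= i) p[i] else NA_character_
      }, character(1))
    ))
    ad_ref[ok, ] <- apply(adx[idx[ok], , drop = FALSE], 2, split2, i = 1)
    ad_alt[ok, ] <- apply(adx[idx[ok], , drop = FALSE], 2, split2, i = 2)
    ad_ref[is.na(ad_ref)] <- 0
    ad_alt[is.na(ad_alt)] <- 0
  }
  if (has("PL")) {
    plx <- vcfR::extract.gt(vcf, element = "PL")
    splitp <- function(x, i) suppressWarnings(as.numeric(
      vapply(strsplit(x, ",", fixed = TRUE), function(p) {
        if (length(p) >= i) p[i] else NA_character_
      }, character(1))
    ))
    pl1[ok, ] <- apply(plx[idx[ok], , drop = FALSE], 2, splitp, i = 1)
    pl2[ok, ] <- apply(plx[idx[ok], , drop = FALSE], 2, splitp, i = 2)
    pl3[ok, ] <- apply(plx[idx[ok], , drop = FALSE], 2, splitp, i = 3)
  }
  structure(
    list(gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
         pl_hom_ref = pl1, pl_het = pl2, pl_hom_alt = pl3,
         panel = panel, samples = samples,
         coverage = stats::setNames(colMeans(dp), samples)),
    class = "geno_matrix"
  )
}

#' Write an accuracy report as TSV files
#'
#' Emits the per-sample accuracy table, pooled row, and discrepancy
#' breakdown of a [per_sample_accuracy()] report, percentages rounded to
#' one decimal.
#'
#' @param report A [per_sample_accuracy()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_accuracy_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  round1 <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "n_comparable"
    df[num] <- lapply(df[num], round, 1)
    df
  }
  paths <- file.path(dir, c("per_sample.tsv", "pooled.tsv", "breakdown.tsv"))
  utils::write.table(round1(report$per_sample), paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(round1(report$pooled), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(round1(report$breakdown), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
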