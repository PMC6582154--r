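#' Filtering treatment specification
#'
#' Bundles every filtering treatment evaluated on the query platform:
#' depth window, heterozygote removal, minimum read length, end trimming,
#' minimum base quality, locus-subset restriction, and the A/T-only panel
#' restriction. Matrix-level parts are applied by [apply_filter_spec()];
#' pileup-level parts (`min_read_length`, `end_trim`, `min_bq`) are applied
#' before/at calling via [filter_pileup()] and [call_genotypes()].
#'
#' @param dp_min,dp_max Inclusive depth window (either may be `NULL`).
#' @param drop_het Replace heterozygous calls with missing.
#' @param min_read_length Keep only observations from reads at least this
#'   long (bp).
#' @param end_trim Remove observations within this many bp of a read end.
#' @param min_bq Minimum phred base quality for the caller (default 13).
#' @param locus_subset Character vector of locus keys (`"chrom:pos"`) to
#'   retain.
#' @param at_only Keep only loci whose ref and alt are both A or T.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(dp_min = NULL, dp_max = NULL, drop_het = FALSE,
                        min_read_length = NULL, end_trim = NULL,
                        min_bq = 13, locus_subset = NULL, at_only = FALSE) {
  if (!is.null(dp_min) && !is.null(dp_max) && dp_min > dp_max) {
    stop("`dp_min` must be <= `dp_max`", call. = FALSE)
  }
  if (!is.null(end_trim) && end_trim < 0) stop("`end_trim` must be >= 0", call. = FALSE)
  structure(
    list(dp_min = dp_min, dp_max = dp_max, drop_het = isTRUE(drop_het),
         min_read_length = min_read_length, end_trim = end_trim,
         min_bq = min_bq, locus_subset = locus_subset,
         at_only = isTRUE(at_only)),
    class = "filter_spec"
  )
}

#' Depth-window filter
#'
#' Calls whose retained depth falls outside the inclusive
#' `[dp_min, dp_max]` window become missing; nothing else changes (a
#' non-missing genotype's class is never altered, only its presence).
#' The canonical window is 2-5 supporting reads.
#'
#' @param m A [geno_matrix].
#' @param dp_min,dp_max Inclusive bounds; `NULL` leaves that side open.
#' @return The filtered `geno_matrix`.
#' @export
filter_depth <- function(m, dp_min = NULL, dp_max = NULL) {
  stopifnot(inherits(m, "geno_matrix"))
  out <- !is.na(m$gt)
  if (!is.null(dp_min)) out <- out & m$dp >= dp_min
  if (!is.null(dp_max)) out <- out & m$dp <= dp_max
  m$gt[!out] <- NA_character_
  m
}

#' Remove heterozygous calls
#'
#' Every heterozygous call becomes missing; homozygous and missing calls
#' are untouched. This is the treatment available in fully homozygous
#' (doubled-haploid) material, where no heterozygote is expected.
#'
#' @param m A [geno_matrix].
#' @return The filtered `geno_matrix`.
#' @export
drop_heterozygotes <- function(m) {
  stopifnot(inherits(m, "geno_matrix"))
  m$gt[!is.na(m$gt) & m$gt == "het"] <- NA_character_
  m
}

#' Minimum read-length filter (pileup level)
#'
#' Removes observations contributed by reads shorter than `min_len` bp,
#' mirroring read-length filtering before alignment; depth shrinks
#' accordingly. Applied before calling.
#'
#' @param pileup A [simulate_pileup()] result.
#' @param min_len Minimum read length (bp); observations from reads with
#'   `read_length < min_len` are removed.
#' @return The filtered pileup.
#' @export
filter_read_length <- function(pileup, min_len) {
  keep <- pileup$read_length >= min_len
  out <- pileup[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("sample", "raw_depth")] <-
    attributes(pileup)[c("sample", "raw_depth")]
  class(out) <- class(pileup)
  out
}

#' End-trimming filter (pileup level)
#'
#' Removes observations that lie within `trim` bp of the nearer read end,
#' mirroring the trimming of the error-prone read extremities. For reads
#' averaging 7,525 bp, trimming 100 bp from each end discards about 2.7%
#' of the sequenced bases.
#'
#' @param pileup A [simulate_pileup()] result.
#' @param trim Trim width in bp; observations with `read_offset < trim`
#'   are removed.
#' @return The filtered pileup.
#' @export
trim_read_ends <- function(pileup, trim) {
  stopifnot(trim >= 0)
  keep <- pileup$read_offset >= trim
  out <- pileup[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("sample", "raw_depth")] <-
    attributes(pileup)[c("sample", "raw_depth")]
  class(out) <- class(pileup)
  out
}

#' Restrict a genotype matrix to a locus subset
#'
#' Either an explicit set of locus keys, or the A/T-only restriction
#' (loci whose ref and alt alleles are both A or T), used to probe the
#' G/C substitution bias.
#'
#' @param m A [geno_matrix].
#' @param subset Character vector of locus keys (`"chrom:pos"`), or `NULL`.
#' @param at_only Keep only loci with ref and alt both in `{A, T}`.
#' @return The restricted `geno_matrix` (possibly with zero loci).
#' @export
restrict_loci <- function(m, subset = NULL, at_only = FALSE) {
  stopifnot(inherits(m, "geno_matrix"))
  keep <- rep(TRUE, nrow(m$panel))
  if (!is.null(subset)) keep <- keep & locus_key(m$panel) %in% subset
  if (isTRUE(at_only)) {
    keep <- keep & m$panel$ref %in% c("A", "T") & m$panel$alt %in% c("A", "T")
  }
  subset_loci(m, keep)
}

#' Apply the matrix-level parts of a filter specification
#'
#' Locus restriction, then the depth window, then heterozygote removal.
#' The pileup-level parts (`min_read_length`, `end_trim`, `min_bq`) must
#' be applied before/at calling and are ignored here.
#'
#' @param m A [geno_matrix].
#' @param spec A [filter_spec()].
#' @return The filtered `geno_matrix`.
#' @export
apply_filter_spec <- function(m, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!is.null(spec$locus_subset) || spec$at_only) {
    m <- restrict_loci(m, spec$locus_subset, spec$at_only)
  }
  if (!is.null(spec$dp_min) || !is.null(spec$dp_max)) {
    m <- filter_depth(m, spec$dp_min, spec$dp_max)
  }
  if (spec$drop_het) m <- drop_heterozygotes(m)
  m
}

#' Apply the pileup-level parts of a filter specification
#'
#' Read-length filtering, then end trimming (the base-quality gate is the
#' caller's, via `spec$min_bq`).
#'
#' @param pileup A [simulate_pileup()] result.
#' @param spec A [filter_spec()].
#' @return The filtered pileup.
#' @export
filter_pileup <- function(pileup, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!is.null(spec$min_read_length)) {
    pileup <- filter_read_length(pileup, spec$min_read_length)
  }
  if (!is.null(spec$end_trim) && spec$end_trim > 0) {
    pileup <- trim_read_ends(pileup, spec$end_trim)
  }
  pileup
}

#' Serialise a filter specification as key=value lines
#'
#' @param spec A [filter_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_spec <- function(spec, path) {
  stopifnot(inherits(spec, "filter_spec"))
  fmt <- function(v) {
    if (is.null(v)) "" else paste(v, collapse = ",")
  }
  lines <- sprintf("%s=%s", names(spec), vapply(spec, fmt, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a filter specification from a key=value file
#'
#' @param path Path written by [write_filter_spec()] (unknown keys are an
#'   error; empty values mean unset).
#' @return A [filter_spec()].
#' @export
read_filter_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  known <- c("dp_min", "dp_max", "drop_het", "min_read_length", "end_trim",
             "min_bq", "locus_subset", "at_only")
  if (any(!keys %in% known)) {
    stop("unknown filter_spec key(s): ", paste(setdiff(keys, known), collapse = ", "),
         call. = FALSE)
  }
  get_num <- function(k) if (k %in% keys && nzchar(vals[keys == k])) as.numeric(vals[keys == k]) else NULL
  get_bool <- function(k) k %in% keys && vals[keys == k] %in% c("TRUE", "true", "1")
  subset <- if ("locus_subset" %in% keys && nzchar(vals[keys == "locus_subset"])) {
    strsplit(vals[keys == "locus_subset"], ",", fixed = TRUE)[[1]]
  } else NULL
  filter_spec(
    dp_min = get_num("dp_min"), dp_max = get_num("dp_max"),
    drop_het = get_bool("drop_het"),
    min_read_length = get_num("min_read_length"),
    end_trim = get_num("end_trim"),
    min_bq = get_num("min_bq") %||% 13,
    locus_subset = subset, at_only = get_bool("at_only")
  )
}
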