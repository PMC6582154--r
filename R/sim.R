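BASES <- c("A", "C", "G", "T")

## Per-sample genome coverage profiles (x) used as the default mean pileup
## depths of the two platform blocks, emulating a nine-sample DH skim
## experiment: one short-read set and long-read sets per sequencing run
## (runs 3 and 4 were unevenly pooled, hence their wide 0.1-3.0x spread).
SRS_COVERAGES <- c(7.6, 9.1, 4.9, 8.4, 4.4, 6.3, 12.0, 14.4, 9.5)
LRS_COVERAGES <- list(
  all  = c(4.2, 7.4, 2.8, 3.9, 1.7, 2.4, 4.9, 4.9, 1.7),
  run1 = c(0.9, 0.9, 0.9, 1.0, 1.0, 1.1, 0.9, 1.1, 0.9),
  run2 = c(0.5, 0.4, 0.6, 0.6, 0.5, 0.5, 0.6, 0.6, 0.5),
  run3 = c(1.5, 3.0, 0.7, 1.2, 0.1, 0.4, 1.8, 1.6, 0.2),
  run4 = c(1.4, 3.0, 0.6, 1.1, 0.1, 0.4, 1.7, 1.6, 0.1)
)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_config(sprintf("`%s` must be a probability in [0, 1]", name))
  }
}

#' Platform block of a simulation configuration
#'
#' Describes one sequencing platform at pileup level: how deep it samples
#' each locus, how often a sequenced base is wrong, whether reads at
#' duplicated loci can originate from the paralogous copy (the short-read
#' misalignment mechanism), and the read-length/quality model.
#'
#' @param mean_depth Mean pileup depth per sample (scalar or one value per
#'   sample), interpreted as the genome coverage multiple of that sample.
#' @param base_error_rate Probability in `[0, 1)` that a sequenced base is
#'   substituted by one of the three other nucleotides.
#' @param misalignment_rate Fraction of reads at duplicated loci that are
#'   drawn from the paralogous region instead of the target locus.
#' @param mean_read_length Mean read length in bp; lengths are geometric,
#'   shifted to a minimum of 100 bp (heavy-tailed, single parameter).
#' @param base_qual Phred base quality attached to every observation. The
#'   caller sees error probability only through this value, so it may be
#'   deliberately mis-calibrated relative to `base_error_rate` (nanopore
#'   quality strings are).
#' @param depth_dispersion Negative-binomial size parameter for per-locus
#'   depth; `Inf` (default) gives Poisson depth. Finite values model the
#'   uneven genome representation of short-read sequencing (GC, PCR and
#'   mappability effects); long reads cover the genome more evenly.
#' @param gc_substitution_mult Multiplier applied to `base_error_rate` when
#'   the sequenced (true) base is G or C; models the G/C substitution bias
#'   of nanopore sequencing. 1 disables the bias.
#' @param at_deletion_rate Probability that an observation whose true base
#'   is A or T is dropped from the pileup (the A/T deletion bias; indels
#'   are modelled only as observation dropout).
#'
#' @return A list of class `platform_config`.
#' @seealso [srs_platform()], [lrs_platform()], [sim_config()]
#' @export
platform_config <- function(mean_depth,
                            base_error_rate,
                            misalignment_rate = 0,
                            mean_read_length = 1000,
                            base_qual = 20,
                            depth_dispersion = Inf,
                            gc_substitution_mult = 1,
                            at_deletion_rate = 0) {
  if (!is.numeric(mean_depth) || anyNA(mean_depth) || any(mean_depth < 0)) {
    stop_config("`mean_depth` must be non-negative")
  }
  if (base_error_rate < 0 || base_error_rate >= 1) {
    stop_config("`base_error_rate` must be in [0, 1)")
  }
  check_prob(misalignment_rate, "misalignment_rate")
  check_prob(at_deletion_rate, "at_deletion_rate")
  if (mean_read_length < 100) stop_config("`mean_read_length` must be >= 100 bp")
  if (base_qual < 0) stop_config("`base_qual` must be a non-negative phred value")
  if (gc_substitution_mult < 0) stop_config("`gc_substitution_mult` must be >= 0")
  structure(
    list(
      mean_depth = mean_depth,
      base_error_rate = base_error_rate,
      misalignment_rate = misalignment_rate,
      mean_read_length = mean_read_length,
      base_qual = base_qual,
      depth_dispersion = depth_dispersion,
      gc_substitution_mult = gc_substitution_mult,
      at_deletion_rate = at_deletion_rate
    ),
    class = "platform_config"
  )
}

#' Default short-read (Illumina-role) platform block
#'
#' Low base error (q30), overdispersed depth, and misalignment at duplicated
#' loci: half of the reads covering a duplicated locus originate from the
#' paralogue. Mean depths default to a nine-sample coverage profile
#' spanning 4.4-14.4x.
#'
#' @param mean_depth Per-sample mean depths; defaults to the profile above.
#' @param ... Overrides passed to [platform_config()].
#' @return A `platform_config`.
#' @export
srs_platform <- function(mean_depth = SRS_COVERAGES, ...) {
  args <- list(
    mean_depth = mean_depth,
    base_error_rate = 0.001,
    misalignment_rate = 0.5,
    mean_read_length = 150,
    base_qual = 30,
    depth_dispersion = 2
  )
  args[names(list(...))] <- list(...)
  do.call(platform_config, args)
}

#' Default long-read (nanopore-role) platform block
#'
#' High random base error (~10%, quality 9 as a typical run-mean value),
#' no misalignment (long reads anchor uniquely), Poisson depth (even genome
#' representation), and heavy-tailed read lengths with mean 7,525 bp.
#'
#' @param runs Which per-sample coverage column to use as mean depths:
#'   `"all"` (all runs combined), or `"run1"`..`"run4"`. Runs 3 and 4 were
#'   unevenly pooled and span 0.1-3.0x, which is what makes the
#'   coverage-heterozygosity correlation observable.
#' @param mean_depth Optional explicit per-sample mean depths (overrides
#'   `runs`).
#' @param ... Overrides passed to [platform_config()].
#' @return A `platform_config`.
#' @export
lrs_platform <- function(runs = c("all", "run1", "run2", "run3", "run4"),
                         mean_depth = NULL, ...) {
  runs <- match.arg(runs)
  args <- list(
    mean_depth = mean_depth %||% LRS_COVERAGES[[runs]],
    base_error_rate = 0.10,
    misalignment_rate = 0,
    mean_read_length = 7525,
    base_qual = 9,
    depth_dispersion = Inf
  )
  args[names(list(...))] <- list(...)
  do.call(platform_config, args)
}

#' Simulation configuration for a doubled-haploid genotyping study
#'
#' Bundles the truth-set parameters (panel size, allele frequency, residual
#' heterozygosity, duplication structure) with one platform block per
#' sequencing role and a master seed. The defaults emulate a typical
#' structure: 9 fully homozygous DH samples, a biallelic SNP panel of which
#' a fraction lies in duplicated (homoeologous) regions, a low-error
#' short-read platform that misaligns at duplicated loci, and a high-error
#' long-read platform that does not.
#'
#' @param n_samples Number of samples (doubled haploids).
#' @param n_loci Number of panel SNP loci.
#' @param allele_freq Probability that the true genotype at a locus is
#'   homozygous-alternate.
#' @param residual_het_rate Probability a true genotype is heterozygous
#'   (doubled-haploid leakage; 0 for ideal DH material).
#' @param dup_fraction Probability that a locus lies in a duplicated region.
#' @param paralog_divergence At a duplicated locus, probability that the
#'   paralogous copy carries the alternate allele (so that samples whose
#'   true genotype is homozygous-reference see a mixed pileup when reads
#'   misalign: the hemi-SNP mechanism).
#' @param platforms Named list of [platform_config()] blocks; defaults to
#'   `list(srs = srs_platform(), lrs = lrs_platform())`.
#' @param seed Integer master seed; every downstream draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 9,
                       n_loci = 1000,
                       allele_freq = 0.5,
                       residual_het_rate = 0,
                       dup_fraction = 0.1,
                       paralog_divergence = 0.9,
                       platforms = list(srs = srs_platform(), lrs = lrs_platform()),
                       seed = 1L) {
  if (n_samples < 0 || n_loci < 0) stop_config("`n_samples` and `n_loci` must be >= 0")
  check_prob(allele_freq, "allele_freq")
  check_prob(residual_het_rate, "residual_het_rate")
  check_prob(dup_fraction, "dup_fraction")
  check_prob(paralog_divergence, "paralog_divergence")
  stopifnot(is.list(platforms))
  for (nm in names(platforms)) {
    p <- platforms[[nm]]
    if (!inherits(p, "platform_config")) stop_config("all platforms must be platform_config objects")
    # per-sample depth vectors are recycled to the sample count
    if (length(p$mean_depth) != 1) {
      platforms[[nm]]$mean_depth <- rep_len(p$mean_depth, n_samples)
    }
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_loci = as.integer(n_loci),
      allele_freq = allele_freq,
      residual_het_rate = residual_het_rate,
      dup_fraction = dup_fraction,
      paralog_divergence = paralog_divergence,
      platforms = platforms,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a doubled-haploid truth set
#'
#' Draws the SNP panel (chromosome, position, ref/alt alleles, duplication
#' flags and paralog alleles) and the true genotype of every sample at every
#' locus. Genotypes are homozygous-alternate with probability
#' `allele_freq`, otherwise homozygous-reference, then flipped to
#' heterozygous with probability `residual_het_rate`. With
#' `residual_het_rate = 0` the truth set contains no heterozygote, which is
#' the doubled-haploid expectation.
#'
#' @param config A [sim_config()].
#' @return A list of class `truth_set` with elements `panel` (data frame:
#'   `chrom`, `pos`, `ref`, `alt`, `dup_flag`, `paralog_allele`), `gt`
#'   (character matrix loci x samples with values `"hom_ref"`, `"het"`,
#'   `"hom_alt"`), and `samples`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  S <- config$n_samples
  samples <- paste0("DH-", seq_len(S))
  if (L == 0L) {
    panel <- data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), dup_flag = logical(), paralog_allele = character(),
      stringsAsFactors = FALSE
    )
    gt <- matrix(character(), nrow = 0, ncol = S, dimnames = list(NULL, samples))
    return(structure(list(panel = panel, gt = gt, samples = samples,
                          config = config),
                     class = "truth_set"))
  }
  pos <- cumsum(sample(50:500, L, replace = TRUE))
  ref <- sample(BASES, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1),
                USE.NAMES = FALSE)
  dup_flag <- stats::runif(L) < config$dup_fraction
  paralog_allele <- ifelse(
    dup_flag,
    ifelse(stats::runif(L) < config$paralog_divergence, alt, ref),
    NA_character_
  )
  panel <- data.frame(
    chrom = "chrA01", pos = pos, ref = ref, alt = alt,
    dup_flag = dup_flag, paralog_allele = paralog_allele,
    stringsAsFactors = FALSE
  )
  gt <- matrix(
    ifelse(stats::runif(L * S) < config$allele_freq, "hom_alt", "hom_ref"),
    nrow = L, ncol = S, dimnames = list(locus_key(panel), samples)
  )
  if (config$residual_het_rate > 0) {
    flip <- stats::runif(L * S) < config$residual_het_rate
    gt[flip] <- "het"
  }
  structure(list(panel = panel, gt = gt, samples = samples, config = config),
            class = "truth_set")
}

#' Key identifying a locus ("chrom:pos")
#' @param panel A panel data frame with `chrom` and `pos` columns.
#' @return Character vector of locus keys.
#' @export
locus_key <- function(panel) paste(panel$chrom, panel$pos, sep = ":")

#' Simulate read lengths
#'
#' Geometric lengths shifted to a minimum of 100 bp with the given mean:
#' heavy-tailed like a nanopore length distribution, one parameter.
#'
#' @param n Number of reads.
#' @param mean_length Mean read length (bp), must be >= 100.
#' @param min_length Minimum length (default 100 bp).
#' @return Integer vector of lengths.
#' @export
simulate_read_lengths <- function(n, mean_length, min_length = 100) {
  stopifnot(mean_length >= min_length)
  p <- 1 / (mean_length - min_length + 1)
  min_length + stats::rgeom(n, p)
}

#' Simulate the pileups of one sample on one platform
#'
#' Per locus, the observation count is Poisson (or negative-binomial when
#' the platform block sets a finite `depth_dispersion`) around the sample's
#' mean depth. Each observation starts from the true allele (heterozygous
#' truth: each allele with probability 1/2); at duplicated loci it is
#' replaced by the paralog allele with probability `misalignment_rate`
#' (read originates from the paralogous region); it is then substituted to
#' one of the three other bases with probability `base_error_rate`
#' (multiplied by `gc_substitution_mult` when the sequenced base is G/C)
#' and dropped with probability `at_deletion_rate` when the sequenced base
#' is A/T. Every observation carries a read length, the distance of the
#' locus from the nearer read end, and the platform base quality.
#'
#' @param truth A [simulate_truth()] result.
#' @param sample Sample index or name.
#' @param platform A [platform_config()].
#' @param seed Integer seed for this sample/platform draw.
#' @return A data frame of class `pileup_set` with columns `locus`
#'   (panel row index), `base`, `qual`, `read_length`, `read_offset`.
#' @export
simulate_pileup <- function(truth, sample, platform, seed) {
  stopifnot(inherits(truth, "truth_set"), inherits(platform, "platform_config"))
  if (is.character(sample)) sample <- match(sample, truth$samples)
  if (is.na(sample) || sample < 1 || sample > length(truth$samples)) {
    stop("unknown sample", call. = FALSE)
  }
  set.seed(as.integer(seed))
  L <- nrow(truth$panel)
  mu <- platform$mean_depth
  if (length(mu) > 1) mu <- mu[sample]
  depth <- if (is.finite(platform$depth_dispersion)) {
    stats::rnbinom(L, size = platform$depth_dispersion, mu = mu)
  } else {
    stats::rpois(L, mu)
  }
  n <- sum(depth)
  empty <- data.frame(
    locus = integer(), base = character(), qual = integer(),
    read_length = integer(), read_offset = integer(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(structure(empty, class = c("pileup_set", "data.frame"),
                     sample = truth$samples[sample], raw_depth = depth))
  }
  locus <- rep(seq_len(L), depth)

  gt <- truth$gt[locus, sample]
  ref <- truth$panel$ref[locus]
  alt <- truth$panel$alt[locus]
  base <- ifelse(gt == "hom_alt", alt, ref)
  is_het <- gt == "het"
  if (any(is_het)) {
    pick_alt <- stats::runif(n) < 0.5
    base[is_het & pick_alt] <- alt[is_het & pick_alt]
  }

  # read-origin mixture at duplicated loci (hemi-SNP mechanism)
  if (platform$misalignment_rate > 0) {
    mis <- truth$panel$dup_flag[locus] & stats::runif(n) < platform$misalignment_rate
    base[mis] <- truth$panel$paralog_allele[locus][mis]
  }

  # random substitution error, optionally inflated for G/C bases
  p_err <- rep(platform$base_error_rate, n)
  if (platform$gc_substitution_mult != 1) {
    gc <- base %in% c("G", "C")
    p_err[gc] <- pmin(p_err[gc] * platform$gc_substitution_mult, 0.999)
  }
  err <- stats::runif(n) < p_err
  if (any(err)) {
    # substitute uniformly to one of the 3 other bases
    cur <- match(base[err], BASES)
    shift <- sample.int(3L, sum(err), replace = TRUE)
    base[err] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  }

  # A/T deletion bias: the observation never makes it into the pileup
  keep <- rep(TRUE, n)
  if (platform$at_deletion_rate > 0) {
    at <- base %in% c("A", "T")
    keep[at] <- stats::runif(sum(at)) >= platform$at_deletion_rate
  }

  read_length <- simulate_read_lengths(n, platform$mean_read_length)
  pos_in_read <- floor(stats::runif(n) * read_length) + 1L
  read_offset <- pmin(pos_in_read, read_length - pos_in_read + 1L)

  out <- data.frame(
    locus = locus, base = base, qual = as.integer(round(platform$base_qual)),
    read_length = as.integer(read_length), read_offset = as.integer(read_offset),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pileup_set", "data.frame"),
            sample = truth$samples[sample], raw_depth = depth)
}

#' Simulate a full platform genotype matrix
#'
#' Draws every sample's pileups on one platform and calls genotypes at the
#' panel loci, returning a [geno_matrix] with per-sample realised coverage
#' (mean raw pileup depth) attached.
#'
#' @param truth A [simulate_truth()] result.
#' @param platform A [platform_config()].
#' @param seed Integer seed; sample `i` uses `seed + i - 1`.
#' @param min_bq Minimum base quality used by the caller (see
#'   [call_genotypes()]). The generator attaches a constant per-platform
#'   quality, so simulation studies usually call with `min_bq = 1` and
#'   exercise the quality gate through explicit sweeps.
#' @param het_prior Heterozygote prior weight (see [call_genotypes()]).
#' @return A [geno_matrix].
#' @export
simulate_platform_matrix <- function(truth, platform, seed,
                                     min_bq = 1, het_prior = 0.25) {
  stopifnot(inherits(truth, "truth_set"))
  S <- length(truth$samples)
  calls <- vector("list", S)
  coverage <- numeric(S)
  for (i in seq_len(S)) {
    pu <- simulate_pileup(truth, i, platform, seed = as.integer(seed) + i - 1L)
    coverage[i] <- mean(attr(pu, "raw_depth"))
    calls[[i]] <- call_genotypes(pu, truth$panel, min_bq = min_bq,
                                 het_prior = het_prior)
  }
  geno_matrix_from_calls(calls, truth$panel, truth$samples, coverage)
}

#' Simulate the full two-platform data set
#'
#' Convenience wrapper: truth set plus one called genotype matrix per
#' platform block in the configuration, all derived from the master seed.
#'
#' @param config A [sim_config()].
#' @inheritParams simulate_platform_matrix
#' @return A list with `truth` and `matrices` (named list of [geno_matrix]).
#' @export
simulate_dataset <- function(config, min_bq = 1, het_prior = 0.25) {
  truth <- simulate_truth(config)
  matrices <- list()
  offset <- 1000L
  for (nm in names(config$platforms)) {
    matrices[[nm]] <- simulate_platform_matrix(
      truth, config$platforms[[nm]],
      seed = (config$seed + offset) %% .Machine$integer.max,
      min_bq = min_bq, het_prior = het_prior
    )
    offset <- offset + 1000L
  }
  list(truth = truth, matrices = matrices)
}

#' Write a truth set to TSV
#'
#' One row per locus: `chrom`, `pos`, `ref`, `alt`, `dup_flag`, then one
#' genotype column per sample.
#'
#' @param truth A [simulate_truth()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- cbind(truth$panel[c("chrom", "pos", "ref", "alt", "dup_flag")],
              as.data.frame(truth$gt))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
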