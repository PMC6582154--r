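test_that("doubled-haploid truth sets contain no heterozygote when leakage is zero", {
  cfg <- sim_config(n_samples = 5, n_loci = 500, residual_het_rate = 0, seed = 3)
  truth <- simulate_truth(cfg)
  expect_equal(sum(truth$gt == "het"), 0)
  expect_setequal(unique(as.vector(truth$gt)), c("hom_ref", "hom_alt"))

  cfg_leak <- sim_config(n_samples = 5, n_loci = 2000,
                         residual_het_rate = 0.1, seed = 3)
  truth_leak <- simulate_truth(cfg_leak)
  p_hat <- mean(truth_leak$gt == "het")
  se <- sqrt(0.1 * 0.9 / length(truth_leak$gt))
  expect_lt(abs(p_hat - 0.1), 3 * se)
})

test_that("empty panels give empty truth sets", {
  truth <- simulate_truth(sim_config(n_loci = 0, seed = 1))
  expect_equal(nrow(truth$panel), 0)
  expect_equal(nrow(truth$gt), 0)
})

test_that("truth genotype and duplication frequencies follow the configuration", {
  cfg <- sim_config(n_samples = 1, n_loci = 10000, allele_freq = 0.5,
                    dup_fraction = 0.1, seed = 11)
  truth <- simulate_truth(cfg)
  f <- mean(truth$gt == "hom_alt")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
  d <- mean(truth$panel$dup_flag)
  expect_lt(abs(d - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
  # paralog alleles only defined at duplicated loci
  expect_true(all(is.na(truth$panel$paralog_allele[!truth$panel$dup_flag])))
  expect_false(anyNA(truth$panel$paralog_allele[truth$panel$dup_flag]))
})

test_that("configuration validation rejects invalid probabilities and depths", {
  expect_error(sim_config(allele_freq = 1.2), "probability")
  expect_error(sim_config(residual_het_rate = -0.1), "probability")
  expect_error(platform_config(mean_depth = -1, base_error_rate = 0.1), "non-negative")
  expect_error(platform_config(mean_depth = 1, base_error_rate = 1), "base_error_rate")
  # per-sample depth vectors are recycled to the sample count
  cfg <- sim_config(n_samples = 4,
                    platforms = list(srs = srs_platform(mean_depth = c(1, 2))))
  expect_equal(cfg$platforms$srs$mean_depth, c(1, 2, 1, 2))
})

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- test_config(n_loci = 300, seed = 99)
  expect_identical(simulate_truth(cfg), simulate_truth(cfg))
  truth <- simulate_truth(cfg)
  p1 <- simulate_pileup(truth, 1, cfg$platforms$lrs, seed = 5)
  p2 <- simulate_pileup(truth, 1, cfg$platforms$lrs, seed = 5)
  expect_identical(p1, p2)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$matrices$lrs$gt, ds2$matrices$lrs$gt)
  expect_identical(ds1$matrices$srs$pl_het, ds2$matrices$srs$pl_het)
})

test_that("zero mean depth yields empty pileups and all-missing calls", {
  cfg <- sim_config(n_samples = 2, n_loci = 50, seed = 2)
  truth <- simulate_truth(cfg)
  pf <- platform_config(mean_depth = 0, base_error_rate = 0.1)
  pu <- simulate_pileup(truth, 1, pf, seed = 1)
  expect_equal(nrow(pu), 0)
  calls <- call_genotypes(pu, truth$panel, min_bq = 1)
  expect_true(all(is.na(calls$gt)))
  expect_true(all(calls$dp == 0))
})

test_that("unknown sample is an index error", {
  truth <- simulate_truth(sim_config(n_samples = 2, n_loci = 10, seed = 1))
  expect_error(simulate_pileup(truth, 7, lrs_platform(), seed = 1), "unknown sample")
  expect_error(simulate_pileup(truth, "DH-99", lrs_platform(), seed = 1), "unknown sample")
})

test_that("uniform substitution error puts e/3 of observations on the alt allele", {
  cfg <- sim_config(n_samples = 1, n_loci = 200, allele_freq = 0,
                    dup_fraction = 0, seed = 17)
  truth <- simulate_truth(cfg)
  pf <- platform_config(mean_depth = 100, base_error_rate = 0.09, base_qual = 10)
  pu <- simulate_pileup(truth, 1, pf, seed = 4)
  alt_frac <- mean(pu$base == truth$panel$alt[pu$locus])
  se <- sqrt(0.03 * 0.97 / nrow(pu))
  expect_lt(abs(alt_frac - 0.03), 3 * se)
  # total error rate is e
  err_frac <- mean(pu$base != truth$panel$ref[pu$locus])
  expect_lt(abs(err_frac - 0.09), 3 * sqrt(0.09 * 0.91 / nrow(pu)))
})

test_that("misaligned reads from a divergent paralog make a half-and-half pileup", {
  cfg <- sim_config(n_samples = 1, n_loci = 200, allele_freq = 0,
                    dup_fraction = 1, paralog_divergence = 1, seed = 23)
  truth <- simulate_truth(cfg)
  pf <- platform_config(mean_depth = 100, base_error_rate = 0,
                        misalignment_rate = 0.5)
  pu <- simulate_pileup(truth, 1, pf, seed = 9)
  alt_frac <- mean(pu$base == truth$panel$alt[pu$locus])
  expect_lt(abs(alt_frac - 0.5), 3 * sqrt(0.25 / nrow(pu)))
})

test_that("error-free, misalignment-free pileups reproduce the truth allele exactly", {
  cfg <- sim_config(n_samples = 3, n_loci = 300, seed = 31)
  truth <- simulate_truth(cfg)
  pf <- platform_config(mean_depth = 4, base_error_rate = 0, misalignment_rate = 0)
  for (i in 1:3) {
    pu <- simulate_pileup(truth, i, pf, seed = i)
    truth_base <- ifelse(truth$gt[pu$locus, i] == "hom_alt",
                         truth$panel$alt[pu$locus], truth$panel$ref[pu$locus])
    expect_true(all(pu$base == truth_base))
  }
})

test_that("realised depth converges to the configured mean", {
  cfg <- sim_config(n_samples = 1, n_loci = 20000, seed = 5)
  truth <- simulate_truth(cfg)
  for (pf in list(platform_config(mean_depth = 2.5, base_error_rate = 0.1),
                  platform_config(mean_depth = 2.5, base_error_rate = 0.001,
                                  depth_dispersion = 2))) {
    pu <- simulate_pileup(truth, 1, pf, seed = 8)
    d <- attr(pu, "raw_depth")
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 2.5), 3 * se)
  }
})

test_that("read offsets stay within half a read length and lengths respect the mean", {
  cfg <- sim_config(n_samples = 1, n_loci = 500, seed = 13)
  truth <- simulate_truth(cfg)
  pu <- simulate_pileup(truth, 1, lrs_platform(mean_depth = 5), seed = 2)
  expect_true(all(pu$read_offset >= 1))
  expect_true(all(pu$read_offset <= pu$read_length / 2 + 1))
  lens <- simulate_read_lengths(200000, 7525)
  expect_true(all(lens >= 100))
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 7525), 3 * se)
})

test_that("G/C substitution bias inflates errors on G/C bases only", {
  cfg <- sim_config(n_samples = 1, n_loci = 400, allele_freq = 0.5,
                    dup_fraction = 0, seed = 19)
  truth <- simulate_truth(cfg)
  pf <- platform_config(mean_depth = 50, base_error_rate = 0.02,
                        gc_substitution_mult = 3)
  pu <- simulate_pileup(truth, 1, pf, seed = 3)
  truth_base <- ifelse(truth$gt[pu$locus, 1] == "hom_alt",
                       truth$panel$alt[pu$locus], truth$panel$ref[pu$locus])
  err <- pu$base != truth_base
  gc <- truth_base %in% c("G", "C")
  expect_gt(mean(err[gc]), 2 * mean(err[!gc]))
})

test_that("A/T deletion bias thins observations of A/T bases", {
  cfg <- sim_config(n_samples = 1, n_loci = 2000, allele_freq = 0.5,
                    dup_fraction = 0, seed = 29)
  truth <- simulate_truth(cfg)
  pf0 <- platform_config(mean_depth = 10, base_error_rate = 0)
  pf1 <- platform_config(mean_depth = 10, base_error_rate = 0,
                         at_deletion_rate = 0.3)
  n_at <- function(pu) sum(pu$base %in% c("A", "T"))
  n_gc <- function(pu) sum(pu$base %in% c("G", "C"))
  pu0 <- simulate_pileup(truth, 1, pf0, seed = 6)
  pu1 <- simulate_pileup(truth, 1, pf1, seed = 6)
  # same seed: identical draws, A/T observations thinned by ~30%
  expect_equal(n_gc(pu1), n_gc(pu0))
  ratio <- n_at(pu1) / n_at(pu0)
  expect_lt(abs(ratio - 0.7), 3 * sqrt(0.3 * 0.7 / n_at(pu0)))
})

test_that("truth sets round-trip to TSV", {
  truth <- simulate_truth(sim_config(n_samples = 3, n_loci = 20, seed = 41))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(truth, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 20)
  expect_equal(df$pos, truth$panel$pos)
  expect_equal(df$DH.2, unname(truth$gt[, 2]))
})
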