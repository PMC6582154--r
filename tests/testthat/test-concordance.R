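test_that("pair classification is exhaustive and mutually exclusive", {
  lv <- c("hom_ref", "het", "hom_alt", NA)
  grid <- expand.grid(ref = lv, query = lv, stringsAsFactors = FALSE)
  cls <- classify_pairs(grid$ref, grid$query)
  expect_true(all(cls %in% c("concordant", "het_ref_hom_query",
                             "hom_ref_het_query", "alt_hom", "not_comparable")))
  # spot checks covering every class
  expect_equal(classify_pairs("hom_ref", "hom_ref"), "concordant")
  expect_equal(classify_pairs("het", "het"), "concordant")
  expect_equal(classify_pairs("het", "hom_alt"), "het_ref_hom_query")
  expect_equal(classify_pairs("het", "hom_ref"), "het_ref_hom_query")
  expect_equal(classify_pairs("hom_alt", "het"), "hom_ref_het_query")
  expect_equal(classify_pairs("hom_ref", "hom_alt"), "alt_hom")
  expect_equal(classify_pairs(NA, "hom_ref"), "not_comparable")
  expect_equal(classify_pairs("hom_ref", NA), "not_comparable")
  # missing exactly when either side is missing
  expect_equal(cls == "not_comparable", is.na(grid$ref) | is.na(grid$query))
})

test_that("identical matrices are 100% concordant; simple ratios are exact", {
  gm <- make_gm(matrix(rep(c("hom_ref", "hom_alt"), 5), 5, 2))
  rep0 <- per_sample_accuracy(gm, gm, ref_dp_min = NULL)
  expect_equal(rep0$pooled$pct_concordant, 100)
  expect_equal(rep0$pooled$n_comparable, 10)

  # one discrepant cell in 10 comparable
  gm2 <- gm
  gm2$gt[1, 1] <- "hom_alt"
  rep1 <- per_sample_accuracy(gm, gm2, ref_dp_min = NULL)
  expect_equal(rep1$pooled$pct_concordant, 90)
  expect_equal(rep1$pooled$pct_discrepant, 10)
  expect_equal(rep1$breakdown$n[rep1$breakdown$cls == "alt_hom"], 1)
})

test_that("zero comparable cells is flagged, not an error", {
  gm <- make_gm(matrix(NA_character_, 3, 2))
  hom <- make_gm(matrix("hom_ref", 3, 2))
  rep0 <- per_sample_accuracy(gm, hom, ref_dp_min = NULL)
  expect_equal(rep0$pooled$n_comparable, 0)
  expect_true(is.na(rep0$pooled$pct_concordant))
})

test_that("the reference platform gets its own minimum-depth treatment", {
  gm_ref <- make_gm(matrix("hom_ref", 4, 1), dp = c(1, 2, 3, 4))
  gm_q <- make_gm(matrix("hom_ref", 4, 1), dp = 5)
  tab <- concordance_table(gm_ref, gm_q, ref_dp_min = 2)
  expect_equal(sum(tab$cls == "not_comparable"), 1)
  tab0 <- concordance_table(gm_ref, gm_q, ref_dp_min = NULL)
  expect_equal(sum(tab0$cls == "not_comparable"), 0)
})

test_that("DH-adjusted accuracy follows the linear reclassification formula", {
  expect_equal(round(dh_adjusted_accuracy(94.7, 5.3, 70.3), 1), 98.4)
  expect_equal(dh_adjusted_accuracy(100, 0, 50), 100)
  expect_equal(dh_adjusted_accuracy(90, 10, 0), 90)
  # bounded by [pct_concordant, 100] and linear in the share
  shares <- seq(0, 100, by = 10)
  vals <- vapply(shares, function(s) dh_adjusted_accuracy(80, 20, s), numeric(1))
  expect_equal(vals, 80 + 0.2 * shares)
  expect_true(all(vals >= 80 & vals <= 100))
  expect_error(dh_adjusted_accuracy(94.7, 5.3, 120), "percentages")
  expect_error(dh_adjusted_accuracy(-1, 101, 10), "percentages")
  expect_error(dh_adjusted_accuracy(60, 20, 10), "equal 100")
})

test_that("per-SNP accuracy and its cumulative curve match a direct tabulation", {
  set.seed(21)
  n_loci <- 20; n_s <- 9
  gt_ref <- matrix(sample(c("hom_ref", "hom_alt", "het"), n_loci * n_s, TRUE,
                          prob = c(0.45, 0.45, 0.1)), n_loci, n_s)
  gt_q <- gt_ref
  flip <- matrix(runif(n_loci * n_s) < 0.2, n_loci, n_s)
  gt_q[flip] <- sample(c("hom_ref", "hom_alt", NA), sum(flip), TRUE)
  ref <- make_gm(gt_ref)
  query <- make_gm(gt_q)
  res <- per_snp_accuracy(ref, query, ref_dp_min = NULL, min_samples = 7)

  # independent tabulation from the raw per-cell comparison
  correct <- !is.na(gt_q) & gt_q == gt_ref
  comparable <- !is.na(gt_q) & !is.na(gt_ref)
  n_cmp <- rowSums(comparable)
  props <- rowSums(correct) / n_cmp
  keep <- n_cmp >= 7
  expect_equal(nrow(res$per_snp), sum(keep))
  expect_equal(sort(res$per_snp$prop_correct), sort(props[keep]))
  for (t in seq(0, 1, 0.1)) {
    expect_equal(res$curve$pct_snps[abs(res$curve$threshold - t) < 1e-9],
                 100 * mean(props[keep] >= t - 1e-12))
  }
  # curve shape: monotone non-increasing, 100% at t = 0
  expect_equal(res$curve$pct_snps[1], 100)
  expect_true(all(diff(res$curve$pct_snps) <= 0))
})

test_that("a SNP wrong in one of nine samples drops out above t = 8/9", {
  gt_ref <- matrix("hom_ref", 1, 9)
  gt_q <- gt_ref
  gt_q[1, 9] <- "hom_alt"
  res <- per_snp_accuracy(make_gm(gt_ref), make_gm(gt_q), ref_dp_min = NULL,
                          min_samples = 7, thresholds = c(0, 8 / 9, 0.9, 1))
  expect_equal(res$per_snp$prop_correct, 8 / 9)
  expect_equal(res$curve$pct_snps, c(100, 100, 0, 0))
})

test_that("counting het-in-reference as correct raises the per-SNP curve", {
  cfg <- test_config(n_loci = 2000, seed = 55)
  ds <- simulate_dataset(cfg)
  spec <- filter_spec(dp_min = 2, dp_max = 5)
  plain <- per_snp_accuracy(ds$matrices$srs, ds$matrices$lrs, spec,
                            hom_only = TRUE)
  adj <- per_snp_accuracy(ds$matrices$srs, ds$matrices$lrs, spec,
                          hom_only = TRUE, count_het_ref_as_correct = TRUE)
  expect_true(all(adj$curve$pct_snps >= plain$curve$pct_snps))
})

test_that("the zygosity breakdown matches a hand tally and sums to 100", {
  # 20 reference-hom cells, one flipped to het in the query
  gt_ref <- matrix("hom_ref", 10, 2)
  gt_q <- gt_ref
  gt_q[1, 1] <- "het"
  z <- zygosity_breakdown(make_gm(gt_ref), make_gm(gt_q), ref_dp_min = NULL)
  expect_equal(z$ref_hom$pct_same, 95)
  expect_equal(z$ref_hom$pct_discrepant, 5)
  expect_equal(z$ref_hom$pct_discrepant_het, 100)
  expect_equal(z$ref_hom$pct_discrepant_hom, 0)

  # fixture with known mixed counts
  gt_ref2 <- matrix(c(rep("hom_ref", 6), rep("het", 4)), 10, 1)
  gt_q2 <- matrix(c("hom_ref", "hom_ref", "hom_ref", "hom_alt", "het", "hom_ref",
                    "het", "het", "hom_ref", "hom_alt"), 10, 1)
  z2 <- zygosity_breakdown(make_gm(gt_ref2), make_gm(gt_q2), ref_dp_min = NULL)
  expect_equal(z2$ref_hom$n, 6)
  expect_equal(z2$ref_hom$pct_same, 100 * 4 / 6)
  expect_equal(z2$ref_hom$pct_discrepant_hom, 50)
  expect_equal(z2$ref_hom$pct_discrepant_het, 50)
  expect_equal(z2$ref_het$pct_same, 50)
  expect_equal(z2$ref_het$pct_query_hom, 50)
  expect_equal(z2$ref_hom$pct_same + z2$ref_hom$pct_discrepant, 100)
  expect_equal(z2$ref_het$pct_same + z2$ref_het$pct_query_hom, 100)
})

test_that("identical query reproduces 100% 'same' in both zygosity rows", {
  gt <- matrix(sample(c("hom_ref", "het", "hom_alt"), 30, TRUE), 15, 2)
  gm <- make_gm(gt)
  z <- zygosity_breakdown(gm, gm, ref_dp_min = NULL)
  expect_equal(z$ref_hom$pct_same, 100)
  expect_equal(z$ref_het$pct_same, 100)
})

test_that("the optimal supporting-read count takes the argmax with ties to smaller depth", {
  # flat accuracy across strata -> smallest depth wins
  acc_flat <- data.frame(dp = 1:5, n = rep(100L, 5), accuracy = rep(90, 5))
  expect_equal(skimgeno:::pick_optimal_depth(acc_flat, min_cells = 50), 1L)
  # single-peaked table -> the peak
  acc_peak <- data.frame(dp = 1:5, n = rep(100L, 5),
                         accuracy = c(80, 90, 97, 93, 88))
  expect_equal(skimgeno:::pick_optimal_depth(acc_peak, min_cells = 50), 3L)
  # thin strata are excluded from the argmax
  acc_thin <- data.frame(dp = 1:3, n = c(100L, 100L, 5L),
                         accuracy = c(80, 90, 100))
  expect_equal(skimgeno:::pick_optimal_depth(acc_thin, min_cells = 50), 2L)
  expect_true(is.na(skimgeno:::pick_optimal_depth(acc_thin[0, ], 50)))
})

test_that("depth-stratified accuracy agrees with a direct split computation", {
  cfg <- test_config(n_loci = 1500, seed = 66)
  ds <- simulate_dataset(cfg)
  tab <- concordance_table(ds$matrices$srs, ds$matrices$lrs)
  one <- tab[tab$sample == "DH-1" & tab$cls != "not_comparable", ]
  acc <- skimgeno:::accuracy_by_depth(tab[tab$sample == "DH-1", ])
  for (d in acc$dp[1:min(3, nrow(acc))]) {
    cells <- one[one$query_dp == d, ]
    expect_equal(acc$accuracy[acc$dp == d],
                 100 * mean(cells$cls == "concordant"))
    expect_equal(acc$n[acc$dp == d], nrow(cells))
  }
})
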