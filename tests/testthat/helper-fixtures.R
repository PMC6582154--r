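# Small builders used across the suite: panels, pileups and genotype
# matrices assembled directly (no simulation), plus an independent
# brute-force likelihood oracle.

make_panel <- function(n, ref = "A", alt = "C", chrom = "chr1",
                       dup_flag = FALSE) {
  data.frame(
    chrom = chrom, pos = seq_len(n) * 100L,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    dup_flag = rep_len(dup_flag, n),
    paralog_allele = NA_character_,
    stringsAsFactors = FALSE
  )
}

make_pileup <- function(locus, base, qual, read_length = 1000L,
                        read_offset = 400L) {
  n <- length(base)
  structure(
    data.frame(
      locus = rep_len(locus, n), base = base, qual = rep_len(qual, n),
      read_length = as.integer(rep_len(read_length, n)),
      read_offset = as.integer(rep_len(read_offset, n)),
      stringsAsFactors = FALSE
    ),
    class = c("pileup_set", "data.frame")
  )
}

# geno_matrix straight from a genotype matrix (+ optional fields)
make_gm <- function(gt, panel = NULL, dp = NULL, ad_ref = NULL,
                    ad_alt = NULL, pl = NULL, coverage = NULL) {
  gt <- as.matrix(gt)
  L <- nrow(gt); S <- ncol(gt)
  if (is.null(panel)) panel <- make_panel(L)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("DH-", seq_len(S))
  dimnames(gt) <- list(skimgeno::locus_key(panel), samples)
  default_dp <- matrix(ifelse(is.na(gt), 0, 3), L, S)
  shape <- function(x, def) {
    x <- if (is.null(x)) def else matrix(x, L, S)
    dimnames(x) <- dimnames(gt)
    x
  }
  dp <- shape(dp, default_dp)
  ad_ref <- shape(ad_ref, matrix(ifelse(!is.na(gt) & gt != "hom_alt", dp, 0), L, S))
  ad_alt <- shape(ad_alt, matrix(ifelse(!is.na(gt) & gt == "hom_alt", dp, 0), L, S))
  if (is.null(pl)) {
    pl1 <- shape(NULL, matrix(ifelse(gt %in% "hom_ref", 0, 30), L, S))
    pl2 <- shape(NULL, matrix(ifelse(gt %in% "het", 0, 30), L, S))
    pl3 <- shape(NULL, matrix(ifelse(gt %in% "hom_alt", 0, 30), L, S))
  } else {
    pl1 <- shape(pl[[1]], NULL); pl2 <- shape(pl[[2]], NULL); pl3 <- shape(pl[[3]], NULL)
  }
  pl1[is.na(gt)] <- NA; pl2[is.na(gt)] <- NA; pl3[is.na(gt)] <- NA
  structure(
    list(gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
         pl_hom_ref = pl1, pl_het = pl2, pl_hom_alt = pl3,
         panel = panel, samples = samples,
         coverage = coverage %||% colMeans(dp)),
    class = "geno_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: direct product of per-read probabilities in linear
# space, phred-scaled with the round-then-shift convention.
brute_force_pl <- function(bases, quals, ref, alt) {
  lik <- function(g) {
    p <- vapply(seq_along(bases), function(i) {
      e <- 10^(-quals[i] / 10)
      p_of <- function(allele) if (bases[i] == allele) 1 - e else e / 3
      switch(g,
        hom_ref = p_of(ref),
        hom_alt = p_of(alt),
        het = (p_of(ref) + p_of(alt)) / 2
      )
    }, numeric(1))
    prod(p)
  }
  L <- c(lik("hom_ref"), lik("het"), lik("hom_alt"))
  pl <- round(-10 * log10(L))
  pl - min(pl)
}

# default study-structure config scaled down for tests
test_config <- function(n_loci = 4000, seed = 42, ...) {
  sim_config(n_loci = n_loci, seed = seed, ...)
}
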