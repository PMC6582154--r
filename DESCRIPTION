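Package: skimgeno
Title: Low-Coverage Long-Read SNP Genotyping Concordance in Doubled Haploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate skim (sub-1x to few-x) whole-genome
    resequencing as a genotyping platform at pre-validated biallelic SNP
    loci, built around the comparison of a high-accuracy short-read
    platform against a high-error long-read platform in doubled-haploid
    (fully homozygous) material. Provides a pileup-level simulator of the
    two error regimes (random base error versus misalignment of reads from
    duplicated regions), an independent-error genotype caller emitting
    GT/DP/AD/PL, composable depth, read-length, end-trim and heterozygote
    filters, platform concordance classification and per-sample and
    per-SNP accuracy summaries, heterozygote reassignment by genotype
    likelihood or allelic depth, coverage-heterozygosity correlation and
    nucleotide-bias analyses, and minimal VCF and SNP-list input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
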