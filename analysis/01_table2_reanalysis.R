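#!/usr/bin/env Rscript
# Re-analysis of the packaged worked-example extract: three variants
# (an in-deletion SNP, a stratified SNP, a miscalled indel) genotyped across
# six super-populations. Tests each genotype distribution for HWE departure,
# classifies the direction, and attaches the five explanatory features.

suppressPackageStartupMessages(library(hweqc))
dir.create("results", showWarnings = FALSE)

counts <- exac_table2_counts()
cnv <- system.file("extdata", "exac_table2_cnv.bed", package = "hweqc")
run <- run_pipeline(counts, total_n = 60706, cnv_intervals = cnv,
                    out_dir = "results/table2")

r <- run$results
cat("Tested", nrow(r), "genotype distributions from",
    length(unique(r$variant_id)), "variants.\n")
cat("Departures: ", sum(r$classification == "LOH"), "LoH, ",
    sum(r$classification == "GOH"), "GoH, ",
    sum(r$classification == "NONE"), "in equilibrium.\n")
cat("\nPer-distribution results (report precision):\n")
print(format_report(r)[, c("variant_id", "population", "allele_a_freq",
                           "p_hwe", "oe_ratio", "classification")],
      row.names = FALSE)
cat("\nPer-variant features:\n")
print(format_report(run$features), row.names = FALSE)
cat("\nThe in-deletion SNP departs as LoH in four populations, the",
    "stratified SNP as LoH in the two admixed/substructured populations,",
    "and the indel as GoH everywhere - the genotyping-error signature.\n")
cat("Outputs under results/table2/.\n")
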