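#!/usr/bin/env Rscript
# Group-comparison analysis on a labelled synthetic cohort: in-equilibrium
# controls, inbred variants (LoH departures) and paralog-collapse indels
# carrying correlated missingness (GoH departures, the genotyping-error
# signature). Reproduces the structure of the departure-vs-control feature
# table and the strict genotyping-rate re-analysis.

suppressPackageStartupMessages(library(hweqc))
dir.create("results", showWarnings = FALSE)
set.seed(33)

n_ind <- 3000
rows <- list()
add <- function(id, draw, ref = "A", alt = "G") {
  for (pop in c("POP1", "POP2")) {
    rows[[length(rows) + 1]] <<- cbind(
      data.frame(variant_id = id, chrom = "1", pos = 1000 * length(rows) + 1,
                 ref = ref, alt = alt, population = pop), draw())
  }
}
for (i in 1:40) {
  p <- runif(1, 0.2, 0.8)
  add(sprintf("ctl%03d", i), function() sim_hwe(n_ind, p, missing_rate = 0.005))
}
for (i in 1:10) add(sprintf("loh%03d", i),
  function() sim_inbreeding(n_ind, 0.5, 0.25, missing_rate = 0.005))
for (i in 1:10) add(sprintf("goh%03d", i),
  function() sim_paralog_collapse(n_ind, 0.5, missing_rate = 0.14),
  ref = "AT", alt = "A")
counts <- do.call(rbind, rows)

run <- run_pipeline(counts, total_n = 2 * n_ind, out_dir = "results/cohort")
cat("Classifications:\n")
print(table(run$results$classification))
cat("\nDeparture-vs-control comparisons:\n")
print(format_report(run$association)[, c("feature", "class", "test", "p_value")],
      row.names = FALSE)
cat("\nThe GoH class shows the error signature: higher missingness and",
    "indel enrichment (both p << 0.001); the LoH class does not.\n")

strict <- run_pipeline(counts, total_n = 2 * n_ind, strict = TRUE)
cat(sprintf("\nStrict mode (call rate >= 98%%): %d GoH, %d LoH calls remain\n",
            sum(strict$results$classification == "GOH"),
            sum(strict$results$classification == "LOH")))
cat("Correlated-missingness GoH variants vanish under the strict filter;\n")
cat("biology-driven LoH departures survive.\n")
cat("Outputs under results/cohort/.\n")
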