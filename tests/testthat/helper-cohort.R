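`%||%` <- function(a, b) if (is.null(a)) b else a

# Labelled two-population cohort: in-equilibrium controls, inbred (LoH)
# variants, and paralog-collapse (GoH) variants carrying extra missingness
# (the error-driven class). Cohort size per population is n_ind, so pipeline
# calls should use total_n = 2 * n_ind.
make_mechanism_cohort <- function(n_ctl = 40, n_loh = 10, n_goh = 10,
                                  n_ind = 3000, goh_missing = 0.14,
                                  seed = 31) {
  set.seed(seed)
  rows <- list()
  add <- function(id, cnt, ref = "A", alt = "G") {
    for (pop in c("POP1", "POP2")) {
      rows[[length(rows) + 1]] <<- cbind(
        data.frame(variant_id = id, chrom = "1",
                   pos = 1000 * length(rows) + 1, ref = ref, alt = alt,
                   population = pop),
        cnt())
    }
  }
  for (i in seq_len(n_ctl)) {
    p <- runif(1, 0.2, 0.8)
    add(sprintf("ctl%03d", i),
        function() sim_hwe(n_ind, p, missing_rate = 0.005))
  }
  for (i in seq_len(n_loh)) {
    add(sprintf("loh%03d", i),
        function() sim_inbreeding(n_ind, 0.5, 0.25, missing_rate = 0.005))
  }
  for (i in seq_len(n_goh)) {
    add(sprintf("goh%03d", i),
        function() sim_paralog_collapse(n_ind, 0.5, missing_rate = goh_missing),
        ref = "AT", alt = "A")
  }
  do.call(rbind, rows)
}
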