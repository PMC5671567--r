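oe_of <- function(cnt) oe_het_ratio(cnt$n_aa, cnt$n_ab, cnt$n_bb)

test_that("generators are seed-reproducible and conserve n", {
  a <- sim_hwe(5000, 0.3, missing_rate = 0.1, seed = 7)
  b <- sim_hwe(5000, 0.3, missing_rate = 0.1, seed = 7)
  expect_identical(a, b)
  draws <- list(sim_hwe(2000, 0.3, missing_rate = 0.1, seed = 1),
                sim_inbreeding(2000, 0.4, 0.3, missing_rate = 0.2, seed = 1),
                sim_stratified(2000, c(0.5, 0.5), c(0.2, 0.8),
                               missing_rate = 0.1, seed = 1),
                sim_deletion_overlay(2000, 0.5, 0.4, "MISSING", seed = 1),
                sim_deletion_overlay(2000, 0.5, 0.4, "FORCED_HOM", seed = 1),
                sim_paralog_collapse(2000, 0.7, missing_rate = 0.05, seed = 1),
                sim_allelic_dropout(2000, 0.5, 0.3, seed = 1))
  for (cnt in draws) {
    expect_equal(cnt$n_aa + cnt$n_ab + cnt$n_bb + cnt$n_missing, 2000)
  }
})

test_that("each generator reduces to the equilibrium draw at zero distortion", {
  expect_identical(sim_inbreeding(1000, 0.3, 0, seed = 5),
                   sim_hwe(1000, 0.3, seed = 5))
  expect_identical(sim_deletion_overlay(1000, 0.3, 0, "MISSING", seed = 5)[
                     , c("n_aa", "n_ab", "n_bb")],
                   sim_hwe(1000, 0.3, seed = 5)[, c("n_aa", "n_ab", "n_bb")])
  expect_identical(sim_allelic_dropout(1000, 0.3, 0, seed = 5)[
                     , c("n_aa", "n_ab", "n_bb")],
                   sim_hwe(1000, 0.3, seed = 5)[, c("n_aa", "n_ab", "n_bb")])
})

test_that("degenerate parameter values give the stated boundary behaviour", {
  expect_equal(unlist(sim_hwe(50, 1, seed = 1)),
               c(n_aa = 50, n_ab = 0, n_bb = 0, n_missing = 0))
  expect_equal(sim_inbreeding(500, 0.5, 1, seed = 1)$n_ab, 0)
  expect_equal(unlist(sim_paralog_collapse(80, 1, seed = 1)),
               c(n_aa = 0, n_ab = 80, n_bb = 0, n_missing = 0))
  expect_equal(oe_of(sim_paralog_collapse(80, 1, seed = 1)), 2.0)
  drop_all <- sim_allelic_dropout(200, 0.5, 1, seed = 1)
  expect_equal(drop_all$n_missing, 200)
})

test_that("simulated O/E ratios match their closed forms", {
  set.seed(41)
  n <- 1e5
  # equilibrium: O/E near 1 at CLT scale
  expect_lt(abs(oe_of(sim_hwe(1e6, 0.5)) - 1), 0.005)
  # inbreeding: O/E = 1 - F
  expect_lt(abs(oe_of(sim_inbreeding(n, 0.5, 0.25)) - 0.75), 0.02)
  # Wahlund: O/E = sum(w 2 p q) / (2 pbar qbar) = 0.32 / 0.50
  expect_lt(abs(oe_of(sim_stratified(n, c(0.5, 0.5), c(0.2, 0.8))) - 0.64),
            0.02)
  # deletion overlay: (1-d)/(1+d) when del/del is missing, (1-d)^2 forced
  expect_lt(abs(oe_of(sim_deletion_overlay(n, 0.5, 0.5, "MISSING")) - 1 / 3),
            0.02)
  expect_lt(abs(oe_of(sim_deletion_overlay(n, 0.5, 0.5, "FORCED_HOM")) - 0.25),
            0.02)
  # allelic dropout: against the per-genotype enumeration oracle
  for (e in c(0.1, 0.2, 0.4)) {
    pr <- oracle_dropout_call_probs(0.5, e)
    expect_lt(abs(oe_of(sim_allelic_dropout(n, 0.5, e)) -
                    expected_oe_from_probs(pr)), 0.02)
  }
  # dropout shifts the apparent genotype mix exactly as enumerated
  pr2 <- oracle_dropout_call_probs(0.3, 0.2)
  cnt <- sim_allelic_dropout(4e5, 0.3, 0.2)
  obs <- unlist(cnt) / 4e5
  expect_equal(unname(obs), unname(pr2), tolerance = 0.01)
})

test_that("stratification at published subpopulation frequencies departs as LoH", {
  # East Asian subpopulation frequencies of the stratified example variant
  cnt <- sim_stratified(1e5, rep(0.2, 5), c(0.21, 0.65, 0.40, 0.67, 0.17),
                        seed = 44)
  res <- hwe_analysis(cbind(data.frame(variant_id = "v", population = "EAS"),
                            cnt))
  expect_equal(res$classification, "LOH")
})

test_that("inbreeding coefficient is recoverable from 1 - O/E with unit slope", {
  set.seed(45)
  grid <- expand.grid(F_coef = seq(0, 0.5, by = 0.1), rep = 1:20)
  grid$loss <- vapply(grid$F_coef, function(f) {
    1 - oe_of(sim_inbreeding(1e5, 0.3, f))
  }, numeric(1))
  fit <- lm(loss ~ F_coef, data = grid)
  expect_lt(abs(coef(fit)["F_coef"] - 1), 0.05)
})

test_that("sim_region embeds mechanisms at the right positions", {
  layout <- data.frame(start = c(2e5, 6e5), end = c(3e5, 6.1e5),
                       mechanism = c("DELETION", "PARALOG"),
                       param = c(0.5, 1.0))
  sim <- sim_region(n = 500, n_variants = 120, region_end = 1e6,
                    layout = layout, seed = 46)
  expect_equal(nrow(sim$counts), 120)
  expect_equal(sort(unique(sim$truth$mechanism)),
               c("DELETION", "HWE", "PARALOG"))
  in_del <- sim$truth$pos >= 2e5 & sim$truth$pos <= 3e5
  expect_true(all(sim$truth$mechanism[in_del] == "DELETION"))
  # genotype matrix is consistent with the tabulated counts
  i <- which(in_del)[1]
  g <- sim$genotypes[i, ]
  expect_equal(sim$counts$n_ab[i], sum(g == "0/1"))
  expect_equal(sim$counts$n_missing[i], sum(g == "./."))
  # same seed, identical simulation
  sim2 <- sim_region(n = 500, n_variants = 120, region_end = 1e6,
                     layout = layout, seed = 46)
  expect_identical(sim$counts, sim2$counts)
  # overlapping mechanism intervals are rejected
  bad <- data.frame(start = c(1, 50), end = c(100, 70),
                    mechanism = c("DELETION", "PARALOG"), param = c(0.5, 1))
  expect_error(sim_region(10, 5, layout = bad), "overlap")
})
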