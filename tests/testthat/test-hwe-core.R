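# Reference rows: published genotype distributions with their printed
# allele frequency, p-value, O/E ratio and departure label.
ref_rows <- data.frame(
  id = c("rs7551421.EAS", "rs7551421.AMR", "rs58896934.AFR",
         "rs58896934.AMR", "rs509360.AMR", "rs509360.SAS"),
  n_aa = c(2392, 1658, 110, 531, 195, 4205),
  n_ab = c(1463, 2593, 1620, 2895, 1396, 3292),
  n_bb = c(429, 1523, 2198, 1412, 4190, 749),
  maf = c(0.73, 0.51, 0.23, 0.41, 0.15, 0.71),
  p = c(8.4e-18, 1.3e-13, 7.6e-20, 3.8e-60, 6.8e-08, 0.02),
  oe = c(0.86, 0.90, 1.15, 1.24, 0.92, 0.97),
  label = c("LOH", "LOH", "GOH", "GOH", "LOH", "NONE")
)

test_that("allele frequency, p-value, O/E and label match the reference rows", {
  for (i in seq_len(nrow(ref_rows))) {
    r <- ref_rows[i, ]
    m <- allele_a_frequency(r$n_aa, r$n_ab, r$n_bb)
    expect_equal(round(m, 2), r$maf, info = r$id)
    res <- hwe_test(r$n_aa, r$n_ab, r$n_bb)
    expect_equal(print_p(res$p_hwe), r$p, info = r$id)
    expect_equal(round(res$oe_ratio, 2), r$oe, info = r$id)
    expect_equal(classify_departure(res$p_hwe, res$oe_ratio), r$label,
                 info = r$id)
  }
})

test_that("expected counts reproduce the reference expectation columns", {
  e <- expected_genotype_counts(195, 1396, 4190)
  expect_equal(round(unlist(e)), c(exp_aa = 138, exp_ab = 1510, exp_bb = 4133))
  # derived: m = 0.3 on n = 100 gives the HW proportions exactly
  e2 <- expected_genotype_counts(9, 42, 49)
  expect_equal(unlist(e2), c(exp_aa = 9, exp_ab = 42, exp_bb = 49))
})

test_that("degenerate and boundary inputs behave as specified", {
  expect_equal(allele_a_frequency(7, 0, 0), 1.0)
  expect_error(allele_a_frequency(0, 0, 0), "untestable")
  expect_error(allele_a_frequency(-1, 2, 3), "non-negative")
  expect_error(allele_a_frequency(1.5, 2, 3), "non-negative")
  # exact HW proportions: chi2 = 0, p = 1, no departure
  res <- hwe_test(25, 50, 25)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_hwe, 1)
  expect_equal(classify_departure(res$p_hwe, res$oe_ratio), "NONE")
  # all-heterozygote sample: chi2 = n, closed-form p
  res2 <- hwe_test(0, 100, 0)
  expect_equal(res2$chi2, 100)
  expect_equal(res2$p_hwe, exp(-50))
  expect_equal(res2$oe_ratio, 2.0)
  # monomorphic: UNDEFINED, never an equilibrium control
  mono <- hwe_test(50, 0, 0)
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$p_hwe))
  expect_equal(classify_departure(mono$p_hwe, mono$oe_ratio), "UNDEFINED")
  # significant departure with O/E exactly 1 has no direction
  expect_equal(classify_departure(1e-9, 1), "UNDEFINED")
})

test_that("expected counts sum to n_called and p = exp(-chi2/2) at dof 2", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(50:5000, 1)
    cnt <- as.integer(rmultinom(1, n, c(0.2, 0.5, 0.3)))
    e <- expected_genotype_counts(cnt[1], cnt[2], cnt[3])
    expect_lt(abs(sum(e) - n), 1e-6 * n)
    res <- hwe_test(cnt[1], cnt[2], cnt[3], dof = 2)
    if (!res$monomorphic) {
      expect_lt(abs(res$p_hwe - exp(-res$chi2 / 2)), 1e-12)
    }
  }
})

test_that("the test is invariant under swapping the allele labels", {
  set.seed(12)
  for (rep in 1:25) {
    cnt <- as.integer(rmultinom(1, sample(30:2000, 1), c(0.5, 0.3, 0.2)))
    a <- hwe_test(cnt[1], cnt[2], cnt[3])
    b <- hwe_test(cnt[3], cnt[2], cnt[1])
    expect_equal(a$chi2, b$chi2)
    expect_equal(a$p_hwe, b$p_hwe)
    expect_equal(a$allele_a_freq, 1 - b$allele_a_freq)
  }
})

test_that("chi-square equals the brute-force oracle for every small sample", {
  for (n in 1:12) {
    for (aa in 0:n) for (ab in 0:(n - aa)) {
      bb <- n - aa - ab
      res <- hwe_test(aa, ab, bb)
      if (res$monomorphic) next
      expect_equal(res$chi2, oracle_hwe_chi2(aa, ab, bb), tolerance = 1e-12,
                   info = paste(aa, ab, bb))
    }
  }
})

test_that("variant_filter applies the call-rate and MAF rules", {
  # pooled call rate 48000/60706 = 0.79 < 0.80
  per_pop <- data.frame(population = c("P1", "P2"),
                        n_aa = c(6000, 6000), n_ab = c(12000, 12000),
                        n_bb = c(6000, 6000), n_missing = c(0, 0))
  f <- variant_filter(per_pop, total_n = 60706)
  expect_false(f$included)
  expect_equal(f$reasons, "LOW_CALL_RATE")
  # same counts pass at a cohort where the rate is above threshold
  f2 <- variant_filter(per_pop, total_n = 50000)
  expect_true(f2$included)
  # pooled folded MAF 0.005 < 0.01
  rare <- data.frame(population = "P1", n_aa = 9900, n_ab = 99, n_bb = 1,
                     n_missing = 0)
  f3 <- variant_filter(rare, total_n = 10000)
  expect_false(f3$included)
  expect_true("LOW_MAF_OVERALL" %in% f3$reasons)
  # one population below the population-level MAF floor is dropped
  mixed <- data.frame(population = c("COMMON", "RARE"),
                      n_aa = c(2500, 4996), n_ab = c(5000, 4), n_bb = c(2500, 0),
                      n_missing = c(0, 0))
  f4 <- variant_filter(mixed, total_n = 15000)
  expect_true(f4$included)
  expect_equal(f4$analyze_pops, "COMMON")
  expect_equal(f4$dropped_pops, "RARE")
  # strict mode raises the call-rate bar to 98%
  ok95 <- data.frame(population = "P1", n_aa = 2500, n_ab = 5000,
                     n_bb = 2000, n_missing = 500)
  expect_true(variant_filter(ok95, total_n = 10000)$included)
  f5 <- variant_filter(ok95, total_n = 10000, strict = TRUE)
  expect_false(f5$included)
  expect_equal(f5$reasons, "LOW_CALL_RATE")
  expect_error(variant_filter(per_pop[0, ], 100))
})

test_that("hwe_analysis carries identifiers through and classifies rows", {
  counts <- data.frame(variant_id = c("v1", "v2"), population = "POP",
                       n_aa = c(25, 0), n_ab = c(50, 100), n_bb = c(25, 0),
                       n_missing = 0L)
  res <- hwe_analysis(counts)
  expect_equal(res$variant_id, c("v1", "v2"))
  expect_equal(res$classification, c("NONE", "GOH"))
})
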