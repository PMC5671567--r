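# A compact simulated region: neutral background with an embedded deletion
# block and a paralog-collapse peak (the geometry of a local departure scan).
region_fixture <- function(seed = 61, n = 2000, n_variants = 200) {
  layout <- data.frame(start = c(3e5, 7.0e5), end = c(4e5, 7.02e5),
                       mechanism = c("DELETION", "PARALOG"),
                       param = c(0.5, 1.0))
  sim_region(n = n, n_variants = n_variants, region_end = 1e6,
             layout = layout, seed = seed)
}

test_that("scan tracks are sorted, MAF-filtered and duplicate-free", {
  sim <- region_fixture()
  track <- scan_region(sim$counts)
  expect_true(all(diff(track$pos) >= 0))
  expect_false(any(duplicated(track$variant_id)))
  called <- track$n_aa + track$n_ab + track$n_bb
  m <- (2 * track$n_aa + track$n_ab) / (2 * called)
  expect_true(all(pmin(m, 1 - m) > 0.01))
  expect_true(all(track$minus_log10_p >= 0))
  # region restriction
  sub <- scan_region(sim$counts, region = c(3e5, 4e5))
  expect_true(all(sub$pos >= 3e5 & sub$pos <= 4e5))
  expect_equal(nrow(scan_region(sim$counts, region = c(1, 2))), 0)
})

test_that("in-deletion variants are flagged LoH and the background is quiet", {
  sim <- region_fixture()
  track <- scan_region(sim$counts)
  in_del <- track$pos >= 3e5 & track$pos <= 4e5
  expect_true(all(track$classification[in_del] == "LOH"))
  bg <- track$variant_id %in%
    sim$truth$variant_id[sim$truth$mechanism == "HWE"]
  # at alpha 1e-5 essentially no background variant departs
  expect_lte(sum(track$classification[bg] != "NONE"), 1)
})

test_that("a track in exact equilibrium yields no significant entries", {
  n_var <- 50
  track <- scan_region(data.frame(
    variant_id = sprintf("v%02d", seq_len(n_var)), chrom = "1",
    pos = seq_len(n_var) * 100, ref = "A", alt = "G",
    n_aa = 25, n_ab = 50, n_bb = 25, n_missing = 0))
  expect_true(all(track$classification == "NONE"))
  expect_true(all(track$minus_log10_p == 0))
})

test_that("cluster detection merges nearby departures and reports direction", {
  # 11 significant GoH variants on a 2.4 kb span over a quiet background
  base <- data.frame(chrom = "17", variant_type = "SNP")
  mk <- function(pos, cls, p) data.frame(
    chrom = "17", pos = pos, variant_id = paste0("v", pos),
    variant_type = "SNP", minus_log10_p = -log10(p), oe_het_ratio = 2,
    classification = cls, p_hwe = p)
  peak <- mk(seq(62900000, 62902400, length.out = 11), "GOH", 1e-12)
  bgp <- mk(seq(62000000, 62800000, length.out = 30), "NONE", 0.5)
  track <- rbind(bgp, peak)
  track <- track[order(track$pos), ]
  calls <- detect_clusters(track)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "GOH")
  expect_equal(calls$n_significant, 11)
  expect_equal(calls$start, 62900000)
  expect_equal(calls$end, 62902400)
  # significant variants 50 kb apart never cluster at a 10 kb window
  sparse <- mk(seq(1e6, 1e6 + 50000 * 7, by = 50000), "LOH", 1e-9)
  expect_equal(nrow(detect_clusters(sparse)), 0)
  # mixed-direction clusters only surface when purity is not required
  mixed <- mk(seq(100, 1100, by = 100), rep(c("LOH", "GOH"), length.out = 11),
              1e-9)
  expect_equal(nrow(detect_clusters(mixed, direction_pure = TRUE)), 0)
  mcall <- detect_clusters(mixed, direction_pure = FALSE)
  expect_equal(mcall$direction, "MIXED")
  # cluster spans are disjoint and each meets the size floor
  sim <- region_fixture()
  calls2 <- detect_clusters(scan_region(sim$counts), min_cluster_size = 5)
  if (nrow(calls2) > 1) {
    o <- order(calls2$start)
    expect_true(all(calls2$start[o][-1] > calls2$end[o][-nrow(calls2)]))
  }
  expect_true(all(calls2$n_significant >= 5))
})

test_that("interval summaries contrast in-deletion and background O/E", {
  sim <- region_fixture()
  track <- scan_region(sim$counts)
  s <- interval_departure_summary(track, 3e5, 4e5)
  expect_equal(s$n_loh_inside, s$n_inside)
  expect_equal(s$n_goh_inside, 0)
  # closed form O/E = (1-d)/(1+d) = 1/3 at deletion frequency 0.5
  expect_lt(abs(s$median_oe_inside - 1 / 3), 0.05)
  expect_lt(abs(s$median_oe_outside - 1), 0.05)
  empty <- interval_departure_summary(track, 1, 2)
  expect_equal(empty$n_inside, 0)
  expect_true(is.na(empty$median_oe_inside))
  whole <- interval_departure_summary(track, 0, 2e6)
  expect_true(is.na(whole$median_oe_outside))
})

test_that("indels with genotyping error depart more often than SNPs", {
  # published chromosome-wide contingency: 1281/31650 indels vs
  # 2661/229021 SNPs departing
  pub <- rbind(INDEL = c(1281, 30369), SNP = c(2661, 226360))
  cmp <- compare_categorical(pub)
  expect_lt(cmp$p_value, 0.001)
  # synthetic track: indels receive an allelic-dropout error overlay
  set.seed(62)
  n <- 4000
  rows <- lapply(seq_len(300), function(i) {
    is_indel <- i <= 100
    cnt <- if (is_indel) sim_allelic_dropout(n, 0.5, 0.25)
           else sim_hwe(n, runif(1, 0.2, 0.8))
    cbind(data.frame(variant_id = sprintf("v%03d", i), chrom = "1",
                     pos = i * 1000,
                     ref = if (is_indel) "AT" else "A", alt = "A"),
          cnt)
  })
  track <- scan_region(do.call(rbind, rows))
  res <- indel_vs_snp_departure_rate(track)
  expect_gt(res$indel_rate, res$snp_rate)
  expect_lt(res$comparison$p_value, 0.001)
  # single-type track: comparison skipped
  snp_only <- track[track$variant_type == "SNP", ]
  expect_warning(nul <- indel_vs_snp_departure_rate(snp_only), "single")
  expect_null(nul)
})

test_that("track TSV and cluster BED writers round-trip", {
  sim <- region_fixture()
  track <- scan_region(sim$counts)
  tf <- tempfile(fileext = ".tsv")
  write_track_tsv(track, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), nrow(track))
  expect_equal(back$pos, track$pos)
  calls <- detect_clusters(track)
  bf <- tempfile(fileext = ".bed")
  write_cluster_bed(calls, bf)
  bed <- read.delim(bf, header = FALSE)
  expect_equal(nrow(bed), nrow(calls))
  expect_equal(bed$V2, calls$start - 1)  # 0-based half-open
  expect_equal(bed$V3, calls$end)
})
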