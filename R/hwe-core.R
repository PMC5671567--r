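#' Allele-A frequency from genotype counts
#'
#' Estimates the frequency of allele A from observed diploid genotype counts
#' by allele counting: m = (2 n_AA + n_AB) / (2 n_called). This is the
#' maximum-likelihood estimate under multinomial sampling and is always taken
#' from the same counts being tested. The folded minor allele frequency is
#' `pmin(m, 1 - m)`.
#'
#' @param n_aa,n_ab,n_bb Non-negative integer vectors of A/A homozygote,
#'   heterozygote and B/B homozygote counts. Recycled to a common length.
#' @return Numeric vector of allele-A frequencies in \[0, 1\].
#' @examples
#' allele_a_frequency(110, 1620, 2198)  # 0.23 (African rs58896934 counts)
#' @export
allele_a_frequency <- function(n_aa, n_ab, n_bb) {
  .check_counts(n_aa, n_ab, n_bb)
  n_called <- n_aa + n_ab + n_bb
  if (any(n_called == 0)) {
    stop("untestable variant: no called genotypes (n_called = 0)")
  }
  (2 * n_aa + n_ab) / (2 * n_called)
}

#' Hardy-Weinberg expected genotype counts
#'
#' Expected counts under random mating at the sample-estimated allele
#' frequency m: n m^2 A/A, 2 n m (1 - m) A/B, n (1 - m)^2 B/B, where n is the
#' number of called genotypes. The three components always sum to n.
#'
#' @inheritParams allele_a_frequency
#' @return A data.frame with columns `exp_aa`, `exp_ab`, `exp_bb`.
#' @examples
#' expected_genotype_counts(195, 1396, 4190)  # approx (138, 1510, 4133)
#' @export
expected_genotype_counts <- function(n_aa, n_ab, n_bb) {
  m <- allele_a_frequency(n_aa, n_ab, n_bb)
  n_called <- n_aa + n_ab + n_bb
  data.frame(
    exp_aa = n_called * m^2,
    exp_ab = 2 * n_called * m * (1 - m),
    exp_bb = n_called * (1 - m)^2
  )
}

#' Observed/expected heterozygote ratio
#'
#' The ratio of the observed heterozygote count to the count expected under
#' Hardy-Weinberg equilibrium. Values below 1 indicate a heterozygote deficit
#' (loss of heterozygosity), values above 1 an excess (gain). Undefined (NA)
#' for monomorphic samples, where the expected heterozygote count is 0.
#'
#' @inheritParams allele_a_frequency
#' @return Numeric vector of O/E ratios (NA where expected het count is 0).
#' @examples
#' oe_het_ratio(531, 2895, 1412)  # 1.24
#' @export
oe_het_ratio <- function(n_aa, n_ab, n_bb) {
  e <- expected_genotype_counts(n_aa, n_ab, n_bb)
  ratio <- ifelse(e$exp_ab > 0, n_ab / e$exp_ab, NA_real_)
  ratio
}

#' Chi-square goodness-of-fit test for Hardy-Weinberg equilibrium
#'
#' Tests observed genotype counts against Hardy-Weinberg expectations with a
#' three-category Pearson chi-square statistic, no continuity correction.
#'
#' The default `dof = 2` treats all three genotype categories as free, which
#' yields the closed form p = exp(-chi2 / 2); this is the reporting convention
#' the package's reference tables were produced under. The conventional test,
#' which subtracts the one estimated parameter (the allele frequency), is
#' obtained with `dof = 1` and is the calibrated choice when the p-value is
#' used as a frequentist error rate (see the methods vignette).
#'
#' Monomorphic samples (m = 0 or 1) are returned with `NA` statistic and
#' p-value and flagged `monomorphic`, so they are never mistaken for
#' equilibrium controls.
#'
#' @inheritParams allele_a_frequency
#' @param n_missing Optional vector of missing-genotype counts (carried
#'   through to the result, not used by the statistic).
#' @param dof Degrees of freedom for the chi-square reference distribution
#'   (2 by default, 1 for the conventional test).
#' @return A data.frame with one row per input: `n_aa`, `n_ab`, `n_bb`,
#'   `n_missing`, `n_called`, `allele_a_freq`, `exp_aa`, `exp_ab`, `exp_bb`,
#'   `chi2`, `dof`, `p_hwe`, `oe_ratio`, `monomorphic`.
#' @examples
#' hwe_test(2392, 1463, 429)  # chi2 approx 78.6, p approx 8.4e-18
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, n_missing = 0, dof = 2) {
  stopifnot(length(dof) == 1, dof >= 1)
  k <- max(length(n_aa), length(n_ab), length(n_bb), length(n_missing))
  n_aa <- rep_len(n_aa, k); n_ab <- rep_len(n_ab, k)
  n_bb <- rep_len(n_bb, k); n_missing <- rep_len(n_missing, k)
  m <- allele_a_frequency(n_aa, n_ab, n_bb)
  n_called <- n_aa + n_ab + n_bb
  e <- expected_genotype_counts(n_aa, n_ab, n_bb)
  mono <- m == 0 | m == 1

  obs <- cbind(n_aa, n_ab, n_bb)
  exp_ <- as.matrix(e)
  # categories with zero expectation contribute nothing; only arises when
  # m is 0 or 1, which is flagged monomorphic anyway
  dev <- (obs - exp_)^2 / ifelse(exp_ > 0, exp_, NA_real_)
  chi2 <- rowSums(dev, na.rm = TRUE)
  chi2[mono] <- NA_real_
  p <- stats::pchisq(chi2, df = dof, lower.tail = FALSE)

  data.frame(
    n_aa = n_aa, n_ab = n_ab, n_bb = n_bb, n_missing = n_missing,
    n_called = n_called,
    allele_a_freq = m,
    exp_aa = e$exp_aa, exp_ab = e$exp_ab, exp_bb = e$exp_bb,
    chi2 = chi2, dof = dof, p_hwe = p,
    oe_ratio = ifelse(e$exp_ab > 0, n_ab / e$exp_ab, NA_real_),
    monomorphic = mono
  )
}

#' Classify the direction of a Hardy-Weinberg departure
#'
#' Splits significant departures by the sign of the heterozygote O/E ratio:
#' `"LOH"` (loss of heterozygosity, O/E < 1) versus `"GOH"` (gain of
#' heterozygosity, O/E > 1). Non-significant tests are `"NONE"`. A departure
#' with O/E exactly 1, or any monomorphic/untestable input (NA p-value or
#' ratio), is `"UNDEFINED"`: the dichotomy presumes a direction, and
#' monomorphic variants must not pass as equilibrium controls.
#'
#' @param p_value Vector of HWE test p-values.
#' @param oe_ratio Vector of observed/expected heterozygote ratios.
#' @param alpha Significance threshold for departure (default 1e-5).
#' @return Character vector over `c("NONE", "LOH", "GOH", "UNDEFINED")`.
#' @examples
#' classify_departure(c(8.4e-18, 0.59), c(0.86, 1.01))  # "LOH"  "NONE"
#' @export
classify_departure <- function(p_value, oe_ratio, alpha = 1e-5) {
  stopifnot(length(alpha) == 1, alpha > 0, alpha < 1)
  k <- max(length(p_value), length(oe_ratio))
  p_value <- rep_len(p_value, k)
  oe_ratio <- rep_len(oe_ratio, k)
  out <- rep("UNDEFINED", k)
  ok <- !is.na(p_value) & !is.na(oe_ratio)
  out[ok & p_value >= alpha] <- "NONE"
  out[ok & p_value < alpha & oe_ratio < 1] <- "LOH"
  out[ok & p_value < alpha & oe_ratio > 1] <- "GOH"
  out
}

#' Run the HWE departure test over a genotype-counts table
#'
#' The per-population workhorse: tests every row of a long counts table
#' (one row per variant x population) and attaches the directional
#' classification. Columns other than the count columns are carried through.
#'
#' @param counts A data.frame with columns `n_aa`, `n_ab`, `n_bb` and
#'   optionally `n_missing` (assumed 0 when absent), typically also
#'   `variant_id` and `population`.
#' @param alpha Departure significance threshold (default 1e-5).
#' @param dof Chi-square degrees of freedom (default 2; see [hwe_test()]).
#' @return `counts` with the [hwe_test()] result columns and
#'   `classification` appended.
#' @export
hwe_analysis <- function(counts, alpha = 1e-5, dof = 2) {
  stopifnot(is.data.frame(counts),
            all(c("n_aa", "n_ab", "n_bb") %in% names(counts)))
  n_missing <- if ("n_missing" %in% names(counts)) counts$n_missing else 0
  res <- hwe_test(counts$n_aa, counts$n_ab, counts$n_bb, n_missing, dof = dof)
  res$classification <- classify_departure(res$p_hwe, res$oe_ratio, alpha)
  keep <- setdiff(names(counts), names(res))
  out <- cbind(counts[, keep, drop = FALSE], res)
  rownames(out) <- NULL
  out
}

#' Variant inclusion filter
#'
#' Applies the cohort-level inclusion rules for one variant: exclusion when
#' the pooled genotyping call rate falls below `min_call_rate` (default 80%;
#' `strict = TRUE` raises this to `strict_call_rate`, default 98%) or when
#' the pooled folded minor allele frequency falls below `min_maf` (default
#' 1%). Included variants additionally drop from analysis any population
#' whose own folded MAF is below `pop_min_maf` (default 0.001).
#'
#' @param per_pop A data.frame with columns `population`, `n_aa`, `n_ab`,
#'   `n_bb` (and optionally `n_missing`), one row per population, all rows
#'   belonging to one variant.
#' @param total_n Total cohort size used as the call-rate denominator.
#' @param min_call_rate,min_maf,pop_min_maf,strict_call_rate Thresholds as
#'   described above.
#' @param strict Use `strict_call_rate` instead of `min_call_rate`.
#' @return A list with `included` (logical), `reasons` (character vector of
#'   rejection codes among `"LOW_CALL_RATE"`, `"LOW_MAF_OVERALL"`),
#'   `analyze_pops` (populations passing the population-level MAF rule) and
#'   `dropped_pops`.
#' @export
variant_filter <- function(per_pop, total_n,
                           min_call_rate = 0.80, min_maf = 0.01,
                           pop_min_maf = 0.001,
                           strict = FALSE, strict_call_rate = 0.98) {
  stopifnot(is.data.frame(per_pop), nrow(per_pop) > 0,
            all(c("population", "n_aa", "n_ab", "n_bb") %in% names(per_pop)),
            length(total_n) == 1, total_n > 0)
  if (anyDuplicated(per_pop$population)) {
    stop("duplicate population rows for one variant")
  }
  called <- per_pop$n_aa + per_pop$n_ab + per_pop$n_bb
  call_rate <- sum(called) / total_n
  rate_needed <- if (strict) strict_call_rate else min_call_rate

  reasons <- character(0)
  if (call_rate < rate_needed) reasons <- c(reasons, "LOW_CALL_RATE")

  pooled_m <- (2 * sum(per_pop$n_aa) + sum(per_pop$n_ab)) / (2 * sum(called))
  pooled_maf <- min(pooled_m, 1 - pooled_m)
  if (pooled_maf < min_maf) reasons <- c(reasons, "LOW_MAF_OVERALL")

  pop_m <- ifelse(called > 0, (2 * per_pop$n_aa + per_pop$n_ab) / (2 * called), 0)
  pop_maf <- pmin(pop_m, 1 - pop_m)
  keep <- pop_maf >= pop_min_maf
  list(
    included = length(reasons) == 0,
    reasons = reasons,
    call_rate = call_rate,
    pooled_maf = pooled_maf,
    analyze_pops = as.character(per_pop$population[keep]),
    dropped_pops = as.character(per_pop$population[!keep])
  )
}

#' Filter a long counts table
#'
#' Applies [variant_filter()] to every variant in a long counts table and
#' returns the surviving variant x population rows (populations failing the
#' population-level MAF rule removed).
#'
#' @param counts Long data.frame with `variant_id`, `population`, `n_aa`,
#'   `n_ab`, `n_bb` (and optionally `n_missing`).
#' @param total_n Cohort size (call-rate denominator).
#' @inheritParams variant_filter
#' @return A list with `counts` (the retained rows) and `decisions` (a
#'   data.frame of per-variant filter outcomes with columns `variant_id`,
#'   `included`, `reasons`, `call_rate`, `pooled_maf`).
#' @export
filter_variants <- function(counts, total_n,
                            min_call_rate = 0.80, min_maf = 0.01,
                            pop_min_maf = 0.001,
                            strict = FALSE, strict_call_rate = 0.98) {
  stopifnot(all(c("variant_id", "population") %in% names(counts)))
  pieces <- split(counts, counts$variant_id)
  dec <- lapply(pieces, function(v) {
    f <- variant_filter(v, total_n, min_call_rate, min_maf, pop_min_maf,
                        strict, strict_call_rate)
    keep <- if (f$included) v[v$population %in% f$analyze_pops, , drop = FALSE]
            else v[0, , drop = FALSE]
    list(keep = keep,
         row = data.frame(variant_id = v$variant_id[1],
                          included = f$included,
                          reasons = paste(f$reasons, collapse = ";"),
                          call_rate = f$call_rate,
                          pooled_maf = f$pooled_maf))
  })
  kept <- do.call(rbind, lapply(dec, `[[`, "keep"))
  rownames(kept) <- NULL
  decisions <- do.call(rbind, lapply(dec, `[[`, "row"))
  rownames(decisions) <- NULL
  list(counts = kept, decisions = decisions)
}

.check_counts <- function(n_aa, n_ab, n_bb) {
  for (v in list(n_aa, n_ab, n_bb)) {
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != round(v))) {
      stop("genotype counts must be non-negative integers")
    }
  }
  invisible(TRUE)
}
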