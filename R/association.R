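#' Compare a continuous feature between a departure group and controls
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. For groups of at most 20
#' observations each, and in the absence of ties, the exact null distribution
#' is used; otherwise the normal approximation with tie correction. Medians
#' and interquartile ranges are reported alongside, the summary convention
#' used for the group-comparison tables.
#'
#' @param group_values Numeric vector for the departure group.
#' @param control_values Numeric vector for the control group.
#' @param exact_max Per-group size at or below which the exact distribution
#'   is used (default 20).
#' @return A one-row data.frame: `test`, `statistic`, `p_value`,
#'   `group_n`, `group_median`, `group_iqr`, `control_n`, `control_median`,
#'   `control_iqr`.
#' @export
compare_continuous <- function(group_values, control_values, exact_max = 20) {
  if (length(group_values) == 0 || length(control_values) == 0) {
    stop("both groups must be non-empty")
  }
  exact <- length(group_values) <= exact_max &&
    length(control_values) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(group_values, control_values,
                       alternative = "two.sided",
                       exact = exact, correct = FALSE)
  )
  data.frame(
    test = "MANN_WHITNEY",
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    group_n = length(group_values),
    group_median = stats::median(group_values),
    group_iqr = stats::IQR(group_values),
    control_n = length(control_values),
    control_median = stats::median(control_values),
    control_iqr = stats::IQR(control_values)
  )
}

#' Compare a categorical feature between a departure group and controls
#'
#' Pearson chi-square without continuity correction on the 2x2 table when
#' every expected cell is at least `min_expected_for_chi2`; otherwise
#' Fisher's exact test (two-sided), the usual fallback for sparse tables.
#' A table with a zero margin carries no information about association and
#' returns p = 1 with a warning.
#'
#' @param tbl A 2x2 matrix of non-negative integer counts (rows: groups,
#'   columns: feature levels).
#' @param min_expected_for_chi2 Minimum expected cell count for the
#'   chi-square test (default 5).
#' @return A one-row data.frame: `test` (`"CHI2"` or `"FISHER"`),
#'   `statistic` (chi-square statistic, NA for Fisher), `p_value`.
#' @export
compare_categorical <- function(tbl, min_expected_for_chi2 = 5) {
  tbl <- as.matrix(tbl)
  stopifnot(all(dim(tbl) == c(2, 2)), all(tbl >= 0), all(tbl == round(tbl)))
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    warning("zero margin in 2x2 table; no association testable")
    return(data.frame(test = "CHI2", statistic = 0, p_value = 1))
  }
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  if (all(expected >= min_expected_for_chi2)) {
    ct <- stats::chisq.test(tbl, correct = FALSE)
    data.frame(test = "CHI2", statistic = unname(ct$statistic),
               p_value = ct$p.value)
  } else {
    ft <- stats::fisher.test(tbl, alternative = "two.sided")
    data.frame(test = "FISHER", statistic = NA_real_, p_value = ft$p.value)
  }
}

#' Test heterogeneity of departure counts across populations
#'
#' Pearson chi-square on the 2xK table of departure versus control counts by
#' population (K-1 degrees of freedom). A small p-value means the departures
#' are not distributed across populations in proportion to the control
#' variants — the signature of population-specific causes such as
#' stratification or inbreeding.
#'
#' @param departure_counts Named integer vector: departures per population.
#' @param control_counts Named integer vector over the same populations.
#' @return A one-row data.frame: `test`, `statistic`, `dof`, `p_value`.
#' @export
population_heterogeneity <- function(departure_counts, control_counts) {
  if (!setequal(names(departure_counts), names(control_counts)) ||
      is.null(names(departure_counts))) {
    stop("departure and control counts must be named over the same populations")
  }
  pops <- sort(names(departure_counts))
  if (length(pops) < 2) stop("need at least two populations")
  tbl <- rbind(departure = departure_counts[pops],
               control = control_counts[pops])
  ct <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  data.frame(test = "CHI2", statistic = unname(ct$statistic),
             dof = unname(ct$parameter), p_value = ct$p.value)
}

#' Build the group-comparison report
#'
#' Contrasts each departure class (LoH, GoH) against in-equilibrium control
#' distributions on the five explanatory features, plus the
#' heterogeneity-across-populations test. The unit of analysis is the
#' variant x population genotype distribution; variant-level features
#' (variant type, MAF-SD, CNV flags) are replicated across that variant's
#' population rows, which induces pseudo-replication — a deliberate property
#' of this design, documented in the methods vignette.
#'
#' Continuous features (missing fraction, MAF, MAF-SD) are compared by
#' Mann-Whitney test; categorical features (indel type, CNV loss/gain) by
#' chi-square with Fisher fallback. Missing fraction and MAF-SD are reported
#' on the percent scale (x100).
#'
#' @param results A data.frame of per variant x population rows holding
#'   `variant_id`, `population`, `classification` (from [hwe_analysis()])
#'   joined with the feature columns of [build_features()].
#' @return A data.frame with one row per feature per departure class:
#'   `feature`, `class`, summaries, `test`, `statistic`, `p_value`; plus
#'   `heterogeneity` rows. Classes with no members are skipped with a
#'   warning.
#' @export
association_report <- function(results) {
  need <- c("variant_id", "population", "classification", "variant_type",
            "missing_fraction", "maf_overall", "maf_sd",
            "cnv_loss", "cnv_gain")
  stopifnot(all(need %in% names(results)))
  ctl <- results[results$classification == "NONE", , drop = FALSE]
  if (nrow(ctl) == 0) stop("no in-equilibrium control distributions")

  continuous <- list(
    missing_genotypes_pct = function(d) 100 * d$missing_fraction,
    maf = function(d) d$maf_overall,
    maf_sd_pct = function(d) 100 * d$maf_sd
  )
  categorical <- list(
    indel_type = function(d) d$variant_type == "INDEL",
    cnv_loss = function(d) d$cnv_loss,
    cnv_gain = function(d) d$cnv_gain
  )

  out <- list()
  for (cls in c("LOH", "GOH")) {
    grp <- results[results$classification == cls, , drop = FALSE]
    if (nrow(grp) == 0) {
      warning("no variants in class ", cls, "; comparisons skipped")
      next
    }
    for (feat in names(continuous)) {
      gv <- continuous[[feat]](grp); cv <- continuous[[feat]](ctl)
      gv <- gv[!is.na(gv)]; cv <- cv[!is.na(cv)]
      cmp <- compare_continuous(gv, cv)
      out[[length(out) + 1]] <- cbind(
        data.frame(feature = feat, class = cls), cmp)
    }
    for (feat in names(categorical)) {
      gv <- categorical[[feat]](grp); cv <- categorical[[feat]](ctl)
      tbl <- rbind(group = c(sum(gv), sum(!gv)),
                   control = c(sum(cv), sum(!cv)))
      cmp <- compare_categorical(tbl)
      out[[length(out) + 1]] <- cbind(
        data.frame(feature = feat, class = cls,
                   group_n = nrow(grp),
                   group_count = sum(gv),
                   group_pct = 100 * mean(gv),
                   control_n = nrow(ctl),
                   control_count = sum(cv),
                   control_pct = 100 * mean(cv)),
        cmp)
    }
    het_dep <- table(factor(grp$population, levels = sort(unique(results$population))))
    het_ctl <- table(factor(ctl$population, levels = sort(unique(results$population))))
    het <- population_heterogeneity(
      stats::setNames(as.integer(het_dep), names(het_dep)),
      stats::setNames(as.integer(het_ctl), names(het_ctl))
    )
    out[[length(out) + 1]] <- cbind(
      data.frame(feature = "heterogeneity", class = cls), het)
  }
  if (length(out) == 0) {
    return(data.frame(feature = character(0), class = character(0),
                      p_value = numeric(0)))
  }
  cols <- unique(unlist(lapply(out, names)))
  filled <- lapply(out, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols]
  })
  res <- do.call(rbind, filled)
  rownames(res) <- NULL
  res
}
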