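# Mechanism generators. Each returns genotype counts for one variant in one
# cohort of n individuals; all randomness flows through the R RNG, so
# set.seed() upstream (or the seed argument) makes every draw reproducible.

.counts_row <- function(draw, n_missing = 0L) {
  data.frame(n_aa = draw[1], n_ab = draw[2], n_bb = draw[3],
             n_missing = as.integer(n_missing))
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Simulate genotype counts under Hardy-Weinberg equilibrium
#'
#' Multinomial draw of n genotypes with probabilities (p^2, 2p(1-p),
#' (1-p)^2). Degenerate p (0 or 1) yields monomorphic counts.
#'
#' @param n Number of individuals.
#' @param p Allele-A frequency.
#' @param missing_rate Probability an individual's genotype is missing
#'   (applied independently; missing individuals are removed from the
#'   called counts).
#' @param seed Optional seed applied before drawing; NULL uses the current
#'   RNG state.
#' @return One-row data.frame: `n_aa`, `n_ab`, `n_bb`, `n_missing`.
#' @export
sim_hwe <- function(n, p, missing_rate = 0, seed = NULL) {
  stopifnot(n > 0, p >= 0, p <= 1, missing_rate >= 0, missing_rate < 1)
  .with_seed(seed, {
    probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
    .apply_missing(stats::rmultinom(1, n, probs)[, 1], missing_rate)
  })
}

#' Simulate genotype counts under inbreeding
#'
#' Inbreeding with coefficient F shifts heterozygotes into homozygotes:
#' genotype probabilities (p^2 + Fp(1-p), 2p(1-p)(1-F), (1-p)^2 + Fp(1-p)).
#' The expected heterozygote O/E ratio is 1 - F. F = 0 reduces to
#' [sim_hwe()].
#'
#' @inheritParams sim_hwe
#' @param F_coef Inbreeding coefficient in \[0, 1\].
#' @return One-row counts data.frame.
#' @export
sim_inbreeding <- function(n, p, F_coef, missing_rate = 0, seed = NULL) {
  stopifnot(F_coef >= 0, F_coef <= 1)
  .with_seed(seed, {
    q <- 1 - p
    probs <- c(p^2 + F_coef * p * q,
               2 * p * q * (1 - F_coef),
               q^2 + F_coef * p * q)
    .apply_missing(stats::rmultinom(1, n, probs)[, 1], missing_rate)
  })
}

#' Simulate a stratified (Wahlund) genotype distribution
#'
#' Pools K subpopulations, each in internal Hardy-Weinberg equilibrium at
#' its own allele frequency. Pooling depresses heterozygosity: the expected
#' O/E ratio is the Wahlund ratio sum(w_k 2 p_k q_k) / (2 p-bar q-bar).
#'
#' @inheritParams sim_hwe
#' @param weights Subpopulation mixture weights (must sum to 1).
#' @param freqs Subpopulation allele-A frequencies (same length).
#' @return One-row counts data.frame (pooled over subpopulations).
#' @export
sim_stratified <- function(n, weights, freqs, missing_rate = 0, seed = NULL) {
  stopifnot(length(weights) == length(freqs), length(weights) >= 2,
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0),
            all(freqs >= 0), all(freqs <= 1))
  .with_seed(seed, {
    sizes <- stats::rmultinom(1, n, weights)[, 1]
    draw <- c(0L, 0L, 0L)
    for (k in seq_along(sizes)) {
      if (sizes[k] == 0) next
      pk <- freqs[k]
      probs <- c(pk^2, 2 * pk * (1 - pk), (1 - pk)^2)
      draw <- draw + stats::rmultinom(1, sizes[k], probs)[, 1]
    }
    .apply_missing(draw, missing_rate)
  })
}

#' Simulate a SNP inside a deletion polymorphism
#'
#' Individuals carry 0, 1 or 2 copies of a deletion allele at frequency `d`
#' (independent of the SNP allele). Heterozygous-deletion carriers are
#' hemizygous and are CALLED homozygous for their remaining allele.
#' Homozygous-deletion individuals either fail genotyping
#' (`delmode = "MISSING"`, exome-database-like) or are imputed a homozygous
#' call at frequency p (`delmode = "FORCED_HOM"`, emulating datasets that
#' report complete genotyping even inside common deletions). Expected O/E:
#' (1-d)/(1+d) for MISSING, (1-d)^2 for FORCED_HOM; d = 0 reduces to
#' [sim_hwe()].
#'
#' @inheritParams sim_hwe
#' @param d Deletion allele frequency in \[0, 1).
#' @param delmode `"MISSING"` or `"FORCED_HOM"`.
#' @return One-row counts data.frame.
#' @export
sim_deletion_overlay <- function(n, p, d, delmode = c("MISSING", "FORCED_HOM"),
                                 missing_rate = 0, seed = NULL) {
  delmode <- match.arg(delmode)
  stopifnot(d >= 0, d < 1)
  .with_seed(seed, {
    ndel <- stats::rmultinom(1, n, c((1 - d)^2, 2 * d * (1 - d), d^2))[, 1]
    # intact individuals: ordinary HWE draw
    draw <- stats::rmultinom(1, ndel[1],
                             c(p^2, 2 * p * (1 - p), (1 - p)^2))[, 1]
    # hemizygous: one chromosome left, called homozygous for its allele
    n_a <- stats::rbinom(1, ndel[2], p)
    draw <- draw + c(n_a, 0L, ndel[2] - n_a)
    miss <- 0L
    if (delmode == "MISSING") {
      miss <- ndel[3]
    } else {
      n_a2 <- stats::rbinom(1, ndel[3], p)
      draw <- draw + c(n_a2, 0L, ndel[3] - n_a2)
    }
    out <- .apply_missing(draw, missing_rate)
    out$n_missing <- out$n_missing + miss
    out
  })
}

#' Simulate a paralog-collapse (cross-hybridization) locus
#'
#' Emulates two diverged genomic copies read as one locus: a fraction of
#' individuals is called heterozygous regardless of true genotype
#' (constitutive heterozygosity), the remainder drawn in Hardy-Weinberg
#' equilibrium at p = 0.5. With `het_fraction = 1` the counts are (0, n, 0),
#' the apparent allele frequency is 0.5 and the O/E ratio is 2.
#'
#' @inheritParams sim_hwe
#' @param het_fraction Probability an individual is constitutively
#'   heterozygous, in (0, 1\].
#' @return One-row counts data.frame.
#' @export
sim_paralog_collapse <- function(n, het_fraction = 1.0, missing_rate = 0,
                                 seed = NULL) {
  stopifnot(het_fraction > 0, het_fraction <= 1)
  .with_seed(seed, {
    n_forced <- stats::rbinom(1, n, het_fraction)
    draw <- c(0L, n_forced, 0L)
    if (n - n_forced > 0) {
      draw <- draw + stats::rmultinom(1, n - n_forced,
                                      c(0.25, 0.5, 0.25))[, 1]
    }
    .apply_missing(draw, missing_rate)
  })
}

#' Simulate allelic dropout on a Hardy-Weinberg locus
#'
#' Each allele of each individual independently fails to amplify with rate
#' `e`. A heterozygote losing one allele is called homozygous for the
#' survivor; an individual losing both alleles is missing. A homozygote
#' losing one allele still presents a single band and keeps its (correct)
#' homozygous call. Per-genotype call probabilities are therefore exactly
#' enumerable, which the test-suite oracle exploits.
#'
#' @inheritParams sim_hwe
#' @param e Per-allele dropout rate in \[0, 1\].
#' @return One-row counts data.frame.
#' @export
sim_allelic_dropout <- function(n, p, e, seed = NULL) {
  stopifnot(e >= 0, e <= 1)
  .with_seed(seed, {
    q <- 1 - p
    true_probs <- c(p^2, 2 * p * q, q^2)
    # call distribution given true genotype: columns AA, AB, BB, missing
    call_given <- rbind(
      AA = c(1 - e^2, 0, 0, e^2),
      AB = c(e * (1 - e), (1 - e)^2, e * (1 - e), e^2),
      BB = c(0, 0, 1 - e^2, e^2)
    )
    probs <- as.numeric(true_probs %*% call_given)
    draw <- stats::rmultinom(1, n, probs)[, 1]
    .counts_row(draw[1:3], draw[4])
  })
}

.apply_missing <- function(draw, missing_rate) {
  if (missing_rate > 0) {
    lost <- sapply(draw, function(x) stats::rbinom(1, x, missing_rate))
    .counts_row(draw - lost, sum(lost))
  } else {
    .counts_row(draw, 0L)
  }
}

#' Simulate a genomic region with embedded departure mechanisms
#'
#' Places variants uniformly over a region, draws a neutral Hardy-Weinberg
#' background, and overrides variants falling inside user-specified
#' mechanism intervals (a deletion polymorphism block and/or a
#' paralog-collapse segment) with the corresponding generator — the geometry
#' of a local Manhattan plot with an LoH block and a GoH peak. Individual
#' genotypes are drawn explicitly so a multi-sample VCF consistent with the
#' counts can be written, alongside a ground-truth interval BED.
#'
#' @param n Number of individuals.
#' @param n_variants Number of variants to place.
#' @param region_start,region_end 1-based inclusive region bounds.
#' @param chrom Chromosome name for all variants.
#' @param layout Optional data.frame of mechanism intervals with columns
#'   `start`, `end` (1-based inclusive, non-overlapping), `mechanism`
#'   (`"DELETION"` or `"PARALOG"`) and `param` (deletion allele frequency d,
#'   or constitutive-heterozygote fraction).
#' @param p_range Background allele-A frequencies drawn uniformly from this
#'   range.
#' @param indel_fraction Fraction of variants written with indel-type
#'   alleles (REF "AT"/ALT "A"); the rest are SNPs.
#' @param seed Optional seed.
#' @return A list: `counts` (long per-variant counts, one population
#'   `"SIM"`), `truth` (per-variant mechanism and parameters), `genotypes`
#'   (variants x samples matrix of "0/0", "0/1", "1/1", "./."), `layout`.
#' @export
sim_region <- function(n, n_variants, region_start = 1,
                       region_end = 8e6, chrom = "17",
                       layout = NULL, p_range = c(0.1, 0.9),
                       indel_fraction = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(layout) && nrow(layout) > 1) {
    o <- order(layout$start)
    if (any(layout$start[o][-1] <= layout$end[o][-nrow(layout)])) {
      stop("mechanism intervals must not overlap")
    }
  }
  pos <- sort(sample(seq.int(region_start, region_end), n_variants))
  mech <- rep("HWE", n_variants)
  param <- rep(NA_real_, n_variants)
  if (!is.null(layout)) {
    for (i in seq_len(nrow(layout))) {
      inside <- pos >= layout$start[i] & pos <= layout$end[i]
      mech[inside] <- layout$mechanism[i]
      param[inside] <- layout$param[i]
    }
  }
  p <- stats::runif(n_variants, p_range[1], p_range[2])
  is_indel <- stats::runif(n_variants) < indel_fraction

  gt_levels <- c("0/0", "0/1", "1/1", "./.")
  geno <- matrix(NA_character_, n_variants, n,
                 dimnames = list(NULL, sprintf("S%04d", seq_len(n))))
  rows <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    g <- switch(mech[i],
      HWE = sample(gt_levels[1:3], n, TRUE,
                   prob = c(p[i]^2, 2 * p[i] * (1 - p[i]), (1 - p[i])^2)),
      DELETION = .region_deletion_genotypes(n, p[i], param[i]),
      PARALOG = {
        forced <- stats::runif(n) < param[i]
        g0 <- sample(gt_levels[1:3], n, TRUE, prob = c(0.25, 0.5, 0.25))
        g0[forced] <- "0/1"
        g0
      },
      stop("unknown mechanism: ", mech[i]))
    geno[i, ] <- g
    tab <- table(factor(g, levels = gt_levels))
    rows[[i]] <- data.frame(
      variant_id = sprintf("sim%04d", i),
      chrom = chrom, pos = pos[i],
      ref = if (is_indel[i]) "AT" else "A",
      alt = if (is_indel[i]) "A" else "G",
      population = "SIM",
      n_aa = as.integer(tab[1]), n_ab = as.integer(tab[2]),
      n_bb = as.integer(tab[3]), n_missing = as.integer(tab[4])
    )
  }
  counts <- do.call(rbind, rows)
  truth <- data.frame(
    variant_id = counts$variant_id, chrom = chrom, pos = pos,
    mechanism = mech, param = param, p_true = p,
    variant_type = ifelse(is_indel, "INDEL", "SNP")
  )
  list(counts = counts, truth = truth, genotypes = geno, layout = layout)
}

# per-individual genotypes under the deletion overlay (MISSING delmode)
.region_deletion_genotypes <- function(n, p, d) {
  ndel <- sample(0:2, n, TRUE, prob = c((1 - d)^2, 2 * d * (1 - d), d^2))
  g <- character(n)
  intact <- ndel == 0
  g[intact] <- sample(c("0/0", "0/1", "1/1"), sum(intact), TRUE,
                      prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
  hemi <- ndel == 1
  g[hemi] <- ifelse(stats::runif(sum(hemi)) < p, "0/0", "1/1")
  g[ndel == 2] <- "./."
  g
}
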