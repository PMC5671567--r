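# Independent oracles used by the test suite. Each recomputes a quantity
# from first principles by a different arithmetic path than the package.

# Chi-square HWE statistic by explicit per-allele tallying and looping.
oracle_hwe_chi2 <- function(n_aa, n_ab, n_bb) {
  alleles <- c(rep("A", 2 * n_aa + n_ab), rep("B", n_ab + 2 * n_bb))
  m <- sum(alleles == "A") / length(alleles)
  n <- n_aa + n_ab + n_bb
  expected <- c(AA = m * m * n, AB = 2 * m * (1 - m) * n,
                BB = (1 - m) * (1 - m) * n)
  observed <- c(AA = n_aa, AB = n_ab, BB = n_bb)
  chi2 <- 0
  for (g in names(expected)) {
    if (expected[[g]] > 0) {
      chi2 <- chi2 + (observed[[g]] - expected[[g]])^2 / expected[[g]]
    }
  }
  chi2
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- n1 * length(y) / 2
  obs_dev <- abs(u_stat(x, y) - mu)
  combos <- utils::combn(length(pooled), n1)
  devs <- apply(combos, 2, function(idx) {
    abs(u_stat(pooled[idx], pooled[-idx]) - mu)
  })
  mean(devs >= obs_dev - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more probable than observed.
oracle_fisher_p <- function(tbl) {
  r1 <- sum(tbl[1, ]); c1 <- sum(tbl[, 1]); n <- sum(tbl)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_vals, function(a) {
    stats::dhyper(a, c1, n - c1, r1)
  }, numeric(1))
  obs <- stats::dhyper(tbl[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Expected genotype-call distribution under per-allele dropout, by
# enumerating the call outcome of every (true genotype, dropout pattern).
oracle_dropout_call_probs <- function(p, e) {
  q <- 1 - p
  probs <- c(AA = 0, AB = 0, BB = 0, MISS = 0)
  for (g in c("AA", "AB", "BB")) {
    pg <- switch(g, AA = p^2, AB = 2 * p * q, BB = q^2)
    for (fail1 in c(FALSE, TRUE)) for (fail2 in c(FALSE, TRUE)) {
      pf <- (if (fail1) e else 1 - e) * (if (fail2) e else 1 - e)
      surviving <- c(substr(g, 1, 1), substr(g, 2, 2))[!c(fail1, fail2)]
      call <- if (length(surviving) == 0) "MISS"
        else if (length(unique(surviving)) == 2) "AB"
        else paste0(surviving[1], surviving[1])
      probs[call] <- probs[call] + pg * pf
    }
  }
  probs
}

# O/E heterozygote ratio implied by a genotype-call probability vector
# (AA, AB, BB, MISS), at infinite sample size.
expected_oe_from_probs <- function(pr) {
  called <- pr[1] + pr[2] + pr[3]
  m <- (2 * pr[1] + pr[2]) / (2 * called)
  pr[2] / (called * 2 * m * (1 - m))
}

# Counts table in exact Hardy-Weinberg proportions (chi2 identically 0).
exact_hw_counts <- function(n, m) {
  data.frame(n_aa = n * m^2, n_ab = 2 * n * m * (1 - m),
             n_bb = n * (1 - m)^2)
}

# Print convention of the reference table: p-values >= 0.01 to 2 decimals,
# smaller ones to 2 significant figures, underflow as 0.
print_p <- function(p) {
  ifelse(p < 1e-300, 0, ifelse(p >= 0.01, round(p, 2), signif(p, 2)))
}
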