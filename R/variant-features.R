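#' Classify a variant as SNP, indel or other
#'
#' SNPs have single-base REF and ALT; indels have REF and ALT of different
#' length. Equal-length multi-base substitutions (MNPs) fit neither class of
#' the SNP-vs-indel contrast and are returned as `"OTHER"` rather than
#' silently binned.
#'
#' @param ref,alt Allele strings over A/C/G/T (vectors recycled).
#' @return Character vector over `c("SNP", "INDEL", "OTHER")`.
#' @examples
#' classify_variant_type(c("A", "A", "AT"), c("T", "AT", "GC"))
#' @export
classify_variant_type <- function(ref, alt) {
  k <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), k); alt <- rep_len(toupper(alt), k)
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("invalid allele string (symbolic, empty or non-ACGT): ",
         paste(unique(c(ref[bad], alt[bad])), collapse = ", "))
  }
  type <- rep("OTHER", k)
  type[nchar(ref) == 1 & nchar(alt) == 1] <- "SNP"
  type[nchar(ref) != nchar(alt)] <- "INDEL"
  type
}

#' Fraction of the cohort without a genotype call
#'
#' Number of individuals not genotyped for the variant divided by the total
#' cohort size: `(total_n - sum of called genotypes) / total_n`. The
#' complement of the call rate.
#'
#' @param n_called_total Total called genotypes for the variant, summed over
#'   populations.
#' @param total_n Total cohort size.
#' @return Missing fraction in \[0, 1\].
#' @examples
#' missing_fraction(60584, 60706)  # 0.0020
#' @export
missing_fraction <- function(n_called_total, total_n) {
  stopifnot(total_n > 0)
  if (any(n_called_total > total_n)) {
    stop("called genotypes exceed the cohort size")
  }
  (total_n - n_called_total) / total_n
}

#' Cross-population allele-frequency standard deviation (MAF-SD)
#'
#' The population standard deviation (divisor N, not N-1) of the UNFOLDED
#' per-population allele-A frequencies, a surrogate for population
#' substructure: variants whose frequency varies strongly between
#' super-populations are more likely to be stratified within them too.
#' Folding the frequencies or using the sample (N-1) divisor does not
#' reproduce the reference values this convention was validated against
#' (see the methods vignette).
#'
#' @param freqs Named numeric vector of per-population allele-A frequencies.
#' @param included_pops Optional character vector restricting which
#'   populations enter (default: all).
#' @return The divisor-N standard deviation, or NA if fewer than two
#'   populations are included.
#' @examples
#' maf_sd(c(AFR = 0.83, EAS = 0.45, FIN = 0.35,
#'          NFE = 0.32, AMR = 0.15, SAS = 0.71))  # 0.23
#' @export
maf_sd <- function(freqs, included_pops = NULL) {
  if (!is.null(included_pops)) {
    freqs <- freqs[names(freqs) %in% included_pops]
  }
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) < 2) return(NA_real_)
  sqrt(mean((freqs - mean(freqs))^2))
}

#' Read a CNV interval file (BED dialect)
#'
#' Reads copy-number polymorphism intervals from a BED-like TSV: chrom,
#' start, end (0-based half-open), a 4th column giving the CNV kind
#' (`loss`/deletion or `gain`/duplication) and an optional 5th column with
#' the CNV allele frequency. Lines starting with `#` are skipped.
#'
#' @param path Path to the interval file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `kind`
#'   (`"LOSS"`/`"GAIN"`) and `frequency` (NA when absent).
#' @export
read_cnv_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("CNV BED needs chrom/start/end/kind columns")
  out <- data.frame(
    chrom = normalize_chrom(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    kind = toupper(raw[[4]]),
    frequency = if (ncol(raw) >= 5) as.numeric(raw[[5]]) else NA_real_
  )
  if (!all(out$kind %in% c("LOSS", "GAIN"))) {
    stop("CNV kind column must be loss or gain")
  }
  if (any(out$start >= out$end)) stop("CNV intervals must have start < end")
  out
}

#' Flag variants falling inside CNV loss/gain intervals
#'
#' Point-in-interval annotation: a variant is flagged when its anchor
#' position (1-based VCF POS, converted to 0-based) lies within at least one
#' LOSS (resp. GAIN) interval. Chromosome names are normalized ("chr17" and
#' "17" match). Overlap is computed with GenomicRanges.
#'
#' @param chrom,pos Vectors of variant chromosome names and 1-based
#'   positions.
#' @param intervals CNV interval data.frame as from [read_cnv_bed()].
#' @return A data.frame with logical columns `cnv_loss` and `cnv_gain`.
#' @export
annotate_cnv_overlap <- function(chrom, pos, intervals) {
  k <- max(length(chrom), length(pos))
  chrom <- rep_len(normalize_chrom(chrom), k)
  pos <- rep_len(as.numeric(pos), k)
  out <- data.frame(cnv_loss = logical(k), cnv_gain = logical(k))
  if (is.null(intervals) || nrow(intervals) == 0) return(out)
  # variant anchor: 1-bp range at POS; BED half-open [start, end) in 0-based
  # is [start + 1, end] in 1-based closed coordinates
  vr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  ir <- GenomicRanges::GRanges(
    normalize_chrom(intervals$chrom),
    IRanges::IRanges(intervals$start + 1, intervals$end)
  )
  hits <- GenomicRanges::findOverlaps(vr, ir)
  q <- S4Vectors::queryHits(hits)
  kind <- intervals$kind[S4Vectors::subjectHits(hits)]
  out$cnv_loss[unique(q[kind == "LOSS"])] <- TRUE
  out$cnv_gain[unique(q[kind == "GAIN"])] <- TRUE
  out
}

#' Assemble the five explanatory features for each variant
#'
#' Computes, per variant, the five features used to characterize the causes
#' of Hardy-Weinberg departure: missing-genotype fraction, variant type
#' (SNP vs indel), overall folded minor allele frequency, cross-population
#' allele-frequency standard deviation (MAF-SD), and CNV loss/gain overlap.
#'
#' @param counts Long counts data.frame with `variant_id`, `population`,
#'   `chrom`, `pos`, `ref`, `alt`, `n_aa`, `n_ab`, `n_bb` columns (rows
#'   restricted to the populations retained for analysis).
#' @param total_n Total cohort size (missing-fraction denominator).
#' @param cnv_intervals Optional CNV interval table ([read_cnv_bed()]).
#' @return One row per variant: `variant_id`, `chrom`, `pos`,
#'   `variant_type`, `missing_fraction`, `maf_overall` (folded),
#'   `maf_sd`, `cnv_loss`, `cnv_gain`.
#' @export
build_features <- function(counts, total_n, cnv_intervals = NULL) {
  need <- c("variant_id", "population", "chrom", "pos", "ref", "alt",
            "n_aa", "n_ab", "n_bb")
  stopifnot(all(need %in% names(counts)))
  pieces <- split(counts, counts$variant_id)
  rows <- lapply(pieces, function(v) {
    called <- v$n_aa + v$n_ab + v$n_bb
    pooled_m <- (2 * sum(v$n_aa) + sum(v$n_ab)) / (2 * sum(called))
    freqs <- stats::setNames(
      ifelse(called > 0, (2 * v$n_aa + v$n_ab) / (2 * called), NA_real_),
      as.character(v$population)
    )
    data.frame(
      variant_id = v$variant_id[1],
      chrom = v$chrom[1], pos = v$pos[1],
      variant_type = classify_variant_type(v$ref[1], v$alt[1]),
      missing_fraction = missing_fraction(sum(called), total_n),
      maf_overall = min(pooled_m, 1 - pooled_m),
      maf_sd = maf_sd(freqs)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cnv <- annotate_cnv_overlap(out$chrom, out$pos, cnv_intervals)
  out$cnv_loss <- cnv$cnv_loss
  out$cnv_gain <- cnv$cnv_gain
  out[order(out$variant_id), , drop = FALSE]
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (case-insensitive) so "chr17" and "17"
#' join.
#'
#' @param chrom Character vector of chromosome names.
#' @return Normalized character vector.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}
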