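#' Scan a genomic region for Hardy-Weinberg departures
#'
#' Runs the HWE departure test across one population's variants in a
#' region and emits a plot-ready track: per-variant -log10 p (capped so
#' that underflowed p-values remain plottable), heterozygote O/E ratio and
#' directional classification, sorted by position. Variants with folded
#' MAF at or below `min_maf` are dropped first.
#'
#' @param variants Long counts data.frame for one population with columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `n_aa`, `n_ab`, `n_bb`
#'   (optionally `n_missing`).
#' @param region Optional `c(start, end)` (1-based inclusive) restricting
#'   the scan; NULL scans everything supplied.
#' @param alpha Departure threshold (default 1e-5).
#' @param min_maf Folded MAF must exceed this to enter the scan
#'   (default 0.01).
#' @param dof Chi-square degrees of freedom (default 2).
#' @param log10p_cap Cap for -log10 p (default 320, just inside double
#'   underflow).
#' @return A data.frame track: `chrom`, `pos`, `variant_id`,
#'   `variant_type`, `minus_log10_p`, `oe_het_ratio`, `classification`,
#'   plus the test columns. Attribute `missingness_usable` is FALSE when
#'   every variant reports zero missing genotypes (datasets reporting
#'   complete genotyping carry no missingness signal).
#' @export
scan_region <- function(variants, region = NULL, alpha = 1e-5,
                        min_maf = 0.01, dof = 2, log10p_cap = 320) {
  need <- c("variant_id", "chrom", "pos", "ref", "alt",
            "n_aa", "n_ab", "n_bb")
  stopifnot(all(need %in% names(variants)))
  v <- variants
  if (!is.null(region)) {
    v <- v[v$pos >= region[1] & v$pos <= region[2], , drop = FALSE]
  }
  if (nrow(v) == 0) {
    return(structure(v, missingness_usable = FALSE))
  }
  called <- v$n_aa + v$n_ab + v$n_bb
  m <- ifelse(called > 0, (2 * v$n_aa + v$n_ab) / (2 * called), 0)
  v <- v[pmin(m, 1 - m) > min_maf, , drop = FALSE]
  res <- hwe_analysis(v, alpha = alpha, dof = dof)
  res$variant_type <- classify_variant_type(res$ref, res$alt)
  res$minus_log10_p <- pmin(-log10(pmax(res$p_hwe, 10^(-log10p_cap - 1))),
                            log10p_cap)
  res$oe_het_ratio <- res$oe_ratio
  res <- res[order(normalize_chrom(res$chrom), res$pos), , drop = FALSE]
  rownames(res) <- NULL
  miss <- if ("n_missing" %in% names(res)) res$n_missing else 0
  structure(res, missingness_usable = any(miss > 0))
}

#' Detect clusters of Hardy-Weinberg-departing variants
#'
#' Greedy positional clustering of the significant variants in a scan
#' track: consecutive significant variants closer than `window_bp` are
#' merged into one cluster; clusters with at least `min_cluster_size`
#' significant members are reported with their departure direction. With
#' `direction_pure = TRUE` only clusters whose significant members share
#' one direction are returned (deletion LoH blocks and paralog GoH peaks
#' are both direction-pure); otherwise mixed clusters are reported as
#' `"MIXED"`.
#'
#' @param track A [scan_region()] track.
#' @param window_bp Maximum gap between consecutive significant variants in
#'   one cluster (default 10000).
#' @param min_cluster_size Minimum significant variants per cluster
#'   (default 5).
#' @param direction_pure Keep only single-direction clusters (default TRUE).
#' @return A data.frame of cluster calls: `chrom`, `start`, `end` (1-based
#'   inclusive span of the clustered variants), `n_variants` (track
#'   variants inside the span), `n_significant`, `direction`.
#' @export
detect_clusters <- function(track, window_bp = 10000, min_cluster_size = 5,
                            direction_pure = TRUE) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_variants = integer(0),
                      n_significant = integer(0), direction = character(0))
  sig <- track[track$classification %in% c("LOH", "GOH"), , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > window_bp))
    for (g in unique(grp)) {
      members <- s[grp == g, , drop = FALSE]
      if (nrow(members) < min_cluster_size) next
      dirs <- unique(members$classification)
      direction <- if (length(dirs) == 1) dirs else "MIXED"
      if (direction_pure && direction == "MIXED") next
      span <- range(members$pos)
      inside <- track$chrom == ch & track$pos >= span[1] &
        track$pos <= span[2]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = span[1], end = span[2],
        n_variants = sum(inside),
        n_significant = nrow(members),
        direction = direction
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize departure inside and outside an interval
#'
#' Counts and medians contrasting the variants inside a genomic interval
#' (for instance a deletion polymorphism) with the rest of the track:
#' inside a common deletion every variant is expected to depart with loss
#' of heterozygosity, while the background O/E ratio sits near 1.
#'
#' @param track A [scan_region()] track.
#' @param start,end Interval bounds, 1-based inclusive.
#' @param chrom Optional chromosome restriction (default: track's single
#'   chromosome).
#' @return A one-row data.frame: `n_inside`, `n_significant_inside`,
#'   `n_loh_inside`, `n_goh_inside`, `median_oe_inside`,
#'   `median_oe_outside` (NA where empty).
#' @export
interval_departure_summary <- function(track, start, end, chrom = NULL) {
  if (!is.null(chrom)) {
    track <- track[normalize_chrom(track$chrom) == normalize_chrom(chrom), ,
                   drop = FALSE]
  }
  inside <- track$pos >= start & track$pos <= end
  med <- function(x) if (length(x) == 0) NA_real_ else stats::median(x)
  data.frame(
    n_inside = sum(inside),
    n_significant_inside =
      sum(track$classification[inside] %in% c("LOH", "GOH")),
    n_loh_inside = sum(track$classification[inside] == "LOH"),
    n_goh_inside = sum(track$classification[inside] == "GOH"),
    median_oe_inside = med(track$oe_het_ratio[inside]),
    median_oe_outside = med(track$oe_het_ratio[!inside])
  )
}

#' Departure rate in indels versus SNPs
#'
#' Cross-tabulates variant type against departure significance over a scan
#' track and tests the association ([compare_categorical()]): indel calls
#' are error-prone and depart from equilibrium more often than true SNPs.
#'
#' @param track A [scan_region()] track containing both types.
#' @return A list: `table` (2x2 counts, rows INDEL/SNP, columns
#'   significant/not), `indel_rate`, `snp_rate`, `comparison` (test row),
#'   or NULL with a warning when only one type is present.
#' @export
indel_vs_snp_departure_rate <- function(track) {
  t2 <- track[track$variant_type %in% c("SNP", "INDEL"), , drop = FALSE]
  if (length(unique(t2$variant_type)) < 2) {
    warning("track contains a single variant type; comparison skipped")
    return(NULL)
  }
  sig <- t2$classification %in% c("LOH", "GOH")
  tbl <- rbind(
    INDEL = c(sum(sig & t2$variant_type == "INDEL"),
              sum(!sig & t2$variant_type == "INDEL")),
    SNP = c(sum(sig & t2$variant_type == "SNP"),
            sum(!sig & t2$variant_type == "SNP"))
  )
  colnames(tbl) <- c("significant", "not_significant")
  list(
    table = tbl,
    indel_rate = tbl[1, 1] / sum(tbl[1, ]),
    snp_rate = tbl[2, 1] / sum(tbl[2, ]),
    comparison = compare_categorical(tbl)
  )
}

#' Write a scan track as TSV
#'
#' @param track A [scan_region()] track.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  cols <- c("chrom", "pos", "variant_id", "variant_type", "minus_log10_p",
            "oe_het_ratio", "classification")
  utils::write.table(track[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write cluster calls as BED
#'
#' 0-based half-open intervals with the direction in the name column and
#' the significant-variant count as score.
#'
#' @param clusters A [detect_clusters()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(clusters, path) {
  bed <- data.frame(
    chrom = clusters$chrom,
    start = clusters$start - 1,
    end = clusters$end,
    name = clusters$direction,
    score = clusters$n_significant
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
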