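# Readers/writers for the genotype-counts TSV dialect, multi-sample VCFs,
# and the end-to-end pipeline driver.

.counts_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "population",
                  "n_aa", "n_ab", "n_bb", "n_missing")

#' Read a genotype-counts table
#'
#' Reads the long TSV dialect used throughout the package: one row per
#' variant x population with columns `variant_id`, `chrom`, `pos`, `ref`,
#' `alt`, `population`, `n_aa`, `n_ab`, `n_bb`, `n_missing`. The header is
#' required; lines starting with `#` are comments. Counts are parsed
#' strictly as non-negative integers (thousands separators and decimals are
#' rejected) and duplicate variant x population rows are an error. The
#' allele-A convention (which allele the AA column counts) is whatever the
#' producing file states; for VCF-derived tables A is the REF allele.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame in column order
#'   `variant_id, chrom, pos, ref, alt, population, n_aa, n_ab, n_bb,
#'   n_missing`.
#' @export
read_counts_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) < 2) stop("counts table needs a header and >= 1 row")
  tab <- utils::read.table(text = lines[keep], sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           check.names = FALSE)
  missing_cols <- setdiff(.counts_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("counts table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, .counts_cols]
  int_cols <- c("pos", "n_aa", "n_ab", "n_bb", "n_missing")
  for (cc in int_cols) {
    bad <- !grepl("^[0-9]+$", tab[[cc]])
    if (any(bad)) {
      stop("malformed integer in column '", cc, "' at line ",
           lineno[-1][which(bad)[1]], ": '", tab[[cc]][bad][1], "'")
    }
    tab[[cc]] <- as.integer(tab[[cc]])
  }
  dup <- duplicated(tab[, c("variant_id", "population")])
  if (any(dup)) {
    stop("duplicate variant x population row: ",
         tab$variant_id[dup][1], " / ", tab$population[dup][1])
  }
  tab
}

#' Write a genotype-counts table
#'
#' @param counts Counts data.frame ([read_counts_table()] layout).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  utils::write.table(counts[, intersect(.counts_cols, names(counts))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count genotypes per population from a multi-sample VCF
#'
#' Reads a VCF (via vcfR), restricts to biallelic non-symbolic records,
#' and tallies per-population genotype counts from the GT field. Allele A
#' is the REF allele. Phased and unphased separators are equivalent;
#' half-calls and missing GTs count as missing. Multi-allelic and symbolic
#' records are skipped and tallied in the `skipped` attribute. Samples not
#' in the population map are excluded with a warning.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param sample_to_population Named character vector mapping sample IDs to
#'   population labels.
#' @param region Optional `c(start, end)` positional filter (1-based,
#'   applied after reading).
#' @return A counts data.frame ([read_counts_table()] layout), with
#'   attribute `skipped` = number of non-biallelic records dropped.
#' @export
read_vcf_counts <- function(path, sample_to_population, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF has no genotype columns")
  samples <- colnames(gt)[-1]
  unknown <- setdiff(samples, names(sample_to_population))
  if (length(unknown) > 0) {
    warning(length(unknown), " VCF sample(s) not in the population map; excluded")
  }
  samples <- intersect(samples, names(sample_to_population))
  if (length(samples) == 0) stop("no VCF samples covered by the population map")

  biallelic <- !grepl(",", fix$ALT) & !grepl("[<>]", fix$ALT) &
    !grepl("[<>]", fix$REF) & !is.na(fix$ALT)
  skipped <- sum(!biallelic)
  fix <- fix[biallelic, , drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]
  pos <- as.integer(fix$POS)
  if (!is.null(region)) {
    inr <- pos >= region[1] & pos <= region[2]
    fix <- fix[inr, , drop = FALSE]; gt <- gt[inr, , drop = FALSE]
    pos <- pos[inr]
  }
  if (nrow(fix) == 0) {
    out <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), population = character(0),
                      n_aa = integer(0), n_ab = integer(0),
                      n_bb = integer(0), n_missing = integer(0))
    return(structure(out, skipped = skipped))
  }

  gt_only <- sub(":.*$", "", gt[, samples, drop = FALSE])
  gt_only <- gsub("|", "/", gt_only, fixed = TRUE)
  cat_mat <- matrix("MISS", nrow(gt_only), ncol(gt_only))
  cat_mat[gt_only == "0/0"] <- "AA"
  cat_mat[gt_only %in% c("0/1", "1/0")] <- "AB"
  cat_mat[gt_only == "1/1"] <- "BB"

  pops <- sample_to_population[samples]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(normalize_chrom(fix$CHROM), ":", pos), fix$ID)
  rows <- list()
  for (pp in sort(unique(pops))) {
    sel <- pops == pp
    sub <- cat_mat[, sel, drop = FALSE]
    rows[[pp]] <- data.frame(
      variant_id = ids,
      chrom = normalize_chrom(fix$CHROM), pos = pos,
      ref = fix$REF, alt = fix$ALT,
      population = pp,
      n_aa = rowSums(sub == "AA"),
      n_ab = rowSums(sub == "AB"),
      n_bb = rowSums(sub == "BB"),
      n_missing = rowSums(sub == "MISS")
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out[order(out$variant_id, out$population), , drop = FALSE],
            skipped = skipped)
}

#' Write a simulated region as a GT-only VCF 4.2
#'
#' Serializes a [sim_region()] result as an uncompressed multi-sample VCF
#' with a GT-only FORMAT, byte-stable given the same simulation.
#'
#' @param sim A [sim_region()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_region_vcf <- function(sim, path) {
  counts <- sim$counts
  geno <- sim$genotypes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hweqc.sim_region",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(geno)), collapse = "\t")
  ), con)
  body <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(counts$chrom[i], counts$pos[i], counts$variant_id[i],
            counts$ref[i], counts$alt[i], ".", "PASS", ".", "GT",
            geno[i, ]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a simulated region's mechanism layout as a truth BED
#'
#' @param sim A [sim_region()] result with a non-NULL layout.
#' @param path Output file.
#' @param chrom Chromosome name (default: the simulated one).
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(sim, path, chrom = NULL) {
  lay <- sim$layout
  if (is.null(lay) || nrow(lay) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(chrom)) chrom <- sim$counts$chrom[1]
  bed <- data.frame(chrom = chrom, start = lay$start - 1, end = lay$end,
                    name = lay$mechanism, score = lay$param)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' The worked-example genotype-counts extract
#'
#' Loads the packaged transcription of three published example variants
#' (an in-deletion SNP, a stratified SNP and a miscalled indel) genotyped
#' across six super-populations — 18 genotype distributions used throughout
#' the documentation and tests. Genotype counts and labels are the printed
#' values; coordinates are placeholders (not printed in the source table)
#' except the deletion interval, and per-population missing counts are
#' derived as super-population size minus called genotypes.
#'
#' @return A counts data.frame ([read_counts_table()] layout).
#' @export
exac_table2_counts <- function() {
  read_counts_table(system.file("extdata", "exac_table2_counts.tsv",
                                package = "hweqc", mustWork = TRUE))
}

#' Run the full departure-QC pipeline
#'
#' Orchestrates filter -> test -> classify -> features -> association over a
#' genotype-counts table, optionally writing the per-distribution results
#' TSV, the group-comparison TSV and a run log.
#'
#' @param counts Counts data.frame or path to a counts TSV.
#' @param total_n Total cohort size (call-rate/missingness denominator);
#'   default: the largest per-variant total of called + missing.
#' @param cnv_intervals Optional CNV table ([read_cnv_bed()]) or BED path.
#' @param alpha,dof,min_call_rate,min_maf,pop_min_maf,strict,strict_call_rate
#'   Passed to [filter_variants()] and [hwe_analysis()].
#' @param out_dir Optional output directory; when given, writes
#'   `hwe_results.tsv`, `features.tsv`, `association.tsv`,
#'   `filter_decisions.tsv` and `run_log.txt`.
#' @return A list: `results` (per variant x population test rows joined
#'   with features), `features`, `association`, `filter_decisions`,
#'   `config`, `stage_counts`.
#' @export
run_pipeline <- function(counts, total_n = NULL, cnv_intervals = NULL,
                         alpha = 1e-5, dof = 2,
                         min_call_rate = 0.80, min_maf = 0.01,
                         pop_min_maf = 0.001,
                         strict = FALSE, strict_call_rate = 0.98,
                         out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts_table(counts)
  if (is.character(cnv_intervals)) cnv_intervals <- read_cnv_bed(cnv_intervals)
  if (nrow(counts) == 0) {
    warning("empty input; writing empty outputs")
    return(list(results = counts, features = NULL, association = NULL,
                filter_decisions = NULL,
                stage_counts = c(input = 0, filtered = 0)))
  }
  if (is.null(total_n)) {
    per_var <- tapply(
      counts$n_aa + counts$n_ab + counts$n_bb + counts$n_missing,
      counts$variant_id, sum)
    total_n <- max(per_var)
  }
  config <- list(alpha = alpha, dof = dof, min_call_rate = min_call_rate,
                 min_maf = min_maf, pop_min_maf = pop_min_maf,
                 strict = strict, strict_call_rate = strict_call_rate,
                 total_n = total_n)

  filt <- filter_variants(counts, total_n, min_call_rate, min_maf,
                          pop_min_maf, strict, strict_call_rate)
  results <- if (nrow(filt$counts) > 0) {
    hwe_analysis(filt$counts, alpha = alpha, dof = dof)
  } else filt$counts

  features <- NULL
  assoc <- NULL
  if (nrow(filt$counts) > 0 &&
      all(c("chrom", "pos", "ref", "alt") %in% names(filt$counts))) {
    features <- build_features(filt$counts, total_n, cnv_intervals)
    results <- merge(results,
                     features[, setdiff(names(features), c("chrom", "pos"))],
                     by = "variant_id", sort = FALSE)
    results <- results[order(results$variant_id, results$population), ]
    rownames(results) <- NULL
    n_classes <- unique(results$classification)
    if (any(c("LOH", "GOH") %in% n_classes) && "NONE" %in% n_classes) {
      assoc <- suppressWarnings(association_report(results))
    }
  }

  stage_counts <- c(
    input_rows = nrow(counts),
    input_variants = length(unique(counts$variant_id)),
    filtered_rows = nrow(filt$counts),
    filtered_variants = length(unique(filt$counts$variant_id)),
    tested_rows = nrow(results)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) if (!is.null(d)) {
      utils::write.table(format_report(d), file.path(out_dir, f),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wt(results, "hwe_results.tsv")
    wt(features, "features.tsv")
    wt(assoc, "association.tsv")
    wt(filt$decisions, "filter_decisions.tsv")
    writeLines(c(
      paste0("hweqc ", as.character(utils::packageVersion("hweqc"))),
      paste0("R ", R.version.string),
      paste0("config: ", paste(names(config), unlist(config),
                               sep = "=", collapse = " ")),
      paste0("stage_counts: ", paste(names(stage_counts), stage_counts,
                                     sep = "=", collapse = " "))
    ), file.path(out_dir, "run_log.txt"))
  }

  list(results = results, features = features, association = assoc,
       filter_decisions = filt$decisions, config = config,
       stage_counts = stage_counts)
}

#' Round a results table to report precision
#'
#' Report files print expected counts to the nearest integer, frequencies
#' and O/E ratios to 2 decimals, and p-values to 2 significant figures;
#' machine precision is retained in the in-memory objects.
#'
#' @param d A results data.frame.
#' @return The data.frame with display rounding applied.
#' @export
format_report <- function(d) {
  for (cc in intersect(c("exp_aa", "exp_ab", "exp_bb"), names(d))) {
    d[[cc]] <- round(d[[cc]])
  }
  for (cc in intersect(c("allele_a_freq", "oe_ratio", "oe_het_ratio",
                         "maf_overall", "maf_sd"), names(d))) {
    d[[cc]] <- round(d[[cc]], 2)
  }
  for (cc in intersect(c("p_hwe", "p_value"), names(d))) {
    d[[cc]] <- signif(d[[cc]], 2)
  }
  d
}
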