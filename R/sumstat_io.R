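#' Canonical summary-statistic column dialect
#'
#' Maps internal field names to the column headers of the canonical
#' tab-delimited dialect (`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`).
#' Supply a modified copy to [read_sumstats()] to parse other layouts; there
#' is deliberately no header auto-detection.
#'
#' @return Named character vector mapping internal names to file columns.
#' @export
canonical_dialect <- function() {
  c(
    snp_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N"
  )
}

SUMSTAT_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

#' Construct a GWAS summary-statistic table
#'
#' The central per-trait container: one row per SNP with alleles, effect
#' estimate, standard error, p-value and sample size. Betas are in SD units
#' of the exposure for continuous traits and log odds ratios for binary
#' traits. Positions are 1-based.
#'
#' @param records Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (may be `NA`), `beta`, `se`,
#'   `pvalue`, `n`.
#' @param trait_id Trait identifier.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param cohort_label Free-text label for the source cohort.
#' @param validate Drop rows violating record invariants (with a message)?
#'
#' @return A `sumstat_table`: a data frame with trait metadata attributes.
#' @export
sumstat_table <- function(records, trait_id, trait_type = c("continuous", "binary"),
                          cohort_label = "unknown", validate = TRUE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTAT_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop_trigmr("trigmr_format_error", "missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, SUMSTAT_COLS]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) records[[col]] <- as.numeric(records[[col]])
  records$n <- as.numeric(records$n)

  if (validate) {
    keep <- valid_snp_record(records)
    if (any(!keep)) {
      message(sprintf("[%s] dropped %d record(s) violating SNP-record invariants",
                      trait_id, sum(!keep)))
      records <- records[keep, , drop = FALSE]
    }
    records <- resolve_duplicates(records, trait_id)
  }
  if (nrow(records) == 0) {
    stop_trigmr("trigmr_empty_input", "no valid records for trait '%s'", trait_id)
  }
  rownames(records) <- NULL
  structure(records,
    trait_id = trait_id, trait_type = trait_type, cohort_label = cohort_label,
    class = c("sumstat_table", "data.frame")
  )
}

# Row-level invariants: ACGT single-nucleotide alleles, distinct alleles,
# se > 0, p in (0, 1], positive n, eaf in [0, 1] or missing.
valid_snp_record <- function(df) {
  nuc <- c("A", "C", "G", "T")
  !is.na(df$snp_id) & nzchar(df$snp_id) &
    df$effect_allele %in% nuc & df$other_allele %in% nuc &
    df$effect_allele != df$other_allele &
    !is.na(df$beta) & is.finite(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    !is.na(df$n) & df$n > 0 &
    !is.na(df$pos) & df$pos >= 1 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
}

# Duplicate snp_id: keep the row with the smallest p (strongest signal),
# mirroring the clump preference. Ties broken by file order.
resolve_duplicates <- function(df, trait_id) {
  if (!anyDuplicated(df$snp_id)) return(df)
  ord <- order(df$pvalue, seq_len(nrow(df)))
  dup <- duplicated(df$snp_id[ord])
  n_dropped <- sum(dup)
  df <- df[sort(ord[!dup]), , drop = FALSE]
  message(sprintf("[%s] dropped %d duplicate snp_id record(s), keeping smallest p",
                  trait_id, n_dropped))
  df
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("<sumstat_table> trait '%s' (%s, cohort %s): %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"),
              attr(x, "cohort_label"), nrow(x)))
  utils::str(utils::head(as.data.frame(x), 5))
  invisible(x)
}

trait_id <- function(x) attr(x, "trait_id")
trait_type <- function(x) attr(x, "trait_type")

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a header-bearing tab-delimited file (gzip accepted) into a
#' [sumstat_table()]. Rows violating record invariants are dropped with a
#' logged count; duplicate `snp_id`s keep the record with the smallest p.
#'
#' @param path File path.
#' @param dialect Named mapping from internal field names to file column
#'   headers; defaults to [canonical_dialect()].
#' @param trait_id,trait_type,cohort_label Trait metadata (see
#'   [sumstat_table()]).
#' @param drop_multiallelic Drop every record of a `snp_id` that appears
#'   with more than one distinct allele pair, instead of applying the
#'   smallest-p duplicate rule.
#'
#' @return A `sumstat_table`.
#' @export
read_sumstats <- function(path, dialect = canonical_dialect(), trait_id = basename(path),
                          trait_type = c("continuous", "binary"),
                          cohort_label = "unknown", drop_multiallelic = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    stop_trigmr("trigmr_io_error", "file not found: %s", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = "NA", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(unname(dialect[SUMSTAT_COLS]), names(raw))
  if (length(missing_cols) > 0) {
    stop_trigmr("trigmr_format_error", "missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  df <- stats::setNames(raw[, unname(dialect[SUMSTAT_COLS])], SUMSTAT_COLS)
  if (drop_multiallelic) {
    pair <- paste(pmin(df$effect_allele, df$other_allele),
                  pmax(df$effect_allele, df$other_allele))
    n_pairs <- tapply(pair, df$snp_id, function(p) length(unique(p)))
    bad <- names(n_pairs)[n_pairs > 1]
    if (length(bad) > 0) {
      message(sprintf("[%s] dropped %d record(s) at %d multi-allelic site(s)",
                      trait_id, sum(df$snp_id %in% bad), length(bad)))
      df <- df[!df$snp_id %in% bad, , drop = FALSE]
    }
  }
  sumstat_table(df, trait_id = trait_id, trait_type = trait_type,
                cohort_label = cohort_label)
}

#' Write a summary-statistic table in the canonical dialect
#'
#' @param table A `sumstat_table`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  df <- stats::setNames(as.data.frame(table), unname(canonical_dialect()))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RESULT_COLS <- c("trait_id", "estimator", "n_snps", "beta", "se",
                 "or_", "ci_low", "ci_high", "pvalue", "tier")

#' Write MR results or tier calls to a tab-delimited file
#'
#' Fixed column order `trait_id, estimator, n_snps, beta, se, or_, ci_low,
#' ci_high, pvalue, tier`; fields a result type does not carry are written
#' as `NA`. [read_results()] round-trips the output.
#'
#' @param results Non-empty data frame of results (rows from [mr_result()]
#'   collections or [assign_tiers()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0) {
    stop_trigmr("trigmr_empty_input", "refusing to write an empty result collection")
  }
  for (col in setdiff(RESULT_COLS, names(results))) results[[col]] <- NA
  out <- results[, RESULT_COLS]
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path File path.
#' @return Data frame with the fixed result columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_trigmr("trigmr_io_error", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = "NA", stringsAsFactors = FALSE)
  missing_cols <- setdiff(RESULT_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop_trigmr("trigmr_format_error", "missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  df$trait_id <- as.character(df$trait_id)
  df$tier <- as.character(df$tier)
  df
}

#' Construct an LD reference panel
#'
#' Pairwise r-squared among a set of SNPs plus their genomic positions, as
#' consumed by [ld_clump()].
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param chrom,pos Matching chromosome labels and 1-based positions.
#' @param r2 Symmetric matrix of r-squared values in `[0, 1]` with unit
#'   diagonal; dimension must match `length(snp_ids)`.
#' @param tol Largest tolerated absolute asymmetry.
#'
#' @return An `ld_panel` object.
#' @export
ld_panel <- function(snp_ids, chrom, pos, r2, tol = 1e-8) {
  snp_ids <- as.character(snp_ids)
  m <- length(snp_ids)
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) {
    stop_trigmr("trigmr_format_error", "LD matrix is not square (%d x %d)",
                nrow(r2), ncol(r2))
  }
  if (nrow(r2) != m || length(chrom) != m || length(pos) != m) {
    stop_trigmr("trigmr_format_error",
                "LD matrix dimension %d does not match %d SNP ids", nrow(r2), m)
  }
  if (anyDuplicated(snp_ids)) {
    stop_trigmr("trigmr_format_error", "duplicate snp_id in LD panel")
  }
  if (max(abs(r2 - t(r2))) > tol) {
    stop_trigmr("trigmr_format_error", "LD matrix asymmetry exceeds tolerance %g", tol)
  }
  if (any(abs(diag(r2) - 1) > tol)) {
    stop_trigmr("trigmr_format_error", "LD matrix diagonal is not 1")
  }
  if (any(r2 < -tol | r2 > 1 + tol)) {
    stop_trigmr("trigmr_format_error", "r2 values outside [0, 1]")
  }
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(
    list(snp_ids = snp_ids, chrom = as.character(chrom), pos = as.integer(pos), r2 = r2),
    class = "ld_panel"
  )
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d SNPs, mean off-diagonal r2 %.3f\n",
              length(x$snp_ids),
              if (length(x$snp_ids) > 1) mean(x$r2[upper.tri(x$r2)]) else NA_real_))
  invisible(x)
}

#' Read an LD panel from disk
#'
#' Two layouts are accepted: a square tab-delimited matrix whose first
#' column holds SNP ids (header row repeats the ids), or a long-format
#' three-column file `snpA  snpB  r2` — recognised by its third column being
#' named `r2` — where unlisted pairs default to r2 = 0. Either layout needs
#' a sidecar positions file with columns `SNP CHR POS`.
#'
#' @param path Matrix or long-format file.
#' @param positions_path Tab-delimited `SNP CHR POS` file.
#' @return An [ld_panel()].
#' @export
read_ld_panel <- function(path, positions_path) {
  for (p in c(path, positions_path)) {
    if (!file.exists(p)) stop_trigmr("trigmr_io_error", "file not found: %s", p)
  }
  posdf <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("SNP", "CHR", "POS") %in% names(posdf))) {
    stop_trigmr("trigmr_format_error", "positions file needs columns SNP, CHR, POS")
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  long_format <- ncol(raw) == 3 && tolower(names(raw)[3]) %in% c("r2", "rsq", "r.2")
  if (long_format) {
    ids <- posdf$SNP
    r2 <- diag(1, length(ids))
    dimnames(r2) <- list(ids, ids)
    a <- match(raw[[1]], ids); b <- match(raw[[2]], ids)
    if (anyNA(a) || anyNA(b)) {
      stop_trigmr("trigmr_format_error", "long-format LD pair names a SNP absent from the positions file")
    }
    r2[cbind(a, b)] <- raw[[3]]
    r2[cbind(b, a)] <- raw[[3]]
  } else {
    ids <- as.character(raw[[1]])
    r2 <- as.matrix(raw[, -1, drop = FALSE])
    if (nrow(r2) != ncol(r2)) {
      stop_trigmr("trigmr_format_error", "LD matrix is not square (%d x %d)",
                  nrow(r2), ncol(r2))
    }
    ord <- match(ids, posdf$SNP)
    if (anyNA(ord)) {
      stop_trigmr("trigmr_format_error", "LD matrix names a SNP absent from the positions file")
    }
    posdf <- posdf[ord, ]
  }
  idx <- match(ids, posdf$SNP)
  ld_panel(ids, posdf$CHR[idx], posdf$POS[idx], r2)
}

#' Write an LD panel as a square matrix plus positions sidecar
#'
#' @param panel An [ld_panel()].
#' @param path,positions_path Output paths for matrix and positions.
#' @return `path`, invisibly.
#' @export
write_ld_panel <- function(panel, path, positions_path) {
  mat <- data.frame(SNP = panel$snp_ids, panel$r2, check.names = FALSE)
  utils::write.table(format(mat, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(SNP = panel$snp_ids, CHR = panel$chrom, POS = panel$pos),
    positions_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
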