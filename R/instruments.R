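#' Clumping parameters
#'
#' Defaults are the PLINK clump settings used for lipid-instrument
#' selection: index p-value threshold 5e-8, secondary threshold 5e-4,
#' r-squared 0.05, window 250 kb.
#'
#' @param p1 Index-SNP p-value threshold.
#' @param p2 Secondary p-value threshold (`p1 <= p2`).
#' @param r2_threshold SNPs with r2 at or above this to an index SNP are
#'   pruned; must lie in (0, 1).
#' @param kb_window Physical window in kilobases around each index SNP.
#' @return A `clump_params` list.
#' @export
clump_params <- function(p1 = 5e-8, p2 = 5e-4, r2_threshold = 0.05, kb_window = 250) {
  if (p1 > p2) stop_trigmr("trigmr_param_error", "p1 must be <= p2")
  if (r2_threshold <= 0 || r2_threshold >= 1) {
    stop_trigmr("trigmr_param_error", "r2_threshold must be in (0, 1)")
  }
  if (kb_window <= 0) stop_trigmr("trigmr_param_error", "kb_window must be positive")
  structure(list(p1 = p1, p2 = p2, r2_threshold = r2_threshold,
                 kb_window = kb_window), class = "clump_params")
}

#' Filter a summary-statistic table to genome-wide-significant SNPs
#'
#' @param table A [sumstat_table()].
#' @param p_threshold Retain SNPs with `pvalue < p_threshold` (default the
#'   conventional genome-wide threshold 5e-8). Original row order is kept.
#' @return Filtered `sumstat_table`.
#' @export
select_genome_wide <- function(table, p_threshold = 5e-8) {
  keep <- table$pvalue < p_threshold
  if (!any(keep)) {
    stop_trigmr("trigmr_empty_input",
                "no SNPs reach p < %g for trait '%s'", p_threshold, trait_id(table))
  }
  subset_sumstat(table, which(keep))
}

subset_sumstat <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    trait_id = attr(table, "trait_id"), trait_type = attr(table, "trait_type"),
    cohort_label = attr(table, "cohort_label"),
    class = c("sumstat_table", "data.frame")
  )
}

#' Greedy LD clumping of a summary-statistic table
#'
#' PLINK-style clumping: candidates with `p < p1` are visited in ascending
#' p-value order (ties broken lexicographically by `snp_id` for
#' determinism); each becomes an index SNP and removes every remaining SNP
#' with `p < p2`, r2 at or above `r2_threshold` to the index, and position
#' within `kb_window` kb of it on the same chromosome. SNPs absent from the
#' LD panel are dropped (logged) before clumping.
#'
#' @param table A [sumstat_table()].
#' @param ld An [ld_panel()] covering the table's SNPs.
#' @param params A [clump_params()].
#' @return `sumstat_table` of index SNPs, in the table's original order.
#' @export
ld_clump <- function(table, ld, params = clump_params()) {
  in_panel <- table$snp_id %in% ld$snp_ids
  if (any(!in_panel)) {
    message(sprintf("[%s] dropped %d SNP(s) absent from the LD panel",
                    trait_id(table), sum(!in_panel)))
    table <- subset_sumstat(table, which(in_panel))
  }
  cand <- which(table$pvalue < params$p1)
  if (length(cand) == 0) {
    stop_trigmr("trigmr_empty_input", "no clump candidates with p < %g", params$p1)
  }
  panel_idx <- match(table$snp_id, ld$snp_ids)
  alive <- rep(TRUE, nrow(table))
  is_index <- rep(FALSE, nrow(table))
  ord <- cand[order(table$pvalue[cand], table$snp_id[cand])]
  for (i in ord) {
    if (!alive[i]) next
    is_index[i] <- TRUE
    prune <- alive & !is_index &
      table$pvalue < params$p2 &
      table$chrom == table$chrom[i] &
      abs(table$pos - table$pos[i]) <= params$kb_window * 1000 &
      ld$r2[panel_idx, panel_idx[i]] >= params$r2_threshold
    alive[prune] <- FALSE
  }
  subset_sumstat(table, which(is_index))
}

#' Restrict instruments to SNPs available in an outcome dataset
#'
#' @param instruments,outcome [sumstat_table()]s.
#' @return `instruments` restricted (in original order) to `snp_id`s
#'   present in `outcome`; the drop count is logged.
#' @export
intersect_with_outcome <- function(instruments, outcome) {
  keep <- instruments$snp_id %in% outcome$snp_id
  if (!any(keep)) {
    stop_trigmr("trigmr_empty_input",
                "no instrument overlaps outcome trait '%s'", trait_id(outcome))
  }
  if (any(!keep)) {
    message(sprintf("[%s] %d instrument(s) absent from outcome '%s', dropped",
                    trait_id(instruments), sum(!keep), trait_id(outcome)))
  }
  subset_sumstat(instruments, which(keep))
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")
is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effect of every shared SNP to the exposure's effect
#' allele. Matching alleles are kept as-is; swapped alleles negate the
#' outcome beta and complement its frequency; complementary-strand
#' encodings of either case are first complemented. Palindromic SNPs (A/T
#' or C/G) are resolved by effect-allele-frequency agreement when both
#' frequencies are outside `[limit, 1 - limit]`, and dropped (counted)
#' otherwise; irreconcilable allele pairs are dropped and counted.
#'
#' @param exposure,outcome [sumstat_table()]s sharing SNPs.
#' @param palindromic_eaf_limit Frequency band half-width inside which a
#'   palindromic SNP is considered ambiguous; default 0.42.
#' @return An [instrument_set()] of harmonized effect pairs.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) {
    stop_trigmr("trigmr_empty_input", "no shared SNPs to harmonize")
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$snp_id), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp_id), ]

  n <- length(shared)
  keep <- rep(TRUE, n)
  flip <- rep(FALSE, n)
  n_pal <- 0L; n_unm <- 0L

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  o_ea <- ou$effect_allele; o_oa <- ou$other_allele
  # strand-flip non-palindromic outcome records whose alleles only match
  # after complementing
  same <- o_ea == ex$effect_allele & o_oa == ex$other_allele
  swap <- o_ea == ex$other_allele & o_oa == ex$effect_allele
  comp_needed <- !pal & !same & !swap
  if (any(comp_needed)) {
    o_ea[comp_needed] <- unname(COMPLEMENT[o_ea[comp_needed]])
    o_oa[comp_needed] <- unname(COMPLEMENT[o_oa[comp_needed]])
    same <- o_ea == ex$effect_allele & o_oa == ex$other_allele
    swap <- o_ea == ex$other_allele & o_oa == ex$effect_allele
  }

  for (j in seq_len(n)) {
    if (pal[j]) {
      # palindromic: alleles alone cannot fix strand; use frequencies
      if (!(same[j] || swap[j])) { keep[j] <- FALSE; n_unm <- n_unm + 1L; next }
      fx <- ex$eaf[j]; fy <- ou$eaf[j]
      if (swap[j]) fy <- 1 - fy
      lim <- palindromic_eaf_limit
      informative <- !is.na(fx) && !is.na(fy) &&
        (fx < lim || fx > 1 - lim) && (fy < lim || fy > 1 - lim)
      if (!informative) { keep[j] <- FALSE; n_pal <- n_pal + 1L; next }
      # frequencies disagreeing on the minor allele imply the outcome is on
      # the opposite strand: flip relative to the allele-label alignment
      flip[j] <- xor(swap[j], (fx < 0.5) != (fy < 0.5))
    } else if (same[j]) {
      flip[j] <- FALSE
    } else if (swap[j]) {
      flip[j] <- TRUE
    } else {
      keep[j] <- FALSE; n_unm <- n_unm + 1L
    }
  }
  if (!any(keep)) {
    stop_trigmr("trigmr_empty_input", "no SNPs survived harmonization")
  }
  beta_y <- ifelse(flip, -ou$beta, ou$beta)
  instrument_set(
    snp_ids = shared[keep],
    beta_exposure = unname(ex$beta[keep]), se_exposure = unname(ex$se[keep]),
    beta_outcome = beta_y[keep], se_outcome = ou$se[keep],
    exposure_labels = trait_id(exposure), outcome_label = trait_id(outcome),
    n_dropped_palindromic = n_pal, n_dropped_unmatched = n_unm
  )
}

#' Construct a harmonized instrument set
#'
#' Effect pairs ready for estimation. `beta_exposure`/`se_exposure` may be
#' matrices with one column per exposure for multivariable MR.
#'
#' @param snp_ids SNP identifiers.
#' @param beta_exposure,se_exposure Exposure effects and SEs (vector, or
#'   matrix with one column per exposure).
#' @param beta_outcome,se_outcome Outcome effects and SEs.
#' @param exposure_labels Character vector naming the exposure column(s).
#' @param outcome_label Outcome trait id.
#' @param n_dropped_palindromic,n_dropped_unmatched Harmonization
#'   provenance counts.
#' @return An `instrument_set`.
#' @export
instrument_set <- function(snp_ids, beta_exposure, se_exposure, beta_outcome,
                           se_outcome, exposure_labels = "exposure",
                           outcome_label = "outcome",
                           n_dropped_palindromic = 0L, n_dropped_unmatched = 0L) {
  bx <- as.matrix(beta_exposure); sx <- as.matrix(se_exposure)
  m <- length(snp_ids)
  if (m < 1 || nrow(bx) != m || nrow(sx) != m ||
      length(beta_outcome) != m || length(se_outcome) != m) {
    stop_trigmr("trigmr_param_error", "instrument arrays must share length >= 1")
  }
  if (ncol(bx) != length(exposure_labels)) {
    stop_trigmr("trigmr_param_error", "one exposure label per exposure column required")
  }
  if (any(sx <= 0) || any(se_outcome <= 0)) {
    stop_trigmr("trigmr_param_error", "standard errors must be positive")
  }
  dimnames(bx) <- dimnames(sx) <- list(NULL, exposure_labels)
  structure(
    list(snp_ids = as.character(snp_ids), beta_exposure = bx, se_exposure = sx,
         beta_outcome = as.numeric(beta_outcome), se_outcome = as.numeric(se_outcome),
         exposure_labels = exposure_labels, outcome_label = outcome_label,
         n_dropped_palindromic = as.integer(n_dropped_palindromic),
         n_dropped_unmatched = as.integer(n_dropped_unmatched)),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d SNPs: %s -> %s (dropped: %d palindromic, %d unmatched)\n",
              length(x$snp_ids), paste(x$exposure_labels, collapse = " + "),
              x$outcome_label, x$n_dropped_palindromic, x$n_dropped_unmatched))
  invisible(x)
}

n_snps <- function(instr) length(instr$snp_ids)

# Subset an instrument set by SNP index or id.
subset_instruments <- function(instr, keep) {
  if (is.character(keep)) keep <- match(keep, instr$snp_ids)
  instrument_set(
    instr$snp_ids[keep],
    instr$beta_exposure[keep, , drop = FALSE], instr$se_exposure[keep, , drop = FALSE],
    instr$beta_outcome[keep], instr$se_outcome[keep],
    exposure_labels = instr$exposure_labels, outcome_label = instr$outcome_label,
    n_dropped_palindromic = instr$n_dropped_palindromic,
    n_dropped_unmatched = instr$n_dropped_unmatched
  )
}

#' Build a multivariable instrument set around a primary exposure
#'
#' Extracts the primary instruments' SNPs from each co-exposure table,
#' aligning co-exposure betas to the primary exposure's effect allele
#' (negating swapped records, complement-strand aware), then harmonizes the
#' primary exposure against the outcome and carries the co-exposure columns
#' along. SNPs missing from any co-exposure are dropped; losing more than
#' `max_loss` of them raises a warning.
#'
#' @param primary [sumstat_table()] of the primary-exposure instruments.
#' @param co_exposures Named list of [sumstat_table()]s, one per
#'   co-exposure.
#' @param outcome Outcome [sumstat_table()].
#' @param palindromic_eaf_limit Passed to [harmonize()].
#' @param max_loss Tolerated fraction of primary instruments missing from a
#'   co-exposure before warning.
#' @return An [instrument_set()] with `1 + length(co_exposures)` exposure
#'   columns.
#' @export
make_mvmr_set <- function(primary, co_exposures, outcome,
                          palindromic_eaf_limit = 0.42, max_loss = 0.2) {
  stopifnot(length(co_exposures) >= 1, !is.null(names(co_exposures)))
  shared <- primary$snp_id
  for (nm in names(co_exposures)) {
    avail <- shared %in% co_exposures[[nm]]$snp_id
    if (mean(!avail) > max_loss) {
      warning(sprintf("co-exposure '%s' is missing %.0f%% of primary instruments",
                      nm, 100 * mean(!avail)))
    }
    shared <- shared[avail]
  }
  if (length(shared) == 0) {
    stop_trigmr("trigmr_empty_input", "no primary instruments shared by all co-exposures")
  }
  primary <- subset_sumstat(primary, match(shared, primary$snp_id))
  uni <- harmonize(primary, outcome, palindromic_eaf_limit)
  idx <- match(uni$snp_ids, primary$snp_id)
  ea <- primary$effect_allele[idx]; oa <- primary$other_allele[idx]

  k <- length(co_exposures)
  bx <- cbind(uni$beta_exposure, matrix(NA_real_, length(uni$snp_ids), k))
  sx <- cbind(uni$se_exposure, matrix(NA_real_, length(uni$snp_ids), k))
  for (j in seq_len(k)) {
    co <- co_exposures[[j]]
    ci <- match(uni$snp_ids, co$snp_id)
    c_ea <- co$effect_allele[ci]; c_oa <- co$other_allele[ci]
    same <- c_ea == ea & c_oa == oa
    swap <- c_ea == oa & c_oa == ea
    flipstrand <- !same & !swap
    c_ea[flipstrand] <- unname(COMPLEMENT[c_ea[flipstrand]])
    c_oa[flipstrand] <- unname(COMPLEMENT[c_oa[flipstrand]])
    same <- c_ea == ea & c_oa == oa
    swap <- c_ea == oa & c_oa == ea
    if (any(!same & !swap)) {
      stop_trigmr("trigmr_format_error",
                  "co-exposure '%s' has irreconcilable alleles at %d SNP(s)",
                  names(co_exposures)[j], sum(!same & !swap))
    }
    bx[, j + 1] <- ifelse(swap, -co$beta[ci], co$beta[ci])
    sx[, j + 1] <- co$se[ci]
  }
  instrument_set(
    uni$snp_ids, bx, sx, uni$beta_outcome, uni$se_outcome,
    exposure_labels = c(uni$exposure_labels, names(co_exposures)),
    outcome_label = uni$outcome_label,
    n_dropped_palindromic = uni$n_dropped_palindromic,
    n_dropped_unmatched = uni$n_dropped_unmatched
  )
}
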