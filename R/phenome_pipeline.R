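#' Construct an outcome manifest
#'
#' The per-trait registry driving a phenome scan. Each entry names a trait
#' and carries (or points to) its discovery-cohort and, when mappable, its
#' replication-cohort summary statistics.
#'
#' @param entries List of entries, each a list with `trait_id`,
#'   `discovery` (a [sumstat_table()] or file path), `replication` (table,
#'   path, or `NULL`), `trait_type`, `mappable` (logical).
#' @return An `outcome_manifest`.
#' @export
outcome_manifest <- function(entries) {
  ids <- vapply(entries, function(e) e$trait_id, character(1))
  if (anyDuplicated(ids)) {
    stop_trigmr("trigmr_format_error", "duplicate trait_id in manifest")
  }
  for (e in entries) {
    if (isTRUE(e$mappable) && is.null(e$replication)) {
      stop_trigmr("trigmr_format_error",
                  "trait '%s' is mappable but has no replication data", e$trait_id)
    }
  }
  structure(stats::setNames(entries, ids), class = "outcome_manifest")
}

#' @export
print.outcome_manifest <- function(x, ...) {
  cat(sprintf("<outcome_manifest> %d trait(s), %d mappable\n", length(x),
              sum(vapply(x, function(e) isTRUE(e$mappable), logical(1)))))
  invisible(x)
}

# Resolve a manifest entry's table, reading from disk when given a path.
resolve_table <- function(x, trait_id) {
  if (inherits(x, "sumstat_table")) return(x)
  if (is.character(x)) {
    return(read_sumstats(x, trait_id = trait_id, trait_type = "binary"))
  }
  stop_trigmr("trigmr_format_error", "entry for '%s' is neither a table nor a path",
              trait_id)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop_trigmr("trigmr_param_error", "alpha must be in (0, 1)")
  if (n_tests < 1) stop_trigmr("trigmr_param_error", "n_tests must be >= 1")
  alpha / n_tests
}

#' Pipeline configuration
#'
#' @param alpha Family-wise error rate for both Bonferroni corrections.
#' @param nominal_p Nominal significance threshold gating replication.
#' @param palindromic_eaf_limit Passed to [harmonize()].
#' @param presso_n_sim,presso_threshold MR-PRESSO settings
#'   (`presso_threshold = NULL` uses `0.05 / n_snps`).
#' @param wm_n_boot Weighted-median bootstrap replicates.
#' @param seed Master seed for seeded estimators.
#' @return A `mr_config` list.
#' @export
mr_config <- function(alpha = 0.05, nominal_p = 0.05, palindromic_eaf_limit = 0.42,
                      presso_n_sim = 1000, presso_threshold = NULL,
                      wm_n_boot = 1000, seed = 1L) {
  structure(list(alpha = alpha, nominal_p = nominal_p,
                 palindromic_eaf_limit = palindromic_eaf_limit,
                 presso_n_sim = presso_n_sim, presso_threshold = presso_threshold,
                 wm_n_boot = wm_n_boot, seed = as.integer(seed)),
            class = "mr_config")
}

# Run intersect + harmonize + IVW for one trait, capturing failures.
scan_one <- function(instruments, outcome_table, config) {
  instr_t <- intersect_with_outcome(instruments, outcome_table)
  set <- harmonize(instr_t, outcome_table, config$palindromic_eaf_limit)
  list(result = ivw_fixed(set), set = set)
}

#' Phenome-wide discovery scan
#'
#' Runs intersect, harmonize and fixed-effect IVW for every manifest
#' trait. Per-trait failures (empty intersection, degenerate instruments,
#' unreadable files) are recorded as skipped rows with the failure reason;
#' the scan never aborts on one trait.
#'
#' @param exposure_instruments [sumstat_table()] of selected instruments.
#' @param manifest An [outcome_manifest()].
#' @param config An [mr_config()].
#' @param stage Which manifest table to scan (`"discovery"` or
#'   `"replication"`).
#' @return List with `results` (data frame sorted by p, skipped traits
#'   carrying `status = "skipped"` and a reason) and `sets` (named list of
#'   the harmonized [instrument_set()]s for downstream sensitivity runs).
#' @export
run_discovery <- function(exposure_instruments, manifest, config = mr_config(),
                          stage = "discovery") {
  stopifnot(inherits(manifest, "outcome_manifest"), length(manifest) > 0)
  rows <- vector("list", length(manifest))
  sets <- list()
  for (i in seq_along(manifest)) {
    e <- manifest[[i]]
    out <- tryCatch({
      tab <- resolve_table(e[[stage]], e$trait_id)
      fit <- scan_one(exposure_instruments, tab, config)
      sets[[e$trait_id]] <- fit$set
      cbind(trait_id = e$trait_id, fit$result, status = "ok", reason = NA_character_)
    }, error = function(err) {
      data.frame(trait_id = e$trait_id, estimator = "ivw_fe",
                 exposure_label = trait_id(exposure_instruments) %||% NA_character_,
                 outcome_label = e$trait_id, n_snps = NA_integer_,
                 beta = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 or_ = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
                 pvalue = NA_real_, status = "skipped",
                 reason = conditionMessage(err), stringsAsFactors = FALSE)
    })
    rows[[i]] <- out
  }
  results <- do.call(rbind, rows)
  if (all(results$status == "skipped")) {
    stop_trigmr("trigmr_pipeline_error", "every trait failed the %s scan", stage)
  }
  results <- results[order(is.na(results$pvalue), results$pvalue), ]
  rownames(results) <- NULL
  list(results = results, sets = sets)
}

#' Replication scan of nominally significant discovery traits
#'
#' Runs IVW on the replication-cohort outcome tables for traits that were
#' at least nominally significant in discovery and are mappable between
#' cohorts, using a replication-specific instrument set (the design swaps
#' the exposure GWAS between stages). Unmappable nominal traits are
#' counted but not tested.
#'
#' @param replication_instruments Instruments selected from the
#'   replication-stage exposure GWAS.
#' @param discovery_results Results data frame from [run_discovery()].
#' @param manifest The same [outcome_manifest()].
#' @param config An [mr_config()].
#' @return List with `results`, `sets`, `n_tested` and `n_unmappable`;
#'   when no trait is eligible, `results` is an empty data frame (with a
#'   warning).
#' @export
run_replication <- function(replication_instruments, discovery_results, manifest,
                            config = mr_config()) {
  ok <- discovery_results$status == "ok" &
    discovery_results$pvalue < config$nominal_p
  nominal_ids <- discovery_results$trait_id[ok]
  mappable <- vapply(manifest, function(e) isTRUE(e$mappable), logical(1))
  eligible <- nominal_ids[nominal_ids %in% names(manifest)[mappable]]
  n_unmappable <- sum(!nominal_ids %in% eligible)
  if (length(eligible) == 0) {
    warning("no traits eligible for replication")
    return(list(results = data.frame(), sets = list(),
                n_tested = 0L, n_unmappable = n_unmappable))
  }
  sub <- outcome_manifest(unname(manifest[eligible]))
  scan <- run_discovery(replication_instruments, sub, config, stage = "replication")
  list(results = scan$results, sets = scan$sets,
       n_tested = length(eligible), n_unmappable = n_unmappable)
}

tier_label <- function(p_disc, p_repl, thr_disc, thr_repl, nominal_p = 0.05) {
  if (is.na(p_disc)) return("none")
  disc_b <- p_disc < thr_disc
  disc_n <- p_disc < nominal_p
  if (is.na(p_repl)) return("none")
  repl_b <- p_repl < thr_repl
  repl_n <- p_repl < nominal_p
  if (disc_b && repl_b) return("BB")
  if (disc_b && repl_n) return("BN")
  if (disc_n && repl_b) return("NB")
  "none"
}

#' Assign three-tier discovery/replication evidence labels
#'
#' Tiers follow Bonferroni (B) versus nominal-only (N) significance in the
#' two stages: `BB` = Bonferroni-significant in both; `BN` = Bonferroni in
#' discovery, at least nominal in replication; `NB` = at least nominal in
#' discovery, Bonferroni in replication; `none` otherwise (including
#' traits never tested in replication). Bonferroni thresholds are
#' `alpha / n` for the stated test counts.
#'
#' @param discovery,replication Result data frames from [run_discovery()]
#'   and [run_replication()].
#' @param n_discovery_tests,n_replication_tests Test counts behind the two
#'   Bonferroni corrections.
#' @param alpha,nominal_p Family-wise and nominal significance levels.
#' @return Data frame with one row per discovery trait: p-values, betas,
#'   `tier`, `direction_concordant`, and the thresholds used.
#' @export
assign_tiers <- function(discovery, replication, n_discovery_tests,
                         n_replication_tests, alpha = 0.05, nominal_p = 0.05) {
  thr_d <- bonferroni_threshold(alpha, n_discovery_tests)
  thr_r <- bonferroni_threshold(alpha, max(1L, n_replication_tests))
  ri <- if (nrow(replication) > 0) match(discovery$trait_id, replication$trait_id) else
    rep(NA_integer_, nrow(discovery))
  p_repl <- if (nrow(replication) > 0) replication$pvalue[ri] else rep(NA_real_, nrow(discovery))
  b_repl <- if (nrow(replication) > 0) replication$beta[ri] else rep(NA_real_, nrow(discovery))
  out <- data.frame(
    trait_id = discovery$trait_id,
    beta_discovery = discovery$beta, pvalue_discovery = discovery$pvalue,
    beta_replication = b_repl, pvalue_replication = p_repl,
    tier = vapply(seq_len(nrow(discovery)), function(i) {
      tier_label(discovery$pvalue[i], p_repl[i], thr_d, thr_r, nominal_p)
    }, character(1)),
    direction_concordant = sign(discovery$beta) == sign(b_repl),
    alpha_discovery_bonf = thr_d, alpha_replication_bonf = thr_r,
    alpha_nominal = nominal_p,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Sensitivity analyses for tiered traits
#'
#' Runs MR-Egger, the weighted median and the MR-PRESSO outlier test on
#' the discovery-stage instruments of every trait with tier `BB`, `BN` or
#' `NB`. The IVW refit after outlier removal is produced only when the
#' global MR-PRESSO test is significant (p < 0.05) and outliers are found.
#' Per-trait failures are recorded and the scan continues.
#'
#' @param tier_calls Output of [assign_tiers()].
#' @param sets Named list of discovery-stage [instrument_set()]s (from
#'   [run_discovery()]).
#' @param config An [mr_config()].
#' @return Named list per trait: `egger` (slope + intercept),
#'   `weighted_median`, `presso` (a `presso_result`, `refit` included when
#'   triggered), or `error` with the failure message.
#' @export
run_sensitivity <- function(tier_calls, sets, config = mr_config()) {
  ids <- tier_calls$trait_id[tier_calls$tier %in% c("BB", "BN", "NB")]
  out <- list()
  for (id in ids) {
    out[[id]] <- tryCatch({
      instr <- sets[[id]]
      if (is.null(instr)) stop_trigmr("trigmr_empty_input", "no instrument set for '%s'", id)
      list(
        egger = mr_egger(instr),
        weighted_median = weighted_median(instr, n_boot = config$wm_n_boot,
                                          seed = derive_seed(config$seed, match(id, ids), 1L)),
        presso = presso_outlier(instr, n_sim = config$presso_n_sim,
                                seed = derive_seed(config$seed, match(id, ids), 2L),
                                corrected_threshold = config$presso_threshold)
      )
    }, error = function(err) list(error = conditionMessage(err)))
  }
  out
}

#' Multivariable MR pass over tiered traits
#'
#' Fits the four conventional lipid MVMR models per trait — primary
#' exposure plus LDL; plus HDL; plus HDL and LDL; plus HDL, LDL and ApoB —
#' and flags whether the primary exposure's direct effect keeps the
#' direction of its univariable IVW estimate.
#'
#' @param tier_calls Output of [assign_tiers()].
#' @param primary_instruments [sumstat_table()] of the primary-exposure
#'   instruments.
#' @param co_exposure_tables Named list with elements `LDL`, `HDL`, `ApoB`
#'   ([sumstat_table()]s over the instrument SNPs).
#' @param outcome_tables Named list of discovery outcome tables per trait.
#' @param config An [mr_config()].
#' @return Named list per trait of per-model [mvmr_ivw()] outputs plus
#'   `direction_concordant`; failures recorded per trait/model.
#' @export
run_mvmr_pass <- function(tier_calls, primary_instruments, co_exposure_tables,
                          outcome_tables, config = mr_config()) {
  stopifnot(all(c("LDL", "HDL", "ApoB") %in% names(co_exposure_tables)))
  models <- list(
    TG_LDL = "LDL", TG_HDL = "HDL",
    TG_HDL_LDL = c("HDL", "LDL"), TG_HDL_LDL_ApoB = c("HDL", "LDL", "ApoB")
  )
  ids <- tier_calls$trait_id[tier_calls$tier %in% c("BB", "BN", "NB")]
  out <- list()
  for (id in ids) {
    uni_beta <- tier_calls$beta_discovery[tier_calls$trait_id == id]
    trait_models <- list()
    for (mn in names(models)) {
      trait_models[[mn]] <- tryCatch({
        set <- make_mvmr_set(primary_instruments,
                             co_exposure_tables[models[[mn]]],
                             outcome_tables[[id]],
                             palindromic_eaf_limit = config$palindromic_eaf_limit)
        fits <- mvmr_ivw(set)
        primary_fit <- fits[[1]]
        list(fits = fits,
             direction_concordant = sign(primary_fit$beta) == sign(uni_beta))
      }, error = function(err) list(error = conditionMessage(err)))
    }
    out[[id]] <- trait_models
  }
  out
}

#' Reverse MR: disease as exposure, lipid trait as outcome
#'
#' Re-runs the full instrument-selection pipeline with roles swapped:
#' genome-wide selection and LD clumping on the disease GWAS, intersection
#' and harmonization against the lipid-exposure GWAS, then fixed-effect
#' IVW. Diseases without at least two clumpable genome-wide-significant
#' SNPs are reported as not testable rather than raising an error.
#'
#' @param disease_table Disease GWAS [sumstat_table()] (now the exposure).
#' @param exposure_table Lipid GWAS [sumstat_table()] (now the outcome).
#' @param ld An [ld_panel()] covering the disease SNPs.
#' @param clump A [clump_params()].
#' @param config An [mr_config()].
#' @return List with `status` (`"ok"` or `"not_testable"`), `result`
#'   ([mr_result()] or `NULL`), `n_instruments` and `reason`.
#' @export
run_reverse <- function(disease_table, exposure_table, ld,
                        clump = clump_params(), config = mr_config()) {
  res <- tryCatch({
    sig <- select_genome_wide(disease_table, clump$p1)
    clumped <- ld_clump(sig, ld, clump)
    if (nrow(clumped) < 2) {
      stop_trigmr("trigmr_insufficient_instruments",
                  "only %d clumped disease instrument(s)", nrow(clumped))
    }
    kept <- intersect_with_outcome(clumped, exposure_table)
    set <- harmonize(kept, exposure_table, config$palindromic_eaf_limit)
    if (n_snps(set) < 2) {
      stop_trigmr("trigmr_insufficient_instruments",
                  "only %d harmonized disease instrument(s)", n_snps(set))
    }
    list(status = "ok", result = ivw_fixed(set), n_instruments = n_snps(set),
         reason = NA_character_)
  }, trigmr_error = function(err) {
    list(status = "not_testable", result = NULL, n_instruments = 0L,
         reason = conditionMessage(err))
  })
  res
}
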