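# Leave-one-out IVW slopes for every SNP, computed from running sums.
loo_ivw_slopes <- function(bx, by, w) {
  num <- sum(w * bx * by) - w * bx * by
  den <- sum(w * bx^2) - w * bx^2
  num / den
}

# Simulated RSS draws shared by the global and per-SNP outlier tests.
# Each replicate resamples every effect pair from normals centred on the
# leave-one-out null (bx_j, theta_loo_j * bx_j) with the observed SEs, then
# recomputes leave-one-out slopes and squared residuals on the simulated
# data. Returns the observed per-SNP squared residuals and an n_sim x m
# matrix of simulated ones.
presso_simulate <- function(instr, n_sim, seed) {
  bx <- instr$beta_exposure[, 1]
  by <- instr$beta_outcome
  sx <- instr$se_exposure[, 1]
  sy <- instr$se_outcome
  w <- 1 / sy^2
  m <- length(bx)
  theta_loo <- loo_ivw_slopes(bx, by, w)
  res2_obs <- (by - theta_loo * bx)^2
  sims <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(n_sim * m, bx, sx), nrow = n_sim, byrow = TRUE)
    bys <- matrix(stats::rnorm(n_sim * m, theta_loo * bx, sy), nrow = n_sim, byrow = TRUE)
    wbxy <- sweep(bxs * bys, 2, w, `*`)
    wbx2 <- sweep(bxs^2, 2, w, `*`)
    th <- (rowSums(wbxy) - wbxy) / (rowSums(wbx2) - wbx2)
    (bys - th * bxs)^2
  })
  list(res2_obs = res2_obs, res2_sim = sims,
       theta_loo = theta_loo, rss_obs = sum(res2_obs))
}

#' MR-PRESSO global heterogeneity test
#'
#' The observed statistic is the residual sum of squares
#' `sum_j (by_j - theta_loo_j * bx_j)^2`, each residual taken against the
#' IVW estimate that leaves SNP j out. Its null distribution is obtained by
#' parametric simulation under the no-pleiotropy model, and the p-value
#' uses the add-one estimator `(1 + #(RSS* >= RSS_obs)) / (n_sim + 1)`.
#'
#' @param instr An [instrument_set()] with >= 4 SNPs, single exposure.
#' @param n_sim Simulation replicates (>= 1000).
#' @param seed RNG seed.
#' @return List with `rss_observed` and `global_p`.
#' @export
presso_global <- function(instr, n_sim = 1000, seed) {
  sim <- presso_check_and_simulate(instr, n_sim, seed)
  list(
    rss_observed = sim$rss_obs,
    global_p = (1 + sum(rowSums(sim$res2_sim) >= sim$rss_obs)) / (n_sim + 1)
  )
}

presso_check_and_simulate <- function(instr, n_sim, seed) {
  check_univariable(instr)
  if (n_snps(instr) < 4) {
    stop_trigmr("trigmr_insufficient_instruments",
                "MR-PRESSO needs >= 4 SNPs, got %d", n_snps(instr))
  }
  if (n_sim < 1000) stop_trigmr("trigmr_param_error", "n_sim must be >= 1000")
  if (missing(seed) || is.null(seed)) {
    stop_trigmr("trigmr_param_error", "MR-PRESSO requires a seed")
  }
  presso_simulate(instr, n_sim, seed)
}

#' MR-PRESSO outlier test with corrected threshold and optional refit
#'
#' Per-SNP p-values compare each observed squared residual with its
#' simulated distribution (same draws as the global test, add-one
#' estimator). SNPs below `corrected_threshold` — defaulting to the
#' Bonferroni cut `0.05 / n_snps` — are flagged as outliers. When the
#' global test is significant (`global_p < 0.05`) and outliers exist, the
#' IVW fit is re-run without them and stored as `refit`.
#'
#' @param instr An [instrument_set()] with >= 4 SNPs, single exposure.
#' @param n_sim Simulation replicates (>= 1000).
#' @param seed RNG seed.
#' @param corrected_threshold Per-SNP significance cutoff; `NULL` uses
#'   `0.05 / n_snps`.
#' @return A `presso_result` list: `global_rss_observed`, `global_p`,
#'   `per_snp_p` (named), `outlier_ids`, `corrected_threshold`, `refit`
#'   ([mr_result()] or `NULL`), `n_sim`, `seed`.
#' @export
presso_outlier <- function(instr, n_sim = 1000, seed, corrected_threshold = NULL) {
  sim <- presso_check_and_simulate(instr, n_sim, seed)
  corrected_threshold <- corrected_threshold %||% (0.05 / n_snps(instr))
  per_snp_p <- (1 + colSums(sweep(sim$res2_sim, 2, sim$res2_obs, `>=`))) / (n_sim + 1)
  names(per_snp_p) <- instr$snp_ids
  global_p <- (1 + sum(rowSums(sim$res2_sim) >= sim$rss_obs)) / (n_sim + 1)
  outlier_ids <- instr$snp_ids[per_snp_p < corrected_threshold]
  out <- structure(
    list(global_rss_observed = sim$rss_obs, global_p = global_p,
         per_snp_p = per_snp_p, outlier_ids = outlier_ids,
         corrected_threshold = corrected_threshold, refit = NULL,
         n_sim = n_sim, seed = seed),
    class = "presso_result"
  )
  if (length(outlier_ids) > 0 && global_p < 0.05) {
    out$refit <- presso_refit(instr, out)
  }
  out
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> RSS %.4g, global p %.4g, %d outlier(s) at threshold %.3g\n",
              x$global_rss_observed, x$global_p, length(x$outlier_ids),
              x$corrected_threshold))
  invisible(x)
}

#' Refit IVW after removing MR-PRESSO outliers
#'
#' @param instr The [instrument_set()] the outlier test ran on.
#' @param result A `presso_result` with a non-empty `outlier_ids`.
#' @return An [mr_result()] from [ivw_fixed()] on the pruned set.
#' @export
presso_refit <- function(instr, result) {
  if (length(result$outlier_ids) == 0) {
    stop_trigmr("trigmr_empty_input", "no outliers to remove before refitting")
  }
  keep <- !(instr$snp_ids %in% result$outlier_ids)
  if (sum(keep) < 2) {
    stop_trigmr("trigmr_insufficient_instruments",
                "outlier removal leaves fewer than 2 SNPs")
  }
  ivw_fixed(subset_instruments(instr, which(keep)))
}
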