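#' Construct an MR causal-effect result
#'
#' One estimator's causal estimate on the log-OR-per-SD scale with its
#' standard error, 95% CI (normal quantile 1.96), odds-ratio scale fields
#' and two-sided normal p-value.
#'
#' @param estimator Estimator label.
#' @param beta,se Estimate and positive standard error.
#' @param n_snps Instrument count.
#' @param exposure_label,outcome_label Trait labels.
#' @param pvalue Optional override for the two-sided normal p-value.
#' @return A one-row `mr_result` data frame.
#' @export
mr_result <- function(estimator, beta, se, n_snps,
                      exposure_label = "exposure", outcome_label = "outcome",
                      pvalue = NULL) {
  stopifnot(se > 0)
  ci_low <- beta - 1.96 * se
  ci_high <- beta + 1.96 * se
  structure(
    data.frame(
      estimator = estimator,
      exposure_label = exposure_label, outcome_label = outcome_label,
      n_snps = as.integer(n_snps), beta = beta, se = se,
      ci_low = ci_low, ci_high = ci_high,
      or_ = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
      pvalue = pvalue %||% two_sided_p(beta / se),
      stringsAsFactors = FALSE
    ),
    class = c("mr_result", "data.frame")
  )
}

#' Re-derive the odds-ratio fields of a result
#'
#' Exponentiates `beta` and its CI bounds into `or_`, `or_ci_low`,
#' `or_ci_high`, the reporting scale for binary outcomes (OR per 1 SD of
#' exposure).
#'
#' @param result An [mr_result()].
#' @return The result with refreshed odds-scale fields.
#' @export
to_odds_scale <- function(result) {
  result$or_ <- exp(result$beta)
  result$or_ci_low <- exp(result$ci_low)
  result$or_ci_high <- exp(result$ci_high)
  result
}

#' Wald ratio for a single instrument
#'
#' `beta = by/bx` with the first-order standard error `sy/|bx|`, which
#' ignores exposure-side uncertainty (standard with strong instruments).
#'
#' @param bx,sx Exposure effect and SE.
#' @param by,sy Outcome effect and SE.
#' @param exposure_label,outcome_label Trait labels.
#' @return An [mr_result()] with estimator `"wald"`.
#' @export
wald_ratio <- function(bx, sx, by, sy, exposure_label = "exposure",
                       outcome_label = "outcome") {
  if (bx == 0) {
    stop_trigmr("trigmr_degenerate_instrument", "exposure effect is zero")
  }
  mr_result("wald", beta = by / bx, se = sy / abs(bx), n_snps = 1L,
            exposure_label = exposure_label, outcome_label = outcome_label)
}

ivw_weights <- function(instr) 1 / instr$se_outcome^2

#' Fixed-effect inverse-variance weighted estimator
#'
#' Weighted regression of SNP-outcome effects on SNP-exposure effects
#' through the origin with weights `1/se_outcome^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, `se = sqrt(1 / sum(w bx^2))`.
#' The fixed-effect form holds the residual variance at 1 (no
#' overdispersion scaling); `random_effects = TRUE` instead floors the
#' estimated residual variance at 1 (multiplicative random effects), the
#' convention of the sensitivity estimators.
#'
#' @param instr An [instrument_set()] with a single exposure column and at
#'   least 2 SNPs.
#' @param random_effects Use the multiplicative random-effects SE?
#' @return An [mr_result()] with estimator `"ivw_fe"` (or `"ivw_mre"`).
#' @export
ivw_fixed <- function(instr, random_effects = FALSE) {
  check_univariable(instr)
  m <- n_snps(instr)
  if (m < 2) {
    stop_trigmr("trigmr_insufficient_instruments", "IVW needs >= 2 SNPs, got %d", m)
  }
  ivw_core(instr, random_effects)
}

# Shared IVW arithmetic without the m >= 2 guard (single-SNP limit equals
# the Wald ratio; used by tests and leave-one-out fits).
ivw_core <- function(instr, random_effects = FALSE) {
  bx <- instr$beta_exposure[, 1]
  by <- instr$beta_outcome
  w <- ivw_weights(instr)
  sww <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sww
  sigma2 <- 1
  label <- "ivw_fe"
  if (random_effects && n_snps(instr) > 1) {
    sigma2 <- max(1, sum(w * (by - beta * bx)^2) / (n_snps(instr) - 1))
    label <- "ivw_mre"
  }
  mr_result(label, beta = beta, se = sqrt(sigma2 / sww), n_snps = n_snps(instr),
            exposure_label = instr$exposure_labels[1],
            outcome_label = instr$outcome_label)
}

check_univariable <- function(instr) {
  stopifnot(inherits(instr, "instrument_set"))
  if (ncol(instr$beta_exposure) != 1) {
    stop_trigmr("trigmr_param_error",
                "univariable estimator called on a %d-exposure set",
                ncol(instr$beta_exposure))
  }
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept (weights `1/se_outcome^2`), after recoding every
#' SNP so its exposure effect is non-negative (Egger is not invariant to
#' allele coding). The slope is the causal estimate; the intercept
#' estimates average directional pleiotropy, and its p-value is the
#' pleiotropy test. Standard errors use a residual variance floored at 1
#' (multiplicative random effects).
#'
#' @param instr An [instrument_set()] with >= 3 SNPs, single exposure.
#' @return List with `slope` and `intercept` [mr_result()]s.
#' @export
mr_egger <- function(instr) {
  check_univariable(instr)
  m <- n_snps(instr)
  if (m < 3) {
    stop_trigmr("trigmr_insufficient_instruments", "Egger needs >= 3 SNPs, got %d", m)
  }
  flip <- sign(instr$beta_exposure[, 1])
  flip[flip == 0] <- 1
  bx <- instr$beta_exposure[, 1] * flip
  by <- instr$beta_outcome * flip
  if (max(bx) - min(bx) < .Machine$double.eps * max(abs(bx), 1)) {
    stop_trigmr("trigmr_collinear", "no spread in exposure effects")
  }
  w <- ivw_weights(instr)
  fit <- suppressWarnings(stats::lm(by ~ bx, weights = w))
  sigma2 <- max(1, sum(w * stats::residuals(fit)^2) / (m - 2))
  X <- cbind("(Intercept)" = 1, bx = bx)
  vc <- solve(crossprod(X, w * X)) * sigma2
  mk <- function(which, est) {
    mr_result(est, beta = stats::coef(fit)[[which]], se = sqrt(vc[which, which]),
              n_snps = m, exposure_label = instr$exposure_labels[1],
              outcome_label = instr$outcome_label)
  }
  list(slope = mk("bx", "egger_slope"),
       intercept = mk("(Intercept)", "egger_intercept"))
}

# Weighted 50th percentile of per-SNP ratio estimates: sort ratios,
# accumulate normalized weights, interpolate linearly between the two SNPs
# bracketing cumulative weight 0.5 (half-weight convention).
weighted_percentile_50 <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(r[1])
  if (0.5 >= cum[length(cum)]) return(r[length(r)])
  stats::approx(cum, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Per-SNP ratio estimates `by/bx` are weighted by the inverse variance of
#' the ratio (`bx^2/se_outcome^2`, first order) and the estimate is the
#' weighted 50th percentile. The standard error is the SD of `n_boot`
#' parametric bootstrap replicates (effects resampled from normals at the
#' observed values with the observed SEs).
#'
#' @param instr An [instrument_set()] with >= 3 SNPs, single exposure.
#' @param n_boot Bootstrap replicates (>= 200; default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_result()] with estimator `"weighted_median"`.
#' @export
weighted_median <- function(instr, n_boot = 1000, seed) {
  check_univariable(instr)
  m <- n_snps(instr)
  if (m < 3) {
    stop_trigmr("trigmr_insufficient_instruments",
                "weighted median needs >= 3 SNPs, got %d", m)
  }
  if (n_boot < 200) stop_trigmr("trigmr_param_error", "n_boot must be >= 200")
  if (missing(seed)) stop_trigmr("trigmr_param_error", "weighted_median requires a seed")
  bx <- instr$beta_exposure[, 1]
  if (any(bx == 0)) {
    stop_trigmr("trigmr_degenerate_instrument", "zero exposure effect in instrument set")
  }
  by <- instr$beta_outcome
  sx <- instr$se_exposure[, 1]
  sy <- instr$se_outcome
  weights <- bx^2 / sy^2
  est <- weighted_percentile_50(by / bx, weights)
  boot <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(n_boot * m, bx, sx), nrow = n_boot, byrow = TRUE)
    bys <- matrix(stats::rnorm(n_boot * m, by, sy), nrow = n_boot, byrow = TRUE)
    vapply(seq_len(n_boot), function(b) {
      weighted_percentile_50(bys[b, ] / bxs[b, ], bxs[b, ]^2 / sy^2)
    }, numeric(1))
  })
  mr_result("weighted_median", beta = est, se = stats::sd(boot), n_snps = m,
            exposure_label = instr$exposure_labels[1],
            outcome_label = instr$outcome_label)
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of outcome effects on the K-column exposure
#' effect matrix without intercept (weights `1/se_outcome^2`), giving each
#' exposure's direct effect conditional on the others. Standard errors use
#' a residual variance floored at 1.
#'
#' @param instr An [instrument_set()] with `K >= 2` exposure columns and
#'   more SNPs than exposures.
#' @param check_rank Raise a collinearity error on a rank-deficient
#'   exposure matrix (default). When disabled, aliased exposures are
#'   returned as `NULL` entries and the remaining coefficients are fitted
#'   as usual.
#' @return List of [mr_result()]s, one per exposure, estimator
#'   `"mvmr_ivw"`.
#' @export
mvmr_ivw <- function(instr, check_rank = TRUE) {
  stopifnot(inherits(instr, "instrument_set"))
  X <- instr$beta_exposure
  K <- ncol(X)
  m <- n_snps(instr)
  if (K < 2) stop_trigmr("trigmr_param_error", "MVMR needs >= 2 exposures")
  if (m <= K) {
    stop_trigmr("trigmr_insufficient_instruments",
                "MVMR needs more SNPs (%d) than exposures (%d)", m, K)
  }
  qrX <- qr(X)
  if (check_rank && qrX$rank < K) {
    bad <- instr$exposure_labels[setdiff(seq_len(K), qrX$pivot[seq_len(qrX$rank)])]
    stop_trigmr("trigmr_collinear",
                "exposure effect matrix is rank deficient (offending: %s)",
                paste(bad, collapse = ", "))
  }
  w <- ivw_weights(instr)
  colnames(X) <- paste0("E", seq_len(K))
  fit <- suppressWarnings(stats::lm(instr$beta_outcome ~ 0 + X, weights = w))
  co <- stats::coef(fit)
  estimable <- which(!is.na(co))
  sigma2 <- max(1, sum(w * stats::residuals(fit)^2) / (m - length(estimable)))
  Xe <- X[, estimable, drop = FALSE]
  vc <- solve(crossprod(Xe, w * Xe)) * sigma2
  lapply(seq_len(K), function(k) {
    pos <- match(k, estimable)
    if (is.na(pos)) return(NULL)
    mr_result("mvmr_ivw", beta = co[[estimable[pos]]], se = sqrt(vc[pos, pos]),
              n_snps = m, exposure_label = instr$exposure_labels[k],
              outcome_label = instr$outcome_label)
  })
}
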