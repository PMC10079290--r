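#' Simulation parameters for synthetic two-sample GWAS summary statistics
#'
#' Bundles every knob of the generator. Defaults mirror the design the
#' pipeline targets: a strong-instrument continuous lipid exposure measured
#' in a large lipid-consortium GWAS (n about 3e5) and binary disease outcomes
#' from an independent biobank-scale cohort.
#'
#' @param m Number of instruments (SNPs).
#' @param theta True causal effect, log-OR of outcome per 1 SD exposure.
#' @param pi_pleio Fraction of SNPs with a direct (pleiotropic) effect.
#' @param mu_alpha Mean direct effect among pleiotropic SNPs (0 = balanced
#'   pleiotropy; non-zero = directional).
#' @param sigma_alpha SD of direct effects.
#' @param inside_violation_rho Correlation between instrument strength and
#'   direct effect; non-zero breaks the InSIDE assumption MR-Egger needs.
#' @param n_exposure,n_outcome Cohort sample sizes.
#' @param case_fraction Case proportion of the binary outcome cohort.
#' @param n_outliers Count of planted outlier SNPs; outliers always receive
#'   a direct effect, which is then inflated.
#' @param outlier_multiplier Factor inflating outlier direct effects.
#' @param ld_blocks,block_size,block_r2 Block LD structure for the matching
#'   reference panel: `ld_blocks * block_size` must equal `m` when a panel
#'   is generated. `NULL` `ld_blocks` means one SNP per block (no LD).
#' @param gamma_range Magnitude range of true SNP-exposure effects, drawn
#'   uniformly with random sign; the default (0.02-0.08 SD per allele) makes
#'   most instruments genome-wide significant at the default `n_exposure`.
#' @param seed RNG seed.
#'
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(m = 141, theta = 0, pi_pleio = 0, mu_alpha = 0,
                       sigma_alpha = 0.01, inside_violation_rho = 0,
                       n_exposure = 3e5, n_outcome = 1.7e5,
                       case_fraction = 0.5, n_outliers = 0,
                       outlier_multiplier = 1, ld_blocks = NULL,
                       block_size = 1, block_r2 = 0,
                       gamma_range = c(0.02, 0.08), seed = 1L) {
  p <- list(
    m = as.integer(m), theta = theta, pi_pleio = pi_pleio, mu_alpha = mu_alpha,
    sigma_alpha = sigma_alpha, inside_violation_rho = inside_violation_rho,
    n_exposure = n_exposure, n_outcome = n_outcome,
    case_fraction = case_fraction, n_outliers = as.integer(n_outliers),
    outlier_multiplier = outlier_multiplier,
    ld_blocks = if (is.null(ld_blocks)) as.integer(m) else as.integer(ld_blocks),
    block_size = as.integer(block_size), block_r2 = block_r2,
    gamma_range = gamma_range, seed = as.integer(seed)
  )
  if (p$m < 1) stop_trigmr("trigmr_param_error", "m must be >= 1")
  if (p$pi_pleio < 0 || p$pi_pleio > 1) {
    stop_trigmr("trigmr_param_error", "pi_pleio must be in [0, 1]")
  }
  if (p$n_outliers > p$m) stop_trigmr("trigmr_param_error", "n_outliers exceeds m")
  if (p$block_r2 < 0 || p$block_r2 > 1) {
    stop_trigmr("trigmr_param_error", "block_r2 must be in [0, 1]")
  }
  if (p$case_fraction <= 0 || p$case_fraction >= 1) {
    stop_trigmr("trigmr_param_error", "case_fraction must be in (0, 1)")
  }
  if (p$n_exposure <= 0 || p$n_outcome <= 0) {
    stop_trigmr("trigmr_param_error", "cohort sizes must be positive")
  }
  if (abs(p$inside_violation_rho) > 1) {
    stop_trigmr("trigmr_param_error", "inside_violation_rho must be in [-1, 1]")
  }
  if (length(p$gamma_range) != 2 || any(p$gamma_range <= 0) ||
      p$gamma_range[1] > p$gamma_range[2]) {
    stop_trigmr("trigmr_param_error", "gamma_range must be 0 < low <= high")
  }
  structure(p, class = "sim_params")
}

# SD of the +/-Uniform(a, b) effect magnitude distribution (mean is 0 by
# sign symmetry, so SD^2 = E[gamma^2]).
gamma_sd <- function(gamma_range) {
  a <- gamma_range[1]; b <- gamma_range[2]
  sqrt((b^3 - a^3) / (3 * (b - a)))
}

# Non-palindromic allele pairs, so default simulations survive
# harmonization without frequency-based strand resolution.
NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

# Shared SNP-level architecture: ids, positions (block-aware), alleles,
# allele frequencies, and true exposure effects.
simulate_architecture <- function(params) {
  m <- params$m
  blocks <- rep(seq_len(params$ld_blocks), length.out = m,
                each = ceiling(m / params$ld_blocks))[seq_len(m)]
  within <- stats::ave(seq_len(m), blocks, FUN = seq_along)
  f <- stats::runif(m, 0.05, 0.5)
  gamma <- sample(c(-1, 1), m, replace = TRUE) *
    stats::runif(m, params$gamma_range[1], params$gamma_range[2])
  pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), m, replace = TRUE), ,
                               drop = FALSE]
  list(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chrom = "1",
    # blocks 1 Mb apart (> 250 kb), SNPs 1 kb apart within a block (< 250 kb)
    pos = as.integer(blocks * 1e6 + within * 1000),
    block = blocks,
    effect_allele = pair[, 1],
    other_allele = pair[, 2],
    f = f,
    gamma = gamma
  )
}

# Direct (pleiotropic) effects alpha_j. Outlier SNPs are always given a
# direct effect before inflation so that outlier_multiplier bites.
simulate_alpha <- function(params, gamma) {
  m <- params$m
  alpha <- numeric(m)
  is_pleio <- stats::runif(m) < params$pi_pleio
  outlier_idx <- if (params$n_outliers > 0) sample.int(m, params$n_outliers) else integer(0)
  is_pleio[outlier_idx] <- TRUE
  k <- sum(is_pleio)
  if (k > 0) {
    mu <- params$mu_alpha + params$inside_violation_rho *
      (gamma[is_pleio] / gamma_sd(params$gamma_range)) * params$sigma_alpha
    alpha[is_pleio] <- stats::rnorm(k, mu, params$sigma_alpha)
  }
  alpha[outlier_idx] <- alpha[outlier_idx] * params$outlier_multiplier
  list(alpha = alpha, outlier_idx = outlier_idx)
}

exposure_se <- function(f, n) 1 / sqrt(n * 2 * f * (1 - f))
outcome_se <- function(f, n, case_fraction) {
  1 / sqrt(n * case_fraction * (1 - case_fraction) * 2 * f * (1 - f))
}

make_table <- function(arch, beta, se, n, trait_id, trait_type, cohort_label) {
  p <- two_sided_p(beta / se)
  sumstat_table(
    data.frame(
      snp_id = arch$snp_id, chrom = arch$chrom, pos = arch$pos,
      effect_allele = arch$effect_allele, other_allele = arch$other_allele,
      eaf = arch$f, beta = beta, se = se, pvalue = p, n = n,
      stringsAsFactors = FALSE
    ),
    trait_id = trait_id, trait_type = trait_type, cohort_label = cohort_label,
    validate = FALSE
  )
}

#' Simulate paired exposure/outcome summary statistics for two-sample MR
#'
#' Generates one continuous-exposure GWAS and one binary-outcome GWAS over
#' the same SNPs, drawn from non-overlapping cohorts (independent noise).
#' True SNP-outcome effects follow `Gamma_j = theta * gamma_j + alpha_j`
#' where `gamma_j` is the SNP-exposure effect and `alpha_j` a direct
#' pleiotropic effect, zero for valid instruments. Standard errors use the
#' standardised-trait approximations `se_X = 1/sqrt(n_X 2f(1-f))` and, on
#' the log-OR scale, `se_Y = 1/sqrt(n_Y phi(1-phi) 2f(1-f))` with case
#' fraction `phi`.
#'
#' @param params A [sim_params()] object.
#' @return List with `exposure` and `outcome` [sumstat_table()]s and
#'   `truth` (a `sim_truth` list: `theta`, `gamma`, `alpha`, `outlier_ids`,
#'   `seed`).
#' @export
simulate_two_sample <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    arch <- simulate_architecture(params)
    al <- simulate_alpha(params, arch$gamma)
    se_x <- exposure_se(arch$f, params$n_exposure)
    se_y <- outcome_se(arch$f, params$n_outcome, params$case_fraction)
    beta_x <- stats::rnorm(params$m, arch$gamma, se_x)
    big_gamma <- params$theta * arch$gamma + al$alpha
    beta_y <- stats::rnorm(params$m, big_gamma, se_y)
    list(
      exposure = make_table(arch, beta_x, se_x, params$n_exposure,
                            "TG", "continuous", "cohort_exposure"),
      outcome = make_table(arch, beta_y, se_y, params$n_outcome,
                           "outcome", "binary", "cohort_outcome"),
      truth = structure(
        list(theta = params$theta, gamma = arch$gamma, alpha = al$alpha,
             big_gamma = big_gamma,
             outlier_ids = arch$snp_id[al$outlier_idx], seed = params$seed),
        class = "sim_truth"
      )
    )
  })
}

#' Simulate a block-diagonal LD reference panel
#'
#' Within-block off-diagonal r2 equals `block_r2`, between-block r2 is 0,
#' diagonal is 1. Positions place within-block SNPs inside a 250 kb window
#' and blocks more than 250 kb apart, matching the clumping window
#' convention.
#'
#' @param params A [sim_params()]; `ld_blocks * block_size` must equal the
#'   number of SNPs.
#' @param snp_ids,chrom,pos SNP identifiers and coordinates, e.g. from a
#'   table produced by [simulate_two_sample()] under the same `params`.
#' @return An [ld_panel()].
#' @export
simulate_ld_panel <- function(params, snp_ids, chrom = NULL, pos = NULL) {
  m <- length(snp_ids)
  if (params$ld_blocks * params$block_size != m) {
    stop_trigmr("trigmr_param_error",
                "ld_blocks (%d) x block_size (%d) != number of SNPs (%d)",
                params$ld_blocks, params$block_size, m)
  }
  blocks <- rep(seq_len(params$ld_blocks), each = params$block_size)
  if (is.null(pos)) {
    within <- stats::ave(seq_len(m), blocks, FUN = seq_along)
    pos <- as.integer(blocks * 1e6 + within * 1000)
    chrom <- rep("1", m)
  }
  r2 <- outer(blocks, blocks, `==`) * params$block_r2
  diag(r2) <- 1
  ld_panel(snp_ids, chrom, pos, r2)
}

#' Simulate a phenome of outcomes across two cohorts
#'
#' Builds one exposure GWAS per cohort over a shared true SNP architecture
#' (same `gamma_j`, independent measurement noise) and, per outcome trait,
#' a discovery-cohort and a replication-cohort outcome GWAS sharing that
#' trait's causal effect. The first `k_causal` traits receive `theta` from
#' `params`; the rest are null. Per-trait seeds are derived
#' deterministically from the master seed.
#'
#' @param params A [sim_params()]; `params$theta` is the causal effect of
#'   the non-null traits.
#' @param k_outcomes Number of outcome traits.
#' @param k_causal Number of traits with a true causal effect
#'   (`k_causal <= k_outcomes`).
#' @param replication_frac Sample-size of the replication cohort relative
#'   to discovery (applied to both exposure and outcomes).
#' @param mappable Logical vector (recycled) marking traits testable in the
#'   replication cohort.
#' @return List with `exposure_discovery`, `exposure_replication`
#'   ([sumstat_table()]s), `manifest` (an [outcome_manifest()] holding the
#'   per-trait outcome tables) and `truth` (named list of `sim_truth`).
#' @export
simulate_phenome <- function(params, k_outcomes, k_causal,
                             replication_frac = 0.6, mappable = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (k_causal > k_outcomes) {
    stop_trigmr("trigmr_param_error", "k_causal exceeds k_outcomes")
  }
  mappable <- rep_len(mappable, k_outcomes)
  arch <- with_seed(derive_seed(params$seed, 0L), simulate_architecture(params))
  se_x_d <- exposure_se(arch$f, params$n_exposure)
  se_x_r <- exposure_se(arch$f, params$n_exposure * replication_frac)
  beta_x_d <- with_seed(derive_seed(params$seed, 1L),
                        stats::rnorm(params$m, arch$gamma, se_x_d))
  beta_x_r <- with_seed(derive_seed(params$seed, 2L),
                        stats::rnorm(params$m, arch$gamma, se_x_r))
  exposure_discovery <- make_table(arch, beta_x_d, se_x_d, params$n_exposure,
                                   "TG", "continuous", "cohort_discovery")
  exposure_replication <- make_table(arch, beta_x_r, se_x_r,
                                     params$n_exposure * replication_frac,
                                     "TG", "continuous", "cohort_replication")

  entries <- vector("list", k_outcomes)
  truth <- vector("list", k_outcomes)
  n_out_r <- params$n_outcome * replication_frac
  se_y_d <- outcome_se(arch$f, params$n_outcome, params$case_fraction)
  se_y_r <- outcome_se(arch$f, n_out_r, params$case_fraction)
  for (t in seq_len(k_outcomes)) {
    id <- sprintf("trait%03d", t)
    theta_t <- if (t <= k_causal) params$theta else 0
    tr <- with_seed(derive_seed(params$seed, t, 1L), {
      al <- simulate_alpha(params, arch$gamma)
      list(alpha = al$alpha, outlier_idx = al$outlier_idx)
    })
    big_gamma <- theta_t * arch$gamma + tr$alpha
    beta_y_d <- with_seed(derive_seed(params$seed, t, 2L),
                          stats::rnorm(params$m, big_gamma, se_y_d))
    beta_y_r <- with_seed(derive_seed(params$seed, t, 3L),
                          stats::rnorm(params$m, big_gamma, se_y_r))
    entries[[t]] <- list(
      trait_id = id,
      discovery = make_table(arch, beta_y_d, se_y_d, params$n_outcome,
                             id, "binary", "cohort_discovery"),
      replication = if (mappable[t]) {
        make_table(arch, beta_y_r, se_y_r, n_out_r, id, "binary",
                   "cohort_replication")
      },
      trait_type = "binary",
      mappable = mappable[t]
    )
    truth[[t]] <- structure(
      list(theta = theta_t, gamma = arch$gamma, alpha = tr$alpha,
           big_gamma = big_gamma, outlier_ids = arch$snp_id[tr$outlier_idx],
           seed = params$seed),
      class = "sim_truth"
    )
    names(truth)[t] <- id
  }
  list(
    exposure_discovery = exposure_discovery,
    exposure_replication = exposure_replication,
    manifest = outcome_manifest(entries),
    truth = truth
  )
}
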