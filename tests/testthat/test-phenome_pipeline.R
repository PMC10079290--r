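test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 2600), 3), 1.92e-5)
  expect_equal(signif(bonferroni_threshold(0.05, 221), 3), 2.26e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0, 10), class = "trigmr_param_error")
  expect_error(bonferroni_threshold(0.05, 0), class = "trigmr_param_error")
})

test_that("all nine significance combinations map to the documented tiers", {
  thr_d <- 1.92e-5
  thr_r <- 2.26e-4
  # representative p-values: below Bonferroni, nominal-only, not significant
  p_d <- c(B = 1e-6, N = 1e-3, x = 0.2)
  p_r <- c(B = 1e-5, N = 1e-2, x = 0.5)
  want <- matrix(c(
    "BB", "BN", "none",
    "NB", "none", "none",
    "none", "none", "none"
  ), nrow = 3, byrow = TRUE, dimnames = list(names(p_d), names(p_r)))
  for (i in names(p_d)) {
    for (j in names(p_r)) {
      disc <- data.frame(trait_id = "t", beta = 0.1, pvalue = p_d[[i]],
                         status = "ok")
      repl <- data.frame(trait_id = "t", beta = 0.1, pvalue = p_r[[j]],
                         status = "ok")
      tc <- assign_tiers(disc, repl, 2600, 221)
      expect_identical(tc$tier, want[i, j])
    }
  }
  # traits never replicated get tier none
  disc <- data.frame(trait_id = "t", beta = 0.1, pvalue = 1e-8, status = "ok")
  tc <- assign_tiers(disc, data.frame(), 2600, 221)
  expect_identical(tc$tier, "none")
})

test_that("discovery ranks true causal traits first and isolates failures", {
  ph <- simulate_phenome(sim_params(m = 30, theta = 0.5, seed = 71),
                         k_outcomes = 10, k_causal = 3)
  d <- run_discovery(ph$exposure_discovery, ph$manifest)
  top3 <- d$results$trait_id[1:3]
  expect_setequal(top3, c("trait001", "trait002", "trait003"))

  d2 <- run_discovery(ph$exposure_discovery, ph$manifest)
  expect_identical(d$results, d2$results)

  broken <- unclass(ph$manifest)
  broken[["trait005"]]$discovery <- "/nonexistent/file.tsv"
  broken <- outcome_manifest(unname(broken))
  d3 <- run_discovery(ph$exposure_discovery, broken)
  skipped <- d3$results[d3$results$status == "skipped", ]
  expect_equal(skipped$trait_id, "trait005")
  expect_match(skipped$reason, "not found")
  expect_equal(sum(d3$results$status == "ok"), 9)
})

test_that("manifest entries may point at files on disk", {
  ph <- simulate_phenome(sim_params(m = 15, theta = 0.4, seed = 73),
                         k_outcomes = 2, k_causal = 1)
  dir <- withr::local_tempdir()
  entries <- lapply(ph$manifest, function(e) {
    path <- file.path(dir, paste0(e$trait_id, ".tsv"))
    write_sumstats(e$discovery, path)
    e$discovery <- path
    e
  })
  d_file <- run_discovery(ph$exposure_discovery, outcome_manifest(unname(entries)))
  d_mem <- run_discovery(ph$exposure_discovery, ph$manifest)
  expect_equal(d_file$results$beta, d_mem$results$beta, tolerance = 1e-9)
})

test_that("replication tests only nominal, mappable traits with swapped instruments", {
  ph <- simulate_phenome(sim_params(m = 30, theta = 0.5, seed = 79),
                         k_outcomes = 6, k_causal = 2,
                         mappable = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  d <- run_discovery(ph$exposure_discovery, ph$manifest)
  r <- run_replication(ph$exposure_replication, d$results, ph$manifest)
  nominal <- d$results$trait_id[d$results$pvalue < 0.05]
  expect_true(all(r$results$trait_id %in% nominal))
  expect_false("trait002" %in% r$results$trait_id)
  expect_equal(r$n_unmappable, sum(nominal == "trait002"))

  # p above nominal is excluded even if mappable
  fake_disc <- d$results
  fake_disc$pvalue[fake_disc$trait_id == "trait003"] <- 0.06
  r2 <- run_replication(ph$exposure_replication, fake_disc, ph$manifest)
  expect_false("trait003" %in% r2$results$trait_id)

  none <- d$results
  none$pvalue <- 0.5
  expect_warning(r3 <- run_replication(ph$exposure_replication, none, ph$manifest),
                 "no traits eligible")
  expect_equal(nrow(r3$results), 0)
})

test_that("strong causal traits replicate at the Bonferroni level", {
  ok <- 0L
  for (s in 1:5) {
    ph <- simulate_phenome(sim_params(m = 40, theta = 0.6, seed = 900 + s),
                           k_outcomes = 5, k_causal = 2)
    d <- run_discovery(ph$exposure_discovery, ph$manifest)
    r <- run_replication(ph$exposure_replication, d$results, ph$manifest)
    tc <- assign_tiers(d$results, r$results, 5, r$n_tested)
    causal <- tc[tc$trait_id %in% c("trait001", "trait002"), ]
    ok <- ok + all(causal$tier == "BB")
  }
  expect_gte(ok, 3)
})

test_that("sensitivity bundles run on tiered traits only, refitting when triggered", {
  ph <- simulate_phenome(sim_params(m = 30, theta = 0.5, seed = 83),
                         k_outcomes = 4, k_causal = 2)
  d <- run_discovery(ph$exposure_discovery, ph$manifest)
  r <- run_replication(ph$exposure_replication, d$results, ph$manifest)
  tc <- assign_tiers(d$results, r$results, 4, r$n_tested)
  sens <- run_sensitivity(tc, d$sets, mr_config(seed = 2))
  tiered <- tc$trait_id[tc$tier != "none"]
  expect_setequal(names(sens), tiered)
  for (id in names(sens)) {
    b <- sens[[id]]
    expect_null(b$error)
    expect_s3_class(b$egger$slope, "mr_result")
    expect_s3_class(b$weighted_median, "mr_result")
    if (b$presso$global_p >= 0.05) expect_null(b$presso$refit)
  }
  # rerunning with the same config reproduces the seeded estimators
  sens2 <- run_sensitivity(tc, d$sets, mr_config(seed = 2))
  for (id in names(sens)) {
    expect_equal(sens[[id]]$weighted_median$se, sens2[[id]]$weighted_median$se)
    expect_equal(sens[[id]]$presso$global_p, sens2[[id]]$presso$global_p)
  }
})

test_that("outlier refits move tiered estimates toward the truth", {
  improved <- 0L
  tested <- 0L
  for (s in 1:10) {
    p <- sim_params(m = 50, theta = 0.3, n_outliers = 1, mu_alpha = 0.01,
                    sigma_alpha = 0.001, outlier_multiplier = 10, seed = 3000 + s)
    sim <- simulate_two_sample(p)
    set <- harmonize(sim$exposure, sim$outcome)
    res <- presso_outlier(set, n_sim = 1000, seed = s)
    if (is.null(res$refit)) next
    tested <- tested + 1L
    pre <- ivw_fixed(set)$beta
    improved <- improved +
      (abs(res$refit$beta - 0.3) < abs(pre - 0.3))
  }
  expect_gte(tested, 5)
  expect_gt(improved / tested, 0.5)
})

test_that("the MVMR pass fits the four lipid models per tiered trait", {
  p <- sim_params(m = 30, theta = 0.5, seed = 89)
  ph <- simulate_phenome(p, k_outcomes = 3, k_causal = 2)
  d <- run_discovery(ph$exposure_discovery, ph$manifest)
  r <- run_replication(ph$exposure_replication, d$results, ph$manifest)
  tc <- assign_tiers(d$results, r$results, 3, r$n_tested)

  # co-exposures with their own SNP effects but no effect on the outcome
  make_co <- function(label, seed) {
    sim <- simulate_two_sample(sim_params(m = 30, theta = 0, seed = seed))
    df <- as.data.frame(ph$exposure_discovery)
    co_eff <- simulate_two_sample(sim_params(m = 30, theta = 0, seed = seed))
    df$beta <- co_eff$exposure$beta
    sumstat_table(df, label)
  }
  co <- list(LDL = make_co("LDL", 11), HDL = make_co("HDL", 12),
             ApoB = make_co("ApoB", 13))
  outcome_tables <- lapply(ph$manifest, function(e) e$discovery)
  mv <- run_mvmr_pass(tc, ph$exposure_discovery, co, outcome_tables,
                      mr_config())
  tiered <- tc$trait_id[tc$tier != "none"]
  expect_setequal(names(mv), tiered)
  for (id in names(mv)) {
    expect_named(mv[[id]], c("TG_LDL", "TG_HDL", "TG_HDL_LDL", "TG_HDL_LDL_ApoB"))
    uni_beta <- tc$beta_discovery[tc$trait_id == id]
    for (mn in names(mv[[id]])) {
      fit <- mv[[id]][[mn]]
      expect_null(fit$error)
      # null co-exposures: TG direct effect stays within its own CI of the
      # univariable estimate
      tg <- fit$fits[[1]]
      expect_true(uni_beta > tg$beta - 3 * tg$se && uni_beta < tg$beta + 3 * tg$se)
      expect_true(isTRUE(fit$direction_concordant))
    }
  }

  # a duplicated exposure column fails only that trait/model
  co_dup <- co
  co_dup$ApoB <- co$LDL
  co_dup$ApoB <- sumstat_table(
    transform(as.data.frame(co$LDL)), "ApoB")
  mv2 <- run_mvmr_pass(tc, ph$exposure_discovery, co_dup, outcome_tables,
                       mr_config())
  for (id in names(mv2)) {
    expect_match(mv2[[id]]$TG_HDL_LDL_ApoB$error, "rank deficient")
    expect_null(mv2[[id]]$TG_LDL$error)
  }
})

test_that("a confounded outcome shrinks the primary MVMR effect toward zero", {
  shrunk <- 0L
  for (s in 1:10) {
    set.seed(6000 + s)
    m <- 40
    f <- runif(m, 0.05, 0.5)
    g_tg <- sample(c(-1, 1), m, TRUE) * runif(m, 0.02, 0.08)
    g_co <- 0.6 * g_tg + sqrt(1 - 0.6^2) *
      sample(c(-1, 1), m, TRUE) * runif(m, 0.02, 0.08)
    se_x <- 1 / sqrt(3e5 * 2 * f * (1 - f))
    se_y <- 1 / sqrt(1.7e5 * 0.25 * 2 * f * (1 - f))
    bx_tg <- rnorm(m, g_tg, se_x)
    bx_co <- rnorm(m, g_co, se_x)
    by <- rnorm(m, 0.4 * g_co, se_y) # outcome depends only on the co-exposure
    uni <- ivw_fixed(instrument_set(sprintf("rs%02d", 1:m), bx_tg, se_x, by, se_y))
    mv <- mvmr_ivw(instrument_set(sprintf("rs%02d", 1:m), cbind(bx_tg, bx_co),
                                  cbind(se_x, se_x), by, se_y,
                                  exposure_labels = c("TG", "co")))
    shrunk <- shrunk + (abs(mv[[1]]$beta) < abs(uni$beta))
  }
  expect_gt(shrunk, 5)
})

test_that("reverse MR swaps roles and reports untestable diseases", {
  # a disease with genome-wide instruments and a true effect on the lipid
  p <- sim_params(m = 25, theta = 0.2, seed = 97)
  sim <- simulate_two_sample(p)
  panel <- simulate_ld_panel(p, sim$exposure$snp_id, sim$exposure$chrom,
                             sim$exposure$pos)
  rev <- run_reverse(sim$exposure, sim$outcome, panel)
  expect_equal(rev$status, "ok")
  expect_gt(rev$n_instruments, 1)
  expect_true(rev$result$ci_low < 0.2 + 0.1 && rev$result$ci_high > 0.2 - 0.1)

  # no genetic effect on the lipid: the CI should usually cover zero
  covered <- 0L
  for (s in 1:10) {
    ps <- sim_params(m = 25, theta = 0, seed = 7000 + s)
    sims <- simulate_two_sample(ps)
    panels <- simulate_ld_panel(ps, sims$exposure$snp_id, sims$exposure$chrom,
                                sims$exposure$pos)
    rv <- run_reverse(sims$exposure, sims$outcome, panels)
    covered <- covered + (rv$result$ci_low < 0 && rv$result$ci_high > 0)
  }
  expect_gt(covered, 5)

  # one significant SNP only: not testable
  df <- snp_frame(5, pvalue = c(1e-10, 0.5, 0.4, 0.3, 0.2),
                  pos = c(1e5L, 2e6L, 4e6L, 6e6L, 8e6L))
  disease <- sumstat_table(df, "disease", "binary")
  lipid <- sumstat_table(snp_frame(5, pos = df$pos, beta = 0.02), "TG")
  panel1 <- ld_panel(df$snp_id, df$chrom, df$pos, diag(5))
  nt <- run_reverse(disease, lipid, panel1)
  expect_equal(nt$status, "not_testable")
  expect_match(nt$reason, "instrument")
})
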