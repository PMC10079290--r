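# Builders -------------------------------------------------------------

# One base constant feeds every Monte-Carlo seed stream in the suite, via
# the package's own deterministic stream derivation.
acc_seed <- function(block, s) trigmr:::derive_seed(20260922L, block, s)

# Minimal valid SNP record frame; override any column.
snp_frame <- function(n = 3, ...) {
  df <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1e6L,
    effect_allele = "A",
    other_allele = "G",
    eaf = 0.3,
    beta = 0.05,
    se = 0.01,
    pvalue = 1e-9,
    n = 1e5,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

toy_table <- function(n = 3, trait_id = "trait", trait_type = "continuous", ...) {
  sumstat_table(snp_frame(n, ...), trait_id = trait_id, trait_type = trait_type)
}

toy_instruments <- function(bx, by, sx = rep(0.01, length(bx)),
                            sy = rep(0.1, length(bx))) {
  instrument_set(sprintf("rs%03d", seq_along(bx)), bx, sx, by, sy)
}

# Independent oracles ---------------------------------------------------

# Weighted least squares by hand-solved normal equations (X'WX) b = X'Wy,
# elementwise accumulation, no lm/solve shortcuts beyond the K x K solve.
oracle_wls <- function(X, y, w, floor_sigma2 = TRUE) {
  X <- as.matrix(X)
  K <- ncol(X)
  A <- matrix(0, K, K)
  b <- numeric(K)
  for (j in seq_along(y)) {
    xj <- X[j, ]
    A <- A + w[j] * tcrossprod(xj)
    b <- b + w[j] * xj * y[j]
  }
  beta <- solve(A, b)
  res <- y - as.numeric(X %*% beta)
  df <- length(y) - K
  sigma2 <- if (df > 0) sum(w * res^2) / df else NA_real_
  if (floor_sigma2 && !is.na(sigma2)) sigma2 <- max(1, sigma2)
  list(beta = beta, se = sqrt(diag(solve(A)) * (if (is.na(sigma2)) 1 else sigma2)),
       se_fixed = sqrt(diag(solve(A))))
}

# Weighted 50th percentile by explicit cumulative-weight scan.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- 0
  prev_cum <- 0
  for (j in seq_along(r)) {
    pj <- sum(w[seq_len(j)]) - w[j] / 2
    if (pj >= 0.5) {
      if (j == 1) return(r[1])
      pprev <- sum(w[seq_len(j - 1)]) - w[j - 1] / 2
      return(r[j - 1] + (r[j] - r[j - 1]) * (0.5 - pprev) / (pj - pprev))
    }
  }
  r[length(r)]
}

# Brute-force greedy clump over explicit loops, mirroring the stated
# ordering rules (ascending p, lexicographic snp_id ties).
oracle_clump <- function(df, r2, params) {
  candidates <- df[order(df$pvalue, df$snp_id), , drop = FALSE]
  candidates <- candidates[candidates$pvalue < params$p1, , drop = FALSE]
  removed <- character(0)
  index <- character(0)
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$snp_id[i]
    if (id %in% removed) next
    index <- c(index, id)
    row_i <- df[df$snp_id == id, ]
    for (j in seq_len(nrow(df))) {
      other <- df$snp_id[j]
      if (other == id || other %in% index || other %in% removed) next
      if (df$pvalue[j] >= params$p2) next
      if (df$chrom[j] != row_i$chrom) next
      if (abs(df$pos[j] - row_i$pos) > params$kb_window * 1000) next
      if (r2[id, other] < params$r2_threshold) next
      removed <- c(removed, other)
    }
  }
  sort(index)
}

# Random clumping instance over a line of SNPs with a valid random r2
# matrix (pairwise values, symmetrized, unit diagonal).
random_clump_instance <- function(m = 20, seed = 1) {
  set.seed(seed)
  df <- snp_frame(m,
    pos = sort(sample.int(2e6, m)),
    pvalue = 10^stats::runif(m, -12, -2)
  )
  r2 <- matrix(stats::runif(m * m), m, m)
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(df$snp_id, df$snp_id)
  list(df = df, r2 = r2)
}
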