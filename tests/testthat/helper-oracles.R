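# Independent oracles and small fixture builders used across the suite.

# Brute-force posture-change counter: scans every adjacent pair against the
# literal transition definitions, independent of the package's rle-based path.
oracle_counts <- function(p) {
  pc <- 0L; risk <- 0L; stopn <- 0L
  risky <- list(c("ST", "LL"), c("ST", "LLU"), c("ST", "SL"),
                c("SL", "LL"), c("SL", "LLU"))
  for (i in seq_len(length(p) - 1L)) {
    if (p[i] != p[i + 1L]) {
      pc <- pc + 1L
      for (r in risky) if (p[i] == r[1] && p[i + 1L] == r[2]) risk <- risk + 1L
      if (p[i] == "LLU") stopn <- stopn + 1L
    }
  }
  c(PCAll = pc, PCRiskCrush = risk, PCStopNurse = stopn)
}

# Hand-written Cox partial log-likelihood (Breslow form; exact = Efron when
# there are no tied event times), single covariate.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1L)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Two-stage grid search maximizer of the partial likelihood.
oracle_cox_grid <- function(time, event, x, lim = 6, coarse = 1e-2,
                            fine = 1e-5) {
  grid <- seq(-lim, lim, by = coarse)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time, event, x)
  b0 <- grid[which.max(ll)]
  grid2 <- seq(b0 - coarse, b0 + coarse, by = fine)
  ll2 <- vapply(grid2, oracle_cox_loglik, numeric(1), time, event, x)
  grid2[which.max(ll2)]
}

# Adjusted Rand index between two labelings (closed-form contingency version).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expected <- si * sj / comb2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Random posture stream of length n (raw six-posture vocabulary).
random_stream_vec <- function(n, vocab = sowactivity::POSTURES) {
  sample(vocab, n, replace = TRUE)
}

# Minimal piglet-level frame with independent survival outcome and a
# dam-level covariate, for selection operating-characteristic checks.
toy_piglet_frame <- function(n_dams, per_litter, hazard = 0.01,
                             beta = 0, covariate = NULL, days = 28L) {
  if (is.null(covariate)) covariate <- rnorm(n_dams)
  dam <- rep(seq_len(n_dams), each = per_litter)
  n <- length(dam)
  lp <- beta * (covariate[dam] - mean(covariate))
  h <- pmin(hazard * exp(lp), 0.99)
  u <- matrix(runif(n * days), n, days)
  first <- apply(u < h, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
  data.frame(
    piglet_id = seq_len(n), dam_id = sprintf("d%03d", dam),
    genetic_type = factor(sample(c("LW/LW", "LW/MS", "MS/LW", "MS/MS"), n, TRUE)),
    litter_class = factor(sample(c("I", "M", "S"), n, TRUE),
                          levels = c("I", "M", "S")),
    pen = factor(sample(c("A", "B", "C", "D"), n, TRUE)),
    x = covariate[dam],
    time = ifelse(is.na(first), days, first),
    event = as.integer(!is.na(first)))
}

tiny_config <- function(...) sowactivity::sim_config(n_sows = 3L, ...)
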