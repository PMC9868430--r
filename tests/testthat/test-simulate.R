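test_that("configuration validation rejects malformed inputs", {
  expect_error(sim_config(stationary = list(bf = c(1, 1, 1, 1, 1, 1) / 6,
                                            df = rep(1 / 6, 6),
                                            af = c(0.5, 0.5, 0, 0, 0, 0.2))),
               "closed")
  expect_error(sim_config(noise_rate = 1.2), "noise_rate")
  expect_error(sim_config(litter_size_range = c(5, 2)), "litter_size_range")
  expect_error(sim_config(baseline_hazard = c(0.1, -0.2)), "baseline_hazard")
  cfg <- sim_config()
  for (Q in cfg$posture_rates) {
    expect_true(all(Q >= 0))
    expect_equal(unname(diag(Q)), rep(0, 6))
  }
  expect_equal(sum(cfg$restlessness_multiplier[c("-3", "-2", "-1")]) / 3, 1,
               tolerance = 1e-12)
  # a tampered rate matrix is caught at simulation time
  cfg$posture_rates$bf[1, 2] <- -1
  pr <- sow_profiles(cfg)
  expect_error(simulate_posture_stream(cfg, pr[1, ]), "negative")
})

test_that("the exchange process has the requested stationary budget and pace", {
  pi <- c(ST = 0.2, SI = 0.05, K = 0.05, SL = 0.1, LL = 0.3, LLU = 0.3)
  Q <- exchange_rate_matrix(pi, 12)
  expect_equal(unname(diag(Q)), rep(0, 6))
  expect_equal(Q[2, 1], 12 * 0.2)
  # detailed balance of the uniformized chain: pi_i q_ij = pi_j q_ji
  for (i in 1:6) for (j in 1:6) {
    expect_equal(unname(pi[i] * Q[i, j]), unname(pi[j] * Q[j, i]),
                 tolerance = 1e-12)
  }
})

test_that("streams are deterministic given seed and sow, and distinct across sows", {
  cfg <- sim_config(n_sows = 2, days = 0:1, seed = 31)
  pr <- sow_profiles(cfg)
  s1 <- simulate_posture_stream(cfg, pr[1, ])
  s2 <- simulate_posture_stream(cfg, pr[1, ])
  expect_identical(s1, s2)
  expect_false(identical(simulate_posture_stream(cfg, pr[2, ])$posture,
                         s1$posture))
  # one tick per 5 s
  expect_equal(nrow(s1), 2 * 17280)
  expect_equal(s1$tick[1:3], 0:2)
})

test_that("adding sows does not perturb existing sow streams", {
  cfg_small <- sim_config(n_sows = 2, days = 0:0, seed = 9)
  cfg_big <- sim_config(n_sows = 5, days = 0:0, seed = 9)
  p_small <- sow_profiles(cfg_small)
  p_big <- sow_profiles(cfg_big)
  expect_identical(
    simulate_posture_stream(cfg_small, p_small[1, ])$posture,
    simulate_posture_stream(cfg_big, p_big[1, ])$posture)
})

test_that("an all-zero rate process is absorbing", {
  cfg <- sim_config(n_sows = 1, seed = 5,
                    pcall_target = setNames(rep(0, 11), -3:7))
  pr <- sow_profiles(cfg)
  s <- simulate_posture_stream(cfg, pr[1, ])
  expect_equal(nrow(s), 11 * 17280)
  expect_equal(length(unique(s$posture)), 1L)
  b <- daily_postural_budget(s[s$day == 0, ])
  expect_equal(max(b), 1)
})

test_that("label noise is Bernoulli per tick and leaves the input untouched", {
  cfg <- sim_config(n_sows = 1, days = 0:0, seed = 2)
  s <- simulate_posture_stream(cfg, sow_profiles(cfg)[1, ])
  expect_identical(inject_label_noise(s, 0, seed = 4), s)

  two <- posture_stream("a", 0, c("LL", "LL"))
  noised <- inject_label_noise(two, 1, seed = 4)
  expect_true(all(noised$posture != "LL"))

  n1 <- inject_label_noise(s, 0.01, seed = 7)
  changed <- sum(n1$posture != s$posture)
  expect_lt(abs(changed - 172.8), 3 * sqrt(17280 * 0.01 * 0.99))
  # activity constraint survives noising
  expect_true(all(is.na(n1$activity[n1$posture != "ST"])))
  expect_true(all(!is.na(n1$activity[n1$posture == "ST"])))
  # reproducible
  expect_identical(inject_label_noise(s, 0.01, seed = 7), n1)
})

test_that("cohorts are reproducible, closed and sized as configured", {
  cfg <- sim_config(n_sows = 3, seed = 11)
  c1 <- build_cohort(cfg, return_streams = FALSE)
  c2 <- build_cohort(cfg, return_streams = FALSE)
  expect_identical(c1$traits, c2$traits)
  expect_identical(c1$piglets, c2$piglets)
  expect_equal(nrow(c1$traits), 3 * 11)
  expect_equal(sum(c1$traits$total_ticks), 3 * 11 * 17280)
  pcols <- paste0("p_", MERGED_POSTURES)
  expect_true(all(abs(rowSums(c1$traits[, pcols]) - 1) < 1e-12))
  expect_true(all(c1$piglets$litter_size >= 12 & c1$piglets$litter_size <= 21))
  expect_true(all(c1$piglets$time > 0))

  empty <- build_cohort(sim_config(n_sows = 0))
  expect_equal(nrow(empty$traits), 0L)
  expect_equal(nrow(empty$piglets), 0L)
})

test_that("whole sow-days are dropped at the configured missingness rate", {
  cfg <- sim_config(n_sows = 4, seed = 3, missing_rate = 0.25)
  coh <- build_cohort(cfg, return_streams = FALSE)
  n_days <- 4 * 11
  expect_equal(nrow(coh$traits) + coh$dropped_days, n_days)
  expect_lt(abs(coh$dropped_days - 0.25 * n_days),
            3 * sqrt(n_days * 0.25 * 0.75) + 1)
})

test_that("null survival and growth generators behave as configured", {
  cfg <- sim_config(n_sows = 3, seed = 21,
                    survival_betas = c(PCAll_af100 = 0),
                    baseline_hazard = rep(0, 28))
  coh <- build_cohort(cfg, return_streams = FALSE)
  expect_true(all(coh$piglets$event == 0L))
  expect_true(all(coh$piglets$time == 28))
  expect_true(all(is.na(coh$piglets$cause)))
  # ADG is exactly (D7 - birth) / 7 for survivors
  expect_equal(compute_adg(coh$piglets),
               (coh$piglets$weight_d7 - coh$piglets$birth_weight) / 7)

  bad <- sim_config(n_sows = 3, seed = 21,
                    survival_betas = c(not_a_trait = 1))
  expect_error(build_cohort(bad, return_streams = FALSE), "unknown sow trait")
})

test_that("doubling a planted log-hazard doubles the recovered log-HR", {
  make_cov <- function(n) {
    set.seed(402)
    data.frame(sow_id = sprintf("s%03d", 1:n),
               breed = sample(c("LW", "MS"), n, TRUE),
               pen = sample(LETTERS[1:4], n, TRUE),
               PCAll_af = rnorm(n, 250, 120),
               PCAll_bf = rnorm(n, 330, 120),
               PCStopNurse_df = rnorm(n, 75, 30),
               PCStopNurse_af = rnorm(n, 67, 30))
  }
  cov <- make_cov(400)
  fit_beta <- function(beta) {
    cfg <- sim_config(n_sows = 400, seed = 77,
                      survival_betas = c(PCAll_af100 = beta),
                      growth = utils::modifyList(sim_config()$growth,
                                                 list(effects = c(PCAll_bf = 0))))
    pig <- simulate_litters(cfg, cov)
    d <- merge(pig, cov, by.x = "dam_id", by.y = "sow_id")
    d$x <- d$PCAll_af / 100
    cox_fit(d, "x")$coefficients$estimate
  }
  b1 <- fit_beta(-0.3)
  b2 <- fit_beta(-0.6)
  expect_equal(b1, -0.3, tolerance = 0.12)
  expect_equal(b2 / b1, 2, tolerance = 0.25)
})
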