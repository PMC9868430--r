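test_that("a strong linear effect is screened in with continuous coding", {
  set.seed(101)
  cand <- list(list(name = "trait", column = "x", kind = "count",
                    raw_traits = character(0)))
  wins <- 0L; kept <- 0L; reps <- 60L
  for (r in seq_len(reps)) {
    d <- toy_piglet_frame(50, 10, hazard = 0.012, beta = -0.6)
    s <- screen_step1(d, cand, "cox", period = "af")
    if (length(s$selected)) {
      kept <- kept + 1L
      if (s$selected[[1]]$coding == "continuous") wins <- wins + 1L
    }
  }
  expect_equal(kept, reps)          # the effect is essentially always found
  expect_gte(wins / reps, 0.9)      # and the true (continuous) coding wins
})

test_that("cluster items can be replaced by the raw trait that drives them", {
  set.seed(111)
  # the cluster label is a noisy discretization of a raw trait that carries
  # the whole effect: the raw trait should win the AIC comparison
  n_dams <- 60
  raw <- rnorm(n_dams)
  clus <- factor(ifelse(raw + rnorm(n_dams, 0, 0.6) > 0, "A", "B"))
  d <- toy_piglet_frame(n_dams, 12, hazard = 0.012, beta = -0.7,
                        covariate = raw)
  d$llu_h_af <- d$x
  d$post_cl_af <- clus[as.integer(factor(d$dam_id))]
  cand <- list(list(name = "postural_pattern_af", column = "post_cl_af",
                    kind = "cluster", raw_traits = "llu_h_af"))
  s <- screen_step1(d, cand, "cox", period = "af")
  expect_equal(length(s$selected), 1L)
  expect_equal(s$selected[[1]]$column, "llu_h_af")
  expect_equal(s$selected[[1]]$coding, "raw_trait")
  expect_true(any(s$trace$action == "raw-trait comparison"))
})

test_that("backward elimination keeps planted terms and sheds noise", {
  set.seed(121)
  d <- toy_piglet_frame(120, 12, hazard = 0.012, beta = -0.6)
  d$noise1 <- rnorm(120)[as.integer(factor(d$dam_id))]
  d$noise2 <- rnorm(120)[as.integer(factor(d$dam_id))]
  s2 <- reduce_step2(d, c("x", "noise1", "noise2"), "cox", period = "af")
  expect_true("x" %in% s2$terms)
  expect_false("noise1" %in% s2$terms && "noise2" %in% s2$terms)
  expect_true(all(c("step", "variable", "decision") %in% names(s2$trace)))
})

test_that("all-noise saturated models usually reduce to the fixed effects", {
  set.seed(131)
  empties <- 0L; retained <- 0L; reps <- 25L
  for (r in seq_len(reps)) {
    d <- toy_piglet_frame(60, 10, hazard = 0.015, beta = 0)
    d$n1 <- rnorm(60)[as.integer(factor(d$dam_id))]
    d$n2 <- rnorm(60)[as.integer(factor(d$dam_id))]
    s2 <- reduce_step2(d, c("x", "n1", "n2"), "cox", period = "af")
    retained <- retained + length(s2$terms)
    if (!length(s2$terms)) empties <- empties + 1L
  }
  expect_gte(empties / reps, 0.6)
  expect_lte(retained / reps, 0.6)
})

test_that("the global step drops collinear cross-period duplicates and records it", {
  set.seed(141)
  d <- toy_piglet_frame(80, 12, hazard = 0.012, beta = -0.6)
  d$x_copy <- d$x
  s3 <- global_step3(d, list(bf = "x", af = "x_copy"), "cox")
  expect_equal(length(s3$terms), 1L)
  expect_true(any(grepl("collinear", s3$trace$decision)))
})

test_that("the growth fitter is ordinary least squares", {
  # ten-row design checked against a hand-written normal-equations solve
  set.seed(151)
  d <- data.frame(adg = rnorm(10, 150, 20), x = rnorm(10),
                  g = factor(rep(c("a", "b"), 5)))
  fit <- sowactivity:::.fit_raw("lm", d, c("g", "x"))$fit
  X <- cbind(1, as.numeric(d$g == "b"), d$x)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$adg)
  expect_equal(unname(coef(fit)), as.vector(beta_hat), tolerance = 1e-10)
})

test_that("growth selection recovers a planted S-class effect within 2 SE", {
  set.seed(161)
  n_dams <- 90; per <- 12
  dam <- rep(seq_len(n_dams), each = per)
  trait <- rnorm(n_dams, 250, 100)
  cls <- tertile_categorize(trait)
  adg <- 200 - 40 * (cls[dam] == "S") + rnorm(n_dams * per, 0, 50)
  d <- data.frame(
    dam_id = sprintf("d%03d", dam),
    genetic_type = factor(sample(c("LW/LW", "LW/MS"), n_dams * per, TRUE)),
    litter_class = factor(sample(c("I", "M", "S"), n_dams * per, TRUE),
                          levels = c("I", "M", "S")),
    pen = factor(sample(LETTERS[1:4], n_dams * per, TRUE)),
    PCAll_af100 = trait[dam] / 100, adg = adg,
    time = 28, event = 0L)
  cand <- list(list(name = "PCAll_af", column = "PCAll_af100",
                    kind = "count", raw_traits = character(0)))
  s <- screen_step1(d, cand, "lm", period = "af")
  expect_equal(length(s$selected), 1L)
  expect_equal(s$selected[[1]]$coding, "S_vs_MI")
  col <- s$selected[[1]]$column
  fit <- sowactivity:::.fit_raw("lm", s$data, c("genetic_type",
                                                "litter_class", "pen", col))
  est <- coef(fit$fit)[[paste0(col, "S")]]
  se <- sqrt(diag(vcov(fit$fit)))[[paste0(col, "S")]]
  expect_lt(abs(est - (-40)), 2 * se)
})

test_that("selection traces replay to the recorded final model", {
  set.seed(171)
  cfg <- sim_config(n_sows = 10, seed = 19)
  coh <- build_cohort(cfg, return_streams = FALSE)
  d <- prepare_association_data(coh)
  res <- three_step_selection(d, "survival")
  refit <- replay_selection(res)
  expect_equal(sort(names(coef(refit))),
               sort(res$final$coefficients$term))
  expect_equal(coef(refit)[res$final$coefficients$term],
               setNames(res$final$coefficients$estimate,
                        res$final$coefficients$term),
               tolerance = 1e-10)
  expect_true(all(res$trace$step %in% 1:3))
})
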