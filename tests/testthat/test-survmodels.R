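test_that("average daily gain is weight gain over seven days", {
  d <- data.frame(birth_weight = c(1000, 1200, 900),
                  weight_d7 = c(2050, 1200, NA))
  expect_equal(compute_adg(d), c(150, 0, NA))
})

test_that("tertile classes follow the <= / > boundary rules", {
  cls <- tertile_categorize(1:9)
  expect_equal(as.character(cls), rep(c("I", "M", "S"), each = 3))
  expect_equal(as.character(tertile_categorize(c(2, 2, 2, 2))),
               rep("I", 4))
  # rank-based: monotone transforms preserve the classes
  x <- rexp(30)
  expect_equal(tertile_categorize(x), tertile_categorize(log(x)))
  expect_error(tertile_categorize(c(1, 2)), "at least 3")
})

test_that("hazard ratios convert to percent risk changes", {
  expect_equal(hazard_ratio_to_pct(0.56), 44)
  expect_equal(hazard_ratio_to_pct(1), 0)
  expect_equal(hazard_ratio_to_pct(c(0.72, 0.74, 1.25)), c(28, 26, -25))
  expect_error(hazard_ratio_to_pct(0), "positive")
})

test_that("Kaplan-Meier matches the product-limit hand calculation", {
  km <- km_estimator(c(1, 2, 3, 7), c(1, 1, 0, 0))
  expect_equal(km$table$survival, c(0.75, 0.5))
  expect_equal(km$table$time, c(1, 2))
  expect_true(is.na(km$logrank_p))

  none <- km_estimator(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(none$fit$surv == 1))

  # two identical groups cannot be told apart
  t2 <- rep(c(1, 2, 4, 9), 2); e2 <- rep(c(1, 0, 1, 0), 2)
  g2 <- rep(c("a", "b"), each = 4)
  expect_equal(km_estimator(t2, e2, g2)$logrank_p, 1, tolerance = 1e-12)
})

test_that("cox_fit maximizes the same partial likelihood as a grid search", {
  set.seed(61)
  checked <- 0L
  while (checked < 5L) {
    n <- sample(4:6, 1)
    d <- data.frame(time = sample(1:50, n), event = 1L,
                    x = sample(c(0, 1), n, replace = TRUE))
    if (length(unique(d$x)) < 2) next
    # skip degenerate draws with a monotone likelihood (infinite MLE)
    flat <- FALSE
    fit <- withCallingHandlers(
      tryCatch(cox_fit(d, "x"), error = function(e) NULL),
      warning = function(w) {
        flat <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (flat || is.null(fit) || abs(fit$coefficients$estimate) > 3) next
    b_grid <- oracle_cox_grid(d$time, d$event, d$x)
    expect_lt(abs(fit$coefficients$estimate - b_grid), 1e-4)
    checked <- checked + 1L
  }
})

test_that("cox_fit returns HR = exp(beta) with ordered Wald intervals", {
  set.seed(71)
  d <- toy_piglet_frame(60, 10, hazard = 0.012, beta = -0.4)
  fit <- cox_fit(d, "x")
  co <- fit$coefficients
  expect_equal(co$hr, exp(co$estimate))
  expect_true(co$hr_lo < co$hr & co$hr < co$hr_hi)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$df)

  # covariate independent of the outcome: log-HR within 2 SE of zero
  d0 <- toy_piglet_frame(150, 14, hazard = 0.01, beta = 0)
  f0 <- cox_fit(d0, "x")
  expect_lt(abs(f0$coefficients$estimate), 2 * f0$coefficients$se)

  expect_error(cox_fit(data.frame(time = 1:4, event = 0L, x = rnorm(4)), "x"),
               "no events")
  d$x2 <- d$x
  expect_error(cox_fit(d, c("x", "x2")), "rank deficient")
})

test_that("robust clustered standard errors are available per dam", {
  set.seed(81)
  d <- toy_piglet_frame(50, 12, hazard = 0.012, beta = -0.3)
  plain <- cox_fit(d, "x")
  robust <- cox_fit(d, "x", cluster = "dam_id")
  expect_equal(plain$coefficients$estimate, robust$coefficients$estimate,
               tolerance = 1e-8)
  expect_false(isTRUE(all.equal(plain$coefficients$se,
                                robust$coefficients$se)))
})

test_that("Schoenfeld checks are calibrated under PH and detect violations", {
  set.seed(91)
  # single-term model: the global test is the term test
  d <- toy_piglet_frame(120, 8, hazard = 0.015, beta = -0.5)
  fit <- cox_fit(d, "x")
  z <- schoenfeld_check(fit)
  expect_equal(z$term[nrow(z)], "GLOBAL")
  expect_equal(z$p[1], z$p[2], tolerance = 1e-8)

  # size under proportional hazards
  rej <- 0L; reps <- 120L
  for (r in seq_len(reps)) {
    dr <- toy_piglet_frame(60, 8, hazard = 0.02, beta = -0.4)
    rej <- rej + (schoenfeld_check(cox_fit(dr, "x"))$p[1] < 0.05)
  }
  expect_gt(rej / reps, 0.005)
  expect_lt(rej / reps, 0.15)

  # power against a strongly time-varying effect
  gen_tv <- function(n) {
    x <- rnorm(n)
    h <- function(t, x) 0.02 * exp(ifelse(t <= 10, -1.2, 1.2) * x)
    time <- rep(28L, n); event <- rep(0L, n)
    for (t in 1:28) {
      alive <- event == 0L & time == 28L
      dies <- alive & runif(n) < h(t, x)
      time[dies] <- t; event[dies] <- 1L
    }
    data.frame(time = time, event = event, x = x)
  }
  hits <- 0L
  for (r in 1:25) {
    dv <- gen_tv(600)
    hits <- hits + (schoenfeld_check(cox_fit(dv, "x"))$p[1] < 0.05)
  }
  expect_gt(hits / 25, 0.5)
})
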