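# Simulation configuration ----------------------------------------------------

# Mean daily posture-change counts used to calibrate the per-day restlessness
# multipliers (relative day -3..7). Restlessness peaks the day before the
# first birth and settles after farrowing.
.PCALL_CALIBRATION <- setNames(
  c(220, 297, 470, 282, 247, 257, 219, 241, 236, 266, 253), -3:7)

# Companion calibration rows for the two transition subsets: crushing-risk
# changes and nursing-stop (udder-hiding) changes. Their per-period shares of
# PCAll set the base pair affinities of the jump kernel.
.PCRISK_CALIBRATION <- setNames(
  c(45, 52, 106, 53, 42, 41, 41, 39, 44, 55, 52), -3:7)
.PCSTOP_CALIBRATION <- setNames(
  c(54, 76, 82, 75, 65, 69, 61, 70, 67, 71, 65), -3:7)

# Per-period stationary postural budgets (raw six-posture ethogram):
# before farrowing sows stand a fifth of the time; on the farrowing day they
# are almost entirely lying (92%); in early lactation 89% lying, dominated by
# lateral lying with the udder exposed.
.STATIONARY_DEFAULTS <- list(
  bf = c(ST = 0.210, SI = 0.015, K = 0.005, SL = 0.120, LL = 0.290, LLU = 0.360),
  df = c(ST = 0.060, SI = 0.015, K = 0.005, SL = 0.120, LL = 0.180, LLU = 0.620),
  af = c(ST = 0.100, SI = 0.008, K = 0.002, SL = 0.080, LL = 0.150, LLU = 0.660))

.ACTIVITY_DEFAULTS <- list(
  bf = c(EAT = 0.24, DRINK = 0.22, OTHER = 0.54),
  df = c(EAT = 0.22, DRINK = 0.24, OTHER = 0.54),
  af = c(EAT = 0.27, DRINK = 0.21, OTHER = 0.52))

# ILR basis over the raw six-posture ethogram, used for between-sow and
# between-breed heterogeneity on the simplex. Coordinates: lying vs upright,
# udder exposed vs hidden lying, sternal vs lateral, standing vs sit/kneel,
# sitting vs kneeling.
raw_posture_ilr_basis <- function() {
  sbp <- rbind(c(-1, -1, -1, 1, 1, 1),
               c(0, 0, 0, -1, -1, 1),
               c(0, 0, 0, 1, -1, 0),
               c(1, -1, -1, 0, 0, 0),
               c(0, 1, -1, 0, 0, 0))
  colnames(sbp) <- POSTURES
  ilr_basis(sbp)
}

#' Map a relative day to its peripartum period
#' @param day integer relative day (-3..7).
#' @return `"bf"`, `"df"` or `"af"`.
#' @export
day_period <- function(day) {
  ifelse(day < 0L, "bf", ifelse(day == 0L, "df", "af"))
}

#' Build a state-exchange transition-rate matrix
#'
#' Off-diagonal rates `q[i, j] = rho * pi[j]` (events/hour): every posture is
#' left at a rate proportional to the popularity of the others, and the
#' stationary distribution of the jump process is exactly `pi`. The expected
#' number of posture changes per day is `24 * rho * sum(pi * (1 - pi))`.
#'
#' @param pi stationary posture distribution (sums to 1).
#' @param rho overall exchange intensity (events/hour).
#' @return Square rate matrix with zero diagonal (events/hour).
#' @export
exchange_rate_matrix <- function(pi, rho) {
  stopifnot(all(pi >= 0), abs(sum(pi) - 1) < 1e-8, rho >= 0)
  Q <- rho * matrix(pi, nrow = length(pi), ncol = length(pi), byrow = TRUE)
  diag(Q) <- 0
  dimnames(Q) <- list(names(pi), names(pi))
  Q
}

.rho_for_target <- function(pi, daily_changes) {
  daily_changes / (24 * sum(pi * (1 - pi)))
}

# Base pair affinities of the jump kernel, solved so the expected shares of
# nursing-stop transitions (r_stop = PCStopNurse/PCAll) and crushing-risk
# transitions (r_crush = PCRiskCrush/PCAll) match their calibration targets.
# Pair classes: N = all pairs involving LLU, D = (ST,SL), (ST,LL), (SL,LL),
# O = the rest (weight 1). Directed counts are half of a pair's flux; the
# ST->LLU and SL->LLU crush transitions live inside class N.
.pair_weight_solve <- function(pi, r_stop, r_crush) {
  pL <- pi[["LLU"]]; pST <- pi[["ST"]]; pSL <- pi[["SL"]]; pLL <- pi[["LL"]]
  S_N <- 2 * pL * (1 - pL)
  S_D <- 2 * (pST * pSL + pST * pLL + pSL * pLL)
  S_O <- sum(pi * (1 - pi)) - S_N - S_D
  crossL <- pL * (pST + pSL)
  denom <- 1 - 2 * r_stop - 2 * r_crush + 4 * r_stop * crossL / S_N
  if (!is.finite(denom) || denom <= 0 || S_O <= 0) {
    return(c(nurse = 1, descent = 1))
  }
  G <- S_O / denom
  w_N <- 2 * r_stop * G / S_N
  w_D <- 2 * (r_crush * G - w_N * crossL) / S_D
  if (!is.finite(w_N) || !is.finite(w_D) || w_N <= 0 || w_D <= 0) {
    return(c(nurse = 1, descent = 1))
  }
  c(nurse = w_N, descent = w_D)
}

#' Simulation configuration for a synthetic peripartum cohort
#'
#' Defines the semi-Markov posture process (per-period transition-rate
#' matrices with exponential holding times, discretized to `tick_s`-second
#' ticks), the per-day restlessness multipliers (peaking at D-1), standing
#' activity distributions, between-sow/between-breed heterogeneity, and the
#' piglet outcome generators (discrete-time proportional-hazards mortality
#' and a linear average-daily-gain model).
#'
#' @param n_sows number of sows.
#' @param breeds named list of breed specs, each with `prop` (share of sows),
#'   optional `posture_shift` (named list per period of length-5 ILR shifts)
#'   and `activity_shift` (length-2 ILR shifts per period).
#' @param days relative day grid (default -3..7).
#' @param tick_s seconds per tick; must divide 86400.
#' @param stationary per-period stationary posture distributions (six raw
#'   postures).
#' @param pcall_target named vector of expected daily posture-change counts
#'   per relative day; sets the rate scale and the day multipliers.
#' @param pcrisk_target,pcstop_target companion daily calibration rows for
#'   the crushing-risk and nursing-stop change counts; their per-period
#'   shares of `pcall_target` fix the base pair affinities of the jump
#'   kernel (how often changes involve the udder-exposed state or the
#'   standing/sternal descents).
#' @param activity_probs per-period distributions over EAT/DRINK/OTHER.
#' @param sow_sdlog lognormal SD of the per-sow restlessness effect.
#' @param day_sdlog lognormal SD of the per-sow-day rate jitter.
#' @param comp_sd SD of per-sow Gaussian heterogeneity in posture ILR space.
#' @param act_sd SD of per-sow heterogeneity in activity ILR space.
#' @param llu_exit_sdlog lognormal SD of the per-sow nursing-interruption
#'   propensity: a turnover multiplier on the `LLU` state that scales the
#'   flux through it (hence PCStopNurse) while leaving the time budget
#'   untouched, giving PCStopNurse dispersion of its own beyond overall
#'   restlessness.
#' @param descent_sdlog lognormal SD of the per-sow descent-style propensity
#'   (turnover multiplier on `ST` and `SL`), the crushing-risk analogue.
#' @param noise_rate probability a tick receives a spurious label.
#' @param missing_rate probability a whole sow-day is dropped (recording
#'   failure).
#' @param litter_size_range inclusive integer range of litter sizes.
#' @param survival_betas named log-hazard coefficients on the model covariate
#'   scale (posture-change counts per 100, budget times in h/day), e.g.
#'   `c(PCAll_af100 = log(0.56))`; covariates are centred at the cohort mean
#'   so the baseline hazard describes an average sow's piglet.
#' @param baseline_hazard per-day death hazard for days 1..28.
#' @param birth_weight list with `mean` (named per genetic type, g) and `sd`.
#' @param growth list with `intercept` (g/d), `genetic`, `pen`, `litter`
#'   additive effects, `effects` (named: sow covariate -> additive g/d shift
#'   for the superior tertile class), and `sd` (residual g/d).
#' @param seed master integer seed; per-sow substreams are derived from it so
#'   adding a sow does not perturb the others.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_sows = 43L,
                       breeds = list(
                         LW = list(prop = 21 / 43,
                                   posture_shift = list(
                                     bf = c(0, 0.35, 0, 0, 0),
                                     df = c(0, 0.10, 0, 0, 0),
                                     af = c(0, 0.15, 0, 0, 0)),
                                   activity_shift = list(
                                     bf = c(0.15, 0), df = c(0, 0), af = c(0.15, 0))),
                         MS = list(prop = 22 / 43,
                                   posture_shift = list(
                                     bf = c(0, -0.35, 0, 0, 0),
                                     df = c(0, -0.10, 0, 0, 0),
                                     af = c(0, -0.15, 0, 0, 0)),
                                   activity_shift = list(
                                     bf = c(-0.15, 0), df = c(0, 0), af = c(-0.15, 0)))),
                       days = -3:7,
                       tick_s = 5L,
                       stationary = .STATIONARY_DEFAULTS,
                       pcall_target = .PCALL_CALIBRATION,
                       pcrisk_target = .PCRISK_CALIBRATION,
                       pcstop_target = .PCSTOP_CALIBRATION,
                       activity_probs = .ACTIVITY_DEFAULTS,
                       sow_sdlog = 0.5,
                       day_sdlog = 0.25,
                       comp_sd = 0.15,
                       act_sd = 0.25,
                       llu_exit_sdlog = 0.4,
                       descent_sdlog = 0.4,
                       noise_rate = 0,
                       missing_rate = 0,
                       litter_size_range = c(12L, 21L),
                       survival_betas = c(PCAll_af100 = log(0.56)),
                       baseline_hazard = rep(0.0055, 28),
                       birth_weight = list(
                         mean = c("LW/LW" = 1292, "LW/MS" = 1283,
                                  "MS/LW" = 1063, "MS/MS" = 875),
                         sd = 230),
                       growth = list(
                         intercept = 229.5,
                         genetic = c("LW/MS" = 0, "LW/LW" = -38.42,
                                     "MS/LW" = -110.80, "MS/MS" = -102.55),
                         pen = c(A = 0, B = 17.43, C = -21.53, D = -14.65),
                         litter = c(I = 0, M = -24.18, S = -23.67),
                         effects = c(PCAll_bf = -22.37, PCStopNurse_df = -45.33,
                                     PCStopNurse_af = 70.84),
                         sd = 50),
                       seed = 1L) {
  stopifnot(n_sows >= 0, tick_s > 0, 86400 %% tick_s == 0)
  if (abs(sum(vapply(breeds, `[[`, numeric(1), "prop")) - 1) > 1e-8) {
    stop("breed proportions must sum to 1", call. = FALSE)
  }
  missing_days <- setdiff(as.character(days), names(pcall_target))
  if (length(missing_days)) {
    stop("pcall_target missing day(s): ", paste(missing_days, collapse = ", "),
         call. = FALSE)
  }
  for (p in c("bf", "df", "af")) {
    pi <- stationary[[p]]
    if (is.null(pi) || length(pi) != 6L || any(pi < 0) ||
        abs(sum(pi) - 1) > 1e-8) {
      stop(sprintf("stationary[['%s']] must be a closed 6-posture distribution", p),
           call. = FALSE)
    }
    ap <- activity_probs[[p]]
    if (is.null(ap) || any(ap < 0) || abs(sum(ap) - 1) > 1e-8) {
      stop(sprintf("activity_probs[['%s']] must sum to 1", p), call. = FALSE)
    }
  }
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate in [0,1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0,1]", call. = FALSE)
  lr <- as.integer(litter_size_range)
  if (length(lr) != 2L || lr[1] > lr[2] || lr[1] < 1L) {
    stop("invalid litter_size_range", call. = FALSE)
  }
  if (any(baseline_hazard < 0) || any(baseline_hazard >= 1)) {
    stop("baseline_hazard entries must be in [0,1)", call. = FALSE)
  }
  # period exchange intensities calibrated to the period-mean daily change
  # counts; per-day multipliers carry the within-period profile
  period_mean <- vapply(c(bf = "bf", df = "df", af = "af"), function(p) {
    mean(pcall_target[as.character(days[day_period(days) == p])])
  }, numeric(1))
  # periods absent from the day grid fall back to the overall pace
  period_mean[!is.finite(period_mean)] <-
    mean(pcall_target[as.character(days)])
  rho <- mapply(function(p) .rho_for_target(stationary[[p]], period_mean[[p]]),
                c(bf = "bf", df = "df", af = "af"))
  posture_rates <- lapply(c(bf = "bf", df = "df", af = "af"), function(p) {
    exchange_rate_matrix(stationary[[p]], rho[[p]])
  })
  restlessness <- setNames(
    as.numeric(pcall_target[as.character(days)]) /
      period_mean[day_period(days)], as.character(days))
  restlessness[!is.finite(restlessness)] <- 1
  pair_weights <- lapply(c(bf = "bf", df = "df", af = "af"), function(p) {
    dd <- as.character(days[day_period(days) == p])
    r_stop <- mean(pcstop_target[dd]) / mean(pcall_target[dd])
    r_crush <- mean(pcrisk_target[dd]) / mean(pcall_target[dd])
    if (!is.finite(r_stop) || !is.finite(r_crush)) {
      return(c(nurse = 1, descent = 1))
    }
    .pair_weight_solve(stationary[[p]], r_stop, r_crush)
  })
  for (Q in posture_rates) {
    if (any(Q < 0) || any(diag(Q) != 0)) {
      stop("invalid rate matrix: negative entry or non-zero diagonal",
           call. = FALSE)
    }
  }
  structure(list(
    n_sows = as.integer(n_sows), breeds = breeds, days = as.integer(days),
    tick_s = as.integer(tick_s), stationary = stationary,
    posture_rates = posture_rates, restlessness_multiplier = restlessness,
    pair_weights = pair_weights,
    activity_probs = activity_probs, sow_sdlog = sow_sdlog,
    day_sdlog = day_sdlog, comp_sd = comp_sd, act_sd = act_sd,
    llu_exit_sdlog = llu_exit_sdlog, descent_sdlog = descent_sdlog,
    noise_rate = noise_rate, missing_rate = missing_rate,
    litter_size_range = lr, survival_betas = survival_betas,
    baseline_hazard = baseline_hazard, birth_weight = birth_weight,
    growth = growth, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d sows (%s), days %d..%d, %d-s ticks, seed %d\n",
    x$n_sows, paste(names(x$breeds), collapse = "/"),
    min(x$days), max(x$days), x$tick_s, x$seed))
  invisible(x)
}

# Seed plumbing ---------------------------------------------------------------

# Derived substream seeds stay below 2^31 - 1.
.sub_seed <- function(seed, stream, index = 0L) {
  (as.numeric(seed) * 48271 + stream * 7919 + index) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
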