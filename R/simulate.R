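# Synthetic cohort generation -------------------------------------------------

#' Draw per-sow profiles
#'
#' Assigns breed, pen, farrowing time (within the D0 window), the per-sow
#' lognormal restlessness effect, the per-sow posture/activity heterogeneity
#' shifts (Gaussian in ILR space), and a derived per-sow RNG seed. All
#' quantities for sow i depend only on the master seed and i, so adding sows
#' does not perturb existing ones.
#'
#' @param config a [sim_config()].
#' @return `data.frame` of class `sow_profiles` (list columns for the ILR
#'   shifts).
#' @export
sow_profiles <- function(config) {
  n <- config$n_sows
  breeds <- names(config$breeds)
  props <- vapply(config$breeds, `[[`, numeric(1), "prop")
  counts <- diff(round(cumsum(c(0, props)) * n))
  breed_vec <- rep(breeds, counts)
  length(breed_vec) <- n
  if (anyNA(breed_vec)) breed_vec[is.na(breed_vec)] <- breeds[1]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- with_seed(.sub_seed(config$seed, 1L, i), {
      list(sow_id = sprintf("sow%03d", i),
           breed = breed_vec[i],
           pen = sample(c("A", "B", "C", "D"), 1L),
           farrowing_time = runif(1, 0, 24),
           restlessness = rlnorm(1, -config$sow_sdlog^2 / 2, config$sow_sdlog),
           llu_exit = rlnorm(1, -config$llu_exit_sdlog^2 / 2,
                             config$llu_exit_sdlog),
           descent = rlnorm(1, -config$descent_sdlog^2 / 2,
                            config$descent_sdlog),
           z_posture = list(rnorm(5, 0, config$comp_sd)),
           z_activity = list(rnorm(2, 0, config$act_sd)),
           stream_seed = .sub_seed(config$seed, 2L, i))
    })
  }
  df <- do.call(rbind, lapply(out, function(x) {
    data.frame(sow_id = x$sow_id, breed = x$breed, pen = x$pen,
               farrowing_time = x$farrowing_time,
               restlessness = x$restlessness,
               llu_exit = x$llu_exit, descent = x$descent,
               stream_seed = x$stream_seed, stringsAsFactors = FALSE)
  }))
  df$z_posture <- lapply(out, function(x) x$z_posture[[1]])
  df$z_activity <- lapply(out, function(x) x$z_activity[[1]])
  class(df) <- c("sow_profiles", "data.frame")
  df
}

# Sow- and period-specific stationary distribution and activity probabilities.
.sow_period_params <- function(config, profile, period) {
  basis <- raw_posture_ilr_basis()
  shift <- config$breeds[[profile$breed]]$posture_shift[[period]]
  if (is.null(shift)) shift <- rep(0, 5)
  pi0 <- zero_replace(config$stationary[[period]], 1e-7)
  pi <- ilr_inverse(ilr_transform(pi0, basis) +
                      shift + profile$z_posture[[1]], basis)
  abasis <- activity_ilr_basis()
  ashift <- config$breeds[[profile$breed]]$activity_shift[[period]]
  if (is.null(ashift)) ashift <- rep(0, 2)
  ap0 <- zero_replace(config$activity_probs[[period]][ACTIVITIES], 1e-7)
  ap <- ilr_inverse(ilr_transform(ap0, abasis) + ashift +
                      profile$z_activity[[1]], abasis)
  list(pi = pi, activity = ap)
}

# Continuous-time jump chain over one day, discretized to tick_s seconds.
# Returns the posture label of each tick.
# Per-sow transition-style mixing. Jump rates q_ij = rho * pi_j * M_ij with
# a SYMMETRIC pairwise multiplier matrix M: the chain stays reversible with
# stationary distribution pi for any positive M, while the flux over a pair
# scales with its multiplier. M carries the sow's nursing-interruption
# propensity (all pairs involving LLU) and descent style (ST-SL, ST-LL,
# SL-LL). Rates are renormalized so the expected total change count at M = 1
# is preserved: styles reallocate WHICH transitions a sow uses, not how
# restless she is.
.mixing_kernel <- function(pi, nurse = 1, descent = 1) {
  states <- names(pi)
  M <- matrix(1, length(pi), length(pi), dimnames = list(states, states))
  M["LLU", ] <- M[, "LLU"] <- nurse
  for (pr in list(c("ST", "SL"), c("ST", "LL"), c("SL", "LL"))) {
    M[pr[1], pr[2]] <- M[pr[2], pr[1]] <- descent
  }
  A <- sweep(M, 2L, pi, "*")
  diag(A) <- 0
  out <- rowSums(A)
  norm <- sum(pi * out) / sum(pi * (1 - pi))
  list(out = out / norm, dest = A / out)
}

.simulate_day_ticks <- function(pi, rho_eff, tick_s, start_state = NULL,
                                mix = NULL) {
  n_ticks <- 86400L %/% tick_s
  states <- names(pi)
  if (is.null(mix)) mix <- .mixing_kernel(pi)
  if (is.null(start_state)) {
    start_state <- sample(states, 1L, prob = pi)
  }
  if (rho_eff <= 0) {
    return(list(postures = rep(start_state, n_ticks), end_state = start_state))
  }
  t_now <- 0
  s_now <- start_state
  jump_t <- numeric(0)
  jump_s <- character(0)
  horizon <- 86400
  repeat {
    out_rate <- rho_eff * mix$out[[s_now]] / 3600
    t_now <- t_now + if (out_rate > 0) rexp(1, out_rate) else Inf
    if (t_now >= horizon) break
    p <- mix$dest[s_now, states != s_now]
    s_now <- sample(states[states != s_now], 1L, prob = p)
    jump_t <- c(jump_t, t_now)
    jump_s <- c(jump_s, s_now)
  }
  seq_states <- c(start_state, jump_s)
  tick_times <- (seq_len(n_ticks) - 1L) * tick_s
  idx <- findInterval(tick_times, jump_t) + 1L
  list(postures = seq_states[idx], end_state = s_now)
}

# Assign one activity per standing bout (run of ST ticks).
.assign_activities <- function(postures, activity_probs) {
  act <- rep(NA_character_, length(postures))
  r <- rle(postures)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  st_runs <- which(r$values == "ST")
  if (length(st_runs)) {
    labs <- sample(ACTIVITIES, length(st_runs), replace = TRUE,
                   prob = activity_probs[ACTIVITIES])
    for (j in seq_along(st_runs)) {
      act[starts[st_runs[j]]:ends[st_runs[j]]] <- labs[j]
    }
  }
  act
}

#' Simulate the 11-day posture/activity stream of one sow
#'
#' Runs the semi-Markov posture process day by day (carrying the posture
#' across farrowing-anchored day boundaries), with the day's exchange
#' intensity scaled by the per-day restlessness multiplier, the sow's
#' restlessness effect, and a per-day lognormal jitter. Standing bouts
#' receive an activity label drawn from the sow's activity distribution.
#' Deterministic given `(config$seed, sow_id)`.
#'
#' @param config a [sim_config()].
#' @param profile one row of [sow_profiles()].
#' @return A `posture_stream` covering all configured days.
#' @export
simulate_posture_stream <- function(config, profile) {
  for (Q in config$posture_rates) {
    if (any(Q < 0)) stop("invalid rate matrix: negative entry", call. = FALSE)
  }
  with_seed(profile$stream_seed, {
    res <- vector("list", length(config$days))
    end_state <- NULL
    for (di in seq_along(config$days)) {
      day <- config$days[di]
      period <- day_period(day)
      pars <- .sow_period_params(config, profile, period)
      # exchange intensity implied by the period rate matrix: Q[i,j] = rho*pi[j]
      rho_base <- sum(config$posture_rates[[period]][1, -1]) /
        sum(config$stationary[[period]][-1])
      jitter <- rlnorm(1, -config$day_sdlog^2 / 2, config$day_sdlog)
      rho_eff <- rho_base * config$restlessness_multiplier[[as.character(day)]] *
        profile$restlessness * jitter
      pw <- config$pair_weights[[period]]
      mix <- .mixing_kernel(pars$pi,
                            nurse = pw[["nurse"]] * profile$llu_exit,
                            descent = pw[["descent"]] * profile$descent)
      sim <- .simulate_day_ticks(pars$pi, rho_eff, config$tick_s, end_state,
                                 mix)
      end_state <- sim$end_state
      act <- .assign_activities(sim$postures, pars$activity)
      res[[di]] <- posture_stream(profile$sow_id, day, sim$postures, act)
    }
    out <- do.call(rbind, res)
    class(out) <- c("posture_stream", "data.frame")
    out
  })
}

#' Inject spurious single-tick labels
#'
#' Each tick independently receives, with probability `noise_rate`, a
#' different random posture label (uniform over the other five), emulating
#' isolated classifier errors; activities are re-drawn uniformly for ticks
#' noised into `ST` and dropped otherwise. The input is not modified.
#'
#' @param stream a `posture_stream`.
#' @param noise_rate probability in `[0, 1]`.
#' @param seed integer seed.
#' @return Noised copy of the stream.
#' @export
inject_label_noise <- function(stream, noise_rate, seed) {
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate in [0,1]", call. = FALSE)
  if (noise_rate == 0) return(stream)
  with_seed(seed, {
    hit <- runif(nrow(stream)) < noise_rate
    if (any(hit)) {
      cur <- stream$posture[hit]
      new <- vapply(cur, function(p) sample(setdiff(POSTURES, p), 1L), "")
      stream$posture[hit] <- new
      stream$activity[hit] <- ifelse(
        new == "ST", sample(ACTIVITIES, length(new), replace = TRUE),
        NA_character_)
    }
    stream
  })
}
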