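# Sow-level covariates and the synthetic piglet generator ---------------------

#' Per-sow per-period behavioural covariates
#'
#' Summarises the daily traits of each sow into the covariates used by the
#' association models: period means of the three posture-change counts, and
#' daily hours spent in informative budget classes (lying with the udder
#' exposed; standing; and eating / drinking / other while standing).
#'
#' @param traits output of [compute_daily_traits()].
#' @return `data.frame`, one row per sow, with columns `<trait>_<period>`
#'   and `n_days_<period>` giving the number of observed days per period.
#' @export
sow_period_covariates <- function(traits) {
  sows <- unique(traits$sow_id)
  rows <- lapply(sows, function(s) {
    tr <- traits[traits$sow_id == s, , drop = FALSE]
    out <- list(sow_id = s)
    for (p in c("bf", "df", "af")) {
      sub <- tr[tr$day %in% period_days(p), , drop = FALSE]
      n <- nrow(sub)
      m <- function(x) if (n) mean(x, na.rm = TRUE) else NA_real_
      st_h <- m(sub$p_ST) * 24
      out[[paste0("PCAll_", p)]] <- m(sub$PCAll)
      out[[paste0("PCRiskCrush_", p)]] <- m(sub$PCRiskCrush)
      out[[paste0("PCStopNurse_", p)]] <- m(sub$PCStopNurse)
      out[[paste0("llu_h_", p)]] <- m(sub$p_LLU) * 24
      out[[paste0("st_h_", p)]] <- st_h
      for (a in c("EAT", "DRINK", "OTHER")) {
        h <- m(ifelse(is.na(sub[[paste0("a_", a)]]), 0,
                      sub[[paste0("a_", a)]] * sub$p_ST)) * 24
        out[[paste0(tolower(a), "_h_", p)]] <- h
      }
      out[[paste0("n_days_", p)]] <- n
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Covariates on the modelling scale: posture-change counts per 100 events,
# budget times in hours/day (already).
.model_scale <- function(cov) {
  for (p in c("bf", "df", "af")) {
    for (v in c("PCAll", "PCRiskCrush", "PCStopNurse")) {
      raw <- cov[[paste0(v, "_", p)]]
      if (!is.null(raw)) cov[[paste0(v, "_", p, "100")]] <- raw / 100
    }
  }
  cov
}

#' Litter-size class
#'
#' Three fixed levels: `I` = 12-14, `M` = 15-16, `S` = 17-21 piglets born
#' alive.
#'
#' @param n integer litter sizes.
#' @return Factor with levels I, M, S.
#' @export
litter_size_class <- function(n) {
  factor(ifelse(n <= 14, "I", ifelse(n <= 16, "M", "S")),
         levels = c("I", "M", "S"))
}

#' Simulate litters and piglet outcomes for a cohort of sows
#'
#' Litter sizes are uniform over the configured range; each piglet's sire
#' breed is drawn from the mixed-semen design (dam breed x LW/MS sire), so
#' four genetic types arise in every litter. Death days follow a
#' discrete-time proportional-hazards model on days 1..28 with log-hazard
#' linear in the configured (cohort-mean-centred) sow covariates; survivors
#' are censored at day 28. Birth weights are drawn per genetic type; weights
#' at D1/D3/D7 follow `birth + ADG * day`, with ADG = intercept + genetic,
#' pen and litter-class effects + superior-tertile shifts for the configured
#' sow traits + Gaussian residual. Piglets that died on or before a weighing
#' day have that weight missing.
#'
#' @param config a [sim_config()].
#' @param covariates output of [sow_period_covariates()] joined with sow
#'   `breed` and `pen` columns (as produced by [build_cohort()]).
#' @return `data.frame` of piglet records: `piglet_id`, `dam_id`,
#'   `genetic_type`, `litter_size`, `litter_class`, `pen`, `birth_weight`,
#'   `weight_d1`, `weight_d3`, `weight_d7`, `time`, `event`, `cause`.
#' @export
simulate_litters <- function(config, covariates) {
  if (!nrow(covariates)) return(data.frame())
  needed <- names(config$survival_betas)
  cov <- .model_scale(covariates)
  for (v in needed) {
    if (is.null(cov[[v]])) stop("unknown sow trait in survival_betas: ", v,
                                call. = FALSE)
    if (anyNA(cov[[v]])) stop("missing sow trait '", v, "' for some sow",
                              call. = FALSE)
  }
  growth_traits <- names(config$growth$effects)
  for (v in growth_traits) {
    if (is.null(cov[[v]])) stop("unknown sow trait in growth effects: ", v,
                                call. = FALSE)
  }
  with_seed(.sub_seed(config$seed, 3L), {
    n_sows <- nrow(cov)
    lr <- config$litter_size_range
    litter_size <- sample(lr[1]:lr[2], n_sows, replace = TRUE)
    # cohort-mean-centred linear predictor per sow
    lp <- rep(0, n_sows)
    for (v in needed) {
      lp <- lp + config$survival_betas[[v]] * (cov[[v]] - mean(cov[[v]]))
    }
    # superior-tertile indicators for the growth effects
    gshift <- rep(0, n_sows)
    for (v in growth_traits) {
      cls <- tertile_categorize(cov[[v]])
      gshift <- gshift + config$growth$effects[[v]] * (cls == "S")
    }
    lclass <- litter_size_class(litter_size)
    pigs <- vector("list", n_sows)
    for (i in seq_len(n_sows)) {
      m <- litter_size[i]
      sire <- sample(c("LW", "MS"), m, replace = TRUE)
      gt <- paste(covariates$breed[i], sire, sep = "/")
      hz <- pmin(config$baseline_hazard * exp(lp[i]), 0.999)
      time <- rep(length(hz), m)
      event <- rep(0L, m)
      for (t in seq_along(hz)) {
        alive <- event == 0L & time == length(hz)
        if (!any(alive)) break
        dies <- alive & runif(m) < hz[t]
        time[dies] <- t
        event[dies] <- 1L
      }
      mu_bw <- config$birth_weight$mean[gt]
      mu_bw[is.na(mu_bw)] <- mean(config$birth_weight$mean)
      bw <- rnorm(m, mu_bw, config$birth_weight$sd)
      bw <- pmax(bw, 300)
      gen_eff <- config$growth$genetic[gt]
      gen_eff[is.na(gen_eff)] <- mean(config$growth$genetic)
      adg <- config$growth$intercept +
        gen_eff +
        config$growth$pen[[covariates$pen[i]]] +
        config$growth$litter[[as.character(lclass[i])]] +
        gshift[i] + rnorm(m, 0, config$growth$sd)
      w <- function(d) ifelse(event == 1L & time <= d, NA_real_, bw + adg * d)
      cause <- ifelse(event == 1L,
                      sample(c("crushing", "starvation", "other"), m,
                             replace = TRUE, prob = c(0.5, 0.35, 0.15)),
                      NA_character_)
      pigs[[i]] <- data.frame(
        piglet_id = sprintf("%s_p%02d", covariates$sow_id[i], seq_len(m)),
        dam_id = covariates$sow_id[i], genetic_type = gt,
        litter_size = m, litter_class = as.character(lclass[i]),
        pen = covariates$pen[i], birth_weight = bw,
        weight_d1 = w(1), weight_d3 = w(3), weight_d7 = w(7),
        time = time, event = event, cause = cause,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, pigs)
  })
}

#' Build a full synthetic study cohort
#'
#' Chains the generators: sow profiles, per-sow posture/activity streams
#' (optionally label-noised and with whole sow-days dropped to emulate
#' recording failures), daily traits, per-period sow covariates, and piglet
#' outcome records. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param return_streams keep the raw tick streams in the result (they are
#'   large: 17,280 ticks per sow-day); traits are always computed.
#' @return List of class `sow_cohort`: `config`, `profiles`, `streams`
#'   (or `NULL`), `traits`, `covariates`, `piglets`, `dropped_days`.
#' @export
build_cohort <- function(config, return_streams = TRUE) {
  if (config$n_sows == 0L) {
    return(structure(list(config = config, profiles = NULL, streams = NULL,
                          traits = data.frame(), covariates = data.frame(),
                          piglets = data.frame(), dropped_days = 0L),
                     class = "sow_cohort"))
  }
  profiles <- sow_profiles(config)
  keep_days <- with_seed(.sub_seed(config$seed, 4L), {
    matrix(runif(config$n_sows * length(config$days)) >= config$missing_rate,
           nrow = config$n_sows)
  })
  streams <- vector("list", config$n_sows)
  traits <- vector("list", config$n_sows)
  dropped <- 0L
  for (i in seq_len(config$n_sows)) {
    pr <- profiles[i, , drop = FALSE]
    st <- simulate_posture_stream(config, pr)
    if (config$noise_rate > 0) {
      st <- inject_label_noise(st, config$noise_rate,
                               .sub_seed(config$seed, 5L, i))
    }
    keep <- config$days[keep_days[i, ]]
    dropped <- dropped + sum(!keep_days[i, ])
    st <- st[st$day %in% keep, , drop = FALSE]
    if (nrow(st)) {
      traits[[i]] <- compute_daily_traits(st)
      if (return_streams) streams[[i]] <- st
    }
  }
  traits <- do.call(rbind, traits)
  streams <- if (return_streams) {
    out <- do.call(rbind, streams)
    if (!is.null(out)) class(out) <- c("posture_stream", "data.frame")
    out
  } else NULL
  covariates <- sow_period_covariates(traits)
  covariates <- merge(covariates,
                      profiles[, c("sow_id", "breed", "pen")], by = "sow_id")
  piglets <- simulate_litters(config, covariates)
  if (nrow(piglets)) {
    covariates <- merge(covariates,
                        unique(piglets[, c("dam_id", "litter_size",
                                           "litter_class")]),
                        by.x = "sow_id", by.y = "dam_id")
  }
  structure(list(config = config, profiles = profiles, streams = streams,
                 traits = traits, covariates = covariates, piglets = piglets,
                 dropped_days = dropped),
            class = "sow_cohort")
}

#' @export
print.sow_cohort <- function(x, ...) {
  cat(sprintf("sow_cohort: %d sows, %d sow-days of traits, %d piglets (%d dropped days)\n",
              x$config$n_sows, nrow(x$traits),
              if (is.null(x$piglets)) 0L else nrow(x$piglets), x$dropped_days))
  invisible(x)
}
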