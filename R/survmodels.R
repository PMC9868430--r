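# Survival and growth primitives ---------------------------------------------

#' Average daily gain from birth to day 7
#'
#' `(weight_d7 - birth_weight) / 7`, in g/day. Piglets without a D7 weight
#' (typically dead before D7) get `NA` and are excluded from growth models.
#'
#' @param piglets piglet record `data.frame` with `birth_weight` and
#'   `weight_d7` columns.
#' @return Numeric vector of ADG (g/d), `NA` where undefined.
#' @export
compute_adg <- function(piglets) {
  (piglets$weight_d7 - piglets$birth_weight) / 7
}

#' Tertile classes I / M / S
#'
#' Splits a numeric vector at the lower and upper tertiles of its empirical
#' distribution (type-7 quantiles): Inferior `I` for values <= the lower
#' tertile, Moderate `M` for values above it and <= the upper tertile,
#' Superior `S` above that. Rank-based, hence invariant to monotone
#' transformations.
#'
#' @param values numeric vector, length >= 3.
#' @return Factor with levels `I`, `M`, `S`.
#' @export
tertile_categorize <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  q <- quantile(values, c(1 / 3, 2 / 3), type = 7, na.rm = TRUE)
  factor(ifelse(values <= q[1], "I", ifelse(values <= q[2], "M", "S")),
         levels = c("I", "M", "S"))
}

#' Convert a hazard ratio to a percent change in instantaneous risk
#'
#' `(1 - hr) * 100`; positive values are risk reductions (an HR of 0.56 is a
#' 44% lower instantaneous risk of dying), negative values are increases.
#'
#' @param hr positive hazard ratio(s).
#' @return Percent change(s).
#' @export
hazard_ratio_to_pct <- function(hr) {
  if (any(hr <= 0)) stop("hazard ratios must be positive", call. = FALSE)
  (1 - hr) * 100
}

#' Kaplan-Meier survival curves with a log-rank test
#'
#' Product-limit survival estimate per group plus the log-rank test of equal
#' survival across groups.
#'
#' @param time days to death or censoring (> 0).
#' @param event 1 = died, 0 = censored.
#' @param group grouping factor (e.g. piglet genetic type); a single level
#'   yields no test (`logrank_p = NA`).
#' @return List of class `km_fit`: `fit` (a [survival::survfit] object),
#'   `logrank_p`, and `table` (time / group / survival / at-risk).
#' @export
km_estimator <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  logrank_p <- NA_real_
  if (nlevels(droplevels(group)) > 1L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    logrank_p <- pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  }
  s <- summary(fit)
  strata <- if (is.null(s$strata)) rep(levels(group)[1], length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  structure(list(fit = fit, logrank_p = logrank_p,
                 table = data.frame(group = strata, time = s$time,
                                    n_risk = s$n.risk, n_event = s$n.event,
                                    survival = s$surv)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate; log-rank p =",
      format.pval(x$logrank_p, digits = 3), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit a Cox proportional-hazards model
#'
#' Thin, contract-carrying wrapper around [survival::coxph()] with the Efron
#' tie correction (deaths are recorded at whole-day resolution, so ties are
#' heavy). Returns hazard ratios with Wald 95% confidence intervals and the
#' model AIC. Optionally uses robust (sandwich) standard errors clustered by
#' dam, since sow-level covariates are shared by littermates.
#'
#' @param data piglet-level `data.frame` with `time` and `event` columns.
#' @param terms character vector of explanatory column names (may be empty
#'   for a baseline-only model).
#' @param cluster optional column name for robust clustered SEs (e.g.
#'   `"dam_id"`).
#' @return Object of class `cox_fit`: `coefficients` table (term, estimate,
#'   se, z, p, hr, hr_lo, hr_hi), `loglik`, `aic`, `n`, `n_event`, `terms`,
#'   and the underlying `fit`.
#' @export
cox_fit <- function(data, terms, cluster = NULL) {
  if (sum(data$event) < 1L) stop("no events: cannot fit a Cox model",
                                 call. = FALSE)
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  f <- as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- if (is.null(cluster)) {
    survival::coxph(f, data = data, ties = "efron")
  } else {
    survival::coxph(f, data = data, ties = "efron",
                    cluster = data[[cluster]])
  }
  beta <- coef(fit)
  if (length(beta) && anyNA(beta)) {
    stop("design matrix is rank deficient (collinear terms)", call. = FALSE)
  }
  se <- if (length(beta)) sqrt(diag(vcov(fit))) else numeric(0)
  tab <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se), z = unname(beta / se),
                    p = 2 * stats::pnorm(-abs(unname(beta / se))),
                    hr = exp(unname(beta)),
                    hr_lo = exp(unname(beta - 1.96 * se)),
                    hr_hi = exp(unname(beta + 1.96 * se)),
                    stringsAsFactors = FALSE)
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(coefficients = tab, loglik = ll,
                 df = length(beta), aic = -2 * ll + 2 * length(beta),
                 n = fit$n, n_event = fit$nevent, terms = terms,
                 ties = "efron", fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d, AIC = %.2f\n",
              x$n, x$n_event, x$aic))
  if (nrow(x$coefficients)) {
    tab <- x$coefficients
    tab$risk_change_pct <- hazard_ratio_to_pct(tab$hr)
    print(format(tab, digits = digits), row.names = FALSE)
  } else cat("(baseline only)\n")
  invisible(x)
}

#' Schoenfeld-residual check of proportional hazards
#'
#' Scaled Schoenfeld residual score test per model term plus the global
#' test, via [survival::cox.zph()].
#'
#' @param fit a [cox_fit()] object.
#' @return `data.frame` with columns `term`, `chisq`, `df`, `p` (the last
#'   row is `GLOBAL`).
#' @export
schoenfeld_check <- function(fit) {
  if (!length(fit$terms)) stop("model has no terms to check", call. = FALSE)
  z <- survival::cox.zph(fit$fit)
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p = z$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}
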