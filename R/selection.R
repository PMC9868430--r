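# Three-step variable-selection protocol --------------------------------------
#
# Step 1: per period, screen each behavioural item one at a time (always
# alongside the fixed effects), choosing continuous vs categorized coding by
# AIC and keeping items with LRT p < alpha; significant cluster variables may
# be replaced by the raw trait that mainly explains the cluster difference,
# again by AIC. Step 2: per period, backward elimination of the significant
# items by likelihood-ratio test. Step 3: pool the survivors of the three
# periods and eliminate again to reach the final model. Fixed effects are
# never dropped.

.FIXED_EFFECTS <- c("genetic_type", "litter_class", "pen")

# Unified fitter for the two outcome types. `terms` are column names; for
# "cox" the data needs time/event, for "lm" an `adg` column.
.fit_raw <- function(type, data, terms) {
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  if (type == "cox") {
    f <- as.formula(paste("survival::Surv(time, event) ~", rhs))
    fit <- survival::coxph(f, data = data, ties = "efron")
    beta <- coef(fit)
    df <- sum(!is.na(beta))
    ll <- fit$loglik[length(fit$loglik)]
    list(fit = fit, ll = ll, df = df, aic = -2 * ll + 2 * df,
         coefs = beta)
  } else {
    f <- as.formula(paste("adg ~", rhs))
    fit <- lm(f, data = data)
    ll <- as.numeric(logLik(fit))
    df <- fit$rank
    list(fit = fit, ll = ll, df = df, aic = AIC(fit), coefs = coef(fit))
  }
}

.lrt <- function(full, reduced) {
  stat <- max(0, 2 * (full$ll - reduced$ll))
  df <- full$df - reduced$df
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1
  list(stat = stat, df = df, p = p)
}

.complete_rows <- function(data, cols, type) {
  need <- c(cols, if (type == "cox") c("time", "event") else "adg")
  need <- intersect(need, names(data))
  data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
}

# Dam-level tertile (or S vs M+I) recoding of a sow covariate carried on
# piglet rows: classes are computed on the per-dam distribution.
.dam_level_classes <- function(data, col, binary = FALSE) {
  dams <- !duplicated(data$dam_id)
  cls <- tertile_categorize(data[[col]][dams])
  map <- setNames(as.character(cls), data$dam_id[dams])
  out <- map[as.character(data$dam_id)]
  if (binary) {
    factor(ifelse(out == "S", "S", "MI"), levels = c("MI", "S"))
  } else factor(out, levels = c("I", "M", "S"))
}

.trace_row <- function(step, period, variable, action, coding = NA, aic = NA,
                       stat = NA, p = NA, decision = NA) {
  data.frame(step = step, period = period, variable = variable,
             action = action, coding = coding, aic = aic, lrt_stat = stat,
             p = p, decision = decision, stringsAsFactors = FALSE)
}

#' Candidate behavioural items per period
#'
#' Builds the spec of behavioural explanatory items tested in step 1 for one
#' period and outcome. Before farrowing only the two pattern (cluster)
#' variables and PCAll are meaningful; PCStopNurse is not tested on the
#' farrowing day for survival; growth analyses use PCAll and PCStopNurse but
#' not PCRiskCrush. Cluster items carry the raw budget traits that can stand
#' in for them.
#'
#' @param period `"bf"`, `"df"` or `"af"`.
#' @param outcome `"survival"` or `"growth"`.
#' @return List of candidate descriptors (`name`, `column`, `kind`,
#'   `raw_traits`).
#' @export
candidate_set <- function(period, outcome = c("survival", "growth")) {
  outcome <- match.arg(outcome)
  p <- period
  post <- list(name = paste0("postural_pattern_", p),
               column = paste0("post_cl_", p), kind = "cluster",
               raw_traits = paste0(c("llu_h_", "st_h_"), p))
  act <- list(name = paste0("activity_pattern_", p),
              column = paste0("act_cl_", p), kind = "cluster",
              raw_traits = paste0(c("other_h_", "eat_h_", "drink_h_"), p))
  count <- function(v) list(name = paste0(v, "_", p),
                            column = paste0(v, "_", p, "100"), kind = "count",
                            raw_traits = character(0))
  if (outcome == "survival") {
    switch(p,
           bf = list(post, act, count("PCAll")),
           df = list(post, act, count("PCAll"), count("PCRiskCrush")),
           af = list(post, act, count("PCAll"), count("PCRiskCrush"),
                     count("PCStopNurse")))
  } else {
    switch(p,
           bf = list(post, act, count("PCAll")),
           df = list(post, act, count("PCAll"), count("PCStopNurse")),
           af = list(post, act, count("PCAll"), count("PCStopNurse")))
  }
}

# Best coding of a count item by AIC: continuous, I/M/S classes, and (for
# growth) the binary S vs M+I collapse.
.fit_count_codings <- function(type, data, col, fixed) {
  codings <- list(continuous = data[[col]])
  cls <- .dam_level_classes(data, col)
  if (nlevels(droplevels(cls)) > 1L) codings$IMS <- cls
  if (type == "lm") {
    b <- .dam_level_classes(data, col, binary = TRUE)
    if (nlevels(droplevels(b)) > 1L) codings$S_vs_MI <- b
  }
  fits <- list()
  for (nm in names(codings)) {
    d <- data
    cc <- paste0(col, "_", nm)
    d[[cc]] <- codings[[nm]]
    fits[[nm]] <- list(fit = .fit_raw(type, d, c(fixed, cc)), data = d,
                       column = if (nm == "continuous") col else cc)
  }
  aics <- vapply(fits, function(x) x$fit$aic, numeric(1))
  best <- names(which.min(aics))
  c(fits[[best]], list(coding = best, aics = aics))
}

# Standardized cluster-centre difference of a dam-level raw trait: range of
# cluster means over the trait's overall SD.
.cluster_trait_separation <- function(data, cluster_col, trait_col) {
  dams <- !duplicated(data$dam_id)
  x <- data[[trait_col]][dams]
  g <- data[[cluster_col]][dams]
  if (sd(x, na.rm = TRUE) == 0) return(0)
  m <- tapply(x, g, mean, na.rm = TRUE)
  (max(m, na.rm = TRUE) - min(m, na.rm = TRUE)) / sd(x, na.rm = TRUE)
}

#' Step 1: screen behavioural items one at a time
#'
#' For each candidate item of one period, fits the outcome model with the
#' fixed effects plus that single item; count items are tried as continuous
#' and as I/M/S tertile classes (growth also as S vs M+I) and the coding
#' with the lower AIC is kept; items are retained when the likelihood-ratio
#' test against the fixed-effects-only model gives p < `alpha`. A
#' significant cluster item is additionally compared (by AIC) against the
#' raw budget trait that best separates the cluster centres.
#'
#' @param data piglet-level `data.frame` (see [prepare_association_data()]).
#' @param candidates list from [candidate_set()].
#' @param type `"cox"` or `"lm"`.
#' @param period period tag used in the trace.
#' @param fixed fixed-effect columns, always included, never dropped.
#' @param alpha significance threshold.
#' @return List: `selected` (list of term descriptors with the realized
#'   column name and coding), `data` (with any coded columns appended),
#'   `trace`.
#' @export
screen_step1 <- function(data, candidates, type = c("cox", "lm"),
                         period = "", fixed = .FIXED_EFFECTS, alpha = 0.05) {
  type <- match.arg(type)
  selected <- list()
  trace <- list()
  for (cand in candidates) {
    col <- cand$column
    if (is.null(data[[col]])) next
    use_cols <- c(fixed, col, "dam_id", cand$raw_traits)
    d <- .complete_rows(data, intersect(use_cols, names(data)), type)
    if (!nrow(d)) next
    null <- .fit_raw(type, d, fixed)
    if (cand$kind == "count") {
      best <- .fit_count_codings(type, d, col, fixed)
      lrt <- .lrt(best$fit, null)
      trace[[length(trace) + 1L]] <- .trace_row(
        1L, period, cand$name, "screen", best$coding, best$fit$aic,
        lrt$stat, lrt$p, if (lrt$p < alpha) "kept" else "dropped")
      if (lrt$p < alpha) {
        if (best$coding != "continuous") data[[best$column]] <- best$data[[best$column]][match(data$dam_id, best$data$dam_id)]
        selected[[length(selected) + 1L]] <- list(
          name = cand$name, column = best$column, coding = best$coding,
          p = lrt$p, aic = best$fit$aic)
      }
    } else {
      g <- droplevels(as.factor(d[[col]]))
      if (nlevels(g) < 2L) next
      d[[col]] <- g
      clfit <- .fit_raw(type, d, c(fixed, col))
      lrt <- .lrt(clfit, null)
      decision <- if (lrt$p < alpha) "kept" else "dropped"
      chosen_col <- col
      chosen_coding <- "cluster"
      chosen_aic <- clfit$aic
      chosen_p <- lrt$p
      if (lrt$p < alpha && length(cand$raw_traits)) {
        seps <- vapply(cand$raw_traits, function(tc) {
          if (is.null(d[[tc]])) return(NA_real_)
          .cluster_trait_separation(d, col, tc)
        }, numeric(1))
        if (any(is.finite(seps))) {
          raw <- names(which.max(seps))
          rawfit <- .fit_raw(type, d, c(fixed, raw))
          raw_lrt <- .lrt(rawfit, null)
          trace[[length(trace) + 1L]] <- .trace_row(
            1L, period, cand$name, "raw-trait comparison", raw, rawfit$aic,
            raw_lrt$stat, raw_lrt$p,
            if (rawfit$aic < clfit$aic) "raw trait wins" else "cluster wins")
          if (rawfit$aic < clfit$aic) {
            chosen_col <- raw
            chosen_coding <- "raw_trait"
            chosen_aic <- rawfit$aic
            chosen_p <- raw_lrt$p
          }
        }
      }
      trace[[length(trace) + 1L]] <- .trace_row(
        1L, period, cand$name, "screen", chosen_coding, chosen_aic,
        lrt$stat, lrt$p, decision)
      if (lrt$p < alpha && chosen_p < alpha) {
        selected[[length(selected) + 1L]] <- list(
          name = cand$name, column = chosen_col, coding = chosen_coding,
          p = chosen_p, aic = chosen_aic)
      }
    }
  }
  list(selected = selected, data = data,
       trace = do.call(rbind, c(trace, list(.trace_row(
         1L, period, "(none)", "no-candidates", decision = "")[0, ]))))
}

# Backward LRT elimination of `terms`, keeping `fixed` always. Ties on the
# LRT p-value are broken by dropping the term with the smaller |z| (largest
# p is virtually never tied in practice; the rule is documented).
.backward_eliminate <- function(data, terms, type, fixed, alpha, step,
                                period = "global") {
  trace <- list()
  terms <- unique(terms)
  repeat {
    d <- .complete_rows(data, c(fixed, terms, "dam_id"), type)
    full <- .fit_raw(type, d, c(fixed, terms))
    if (!length(terms)) break
    # aliased terms (collinear across periods) are removed first
    aliased <- NULL
    if (anyNA(full$coefs)) {
      na_names <- names(full$coefs)[is.na(full$coefs)]
      for (tm in terms) {
        if (any(startsWith(na_names, tm) | startsWith(na_names, paste0("`", tm, "`")))) {
          aliased <- tm
          break
        }
      }
    }
    if (!is.null(aliased)) {
      trace[[length(trace) + 1L]] <- .trace_row(
        step, period, aliased, "eliminate", stat = NA, p = NA,
        decision = "dropped (collinear)")
      terms <- setdiff(terms, aliased)
      next
    }
    ps <- vapply(terms, function(tm) {
      red <- .fit_raw(type, d, c(fixed, setdiff(terms, tm)))
      .lrt(full, red)$p
    }, numeric(1))
    worst <- which(ps == max(ps))
    if (length(worst) > 1L) {
      z <- vapply(terms[worst], function(tm) {
        b <- full$coefs
        sel <- startsWith(names(b), tm) | startsWith(names(b), paste0("`", tm, "`"))
        if (!any(sel)) return(Inf)
        v <- sqrt(diag(vcov(full$fit)))[sel]
        min(abs(b[sel] / v))
      }, numeric(1))
      worst <- worst[which.min(z)]
    } else worst <- worst[1]
    if (ps[worst] > alpha) {
      trace[[length(trace) + 1L]] <- .trace_row(
        step, period, terms[worst], "eliminate", stat = NA, p = ps[worst],
        decision = "dropped")
      terms <- terms[-worst]
    } else {
      for (i in seq_along(terms)) {
        trace[[length(trace) + 1L]] <- .trace_row(
          step, period, terms[i], "eliminate", stat = NA, p = ps[i],
          decision = "kept")
      }
      break
    }
  }
  d <- .complete_rows(data, c(fixed, terms, "dam_id"), type)
  list(terms = terms, fit = .fit_raw(type, d, c(fixed, terms)), data = d,
       trace = do.call(rbind, trace))
}

#' Step 2: per-period backward elimination
#'
#' Starts from the saturated model holding all step-1 survivors of one
#' period plus the fixed effects, and repeatedly removes the term whose
#' removal gives the largest likelihood-ratio p-value while that p-value
#' exceeds `alpha`.
#'
#' @param data (possibly step-1 augmented) piglet-level data.
#' @param terms character vector of step-1 selected columns.
#' @inheritParams screen_step1
#' @return List: `terms` retained, `fit`, `trace`.
#' @export
reduce_step2 <- function(data, terms, type = c("cox", "lm"), period = "",
                         fixed = .FIXED_EFFECTS, alpha = 0.05) {
  type <- match.arg(type)
  .backward_eliminate(data, terms, type, fixed, alpha, 2L, period)
}

#' Step 3: global model across the three periods
#'
#' Pools the step-2 survivors of all periods into one model and re-applies
#' backward likelihood-ratio elimination (collinear cross-period terms are
#' dropped first and recorded). Returns the final fit.
#'
#' @param data piglet-level data (augmented by step 1).
#' @param terms_by_period list of character vectors of surviving columns.
#' @inheritParams screen_step1
#' @return List: `terms`, `fit`, `trace`.
#' @export
global_step3 <- function(data, terms_by_period, type = c("cox", "lm"),
                         fixed = .FIXED_EFFECTS, alpha = 0.05) {
  type <- match.arg(type)
  .backward_eliminate(data, unlist(terms_by_period), type, fixed, alpha, 3L)
}

#' Run the full three-step selection for one outcome
#'
#' Convenience driver: step 1 in each period, step 2 per period, step 3
#' globally. For survival the outcome is (time, event); for growth the ADG
#' (computed if absent).
#'
#' @param data piglet-level data from [prepare_association_data()].
#' @param outcome `"survival"` or `"growth"`.
#' @param fixed fixed-effect columns.
#' @param alpha significance threshold.
#' @return List of class `selection_result`: `outcome`, `final` (a
#'   [cox_fit()] or `lm` summary wrapper including the fixed effects),
#'   `terms`, `trace` (all steps bound together), `step1`, `step2`.
#' @export
three_step_selection <- function(data, outcome = c("survival", "growth"),
                                 fixed = .FIXED_EFFECTS, alpha = 0.05) {
  outcome <- match.arg(outcome)
  type <- if (outcome == "survival") "cox" else "lm"
  if (type == "lm" && is.null(data$adg)) data$adg <- compute_adg(data)
  traces <- list()
  step1 <- list(); step2 <- list()
  terms_by_period <- list()
  for (p in c("bf", "df", "af")) {
    s1 <- screen_step1(data, candidate_set(p, outcome), type, period = p,
                       fixed = fixed, alpha = alpha)
    data <- s1$data
    step1[[p]] <- s1
    traces[[length(traces) + 1L]] <- s1$trace
    cols <- vapply(s1$selected, `[[`, "", "column")
    s2 <- reduce_step2(data, cols, type, period = p, fixed = fixed,
                       alpha = alpha)
    step2[[p]] <- s2
    traces[[length(traces) + 1L]] <- s2$trace
    terms_by_period[[p]] <- s2$terms
  }
  s3 <- global_step3(data, terms_by_period, type, fixed = fixed,
                     alpha = alpha)
  traces[[length(traces) + 1L]] <- s3$trace
  final <- if (type == "cox") {
    cox_fit(s3$data, c(fixed, s3$terms))
  } else {
    s3$fit$fit
  }
  structure(list(outcome = outcome, final = final, terms = s3$terms,
                 data = data,
                 trace = do.call(rbind, traces), step1 = step1,
                 step2 = step2),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Three-step %s selection: %d behavioural term(s) retained\n",
              x$outcome, length(x$terms)))
  if (length(x$terms)) cat("  ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the growth model via the three-step protocol
#'
#' Ordinary least squares for piglet average daily gain D0-D7, with the same
#' screening / per-period reduction / global reduction protocol as the
#' survival analysis; behavioural count items may enter as continuous,
#' I/M/S, or the binary S vs M+I collapse, whichever has the lowest AIC.
#'
#' @inheritParams three_step_selection
#' @return A `selection_result` whose `final` element is the `lm` fit.
#' @export
fit_growth_model <- function(data, fixed = .FIXED_EFFECTS, alpha = 0.05) {
  three_step_selection(data, "growth", fixed = fixed, alpha = alpha)
}

#' Replay a selection trace
#'
#' Refits the final model recorded by a `selection_result` on its data,
#' verifying the trace is sufficient to reproduce the selection outcome.
#'
#' @param result a `selection_result`.
#' @return The refitted model object.
#' @export
replay_selection <- function(result) {
  type <- if (result$outcome == "survival") "cox" else "lm"
  fixed <- .FIXED_EFFECTS
  d <- .complete_rows(result$data, c(fixed, result$terms, "dam_id"), type)
  .fit_raw(type, d, c(fixed, result$terms))$fit
}

#' Assemble piglet-level association data
#'
#' Joins the piglet records with their dam's model-scale covariates and, if
#' given, the dam's cluster labels per period/budget, and computes ADG.
#'
#' @param cohort a `sow_cohort` from [build_cohort()], or a list with
#'   `piglets` and `covariates`.
#' @param cluster_labels optional `data.frame` with `sow_id` and columns
#'   `post_cl_<period>` / `act_cl_<period>`.
#' @return Piglet-level `data.frame` ready for [three_step_selection()].
#' @export
prepare_association_data <- function(cohort, cluster_labels = NULL) {
  cov <- .model_scale(cohort$covariates)
  cov$litter_size <- NULL; cov$litter_class <- NULL; cov$pen <- NULL
  d <- merge(cohort$piglets, cov, by.x = "dam_id", by.y = "sow_id")
  if (!is.null(cluster_labels)) {
    d <- merge(d, cluster_labels, by.x = "dam_id", by.y = "sow_id",
               all.x = TRUE)
  }
  d$adg <- compute_adg(d)
  d$genetic_type <- factor(d$genetic_type)
  d$litter_class <- factor(d$litter_class, levels = c("I", "M", "S"))
  d$pen <- factor(d$pen)
  d
}
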