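# Stream file format, pipeline driver, reporting ------------------------------

#' Write / read posture streams as long CSV
#'
#' One row per 5-s tick: `sow_id, day, tick, posture, activity` (activity
#' empty unless standing). Reading validates the header, the posture and
#' activity vocabularies (reporting offending line numbers) and flags gaps
#' in the tick index as missing ticks.
#'
#' @param streams a `posture_stream` table.
#' @param path CSV file path.
#' @return `write_stream_csv`: the path, invisibly. `read_stream_csv`: a
#'   `posture_stream` with attribute `missing_ticks` (count of index gaps).
#' @export
write_stream_csv <- function(streams, path) {
  out <- streams[, c("sow_id", "day", "tick", "posture", "activity")]
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(
    character = c("sow_id", "posture", "activity")), na.strings = "")
  if (!nrow(dt)) stop("empty stream file: ", path, call. = FALSE)
  need <- c("sow_id", "day", "tick", "posture", "activity")
  if (!all(need %in% names(dt))) {
    stop("stream file header must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(dt$posture %in% POSTURES))
  if (length(bad)) {
    stop(sprintf("unknown posture code '%s' at line %d of %s",
                 dt$posture[bad[1]], bad[1] + 1L, path), call. = FALSE)
  }
  bad_act <- which(!is.na(dt$activity) & !(dt$activity %in% ACTIVITIES))
  if (length(bad_act)) {
    stop(sprintf("unknown activity code '%s' at line %d of %s",
                 dt$activity[bad_act[1]], bad_act[1] + 1L, path),
         call. = FALSE)
  }
  bad_st <- which(!is.na(dt$activity) & dt$posture != "ST")
  if (length(bad_st)) {
    stop(sprintf("activity on non-standing tick at line %d of %s",
                 bad_st[1] + 1L, path), call. = FALSE)
  }
  df <- as.data.frame(dt)
  df <- df[order(df$sow_id, df$day, df$tick), , drop = FALSE]
  key <- paste(df$sow_id, df$day, df$tick)
  if (anyDuplicated(key)) {
    stop("duplicate (sow_id, day, tick) rows in ", path, call. = FALSE)
  }
  gaps <- sum(vapply(split(df$tick, paste(df$sow_id, df$day)), function(tk) {
    sum(diff(sort(tk)) - 1L)
  }, numeric(1)))
  class(df) <- c("posture_stream", "data.frame")
  attr(df, "missing_ticks") <- gaps
  df
}

# Small stable polynomial hash of a config, recorded in artifact logs.
.config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Cluster the two budgets in every period
#'
#' For each period (bf, df, af) and each budget (postural, standing
#' activity): keeps complete sows, zero-replaces and ILR-transforms the
#' daily budgets, fits a k sweep (longitudinal joint-distance k-means for
#' the multi-day periods, cross-sectional for D0), picks k by the elbow
#' rule, and labels clusters A, B, ... by descending size. For the activity
#' budget a sow must additionally have a defined standing budget on every
#' day of the period.
#'
#' @param traits sow-day traits from [compute_daily_traits()].
#' @param ks candidate numbers of clusters (capped at the number of sows).
#' @param n_init random restarts per k.
#' @param seed integer seed.
#' @param delta zero-replacement value.
#' @return List of class `budget_clusters`: per period a list with
#'   `postural` and `activity` (each `model`, `k`, `inertias`), plus
#'   `labels`, a per-sow `data.frame` of cluster letters with columns
#'   `post_cl_<p>` / `act_cl_<p>`.
#' @export
cluster_budgets <- function(traits, ks = 1:5, n_init = 50L, seed = 1L,
                            delta = 1 / (2 * 17280)) {
  pb <- posture_ilr_basis()
  ab <- activity_ilr_basis()
  labels <- data.frame(sow_id = unique(traits$sow_id),
                       stringsAsFactors = FALSE)
  out <- list()
  for (p in c("bf", "df", "af")) {
    pd <- assemble_period_dataset(traits, p)
    res_p <- list()
    for (budget in c("postural", "activity")) {
      cols <- if (budget == "postural") paste0("p_", pb$parts) else
        paste0("a_", ab$parts)
      basis <- if (budget == "postural") pb else ab
      tr <- pd$traits
      ok_sows <- names(pd$complete)[pd$complete]
      if (budget == "activity") {
        has_na <- unique(tr$sow_id[is.na(tr$a_EAT)])
        ok_sows <- setdiff(ok_sows, has_na)
      }
      tr <- tr[tr$sow_id %in% ok_sows, , drop = FALSE]
      if (length(ok_sows) < 2L) {
        res_p[[budget]] <- NULL
        next
      }
      comp <- zero_replace(as.matrix(tr[, cols, drop = FALSE]), delta)
      colnames(comp) <- basis$parts
      y <- ilr_transform(comp, basis)
      trajs <- lapply(split(seq_len(nrow(tr)), tr$sow_id), function(i) {
        y[i[order(tr$day[i])], , drop = FALSE]
      })
      X <- t(vapply(trajs, function(m) as.vector(t(m)),
                    numeric(length(pd$days) * ncol(y))))
      rownames(X) <- names(trajs)
      kmax <- min(max(ks), nrow(X))
      sweep_ks <- seq(min(ks), kmax)
      models <- cluster_sweep(X, sweep_ks, n_init = n_init,
                              seed = .sub_seed(seed, 6L,
                                               match(p, c("bf", "df", "af"))))
      inertias <- vapply(models, `[[`, numeric(1), "inertia")
      k <- if (length(inertias) >= 3L) elbow_select_k(inertias) else
        as.integer(names(inertias)[length(inertias)])
      model <- models[[as.character(k)]]
      res_p[[budget]] <- list(model = model, k = k, inertias = inertias)
      colname <- paste0(if (budget == "postural") "post_cl_" else "act_cl_", p)
      labels[[colname]] <- unname(model$assignments[labels$sow_id])
    }
    out[[p]] <- res_p
  }
  structure(c(out, list(labels = labels)), class = "budget_clusters")
}

#' Run the full analysis pipeline
#'
#' Chains the stages `simulate` (synthetic cohort), `extract` (daily traits
#' from streams), `cluster` (budget clustering), `associate` (three-step
#' survival and growth selection) and `report`, writing intermediate CSV /
#' JSON artifacts into `out_dir`. Each later stage reads the artifacts of
#' the earlier ones, so stages can be re-run individually; a missing
#' dependency is reported by artifact name. Every run writes `run_log.json`
#' with the seed, a config hash and package version; deterministic stages
#' are bit-identical on rerun.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "extract", "cluster", "associate", "report")`.
#' @param ks,n_init clustering controls passed to [cluster_budgets()].
#' @param write_streams also write the (large) tick stream CSV.
#' @return Invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "extract", "cluster",
                                    "associate", "report"),
                         ks = 1:5, n_init = 50L, write_streams = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)
  need <- function(f) {
    if (!file.exists(art(f))) {
      stop("missing pipeline artifact '", f,
           "': run the earlier stage first", call. = FALSE)
    }
    art(f)
  }
  res <- list()
  jsonlite::write_json(
    list(seed = config$seed, config_hash = .config_hash(config),
         package = "sowactivity",
         version = as.character(utils::packageVersion("sowactivity")),
         r_version = R.version.string),
    art("run_log.json"), auto_unbox = TRUE)
  if ("simulate" %in% stages) {
    cohort <- build_cohort(config, return_streams = write_streams)
    if (write_streams && !is.null(cohort$streams)) {
      write_stream_csv(cohort$streams, art("streams.csv"))
    }
    data.table::fwrite(cohort$traits, art("traits.csv"))
    cov <- cohort$covariates
    data.table::fwrite(cov, art("covariates.csv"))
    data.table::fwrite(cohort$piglets, art("piglets.csv"))
    res$cohort <- cohort
  }
  if ("extract" %in% stages) {
    if (!is.null(res$cohort)) {
      traits <- res$cohort$traits
    } else {
      streams <- read_stream_csv(need("streams.csv"))
      traits <- compute_daily_traits(streams)
      data.table::fwrite(traits, art("traits.csv"))
    }
    res$traits <- traits
  }
  if ("cluster" %in% stages) {
    traits <- res$traits
    if (is.null(traits)) traits <- as.data.frame(data.table::fread(need("traits.csv")))
    cl <- cluster_budgets(traits, ks = ks, n_init = n_init,
                          seed = config$seed)
    data.table::fwrite(cl$labels, art("clusters.csv"))
    res$clusters <- cl
  }
  if ("associate" %in% stages) {
    cohort <- res$cohort
    if (is.null(cohort)) {
      cohort <- list(
        piglets = as.data.frame(data.table::fread(need("piglets.csv"))),
        covariates = as.data.frame(data.table::fread(need("covariates.csv"))))
    }
    labels <- if (!is.null(res$clusters)) res$clusters$labels else
      as.data.frame(data.table::fread(need("clusters.csv")))
    d <- prepare_association_data(cohort, labels)
    surv <- three_step_selection(d, "survival")
    growth <- three_step_selection(d, "growth")
    jsonlite::write_json(model_report(surv), art("survival_model.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(model_report(growth), art("growth_model.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    data.table::fwrite(surv$trace, art("survival_trace.csv"))
    data.table::fwrite(growth$trace, art("growth_trace.csv"))
    res$survival <- surv
    res$growth <- growth
  }
  if ("report" %in% stages) {
    txt <- report(res$survival, res$growth, res$clusters)
    writeLines(txt, art("report.txt"))
    res$report <- txt
  }
  invisible(res)
}

#' Serializable model report
#'
#' Flattens a `selection_result` into a list of term rows (estimate, and for
#' survival the hazard ratio with 95% CI and percent risk change) suitable
#' for JSON round-tripping.
#'
#' @param result a `selection_result`.
#' @return List with `outcome`, `behavioural_terms` and `coefficients`.
#' @export
model_report <- function(result) {
  if (result$outcome == "survival") {
    tab <- result$final$coefficients
    tab$risk_change_pct <- hazard_ratio_to_pct(tab$hr)
  } else {
    sm <- summary(result$final)$coefficients
    tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  }
  list(outcome = result$outcome,
       behavioural_terms = as.list(result$terms),
       coefficients = tab)
}

#' Human-readable pipeline report
#'
#' Renders the cluster composition per period (size and centre budgets) and
#' the final survival and growth models; hazard ratios are annotated with
#' the implied percent change in the instantaneous risk of dying.
#'
#' @param survival,growth `selection_result`s (either may be `NULL`).
#' @param clusters a `budget_clusters` (may be `NULL`).
#' @return Character vector of report lines.
#' @export
report <- function(survival = NULL, growth = NULL, clusters = NULL) {
  lines <- character(0)
  if (!is.null(clusters)) {
    lines <- c(lines, "== Activity-pattern clusters ==")
    pb <- posture_ilr_basis(); ab <- activity_ilr_basis()
    for (p in intersect(c("bf", "df", "af"), names(clusters))) {
      for (budget in names(clusters[[p]])) {
        m <- clusters[[p]][[budget]]$model
        basis <- if (budget == "postural") pb else ab
        lines <- c(lines, sprintf("%s %s: k = %d", p, budget, m$k))
        d1 <- ncol(basis$contrast)
        for (cl in rownames(m$centers)) {
          # centre of the (possibly multi-day) trajectory, averaged over days
          cen <- matrix(m$centers[cl, ], ncol = nrow(basis$contrast),
                        byrow = TRUE)
          comp <- ilr_inverse(colMeans(cen), basis)
          lines <- c(lines, sprintf(
            "  cluster %s (n = %d): %s", cl, m$sizes[[cl]],
            paste(sprintf("%s %.1f%%", basis$parts, 100 * comp),
                  collapse = ", ")))
        }
      }
    }
  }
  fmt_model <- function(res, title) {
    out <- c(sprintf("== %s ==", title),
             sprintf("behavioural terms: %s",
                     if (length(res$terms)) paste(res$terms, collapse = ", ")
                     else "(none; covariates-only model)"))
    rep_tab <- model_report(res)$coefficients
    for (i in seq_len(nrow(rep_tab))) {
      r <- rep_tab[i, ]
      out <- c(out, if (!is.null(r$hr)) {
        sprintf("  %s: HR %.2f [%.2f, %.2f] (%.0f%% %s in risk), p = %.3g",
                r$term, r$hr, r$hr_lo, r$hr_hi,
                abs(hazard_ratio_to_pct(r$hr)),
                if (r$hr <= 1) "reduction" else "increase", r$p)
      } else {
        sprintf("  %s: %+.2f g/d (SE %.2f), p = %.3g", r$term, r$estimate,
                r$se, r$p)
      })
    }
    out
  }
  if (!is.null(survival)) lines <- c(lines, fmt_model(survival, "Piglet survival (Cox PH)"))
  if (!is.null(growth)) lines <- c(lines, fmt_model(growth, "Piglet growth (ADG, linear model)"))
  if (!length(lines)) lines <- "(nothing to report)"
  lines
}
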