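# Posture streams and daily behavioural traits ------------------------------

#' Construct a posture stream table
#'
#' A posture stream is a long-format table with one row per 5-s tick, columns
#' `sow_id`, `day` (relative day, -3..7, day 0 = the 24 h after the birth of
#' the first piglet), `tick` (0-based index within the sow-day), `posture`
#' and `activity` (`NA` unless the posture is `ST`). Several sow-days may be
#' stacked in one table; all per-day operations group by (`sow_id`, `day`).
#'
#' @param sow_id character or integer vector (recycled).
#' @param day integer relative day (recycled).
#' @param posture character vector of ethogram posture labels.
#' @param activity character vector of standing-activity labels or `NA`.
#' @param tick 0-based tick indices; defaults to `seq_along(posture) - 1`.
#' @return A `data.frame` of class `posture_stream`.
#' @export
posture_stream <- function(sow_id, day, posture, activity = NA_character_,
                           tick = NULL) {
  n <- length(posture)
  if (n == 0L) stop("empty stream", call. = FALSE)
  if (is.null(tick)) tick <- seq_len(n) - 1L
  df <- data.frame(sow_id = rep_len(as.character(sow_id), n),
                   day = rep_len(as.integer(day), n),
                   tick = as.integer(tick),
                   posture = as.character(posture),
                   activity = rep_len(as.character(activity), n),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$activity) & df$posture != "ST"
  if (any(bad)) stop("activity label on a non-ST tick", call. = FALSE)
  class(df) <- c("posture_stream", "data.frame")
  df
}

.stream_groups <- function(stream) {
  interaction(stream$sow_id, stream$day, drop = TRUE, lex.order = TRUE)
}

# Vector core of the despiking rule. Singleton runs are identified on the raw
# sequence; the pass is left-to-right and the replacement is read from the
# evolving output, so chained singletons propagate the last surviving label.
# A leading singleton has no previous observation and is kept.
.despike_vec <- function(p) {
  n <- length(p)
  if (n == 0L) stop("empty stream", call. = FALSE)
  if (n == 1L) return(seq_len(0L))
  r <- rle(p)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  singles <- starts[r$lengths == 1L]
  singles[singles > 1L]
}

#' Remove single-tick posture runs
#'
#' Postures lasting a single 5-s observation are treated as classifier false
#' predictions and replaced by the posture of the previous observation, in a
#' single left-to-right pass. The activity label of a replaced tick is copied
#' from the tick supplying the replacement posture, keeping the
#' activity-only-while-standing constraint intact. A singleton at the very
#' start of a sow-day has no previous observation and is left unchanged.
#'
#' @param stream a `posture_stream` table (one or many sow-days).
#' @return The despiked stream; every interior run has length >= 2.
#' @export
despike <- function(stream) {
  if (!nrow(stream)) stop("empty stream", call. = FALSE)
  g <- .stream_groups(stream)
  posture <- stream$posture
  activity <- stream$activity
  for (idx in split(seq_len(nrow(stream)), g)) {
    singles <- idx[.despike_vec(posture[idx])]
    for (i in singles) {
      posture[i] <- posture[i - 1L]
      activity[i] <- activity[i - 1L]
    }
  }
  stream$posture <- posture
  stream$activity <- activity
  stream
}

#' Relabel postures through a merge map
#'
#' Applies a label mapping from ethogram postures onto analysis classes. The
#' default map pools the two visually confounded classes sitting (`SI`) and
#' kneeling (`K`) into `SIK`.
#'
#' @param stream a `posture_stream` table.
#' @param merge_map named character vector, names = input labels.
#' @return Stream with relabelled postures.
#' @export
merge_postures <- function(stream, merge_map = default_merge_map()) {
  out <- merge_map[stream$posture]
  if (anyNA(out)) {
    bad <- unique(stream$posture[is.na(out)])
    stop(sprintf("unmapped posture label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  stream$posture <- unname(out)
  stream
}

#' Classify the standing activity from head position
#'
#' While the sow is standing, the distance from her head to the drinking
#' trough and to the feeder decides the activity: `DRINK` if the head is
#' within `r_drink` of the trough, otherwise `EAT` if within `r_eat` of the
#' feeder, otherwise `OTHER`. When both radii are satisfied `DRINK` takes
#' precedence (a head inside the drinking trough cannot be feeding).
#'
#' @param head_xy numeric length-2 vector or n x 2 matrix of head positions.
#' @param trough_xy,feeder_xy length-2 centres of the two troughs.
#' @param r_drink,r_eat positive detection radii (same spatial units).
#' @return Character vector of activity labels.
#' @export
classify_standing_activity <- function(head_xy, trough_xy, feeder_xy,
                                       r_drink, r_eat) {
  if (r_drink <= 0 || r_eat <= 0) stop("radii must be positive", call. = FALSE)
  m <- if (is.matrix(head_xy)) head_xy else matrix(head_xy, ncol = 2L)
  d_trough <- sqrt((m[, 1] - trough_xy[1])^2 + (m[, 2] - trough_xy[2])^2)
  d_feeder <- sqrt((m[, 1] - feeder_xy[1])^2 + (m[, 2] - feeder_xy[2])^2)
  ifelse(d_trough <= r_drink, "DRINK",
         ifelse(d_feeder <= r_eat, "EAT", "OTHER"))
}

#' Daily postural time budget
#'
#' Proportion of ticks spent in each posture class over one sow-day.
#'
#' @param stream a single sow-day `posture_stream`.
#' @param classes posture classes the budget closes over; default guesses the
#'   merged or raw vocabulary from the labels present.
#' @return Named proportion vector summing to 1.
#' @export
daily_postural_budget <- function(stream, classes = NULL) {
  p <- stream$posture
  if (!length(p)) stop("empty stream", call. = FALSE)
  if (is.null(classes)) {
    classes <- if (all(p %in% MERGED_POSTURES)) MERGED_POSTURES else POSTURES
  }
  .assert_postures(p, classes)
  tab <- table(factor(p, levels = classes))
  setNames(as.vector(tab) / length(p), classes)
}

#' Daily standing-activity budget
#'
#' Proportions of `EAT`, `DRINK` and `OTHER` among the standing (`ST`) ticks
#' of one sow-day. A day with no standing tick has no defined budget and
#' returns `NA` (absence, not a zero composition).
#'
#' @param stream a single sow-day `posture_stream`.
#' @return Named proportions over `EAT`, `DRINK`, `OTHER`, or all-`NA`.
#' @export
daily_standing_budget <- function(stream) {
  st <- stream$activity[stream$posture == "ST"]
  if (!length(st)) {
    return(setNames(rep(NA_real_, 3L), ACTIVITIES))
  }
  .assert_postures(st, ACTIVITIES, "activity")
  tab <- table(factor(st, levels = ACTIVITIES))
  setNames(as.vector(tab) / length(st), ACTIVITIES)
}

# Vector core: posture-change counts on one sow-day label sequence.
.count_changes_vec <- function(p) {
  n <- length(p)
  if (n < 2L) return(c(PCAll = 0L, PCRiskCrush = 0L, PCStopNurse = 0L))
  from <- p[-n]
  to <- p[-1L]
  chg <- from != to
  key <- paste(from[chg], to[chg], sep = ">")
  risk_keys <- paste(.RISK_CRUSH_FROM, .RISK_CRUSH_TO, sep = ">")
  c(PCAll = sum(chg),
    PCRiskCrush = sum(key %in% risk_keys),
    PCStopNurse = sum(from[chg] == "LLU"))
}

#' Count daily posture changes
#'
#' Three daily restlessness counts from a (despiked) stream: `PCAll`, every
#' adjacent pair of ticks with different postures; `PCRiskCrush`, transitions
#' at risk of crushing a piglet (standing to lying `ST->{SL,LL,LLU}` and
#' sternal to lateral lying `SL->{LL,LLU}`); `PCStopNurse`, transitions that
#' hide the udder and can end a nursing bout (`LLU->` any other posture).
#'
#' @param stream a single sow-day `posture_stream` (despiked).
#' @return Named integer vector `PCAll`, `PCRiskCrush`, `PCStopNurse`.
#' @export
count_posture_changes <- function(stream) {
  .count_changes_vec(stream$posture)
}

# Daily trait assembly --------------------------------------------------------

#' Compute the five daily behavioural traits for every sow-day
#'
#' Runs the fixed extraction pipeline — despike, merge postures, then budgets
#' and posture-change counts — over a stacked stream table. The order is part
#' of the method: merging before despiking can hide genuine singletons (two
#' distinct raw postures mapping to one class) and is not permitted.
#'
#' @param streams a `posture_stream` table with one or many sow-days.
#' @param merge_map posture merge map, see [merge_postures()].
#' @param despike logical; apply the single-observation despiking rule first.
#' @return `data.frame` with one row per sow-day: posture budget columns
#'   `p_<class>`, standing-activity columns `a_EAT`/`a_DRINK`/`a_OTHER`
#'   (NA on days without standing), the three counts and `total_ticks`.
#' @export
compute_daily_traits <- function(streams, merge_map = default_merge_map(),
                                 despike = TRUE) {
  if (!nrow(streams)) {
    return(data.frame(sow_id = character(), day = integer()))
  }
  .assert_postures(streams$posture, names(merge_map))
  if (despike) streams <- despike(streams)
  streams <- merge_postures(streams, merge_map)
  classes <- unique(unname(merge_map))
  dt <- data.table::as.data.table(streams)
  one_day <- function(posture, activity) {
    n <- length(posture)
    tab <- tabulate(factor(posture, levels = classes), nbins = length(classes))
    st <- activity[posture == "ST"]
    atab <- if (length(st)) {
      tabulate(factor(st, levels = ACTIVITIES), 3L) / length(st)
    } else rep(NA_real_, 3L)
    counts <- .count_changes_vec(posture)
    out <- c(as.list(tab / n), as.list(atab), as.list(counts),
             list(n))
    names(out) <- c(paste0("p_", classes), paste0("a_", ACTIVITIES),
                    names(counts), "total_ticks")
    out
  }
  res <- dt[, one_day(posture, activity), by = c("sow_id", "day")]
  out <- as.data.frame(res)
  out[order(out$sow_id, out$day), , drop = FALSE]
}

# Periods ---------------------------------------------------------------------

#' Relative days covered by each peripartum period
#'
#' `bf` (before farrowing) = D-3..D-1, `df` (day of farrowing) = D0 defined
#' as the 24 h after the birth of the first piglet, `af` (after farrowing) =
#' D1..D7.
#'
#' @param period one of `"bf"`, `"df"`, `"af"`.
#' @return Integer vector of relative days.
#' @export
period_days <- function(period) {
  switch(match.arg(period, c("bf", "df", "af")),
         bf = -3:-1, df = 0L, af = 1:7)
}

#' Assemble the per-period trait dataset
#'
#' Groups sow-day traits into one peripartum period and flags the sows with a
#' complete run of observed days; only complete sows enter the period's
#' clustering.
#'
#' @param traits output of [compute_daily_traits()].
#' @param period `"bf"`, `"df"` or `"af"`.
#' @return A list of class `period_dataset` with elements `period`, `days`,
#'   `traits` (rows of the period) and `complete` (named logical per sow).
#' @export
assemble_period_dataset <- function(traits, period) {
  period <- match.arg(period, c("bf", "df", "af"))
  days <- period_days(period)
  sub <- traits[traits$day %in% days, , drop = FALSE]
  sows <- unique(traits$sow_id)
  complete <- vapply(sows, function(s) {
    all(days %in% sub$day[sub$sow_id == s])
  }, logical(1))
  structure(list(period = period, days = days, traits = sub,
                 complete = setNames(complete, sows)),
            class = "period_dataset")
}

#' @export
print.period_dataset <- function(x, ...) {
  cat(sprintf("Period '%s' (days %s): %d sow-days, %d/%d complete sows\n",
              x$period, paste(range(x$days), collapse = ".."),
              nrow(x$traits), sum(x$complete), length(x$complete)))
  invisible(x)
}
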