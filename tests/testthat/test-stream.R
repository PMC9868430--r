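test_that("despiking replaces singleton runs with the previous posture", {
  s <- posture_stream("a", 0, c("LL", "LL", "ST", "LL", "LL"))
  expect_equal(despike(s)$posture, rep("LL", 5))

  # single-pass semantics: the SL singleton copies the (already final) ST
  s2 <- posture_stream("a", 0, c("LL", "ST", "ST", "SL", "LL", "LL"))
  expect_equal(despike(s2)$posture, c("LL", "ST", "ST", "ST", "LL", "LL"))

  # chained singletons propagate the last surviving posture
  s3 <- posture_stream("a", 0, c("LL", "LL", "SI", "K", "LL"))
  expect_equal(despike(s3)$posture, c("LL", "LL", "LL", "LL", "LL"))

  # a leading singleton has no previous observation and is kept
  s4 <- posture_stream("a", 0, c("ST", "LL", "LL"))
  expect_equal(despike(s4)$posture, c("ST", "LL", "LL"))

  expect_error(despike(posture_stream("a", 0, character(0))), "empty")
})

test_that("despiking is idempotent and never increases PCAll", {
  set.seed(11)
  for (i in 1:50) {
    s <- posture_stream("a", 0, random_stream_vec(60))
    d1 <- despike(s)
    expect_identical(despike(d1)$posture, d1$posture)
    expect_lte(count_posture_changes(d1)[["PCAll"]],
               count_posture_changes(s)[["PCAll"]])
    r <- rle(d1$posture)
    expect_true(all(r$lengths[-1] >= 2))
  }
})

test_that("despiking keeps replaced ticks' activities consistent", {
  s <- posture_stream("a", 0, c("ST", "ST", "LL", "ST", "ST"),
                      c("EAT", "EAT", NA, "DRINK", "DRINK"))
  d <- despike(s)
  expect_equal(d$posture, rep("ST", 5))
  expect_equal(d$activity, c("EAT", "EAT", "EAT", "DRINK", "DRINK"))
  expect_true(all(is.na(d$activity[d$posture != "ST"])))
})

test_that("posture merging follows the map and rejects unknown labels", {
  s <- posture_stream("a", 0, c("K", "SI", "ST"))
  expect_equal(merge_postures(s)$posture, c("SIK", "SIK", "ST"))
  ident <- setNames(POSTURES, POSTURES)
  expect_equal(merge_postures(s, ident)$posture, s$posture)
  expect_error(merge_postures(s, c(ST = "ST")), "unmapped")

  # merged-class budget is the sum of the constituent budgets
  set.seed(2)
  s2 <- posture_stream("a", 0, random_stream_vec(500))
  raw <- daily_postural_budget(s2, POSTURES)
  merged <- daily_postural_budget(merge_postures(s2), MERGED_POSTURES)
  expect_equal(merged[["SIK"]], raw[["SI"]] + raw[["K"]])
  expect_equal(merged[["LLU"]], raw[["LLU"]])
})

test_that("daily budgets count ticks and close to one", {
  s <- posture_stream("a", 0, rep("LL", 100))
  b <- daily_postural_budget(s)
  expect_equal(b[["LL"]], 1)
  expect_equal(sum(b), 1)

  s2 <- posture_stream("a", 0, rep(c("ST", "LL"), each = 8640),
                       c(rep("EAT", 8640), rep(NA, 8640)))
  b2 <- daily_postural_budget(s2)
  expect_equal(b2[["ST"]], 0.5)
  expect_equal(b2[["LL"]], 0.5)
  expect_equal(daily_standing_budget(s2), c(EAT = 1, DRINK = 0, OTHER = 0))
})

test_that("standing budget is missing (not zero) without standing ticks", {
  s <- posture_stream("a", 0, rep("LL", 10))
  expect_true(all(is.na(daily_standing_budget(s))))

  acts <- c(rep("EAT", 27), rep("DRINK", 21), rep("OTHER", 52))
  s2 <- posture_stream("a", 0, rep("ST", 100), acts)
  expect_equal(daily_standing_budget(s2),
               c(EAT = 0.27, DRINK = 0.21, OTHER = 0.52))
})

test_that("posture-change counts match the transition definitions", {
  expect_equal(count_posture_changes(posture_stream("a", 0, rep("LL", 9))),
               c(PCAll = 0L, PCRiskCrush = 0L, PCStopNurse = 0L))
  s <- posture_stream("a", 0, c("ST", "LL", "LL", "SL", "LLU", "ST"))
  expect_equal(count_posture_changes(s),
               c(PCAll = 4L, PCRiskCrush = 2L, PCStopNurse = 1L))
})

test_that("counts agree with the brute-force oracle on random streams", {
  set.seed(99)
  for (i in 1:300) {
    p <- random_stream_vec(sample(2:80, 1))
    expect_identical(unname(count_posture_changes(posture_stream("a", 0, p))),
                     unname(as.integer(oracle_counts(p))))
  }
})

test_that("risk and nursing-stop counts are bounded by total changes", {
  set.seed(5)
  for (i in 1:100) {
    cc <- count_posture_changes(posture_stream("a", 0, random_stream_vec(120)))
    expect_lte(cc[["PCRiskCrush"]] + cc[["PCStopNurse"]], 2 * cc[["PCAll"]])
    expect_true(all(cc >= 0))
  }
})

test_that("standing activity classification uses distance with DRINK precedence", {
  trough <- c(0, 0); feeder <- c(10, 0)
  expect_equal(classify_standing_activity(c(0, 0), trough, feeder, 1, 1), "DRINK")
  expect_equal(classify_standing_activity(c(10, 0), trough, feeder, 1, 1), "EAT")
  expect_equal(classify_standing_activity(c(5, 5), trough, feeder, 1, 1), "OTHER")
  # both radii satisfied: drinking wins
  expect_equal(classify_standing_activity(c(5, 0), trough, feeder, 6, 6), "DRINK")
  m <- rbind(c(0, 0), c(10, 0), c(50, 50))
  expect_equal(classify_standing_activity(m, trough, feeder, 1, 1),
               c("DRINK", "EAT", "OTHER"))
  expect_error(classify_standing_activity(c(0, 0), trough, feeder, 0, 1),
               "positive")
})

test_that("extraction order matters: merging before despiking can hide spikes", {
  p <- c("LL", "SI", "K", "LL")
  s <- posture_stream("a", 0, p)
  despike_first <- merge_postures(despike(s))
  merge_first <- despike(merge_postures(s))
  expect_equal(despike_first$posture, rep("LL", 4))
  expect_equal(merge_first$posture, c("LL", "SIK", "SIK", "SIK"))
  expect_false(identical(despike_first$posture, merge_first$posture))
})

test_that("period datasets flag incomplete sows", {
  days <- -3:7
  traits <- data.frame(sow_id = rep(c("s1", "s2"), each = length(days)),
                       day = rep(days, 2))
  traits <- traits[!(traits$sow_id == "s2" & traits$day == -2), ]
  bf <- assemble_period_dataset(traits, "bf")
  expect_true(bf$complete[["s1"]])
  expect_false(bf$complete[["s2"]])
  expect_true(assemble_period_dataset(traits, "df")$complete[["s2"]])
  expect_true(assemble_period_dataset(traits, "af")$complete[["s2"]])
  expect_equal(assemble_period_dataset(traits, "af")$days, 1:7)
})

test_that("compute_daily_traits assembles budgets, counts and closure", {
  set.seed(31)
  streams <- rbind(
    posture_stream("s1", 0, random_stream_vec(400)),
    posture_stream("s1", 1, random_stream_vec(400)),
    posture_stream("s2", 0, random_stream_vec(400)))
  streams$activity[streams$posture == "ST"] <- "OTHER"
  class(streams) <- c("posture_stream", "data.frame")
  tr <- compute_daily_traits(streams)
  expect_equal(nrow(tr), 3L)
  pcols <- paste0("p_", MERGED_POSTURES)
  expect_true(all(abs(rowSums(tr[, pcols]) - 1) < 1e-12))
  expect_true(all(tr$total_ticks == 400L))
  expect_true(all(tr$PCAll >= tr$PCRiskCrush))
  # counts are computed on the despiked, merged stream
  one <- merge_postures(despike(streams[streams$sow_id == "s2", ]))
  expect_equal(tr$PCAll[tr$sow_id == "s2"],
               count_posture_changes(one)[["PCAll"]])
})
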