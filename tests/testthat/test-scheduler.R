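# Reminder calendar and the within-one-week adherence statistic.

test_that("the default schedule reproduces the study calendar", {
  sch <- build_schedule()
  expect_equal(sch$offsets$memory_word, c(1L, 29L, 99L, 169L))
  expect_equal(sch$offsets$tmt, c(2L, 43L, 113L, 170L))
  expect_equal(sch$offsets$stroop, c(3L, 57L, 127L, 171L))
  expect_equal(sch$offsets$reaction, c(4L, 71L, 141L, 172L))
  expect_equal(sch$offsets$nback, c(15L, 85L, 155L, 173L))
  expect_equal(sch$window_days, 7L)
  for (t in names(sch$offsets)) {
    expect_length(sch$offsets[[t]], 4)
    last <- max(sch$offsets[[t]])
    expect_true(last >= 169 && last <= 173)
    expect_true(all(diff(sch$offsets[[t]]) > 0))
    expect_true(all(sch$offsets[[t]] <= 182))
  }
})

test_that("schedule validation rejects malformed offsets and accepts extras", {
  expect_error(build_schedule(list(offsets = list(stroop = c(10, 5, 20, 30)))),
               class = "invalid_config")
  expect_error(build_schedule(list(offsets = list(stroop = c(1, 50, 100)))),
               class = "invalid_config")
  expect_error(build_schedule(list(offsets = list(stroop = c(1, 50, 100, 200)))),
               class = "invalid_config")
  five <- build_schedule(list(offsets = list(stroop = c(3, 40, 80, 120, 160))))
  expect_length(five$offsets$stroop, 5)
})

test_that("adherence counts sessions inside each reminder window exactly once", {
  sch <- build_schedule()
  mk <- function(days, test = "memory_word", id = "P001") {
    data.frame(participant_id = id, test_id = test, day = days,
               stringsAsFactors = FALSE)
  }
  # exact-day sessions: 100%
  a <- compute_adherence(sch, mk(c(1, 29, 99, 169)))
  mw <- a$by_participant[a$by_participant$test_id == "memory_word", ]
  expect_equal(mw$adherence_pct, 100)
  # three of four windows hit: 75%
  a2 <- compute_adherence(sch, mk(c(1, 30, 99)))
  mw2 <- a2$by_participant[a2$by_participant$test_id == "memory_word", ]
  expect_equal(mw2$adherence_pct, 75)
  # day 37 misses the day-29 window entirely
  a3 <- compute_adherence(sch, mk(37))
  mw3 <- a3$by_participant[a3$by_participant$test_id == "memory_word", ]
  expect_equal(mw3$n_adherent, 0L)
  # one session cannot satisfy two reminders
  sch2 <- build_schedule(list(offsets = list(stroop = c(1, 5, 50, 100))))
  a4 <- compute_adherence(sch2, mk(6, test = "stroop"))
  st <- a4$by_participant[a4$by_participant$test_id == "stroop", ]
  expect_equal(st$n_adherent, 1L)
  # two sessions in overlapping windows satisfy both
  a5 <- compute_adherence(sch2, mk(c(6, 7), test = "stroop"))
  st5 <- a5$by_participant[a5$by_participant$test_id == "stroop", ]
  expect_equal(st5$n_adherent, 2L)
})

test_that("the window boundary day is excluded half-open and included closed", {
  mk <- function(day) data.frame(participant_id = "P001",
                                 test_id = "memory_word", day = day,
                                 stringsAsFactors = FALSE)
  # reminder day 29, window 7: day 36 = reminder + 7
  half_open <- build_schedule()
  closed <- build_schedule(list(window_closed = TRUE))
  n_adh <- function(sch, day) {
    a <- compute_adherence(sch, mk(day))
    sum(a$by_participant$n_adherent)
  }
  expect_equal(n_adh(half_open, 35), 1L)
  expect_equal(n_adh(half_open, 36), 0L)
  expect_equal(n_adh(closed, 36), 1L)
  expect_equal(n_adh(closed, 37), 0L)
  expect_equal(n_adh(half_open, 29), 1L)  # the reminder day itself counts
})

test_that("adherence is monotone in sessions and unknown tests are ignored", {
  sch <- build_schedule()
  base <- data.frame(participant_id = "P001", test_id = "stroop",
                     day = c(3, 58), stringsAsFactors = FALSE)
  a1 <- compute_adherence(sch, base)
  withr::with_seed(4, {
    for (rep in 1:10) {
      extra_day <- sample(1:180, 1)
      extra_test <- sample(names(sch$offsets), 1)
      more <- rbind(base, data.frame(participant_id = "P001",
                                     test_id = extra_test, day = extra_day,
                                     stringsAsFactors = FALSE))
      a2 <- compute_adherence(sch, more)
      expect_true(all(a2$by_participant$adherence_pct >=
                      a1$by_participant$adherence_pct))
    }
  })
  expect_warning(
    compute_adherence(sch, data.frame(participant_id = "P001",
                                      test_id = "sudoku", day = 3,
                                      stringsAsFactors = FALSE),
                      participant_ids = "P001"),
    "unknown test_id")
})

test_that("mean adherence pools each participant's reminders across tests", {
  sch <- build_schedule()
  # P001 hits all 4 memory reminders and nothing else: 4/20 reminders
  sess <- data.frame(participant_id = "P001", test_id = "memory_word",
                     day = c(1, 29, 99, 169), stringsAsFactors = FALSE)
  a <- compute_adherence(sch, sess, participant_ids = c("P001", "P002"))
  pp <- a$per_participant_mean
  expect_equal(pp$adherence_pct[pp$participant_id == "P001"], 20)
  expect_equal(pp$adherence_pct[pp$participant_id == "P002"], 0)
  expect_equal(a$mean_pct, 10)
})

test_that("ever-performed fractions ignore reminder timing", {
  sess <- data.frame(
    participant_id = c("P001", "P002", "P003", "P001"),
    test_id = c("stroop", "stroop", "stroop", "tmt"),
    day = c(3, 90, 181, 100), stringsAsFactors = FALSE)
  f <- ever_performed_fraction(sess, 4)
  expect_equal(unname(f["stroop"]), 0.75)
  expect_equal(unname(f["tmt"]), 0.25)
  expect_length(ever_performed_fraction(sess[0, ], 10), 0)
  expect_error(ever_performed_fraction(sess, 0), class = "invalid_input")
})
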