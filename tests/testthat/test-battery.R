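# The five smartphone test engines: stimulus structure, seeded determinism,
# scoring, and error handling.

test_that("word-memory stimuli have 10 studied and 10 new words in a seeded order", {
  pool <- default_word_pool()
  expect_gte(length(pool), 40)
  s <- generate_word_memory(pool, rng_seed = 11)
  expect_length(s$study_list, 10)
  expect_length(s$recognition_list, 20)
  expect_equal(sum(s$is_old), 10)
  expect_equal(anyDuplicated(s$recognition_list), 0L)
  expect_setequal(s$recognition_list[s$is_old], s$study_list)
  expect_false(any(s$recognition_list[!s$is_old] %in% s$study_list))
  # determinism across seeds
  expect_identical(generate_word_memory(pool, rng_seed = 11), s)
  expect_false(identical(generate_word_memory(pool, rng_seed = 12)$recognition_list,
                         s$recognition_list))
  expect_error(generate_word_memory(pool[1:19], 1), class = "invalid_input")
})

test_that("word-memory scoring counts agreement with the old/new key", {
  s <- generate_word_memory(rng_seed = 5)
  perfect <- score_word_memory(s, s$is_old)
  expect_equal(perfect$n_correct, 20L)
  expect_equal(perfect$n_incorrect, 0L)
  all_yes <- score_word_memory(s, rep(TRUE, 20))
  expect_equal(all_yes$n_correct, 10L)
  flipped <- s$is_old
  flipped[c(2, 7, 19)] <- !flipped[c(2, 7, 19)]
  expect_equal(score_word_memory(s, flipped)$n_correct, 17L)
  # correct + incorrect is always the full 20-item list
  for (seed in 1:5) {
    resp <- withr::with_seed(seed, sample(c(TRUE, FALSE), 20, replace = TRUE))
    sc <- score_word_memory(s, resp)
    expect_equal(sc$n_correct + sc$n_incorrect, 20L)
  }
  expect_error(score_word_memory(s, rep(TRUE, 19)), class = "incomplete_session")
  expect_error(score_word_memory(s, c(rep(TRUE, 19), NA)),
               class = "incomplete_session")
})

test_that("trail sequences follow each part's labelling rule", {
  expect_equal(trail_sequence(1), as.character(1:12))
  expect_equal(trail_sequence(2), LETTERS[1:12])
  expect_equal(trail_sequence(3),
               c("1", "A", "2", "B", "3", "C", "4", "D", "5", "E", "6", "F"))
  expect_equal(trail_sequence(4),
               c("1", "Z", "2", "Y", "3", "X", "4", "W", "5", "V", "6", "U"))
  expect_equal(trail_sequence(4)[1:4], c("1", "Z", "2", "Y"))
  # parts 3 and 4 alternate numbers 1-6 with six distinct letters
  for (part in 3:4) {
    seq <- trail_sequence(part)
    expect_equal(seq[c(TRUE, FALSE)], as.character(1:6))
    letters_used <- seq[c(FALSE, TRUE)]
    expect_length(unique(letters_used), 6)
    expect_true(all(letters_used %in% LETTERS))
  }
  expect_error(trail_sequence(5), class = "invalid_input")
  expect_error(trail_sequence(0), class = "invalid_input")
})

test_that("trail layouts place 12 non-overlapping circles reproducibly", {
  for (part in 1:4) {
    lay <- generate_trail_part(part, rng_seed = part * 7)
    expect_equal(nrow(lay$positions), 12L)
    expect_equal(lay$labels, trail_sequence(part))
    d <- as.matrix(stats::dist(lay$positions))
    diag(d) <- Inf
    expect_gt(min(d), 2 * lay$radius)  # strictly more than one diameter apart
    expect_true(all(lay$positions >= lay$radius & lay$positions <= 1 - lay$radius))
  }
  expect_identical(generate_trail_part(2, 99), generate_trail_part(2, 99))
  expect_false(identical(generate_trail_part(2, 99)$positions,
                         generate_trail_part(2, 100)$positions))
  expect_error(generate_trail_part(1, 1, layout_config = list(radius = 0.4)),
               class = "layout_infeasible")
})

test_that("trail scoring times the last correct tap and counts stray taps", {
  lay <- generate_trail_part(3, 1)
  clean <- clean_trail_taps(lay)
  sc <- score_trail(lay, clean)
  expect_equal(sc$time_s, 12)
  expect_equal(sc$n_errors, 0L)
  # two wrong taps interleaved: same completion time, two errors
  wrong <- rbind(clean, data.frame(time_ms = c(1500, 2500),
                                   label = c("6", "F")))
  wrong <- wrong[order(wrong$time_ms), ]
  sc2 <- score_trail(lay, wrong)
  expect_equal(sc2$time_s, 12)
  expect_equal(sc2$n_errors, 2L)
  expect_error(score_trail(lay, clean[1:11, ]), class = "incomplete_session")
  # duplicate taps within one frame collapse to the first
  dup <- rbind(clean, data.frame(time_ms = 1000, label = "9"))
  dup <- dup[order(dup$time_ms), ]
  expect_equal(score_trail(lay, dup)$n_errors, 0L)
  # alternative policy: a wrong tap is an error and consumes the target
  skipped <- clean
  skipped$label[3] <- "F"   # not the expected "2"
  sc3 <- score_trail(lay, skipped, advance_on_error = TRUE)
  expect_equal(sc3$n_errors, 1L)
  expect_equal(sc3$time_s, 12)
  expect_error(score_trail(lay, skipped), class = "incomplete_session")
})

test_that("stroop panels satisfy each part's display rule on 30 items", {
  colors <- c("red", "green", "blue", "yellow")
  p1 <- generate_stroop_panel(1, colors, 3)
  expect_equal(nrow(p1$items), 30L)
  expect_true(all(p1$items$display_color == "black"))
  expect_equal(p1$items$correct_answer, p1$items$display_text)
  p2 <- generate_stroop_panel(2, colors, 3)
  expect_equal(p2$items$correct_answer, p2$items$display_color)
  p3 <- generate_stroop_panel(3, colors, 3)
  expect_equal(nrow(p3$items), 30L)
  expect_true(all(p3$items$display_text != p3$items$display_color))
  expect_equal(p3$items$correct_answer, p3$items$display_color)
  expect_true(all(p3$items$correct_answer %in% p3$answer_options))
  expect_identical(generate_stroop_panel(3, colors, 8),
                   generate_stroop_panel(3, colors, 8))
  expect_error(generate_stroop_panel(3, "red", 1), class = "invalid_input")
  expect_error(generate_stroop_panel(4, colors, 1), class = "invalid_input")
})

test_that("stroop scoring tallies answers, timing and the below-half flag", {
  p <- generate_stroop_panel(3, rng_seed = 2)
  resp <- data.frame(answer = p$items$correct_answer,
                     time_ms = seq(1500, by = 1500, length.out = 30))
  sc <- score_stroop(p, resp)
  expect_equal(sc$n_correct, 30L)
  expect_equal(sc$time_s, 45)
  expect_false(sc$details$below_half_correct)
  # 14/30 correct is below half, 15/30 is not
  resp14 <- resp
  wrong_idx <- 1:16
  resp14$answer[wrong_idx] <- p$items$display_text[wrong_idx]  # word, not ink
  sc14 <- score_stroop(p, resp14)
  expect_equal(sc14$n_correct, 14L)
  expect_true(sc14$details$below_half_correct)
  resp15 <- resp
  resp15$answer[1:15] <- p$items$display_text[1:15]
  expect_false(score_stroop(p, resp15)$details$below_half_correct)
  expect_error(score_stroop(p, resp[0, ]), class = "incomplete_session")
  expect_error(score_stroop(p, resp[1:29, ]), class = "incomplete_session")
})

test_that("reaction trial sets respect part rules and carry one startle probe", {
  r1 <- generate_reaction_trials(1, 10, 4)
  expect_equal(nrow(r1$trials), 10L)
  expect_true(all(r1$trials$target_type == "blue"))
  expect_equal(sum(r1$trials$is_startle), 1L)
  r2 <- generate_reaction_trials(2, 40, 4)
  expect_setequal(unique(r2$trials$target_type), c("blue", "red"))
  expect_equal(sum(r2$trials$is_startle), 1L)
  expect_equal(r2$trials$target_type[r2$trials$is_startle], "blue")
  expect_true(all(r2$trials$cue_onset_ms >= 1000 & r2$trials$cue_onset_ms <= 3000))
  expect_identical(generate_reaction_trials(2, 10, 7),
                   generate_reaction_trials(2, 10, 7))
  expect_error(generate_reaction_trials(1, 0, 1), class = "invalid_input")
})

test_that("reaction scoring separates latencies, commissions and anticipations", {
  r <- generate_reaction_trials(1, 3, 1)
  r$trials$cue_onset_ms <- c(1000, 1200, 1400)
  r$trials$is_startle <- c(FALSE, FALSE, TRUE)
  sc <- score_reaction(r, c(1350, 1500, 1800))
  expect_equal(sc$latencies_ms, c(350, 300, 400))
  expect_equal(sc$mean_latency_ms, 325)        # startle excluded from the mean
  expect_equal(sc$startle_time_ms, 400)
  expect_equal(sc$n_commission, 0L)
  # commission on a red trial; anticipation before the cue
  r2 <- generate_reaction_trials(2, 3, 2)
  r2$trials$target_type <- c("blue", "red", "blue")
  r2$trials$cue_onset_ms <- c(1000, 1000, 1000)
  r2$trials$is_startle <- c(TRUE, FALSE, FALSE)
  sc2 <- score_reaction(r2, c(1250, 1300, 980))
  expect_equal(sc2$n_commission, 1L)
  expect_equal(sc2$n_anticipatory, 1L)
  expect_equal(sc2$startle_time_ms, 250)
  expect_true(is.na(sc2$mean_latency_ms))      # only valid go was the startle
  expect_error(score_reaction(r2, c(1000, 1000)), class = "invalid_input")
})

test_that("n-back sequences have the fixed lengths and planted target counts", {
  lengths <- c(11, 11, 15, 20)
  defaults <- c(3, 3, 4, 5)
  for (lvl in 0:3) {
    nb <- generate_nback(lvl, rng_seed = 20 + lvl)
    expect_length(nb$letters, lengths[lvl + 1])
    expect_equal(sum(nb$is_target), defaults[lvl + 1])
    if (lvl == 0) {
      expect_equal(nb$is_target, nb$letters == "X")
    } else {
      expect_false(any(which(nb$is_target) <= lvl))
    }
  }
  nb2 <- generate_nback(2, rng_seed = 1, target_config = list(n_targets = 3))
  hits <- sum(vapply(3:15, function(i) nb2$letters[i] == nb2$letters[i - 2],
                     logical(1)))
  expect_equal(hits, 3L)
  expect_identical(generate_nback(3, 42), generate_nback(3, 42))
  expect_error(generate_nback(1, 1, target_config = list(n_targets = 11)),
               class = "invalid_input")
  expect_error(generate_nback(4, 1), class = "invalid_input")
})

test_that("generated n-back target flags always match an independent re-scan", {
  for (seed in 1:25) {
    for (lvl in 0:3) {
      nb <- generate_nback(lvl, rng_seed = seed)
      expect_identical(nb$is_target, oracle_nback_targets(nb$letters, lvl))
    }
  }
})

test_that("n-back scoring decomposes touches into hits, misses and false alarms", {
  nb <- generate_nback(0, rng_seed = 1,
                       target_config = list(n_targets = 4))
  exact <- score_nback(nb, which(nb$is_target))
  expect_equal(exact$details$false_alarms, 0L)
  expect_equal(exact$details$misses, 0L)
  expect_equal(exact$n_correct, 11L)
  none <- score_nback(nb, integer())
  expect_equal(none$details$misses, 4L)
  all_touch <- score_nback(nb, 1:11)
  expect_equal(all_touch$details$hits, 4L)
  expect_equal(all_touch$details$false_alarms, 7L)
  expect_error(score_nback(nb, 12L), class = "invalid_input")
})
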