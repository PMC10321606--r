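# Exclusion filtering, time-locking, condition averaging, analysis window.

test_that("filter_trials applies the sequential rules with stage accounting", {
  tab <- rbind(
    make_events(item_id = 1L, correct = FALSE),
    make_events(item_id = 2L, response_onset = 4.5 + 5.2,
                response_offset = 4.5 + 5.9),           # RT 5.2 s
    make_events(item_id = 3L, hesitation = TRUE),
    make_events(item_id = 4L)
  )
  out <- filter_trials(tab, exclusion_config())
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$item_id, 4L)
  expect_equal(out$report$n_removed, c(2L, 1L, 0L))
  expect_equal(out$report$n_denominator, c(4L, 2L, 1L))

  # all-off config returns the table unchanged
  off <- exclusion_config(max_rt = Inf, excluded_phonemes = character(0),
                          drop_incorrect = FALSE, drop_hesitation = FALSE)
  expect_identical(filter_trials(tab, off)$kept, tab)

  # excluded-phoneme stage and participant subset
  tab2 <- rbind(make_events(item_id = 1L, onset_phoneme = "m"),
                make_events(item_id = 2L, participant_id = 2L))
  out2 <- filter_trials(tab2, exclusion_config())
  expect_equal(out2$report$n_removed, c(0L, 0L, 1L))
  sub <- filter_trials(tab2, exclusion_config(participant_subset = 2L))
  expect_equal(sub$kept$participant_id, 2L)
  expect_equal(sub$report$n_denominator[1], 1L)
})

test_that("filter stage order affects denominators, never the kept set", {
  set.seed(20)
  cfg <- generator_config(n_participants = 1L, n_trials_per_condition = 1L)
  tab <- sample_trial_timelines(cfg, rep("early_planning", 300), item_ids = 1:300)
  keep_direct <- with(tab, correct & response_time(tab) <= 5 & !hesitation &
                        !onset_phoneme %in% artidelta:::EXCLUDED_PHONEMES)
  expect_setequal(filter_trials(tab)$kept$item_id, tab$item_id[keep_direct])
})

test_that("epoch_trace interpolates exactly on and between grid points", {
  fps <- 91.65
  ev <- make_events()
  # trace sampled exactly on the TL1-relative grid: values reproduced exactly
  k_src <- -50:40
  ts <- ev$question_offset + k_src / fps
  vals <- abs(sin(k_src / 7)) + 1
  tr <- delta_trace(ts, vals, fps, sync_time = ev$question_onset)
  ep <- epoch_trace(tr, ev, "TL1")
  shared <- match(k_src, ep$k)
  expect_equal(ep$values[shared], vals)
  expect_true(0 %in% ep$k)
  expect_true(all(ep$valid[shared]))

  # piecewise-linear ramp: interpolated values equal the closed-form line
  slope <- 0.37; icpt <- 2.1
  ts2 <- ev$question_offset + seq(-0.5, 0.5, by = 0.013)  # off-grid sampling
  tr2 <- delta_trace(ts2, icpt + slope * (ts2 - ev$question_offset), fps)
  ep2 <- epoch_trace(tr2, ev, "TL1")
  ok <- ep2$valid
  expect_equal(ep2$values[ok], icpt + slope * ep2$grid_times[ok], tolerance = 1e-9)

  # TL3: grid time 0 is response onset on the trial clock
  k_long <- -50:150
  tr_long <- delta_trace(ev$question_offset + k_long / fps,
                         rep(1, length(k_long)), fps)
  ep3 <- epoch_trace(tr_long, ev, "TL3")
  idx0 <- which(ep3$k == 0)
  expect_equal(ep3$grid_times[idx0] + ev$response_onset, ev$response_onset)
  expect_true(ep3$valid[idx0])

  # lock far beyond the trace span errors
  ev_far <- make_events(response_onset = 50, response_offset = 51)
  expect_error(epoch_trace(tr, ev_far, "TL3"), "outside the trace span")
})

test_that("average_condition averages valid timepoints and counts trials", {
  e1 <- make_epoch(k = 0:5, values = rep(2, 6))
  e2 <- make_epoch(k = 3:8, values = rep(4, 6))
  av <- average_condition(list(e1, e2))
  expect_equal(av$k, 0:8)
  expect_equal(av$mean_values[av$k %in% 3:5], rep(3, 3))   # overlap: mean of 2 and 4
  expect_equal(av$n_trials[av$k %in% 3:5], rep(2L, 3))
  expect_equal(av$mean_values[av$k %in% 0:2], rep(2, 3))
  expect_equal(av$n_trials[av$k %in% 6:8], rep(1L, 3))

  single <- average_condition(list(e1))
  expect_equal(single$mean_values, e1$values)
  expect_equal(single$n_trials, rep(1L, 6))

  bad <- make_epoch(k = 0:5, values = rep(1, 6), step = 0.5)
  expect_error(average_condition(list(e1, bad)), "grid mismatch")
  expect_error(average_condition(list(e1, make_epoch(0:5, rep(1, 6), lock = "TL2"))),
               "grid mismatch")

  # property: the mean lies within [min, max] of contributing values
  set.seed(21)
  eps <- lapply(1:5, function(i) make_epoch(k = 0:30, values = runif(31, 0, i)))
  avp <- average_condition(eps)
  vals <- sapply(eps, `[[`, "values")
  expect_true(all(avp$mean_values >= apply(vals, 1, min) - 1e-12))
  expect_true(all(avp$mean_values <= apply(vals, 1, max) + 1e-12))
})

test_that("build_analysis_matrix intersects windows across participants", {
  fps <- 91.65
  k1 <- round(-1 * fps):round(3 * fps)   # participant 1: [-1, 3] s
  k2 <- round(-2 * fps):round(2 * fps)   # participant 2: [-2, 2] s
  avs <- list(
    make_average(k1, rep(1, length(k1)), participant_id = 1L, condition = "early_planning"),
    make_average(k1, rep(2, length(k1)), participant_id = 1L, condition = "late_planning"),
    make_average(k2, rep(3, length(k2)), participant_id = 2L, condition = "early_planning"),
    make_average(k2, rep(4, length(k2)), participant_id = 2L, condition = "late_planning")
  )
  m <- build_analysis_matrix(avs)
  expect_equal(range(m$times), c(-1, 2), tolerance = 1.01 / fps)
  expect_equal(dim(m$early_planning), c(2, length(intersect(k1, k2))))
  expect_equal(m$late_planning[2, 1], 4)

  expect_error(build_analysis_matrix(avs, min_trials = 5L), "empty common")
  expect_error(build_analysis_matrix(avs[1:3]), "lacks an average")

  # clipping restricts the window
  mc <- build_analysis_matrix(avs, clip_range = c(-0.5, 0.5))
  expect_true(all(m$times >= -1.01 & m$times <= 2.01))
  expect_true(all(mc$times >= -0.5 - 1e-9 & mc$times <= 0.5 + 1e-9))
})

test_that("averaging then windowing commutes with windowing then averaging", {
  set.seed(22)
  eps <- lapply(1:4, function(i) {
    k0 <- sample(-40:-20, 1)
    k1 <- sample(20:40, 1)
    make_epoch(k = k0:k1, values = rnorm(k1 - k0 + 1))
  })
  full <- average_condition(eps)
  win <- -10:10
  # window first: drop out-of-window points from each epoch, then average
  eps_w <- lapply(eps, function(e) {
    keep <- e$k %in% win
    make_epoch(e$k[keep], e$values[keep])
  })
  win_first <- average_condition(eps_w)
  idx <- match(win, full$k)
  expect_equal(full$mean_values[idx], win_first$mean_values[match(win, win_first$k)])
  expect_equal(full$n_trials[idx], win_first$n_trials[match(win, win_first$k)])
})

test_that("dataset-level averaging covers question offset for every trial", {
  cfg <- tiny_config(n_participants = 2L, n_trials_per_condition = 5L, seed = 4L)
  ds <- generate_dataset(cfg, output = c("events", "kinematics"))
  traces <- lapply(ds$kinematics, delta_from_kinematics)
  flt <- filter_trials(ds$events, exclusion_config())
  avs <- average_dataset(traces, flt$kept, "TL1")
  for (a in avs) {
    n_kept <- sum(flt$kept$participant_id == a$participant_id &
                    flt$kept$condition == a$condition)
    expect_equal(a$n_trials[a$k == 0], n_kept)   # every trial spans its question offset
  }
  m <- build_analysis_matrix(avs, min_trials = 1L)
  expect_true(min(m$times) <= -1 && max(m$times) >= 1)  # window contains [-1, 1] s
})
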