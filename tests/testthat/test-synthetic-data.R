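# Generator: trial timelines, latent kinematics, rendered frame stacks.

test_that("timeline invariants hold and degenerate configs are exact", {
  # all variances zero: event times are forced to the configured means
  cfg <- generator_config(
    question_timing = list(
      early_planning = list(word_onset_mean = 1.619, word_onset_sd = 0,
                            word_to_offset_mean = 2.839, word_to_offset_sd = 0),
      late_planning = list(word_onset_mean = 1.788, word_onset_sd = 0,
                           word_to_offset_mean = 2.669, word_to_offset_sd = 0)
    ),
    exclusion_rates = list(incorrect = 0, hesitation = 0, phoneme = 0)
  )
  set.seed(1)
  ev <- sample_trial_timeline(cfg, "early_planning")
  expect_equal(ev$question_offset - ev$question_onset, 4.458)
  expect_equal(ev$critical_word_onset, 1.619)

  # zero exclusion rates: every trial is clean
  set.seed(2)
  trials <- sample_trial_timelines(
    cfg, sample(c("early_planning", "late_planning"), 200, replace = TRUE))
  expect_true(all(trials$correct))
  expect_false(any(trials$hesitation))
  expect_false(any(trials$onset_phoneme %in% artidelta:::EXCLUDED_PHONEMES))
  # ordering invariants across a batch of random draws
  expect_true(all(trials$question_onset < trials$critical_word_onset))
  expect_true(all(trials$critical_word_onset < trials$question_offset))
  expect_true(all(trials$response_onset > trials$critical_word_onset))
  expect_true(all(trials$response_offset > trials$response_onset))
})

test_that("invalid conditions and configurations are rejected", {
  cfg <- tiny_config()
  expect_error(sample_trial_timeline(cfg, "mid_planning"), "invalid condition")
  expect_error(generator_config(burst_duration = 0), "configuration error")
  expect_error(generator_config(exclusion_rates = list(incorrect = 1.2, hesitation = 0, phoneme = 0)),
               "configuration error")
  expect_error(generator_config(frame_rate_hz = -1), "configuration error")
})

test_that("shifted-lognormal RT calibration hits mean and median", {
  p <- rt_lognormal_params(0.626, 0.407, -0.150)
  expect_equal(p$shift + exp(p$meanlog), 0.407)                     # median
  expect_equal(p$shift + exp(p$meanlog + p$sdlog^2 / 2), 0.626)     # mean
  set.seed(11)
  x <- p$shift + rlnorm(20000, p$meanlog, p$sdlog)
  expect_lt(abs(mean(x) - 0.626), 0.03)
  expect_lt(median(x), mean(x))
})

test_that("kinematics follow the stated construction", {
  cfg <- tiny_config(baseline_motion = list(level = 0, decline_rate = 0),
                     prep_amplitude = 0, burst_amplitude = 0, trial_cv = 0,
                     noise = list(kinematic_sd = 0, speckle_sd = 0))
  ev <- make_events()
  kin <- generate_kinematics(ev, cfg)
  expect_true(all(kin$speed == 0))                                  # null model
  expect_equal(length(kin$speed),
               ceiling((ev$response_offset + 1.5 - (ev$question_onset - 0.5)) * cfg$frame_rate_hz))

  # a dominant burst puts the argmax inside the burst window
  cfg2 <- tiny_config(burst_amplitude = 10, trial_cv = 0,
                      noise = list(kinematic_sd = 0, speckle_sd = 0))
  kin2 <- generate_kinematics(ev, cfg2)
  t_peak <- kin2$timestamps[which.max(kin2$speed)]
  expect_gte(t_peak, ev$response_onset)
  expect_lte(t_peak, ev$response_onset + cfg2$burst_duration)
  expect_true(all(kin2$speed >= 0))
  # burst window mean exceeds baseline mean under defaults
  in_burst <- kin2$timestamps >= ev$response_onset &
    kin2$timestamps <= ev$response_onset + cfg2$burst_duration
  in_base <- kin2$timestamps < ev$critical_word_onset
  expect_gt(mean(kin2$speed[in_burst]), mean(kin2$speed[in_base]))
})

test_that("early prep lead raises pre-onset speed relative to late lead", {
  # noise-free closed-form traces, evaluated 0.8 s before response onset
  cfg <- tiny_config(trial_cv = 0, noise = list(kinematic_sd = 0, speckle_sd = 0))
  ev <- make_events()
  kin_ep <- generate_kinematics(ev, cfg, prep_lead = 1.2)
  kin_lp <- generate_kinematics(ev, cfg, prep_lead = 0.3)
  at <- which.min(abs(kin_ep$timestamps - (ev$response_onset - 0.8)))
  expect_gt(kin_ep$speed[at], kin_lp$speed[at])
})

test_that("ramp starting before question onset is clipped, not an error", {
  cfg <- tiny_config(trial_cv = 0, noise = list(kinematic_sd = 0, speckle_sd = 0))
  ev <- make_events(question_offset = 2.0, response_onset = 2.1,
                    response_offset = 2.6, critical_word_onset = 1.0)
  kin <- generate_kinematics(ev, cfg, prep_lead = 10)
  expect_true(kin$ramp_clipped)
  expect_true(all(is.finite(kin$speed)))
})

test_that("rendered stacks obey the quantization and motion contracts", {
  cfg <- tiny_config(trial_cv = 0, noise = list(kinematic_sd = 0, speckle_sd = 0))
  ev <- make_events()
  kin <- generate_kinematics(ev, cfg)

  st <- render_frame_stack(kin, cfg)
  expect_true(all(st$frames >= 0L & st$frames <= 255L))
  expect_true(is.integer(st$frames))

  # zero speed, zero noise: all frames identical
  kin0 <- kin
  kin0$speed <- rep(0, length(kin0$speed))
  st0 <- render_frame_stack(kin0, cfg)
  expect_true(all(st0$frames == c(st0$frames[, , 1])))

  # monotone speed profile: rank correlation between recovered per-step ridge
  # displacement and the configured speed is 1. Uses a tall flat-contour
  # image so the ridge's Gaussian profile is never clipped at the border
  # (clipping biases the center-of-mass estimate, not the renderer).
  cfgm <- tiny_config(image_height_px = 48L, trial_cv = 0,
                      noise = list(kinematic_sd = 0, speckle_sd = 0),
                      render = list(ridge_amplitude = 160, background = 0,
                                    ridge_sd_px = 3, contour_amp_frac = 0,
                                    displacement_gain = 2.0))
  kinm <- kin0
  kinm$timestamps <- kinm$timestamps[1:40]
  kinm$speed <- seq(0.2, 2, length.out = 40)
  stm <- render_frame_stack(kinm, cfgm)
  centers <- apply(stm$frames, 3, function(fr) {
    mean(colSums(fr * seq_len(nrow(fr))) / colSums(fr))
  })
  disp <- abs(diff(centers))
  expect_equal(cor(disp, kinm$speed[-length(kinm$speed)], method = "spearman"), 1)

  expect_error(render_frame_stack(kin, tiny_config(image_height_px = 4)),
               "configuration error")
})

test_that("generate_dataset is deterministic and correctly sized", {
  cfg <- tiny_config(seed = 99L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$events, d2$events)
  expect_equal(nrow(d1$events), 2 * 2 * 3)   # participants x conditions x trials

  # events round-trip through CSV byte-identically
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_events(d1$events, f1)
  write_events(generate_dataset(cfg)$events, f2)
  expect_identical(readLines(f1), readLines(f2))

  # per-participant per-condition trial counts respect the config
  counts <- table(d1$events$participant_id, d1$events$condition)
  expect_true(all(counts == 3))
  # two-list design: each item occurs once per participant
  expect_true(all(table(d1$events$participant_id, d1$events$item_id) == 1))
})

test_that("unequal per-condition trial counts are honored", {
  cfg <- tiny_config(n_trials_per_condition = c(early_planning = 4L, late_planning = 2L))
  d <- generate_dataset(cfg)
  counts <- table(d$events$condition)
  expect_equal(unname(counts[["early_planning"]]), 2 * 4)
  expect_equal(unname(counts[["late_planning"]]), 2 * 2)
})

test_that("surviving fraction matches the product of stage retention rates", {
  # defaults: incorrect 8.1%, hesitation 11.5%, phoneme 4.9%, sequential
  cfg <- generator_config(n_participants = 1L, n_trials_per_condition = 1L)
  set.seed(33)
  trials <- sample_trial_timelines(cfg, rep("early_planning", 5000), item_ids = 1:5000)
  kept <- filter_trials(trials)$kept
  expected <- 0.919 * 0.885 * 0.951
  expect_lt(abs(nrow(kept) / nrow(trials) - expected), 0.02)
})
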