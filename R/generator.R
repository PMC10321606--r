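# Synthetic articulatory-ultrasound generator: trial timelines, latent tongue
# kinematics, and rendered speckle frame stacks for a two-condition
# (early-/late-planning) question-answer paradigm. All times are in seconds on
# the trial clock, with question onset at 0.

CONDITIONS <- c("early_planning", "late_planning")

# Dutch onset phonemes that image poorly under the probe and are excluded from
# analysis; the remainder are admissible answer onsets.
EXCLUDED_PHONEMES <- c("d", "f", "ɣ", "ɦ", "m", "p", "r", "v", "ʋ")
ADMISSIBLE_PHONEMES <- c("b", "t", "k", "s", "z", "n", "l", "j", "w", "x")

#' Configuration for the synthetic dataset generator
#'
#' Defaults reproduce the structure of the study the package emulates: 25
#' participants, 29 trials per condition (58 experimental trials), a 91.65 Hz
#' probe, question timing drawn from the published stimulus statistics, and
#' right-skewed response-time (RT) distributions calibrated so that the
#' early-planning condition has mean 626 ms / median 407 ms and the
#' late-planning condition mean 900 ms / median 741 ms, both relative to
#' question offset. The latent movement model is a declining baseline during
#' the question, a piecewise-linear preparatory ramp that reaches its plateau
#' at response onset (starting `prep_lead` seconds earlier, condition
#' dependent), and a smooth articulation burst spanning the response onset.
#'
#' @param n_participants number of participants.
#' @param n_trials_per_condition trials per condition, either a single count or
#'   a named length-2 vector `c(early_planning=, late_planning=)`.
#' @param frame_rate_hz probe frame rate in Hz.
#' @param image_height_px,image_width_px frame dimensions in pixels. The probe
#'   produced 57 x 842 frames; the default width is reduced to 128 because the
#'   (normalized) Delta statistic is size-agnostic and tests scale down.
#' @param question_timing per-condition normal parameters (seconds) for
#'   question onset to critical/control word onset (`word_onset_*`) and word
#'   onset to question offset (`word_to_offset_*`), truncated below at
#'   `word_onset_min` / `word_to_offset_min`.
#' @param rt per-condition shifted-lognormal RT calibration: target `mean` and
#'   `median` (seconds, relative to question offset) plus the `shift` (lower
#'   bound; negative so responses can overlap the question). `meanlog`/`sdlog`
#'   are derived in closed form, see [rt_lognormal_params()].
#' @param rt_random standard deviations (seconds) of additive participant- and
#'   item-level RT intercepts (crossed random effects).
#' @param answer_duration lognormal parameters of the spoken-answer duration.
#' @param baseline_motion `level` (arbitrary movement units) at question onset
#'   and linear `decline_rate` (units/s) while listening; the decline is
#'   floored at zero and frozen after question offset.
#' @param prep_lead per-condition normal parameters (seconds) of how long
#'   before response onset the preparatory ramp starts; truncated at `min`.
#' @param prep_amplitude plateau height of the preparatory ramp (movement
#'   units, reached at response onset).
#' @param burst_amplitude,burst_duration peak height and length (s) of the
#'   articulation burst starting at response onset.
#' @param trial_cv,participant_cv lognormal coefficients of variation applied
#'   multiplicatively to the movement amplitudes per trial and per participant
#'   (applied to both conditions alike, so they preserve exchangeability under
#'   a null configuration).
#' @param exclusion_rates probabilities of an incorrect response, a hesitation,
#'   and an excluded onset phoneme (applied independently; the analysis-side
#'   filter removes them sequentially).
#' @param noise `kinematic_sd`: scale of the half-normal motion noise added to
#'   the latent speed; `speckle_sd`: pixel speckle standard deviation (0-255
#'   intensity units) in rendered frames.
#' @param render rendering model: `ridge_amplitude` and `background` intensity,
#'   `ridge_sd_px` Gaussian half-width of the bright tongue ridge,
#'   `contour_amp_frac` arch height of the resting contour as a fraction of
#'   image height, `displacement_gain` pixels of ridge displacement per unit of
#'   latent speed.
#' @param record_pre,record_post recording margins (s) before question onset
#'   and after response offset.
#' @param seed integer seed used by [generate_dataset()].
#' @return A validated list of class `artidelta_generator_config`.
#' @export
generator_config <- function(n_participants = 25L,
                             n_trials_per_condition = 29L,
                             frame_rate_hz = 91.65,
                             image_height_px = 57L,
                             image_width_px = 128L,
                             question_timing = list(
                               early_planning = list(word_onset_mean = 1.619, word_onset_sd = 0.740,
                                                     word_to_offset_mean = 2.839, word_to_offset_sd = 0.655),
                               late_planning = list(word_onset_mean = 1.788, word_onset_sd = 0.950,
                                                    word_to_offset_mean = 2.669, word_to_offset_sd = 0.866)
                             ),
                             rt = list(
                               early_planning = list(mean = 0.626, median = 0.407, shift = -0.150),
                               late_planning = list(mean = 0.900, median = 0.741, shift = -0.150)
                             ),
                             rt_random = list(participant_sd = 0.100, item_sd = 0.080),
                             answer_duration = list(meanlog = log(0.6), sdlog = 0.3),
                             baseline_motion = list(level = 1.0, decline_rate = 0.12),
                             prep_lead = list(
                               early_planning = list(mean = 1.2, sd = 0.2),
                               late_planning = list(mean = 0.3, sd = 0.1)
                             ),
                             prep_amplitude = 0.8,
                             burst_amplitude = 3.0,
                             burst_duration = 0.8,
                             trial_cv = 0.3,
                             participant_cv = 0.2,
                             exclusion_rates = list(incorrect = 0.081, hesitation = 0.115, phoneme = 0.049),
                             noise = list(kinematic_sd = 0.3, speckle_sd = 8),
                             render = list(ridge_amplitude = 160, background = 30, ridge_sd_px = 3,
                                           contour_amp_frac = 0.15, displacement_gain = 2.0),
                             record_pre = 0.5,
                             record_post = 1.5,
                             seed = 1L) {
  if (length(n_trials_per_condition) == 1L) {
    n_trials_per_condition <- stats::setNames(rep(as.integer(n_trials_per_condition), 2L), CONDITIONS)
  } else {
    stopifnot(all(CONDITIONS %in% names(n_trials_per_condition)))
    n_trials_per_condition <- as.integer(n_trials_per_condition[CONDITIONS])
    names(n_trials_per_condition) <- CONDITIONS
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_trials_per_condition = n_trials_per_condition,
    frame_rate_hz = frame_rate_hz,
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    question_timing = question_timing,
    rt = rt,
    rt_random = rt_random,
    answer_duration = answer_duration,
    baseline_motion = baseline_motion,
    prep_lead = prep_lead,
    prep_amplitude = prep_amplitude,
    burst_amplitude = burst_amplitude,
    burst_duration = burst_duration,
    trial_cv = trial_cv,
    participant_cv = participant_cv,
    exclusion_rates = exclusion_rates,
    noise = noise,
    render = render,
    record_pre = record_pre,
    record_post = record_post,
    word_onset_min = 0.1,
    word_to_offset_min = 0.5,
    prep_lead_min = 0.05,
    seed = as.integer(seed)
  ), class = "artidelta_generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "artidelta_generator_config"))
  if (cfg$n_participants < 1L || any(cfg$n_trials_per_condition < 1L))
    stop("configuration error: participant and trial counts must be positive")
  if (cfg$frame_rate_hz <= 0)
    stop("configuration error: frame_rate_hz must be strictly positive")
  if (cfg$image_height_px < 1L || cfg$image_width_px < 1L)
    stop("configuration error: image dimensions must be positive")
  for (cond in CONDITIONS) {
    qt <- cfg$question_timing[[cond]]
    if (qt$word_onset_mean <= 0 || qt$word_to_offset_mean <= 0)
      stop("configuration error: question timing means must be strictly positive")
    if (qt$word_onset_sd < 0 || qt$word_to_offset_sd < 0)
      stop("configuration error: question timing sds must be nonnegative")
    r <- cfg$rt[[cond]]
    if (r$mean <= r$shift || r$median <= r$shift || r$mean < r$median)
      stop("configuration error: rt calibration requires shift < median <= mean")
    pl <- cfg$prep_lead[[cond]]
    if (pl$mean <= 0 || pl$sd < 0)
      stop("configuration error: prep_lead mean must be positive")
  }
  if (cfg$prep_amplitude < 0 || cfg$burst_amplitude < 0)
    stop("configuration error: amplitudes must be nonnegative")
  if (cfg$burst_duration <= 0)
    stop("configuration error: burst_duration must be strictly positive")
  rates <- unlist(cfg$exclusion_rates)
  if (any(rates < 0 | rates > 1))
    stop("configuration error: exclusion rates must lie in [0, 1]")
  if (cfg$noise$kinematic_sd < 0 || cfg$noise$speckle_sd < 0)
    stop("configuration error: noise sds must be nonnegative")
  if (cfg$record_pre < 0 || cfg$record_post < 0)
    stop("configuration error: recording margins must be nonnegative")
  invisible(cfg)
}

#' Closed-form calibration of a shifted-lognormal RT distribution
#'
#' Given a target mean, median and shift (lower bound), returns the
#' `meanlog`/`sdlog` of the lognormal part such that `shift + rlnorm(...)` has
#' exactly the requested mean and median. A lognormal has median `exp(meanlog)`
#' and mean `exp(meanlog + sdlog^2/2)`, so
#' `meanlog = log(median - shift)` and
#' `sdlog = sqrt(2 * log((mean - shift) / (median - shift)))`.
#' Note the SD is then determined (not free): mean, median and SD cannot all be
#' matched by this family in general.
#'
#' @param mean,median,shift targets in seconds; requires `shift < median <= mean`.
#' @return list with `shift`, `meanlog`, `sdlog`.
#' @export
rt_lognormal_params <- function(mean, median, shift = -0.150) {
  stopifnot(shift < median, median <= mean)
  list(shift = shift,
       meanlog = log(median - shift),
       sdlog = sqrt(2 * log((mean - shift) / (median - shift))))
}

# Normal draw truncated below (resampling; degenerate sd returns the mean).
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(pmax(rep(mean, n), lower))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Sample trial timelines
#'
#' Draws the event times for one trial per element of `conditions`: word
#' onset and word-to-question-offset intervals from each condition's
#' truncated normal timing distributions, a response time from its
#' shifted-lognormal RT distribution, an answer duration, and the
#' correctness/hesitation/onset phoneme annotations at the configured rates.
#' Question onset is time 0 on the trial clock.
#'
#' @param config a [generator_config()].
#' @param conditions character vector of `"early_planning"` /
#'   `"late_planning"` labels, one per trial to draw.
#' @param participant_ids,item_ids identifiers stored on the returned rows
#'   (recycled).
#' @return `data.frame` of trial events, one row per element of `conditions`
#'   (see [read_events()] for the column contract).
#' @export
sample_trial_timelines <- function(config, conditions, participant_ids = 1L,
                                   item_ids = seq_along(conditions)) {
  validate_generator_config(config)
  bad <- setdiff(unique(conditions), CONDITIONS)
  if (length(bad) > 0L)
    stop("invalid condition label: ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(CONDITIONS, collapse = ", "), ")")
  n <- length(conditions)
  word_onset <- word_to_offset <- rt <- numeric(n)
  for (cond in CONDITIONS) {
    i <- which(conditions == cond)
    if (length(i) == 0L) next
    qt <- config$question_timing[[cond]]
    word_onset[i] <- rtruncnorm_lower(length(i), qt$word_onset_mean, qt$word_onset_sd,
                                      config$word_onset_min)
    word_to_offset[i] <- rtruncnorm_lower(length(i), qt$word_to_offset_mean,
                                          qt$word_to_offset_sd, config$word_to_offset_min)
    rp <- config$rt[[cond]]
    lp <- rt_lognormal_params(rp$mean, rp$median, rp$shift)
    rt[i] <- lp$shift + if (lp$sdlog == 0) exp(lp$meanlog) else
      stats::rlnorm(length(i), lp$meanlog, lp$sdlog)
  }
  ans <- stats::rlnorm(n, config$answer_duration$meanlog, config$answer_duration$sdlog)

  rates <- config$exclusion_rates
  correct <- stats::runif(n) >= rates$incorrect
  hesitation <- stats::runif(n) < rates$hesitation
  phoneme <- sample(ADMISSIBLE_PHONEMES, n, replace = TRUE)
  excl <- stats::runif(n) < rates$phoneme
  if (any(excl)) phoneme[excl] <- sample(EXCLUDED_PHONEMES, sum(excl), replace = TRUE)

  question_offset <- word_onset + word_to_offset
  ev <- data.frame(
    participant_id = as.integer(rep_len(participant_ids, n)),
    item_id = as.integer(rep_len(item_ids, n)),
    condition = conditions,
    question_onset = rep(0, n),
    critical_word_onset = word_onset,
    question_offset = question_offset,
    response_onset = question_offset + rt,
    response_offset = question_offset + rt + ans,
    correct = correct,
    hesitation = hesitation,
    onset_phoneme = phoneme,
    stringsAsFactors = FALSE
  )
  validate_trial_events(ev)
  ev
}

#' @rdname sample_trial_timelines
#' @param condition single condition label.
#' @param participant_id,item_id identifiers stored on the returned row.
#' @export
sample_trial_timeline <- function(config, condition, participant_id = 1L, item_id = 1L) {
  sample_trial_timelines(config, condition, participant_id, item_id)
}

#' Validate a trial-events table against its invariants
#'
#' Checks column completeness and the event-ordering invariants
#' (question onset < word onset < question offset; response onset after word
#' onset; response offset after response onset). Response time (response onset
#' minus question offset) may be negative: answers can overlap the question.
#'
#' @param events data.frame of one or more trial rows.
#' @return the table, invisibly; errors name the offending rows.
#' @export
validate_trial_events <- function(events) {
  required <- c("participant_id", "item_id", "condition", "question_onset",
                "critical_word_onset", "question_offset", "response_onset",
                "response_offset", "correct", "hesitation", "onset_phoneme")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0L)
    stop("events table is missing required column(s): ", paste(missing, collapse = ", "))
  bad_cond <- which(!events$condition %in% CONDITIONS)
  if (length(bad_cond) > 0L)
    stop("invalid condition label in row(s): ", paste(bad_cond, collapse = ", "))
  ok <- events$question_onset < events$critical_word_onset &
    events$critical_word_onset < events$question_offset &
    events$response_onset > events$critical_word_onset &
    events$response_offset > events$response_onset
  if (!all(ok))
    stop("event-ordering invariant violated in row(s): ", paste(which(!ok), collapse = ", "))
  invisible(events)
}

#' Response time relative to question offset
#'
#' @param events trial-events table.
#' @return numeric vector of RTs in seconds (negative when the response
#'   overlaps the question).
#' @export
response_time <- function(events) {
  events$response_onset - events$question_offset
}

#' Generate the latent tongue-movement kinematics for one trial
#'
#' The latent speed trace, sampled on the trial's frame grid (from
#' `record_pre` s before question onset to `record_post` s after response
#' offset), is the sum of: a baseline that declines linearly while the
#' question is playing (floored at 0, frozen after question offset), a
#' piecewise-linear preparatory ramp that starts `prep_lead` s before response
#' onset and reaches `prep_amplitude` at response onset, a raised-cosine
#' articulation burst of height `burst_amplitude` over
#' `[response_onset, response_onset + burst_duration]`, and half-normal
#' nonnegative noise. A ramp that would start before question onset is clipped
#' to question onset (recorded in the `ramp_clipped` field, not an error).
#'
#' @param events one-row trial-events table.
#' @param config a [generator_config()].
#' @param amplitude_scale optional multiplicative factor on all deterministic
#'   movement amplitudes (used for participant/trial heterogeneity).
#' @param prep_lead optional fixed preparatory lead (s); by default drawn from
#'   the condition's configured distribution.
#' @return list of class `artidelta_kinematics` with `timestamps`, `speed`
#'   (both length = frame count), the realized `prep_lead`, and the events row.
#' @export
generate_kinematics <- function(events, config, amplitude_scale = 1, prep_lead = NULL) {
  validate_trial_events(events)
  stopifnot(nrow(events) == 1L)
  fps <- config$frame_rate_hz
  t0 <- events$question_onset - config$record_pre
  t1 <- events$response_offset + config$record_post
  n <- ceiling((t1 - t0) * fps)
  tt <- t0 + (seq_len(n) - 1L) / fps

  if (is.null(prep_lead)) {
    pl <- config$prep_lead[[events$condition]]
    prep_lead <- rtruncnorm_lower(1L, pl$mean, pl$sd, config$prep_lead_min)
  }
  if (config$trial_cv > 0) {
    sdl <- sqrt(log(1 + config$trial_cv^2))
    amplitude_scale <- amplitude_scale * stats::rlnorm(1L, -sdl^2 / 2, sdl)
  }

  bm <- config$baseline_motion
  q_dur <- events$question_offset - events$question_onset
  listened <- pmin(pmax(tt - events$question_onset, 0), q_dur)
  baseline <- pmax(bm$level - bm$decline_rate * listened, 0)

  ramp_start <- events$response_onset - prep_lead
  ramp_clipped <- FALSE
  if (ramp_start < events$question_onset) {
    ramp_start <- events$question_onset
    ramp_clipped <- TRUE
    if (isTRUE(getOption("artidelta.verbose", FALSE)))
      message("preparatory ramp start clipped to question onset")
  }
  ramp_len <- events$response_onset - ramp_start
  ramp <- if (ramp_len > 0) {
    config$prep_amplitude * pmin(pmax((tt - ramp_start) / ramp_len, 0), 1)
  } else rep(0, n)

  u <- (tt - events$response_onset) / config$burst_duration
  burst <- ifelse(u >= 0 & u <= 1,
                  config$burst_amplitude * sin(pi * u)^2, 0)

  speed <- amplitude_scale * (baseline + ramp + burst)
  if (config$noise$kinematic_sd > 0)
    speed <- speed + abs(stats::rnorm(n, 0, config$noise$kinematic_sd))
  speed <- pmax(speed, 0)

  structure(list(
    timestamps = tt,
    speed = speed,
    frame_rate_hz = fps,
    prep_lead = prep_lead,
    ramp_clipped = ramp_clipped,
    events = events
  ), class = "artidelta_kinematics")
}

#' Render an ultrasound-like frame stack from a kinematic trace
#'
#' The observation model is deliberately simple: each frame is a constant
#' background plus pixel speckle plus a bright horizontal ridge (a column-wise
#' Gaussian intensity profile around a smooth resting arch). Between
#' consecutive frames the ridge is displaced vertically by
#' `displacement_gain * speed` pixels, zig-zagging (direction reverses at
#' +/- H/6) so it stays inside the image; the displacement *magnitude* is thus
#' exactly proportional to the latent speed. Pixel values are quantized to
#' integers in [0, 255] (0 = black, 255 = white). The sync-pulse frame marks
#' question onset.
#'
#' @param kin an `artidelta_kinematics` trace.
#' @param config a [generator_config()] (image geometry, render and noise
#'   parameters).
#' @return list of class `artidelta_frame_stack`: integer array `frames`
#'   (H x W x n), `frame_rate_hz`, `sync_frame_index` (1-based), `sync_time`
#'   (trial-clock time of that frame), ids and condition.
#' @export
render_frame_stack <- function(kin, config) {
  stopifnot(inherits(kin, "artidelta_kinematics"))
  H <- config$image_height_px
  W <- config$image_width_px
  rd <- config$render
  if (H < ceiling(6 * rd$ridge_sd_px) || W < 8L)
    stop("configuration error: image dimensions too small for the ridge width")
  n <- length(kin$speed)
  fps <- kin$frame_rate_hz

  contour <- H / 2 + rd$contour_amp_frac * H * sin(pi * (seq_len(W) - 1L) / (W - 1L))
  # row-minus-contour offsets, fixed across frames
  R0 <- outer(seq_len(H), contour, "-")

  d_max <- H / 6
  d <- numeric(n)
  dir <- 1
  for (f in seq_len(n - 1L)) {
    step <- min(rd$displacement_gain * kin$speed[f], 2 * d_max)
    if (abs(d[f] + dir * step) > d_max) dir <- -dir
    d[f + 1L] <- d[f] + dir * step
  }

  frames <- array(0L, dim = c(H, W, n))
  two_s2 <- 2 * rd$ridge_sd_px^2
  for (f in seq_len(n)) {
    img <- rd$background + rd$ridge_amplitude * exp(-(R0 - d[f])^2 / two_s2)
    if (config$noise$speckle_sd > 0)
      img <- img + stats::rnorm(H * W, 0, config$noise$speckle_sd)
    frames[, , f] <- pmin.int(pmax.int(as.integer(round(img)), 0L), 255L)
  }

  sync_frame_index <- which.min(abs(kin$timestamps - kin$events$question_onset))
  frame_stack(frames, fps,
              sync_frame_index = sync_frame_index,
              sync_time = kin$timestamps[sync_frame_index],
              participant_id = kin$events$participant_id,
              item_id = kin$events$item_id,
              condition = kin$events$condition)
}

#' Construct a frame stack object
#'
#' @param frames H x W x n integer array of grayscale intensities in [0, 255].
#' @param frame_rate_hz frames per second.
#' @param sync_frame_index 1-based index of the sync-pulse frame (question
#'   onset).
#' @param sync_time trial-clock time (s) of the sync frame (0 if unknown;
#'   [align_to_events()] re-anchors it).
#' @param participant_id,item_id,condition optional trial identifiers.
#' @return list of class `artidelta_frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, sync_frame_index = 1L, sync_time = 0,
                        participant_id = NA_integer_, item_id = NA_integer_,
                        condition = NA_character_) {
  stopifnot(length(dim(frames)) == 3L)
  n <- dim(frames)[3L]
  if (sync_frame_index < 1L || sync_frame_index > n)
    stop("sync_frame_index must lie within the stack")
  structure(list(
    frames = frames,
    frame_rate_hz = frame_rate_hz,
    sync_frame_index = as.integer(sync_frame_index),
    sync_time = sync_time,
    participant_id = participant_id,
    item_id = item_id,
    condition = condition
  ), class = "artidelta_frame_stack")
}

#' Generate a full synthetic dataset
#'
#' Samples `n_participants x 2 x n_trials_per_condition` trials. Items are
#' shared across participants in a two-list design (each item appears in the
#' early-planning condition for one half of the participants and in the
#' late-planning condition for the other half), and participant- and item-level
#' RT intercepts are added so the response times carry the crossed
#' random-effects structure the RT model assumes. Deterministic under
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @param output which artifacts to produce: `"events"` (always), optionally
#'   `"kinematics"` (latent traces) and/or `"frames"` (rendered stacks;
#'   expensive at paper scale).
#' @param out_dir if given and `"frames"` is requested, stacks are written
#'   there as raw binary files `P<participant>_I<item>_<condition>.bin` (see
#'   [write_frame_stack()]) and paths are returned instead of in-memory stacks.
#' @return list with `events` (data.frame; includes `sync_frame_index` when
#'   frames are rendered), and optionally `kinematics` / `stacks` lists keyed
#'   `P<participant>_I<item>_<condition>`.
#' @export
generate_dataset <- function(config, output = "events", out_dir = NULL) {
  validate_generator_config(config)
  output <- match.arg(output, c("events", "kinematics", "frames"), several.ok = TRUE)
  set.seed(config$seed)

  n_items <- sum(config$n_trials_per_condition)
  item_effect <- stats::rnorm(n_items, 0, config$rt_random$item_sd)
  psd <- sqrt(log(1 + config$participant_cv^2))

  events <- vector("list", config$n_participants)
  kinematics <- if ("kinematics" %in% output || "frames" %in% output) list() else NULL
  stacks <- if ("frames" %in% output) list() else NULL
  n_ep <- config$n_trials_per_condition[["early_planning"]]
  n_lp <- config$n_trials_per_condition[["late_planning"]]
  items <- seq_len(n_items)

  for (p in seq_len(config$n_participants)) {
    p_effect <- stats::rnorm(1L, 0, config$rt_random$participant_sd)
    p_scale <- if (config$participant_cv > 0) stats::rlnorm(1L, -psd^2 / 2, psd) else 1
    # two-list design: list A participants see the first block of items in the
    # early-planning condition, list B participants the complementary block
    conds <- if (p %% 2L == 1L) {
      ifelse(items <= n_ep, "early_planning", "late_planning")
    } else {
      ifelse(items <= n_lp, "late_planning", "early_planning")
    }
    ev <- sample_trial_timelines(config, conds, participant_ids = p, item_ids = items)
    shift <- p_effect + item_effect
    ev$response_onset <- ev$response_onset + shift
    ev$response_offset <- ev$response_offset + shift
    validate_trial_events(ev)
    if (!is.null(kinematics)) {
      ev$sync_frame_index <- NA_integer_
      for (i in items) {
        evi <- ev[i, , drop = FALSE]
        key <- sprintf("P%d_I%d_%s", p, i, conds[i])
        kin <- generate_kinematics(evi, config, amplitude_scale = p_scale)
        kinematics[[key]] <- kin
        if (!is.null(stacks)) {
          st <- render_frame_stack(kin, config)
          ev$sync_frame_index[i] <- st$sync_frame_index
          if (!is.null(out_dir)) {
            path <- file.path(out_dir, paste0(key, ".bin"))
            write_frame_stack(st, path)
            stacks[[key]] <- path
          } else {
            stacks[[key]] <- st
          }
        }
      }
      if (is.null(stacks)) ev$sync_frame_index <- NULL
    }
    events[[p]] <- ev
  }
  events <- do.call(rbind, events)
  rownames(events) <- NULL
  out <- list(events = events)
  if ("kinematics" %in% output) out$kinematics <- kinematics
  if (!is.null(stacks)) out$stacks <- stacks
  out
}
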