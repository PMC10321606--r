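# Shared fixtures and independent oracles. Oracles are deliberately written
# in the most literal style available (explicit loops, stats::t.test) so they
# share no code path with the implementation they check.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 2L, n_trials_per_condition = 3L,
         image_height_px = 24L, image_width_px = 32L),
    list(...))
  do.call(generator_config, args)
}

# Hand-built one-row events table with sensible defaults.
make_events <- function(participant_id = 1L, item_id = 1L,
                        condition = "early_planning",
                        question_onset = 0, critical_word_onset = 1.6,
                        question_offset = 4.5, response_onset = 5.1,
                        response_offset = 5.8, correct = TRUE,
                        hesitation = FALSE, onset_phoneme = "k") {
  data.frame(participant_id = participant_id, item_id = item_id,
             condition = condition, question_onset = question_onset,
             critical_word_onset = critical_word_onset,
             question_offset = question_offset,
             response_onset = response_onset,
             response_offset = response_offset, correct = correct,
             hesitation = hesitation, onset_phoneme = onset_phoneme,
             stringsAsFactors = FALSE)
}

random_stack <- function(n_frames, H, W, fps = 91.65) {
  frames <- array(sample.int(256L, H * W * n_frames, replace = TRUE) - 1L,
                  dim = c(H, W, n_frames))
  frame_stack(frames, fps, sync_frame_index = 1L)
}

# Brute-force Delta oracle: explicit double loop over pixels per frame pair.
delta_oracle_loop <- function(stack, normalization = "none") {
  dm <- dim(stack$frames)
  out <- numeric(dm[3L] - 1L)
  for (f in seq_len(dm[3L] - 1L)) {
    acc <- 0
    for (r in seq_len(dm[1L])) {
      for (c in seq_len(dm[2L])) {
        d <- as.numeric(stack$frames[r, c, f + 1L]) - as.numeric(stack$frames[r, c, f])
        acc <- acc + d * d
      }
    }
    out[f] <- sqrt(acc)
    if (normalization == "per_pixel_rms") out[f] <- out[f] / sqrt(dm[1L] * dm[2L])
  }
  out
}

# Brute-force run-scan clustering oracle: walks the series timepoint by
# timepoint.
clusters_oracle_scan <- function(t_values, t_crit) {
  out <- list()
  i <- 1L
  n <- length(t_values)
  lab <- function(tv) {
    if (is.nan(tv)) 0L else if (tv > t_crit) 1L else if (tv < -t_crit) -1L else 0L
  }
  while (i <= n) {
    s <- lab(t_values[i])
    if (s == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && lab(t_values[j + 1L]) == s) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(start_idx = i, end_idx = j, sign = s,
                                          mass = sum(t_values[i:j]))
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      sign = integer(0), mass = numeric(0)))
  do.call(rbind, out)
}

# Monolithic brute-force cluster permutation test: per-column stats::t.test,
# oracle clustering, exhaustive sign enumeration via expand.grid, p as the
# plain proportion of null max |mass| >= observed |mass| over all 2^P
# patterns.
brute_force_cluster_test <- function(ep, lp, alpha_cluster = 0.05) {
  P <- nrow(ep); Tn <- ncol(ep)
  tv <- numeric(Tn)
  for (j in seq_len(Tn)) tv[j] <- stats::t.test(ep[, j], lp[, j], paired = TRUE)$statistic
  t_crit <- stats::qt(1 - alpha_cluster / 2, P - 1L)
  obs <- clusters_oracle_scan(tv, t_crit)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), P)))
  null <- numeric(nrow(signs))
  D <- ep - lp
  for (i in seq_len(nrow(signs))) {
    Df <- D * signs[i, ]
    tvi <- numeric(Tn)
    for (j in seq_len(Tn)) tvi[j] <- stats::t.test(Df[, j])$statistic
    cl <- clusters_oracle_scan(tvi, t_crit)
    null[i] <- if (nrow(cl) == 0L) 0 else max(abs(cl$mass))
  }
  obs$p_value <- vapply(obs$mass, function(m) mean(null >= abs(m) - 1e-12), 0)
  list(clusters = obs, null = null, t_values = tv)
}

# Hand-built epoch object on grid indices `k` (step defaults to one frame).
make_epoch <- function(k, values, lock = "TL1", step = 1 / 91.65,
                       valid = rep(TRUE, length(k)), participant_id = 1L,
                       condition = "early_planning") {
  structure(list(lock = lock, k = k, grid_times = k * step, values = values,
                 valid = valid, step = step, participant_id = participant_id,
                 item_id = 1L, condition = condition),
            class = "artidelta_epoch")
}

# Hand-built condition average with unit trial counts over `k`.
make_average <- function(k, values, n_trials = rep(1L, length(k)),
                         participant_id = 1L, condition = "early_planning",
                         lock = "TL1", step = 1 / 91.65) {
  structure(list(participant_id = participant_id, condition = condition,
                 lock = lock, k = k, grid_times = k * step,
                 mean_values = values, n_trials = n_trials, step = step),
            class = "artidelta_condition_average")
}
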