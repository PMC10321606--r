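# Trial exclusion, event time-locking (TL1 = question offset, TL2 =
# critical-word onset, TL3 = response onset), and per-participant condition
# averaging on a lock-relative uniform grid.

LOCKS <- c("TL1", "TL2", "TL3")

lock_time <- function(events, lock) {
  switch(lock,
         TL1 = events$question_offset,
         TL2 = events$critical_word_onset,
         TL3 = events$response_onset,
         stop("unknown lock: ", lock))
}

#' Trial-exclusion configuration
#'
#' @param max_rt responses later than this many seconds after question offset
#'   count as incorrect (default 5, the task deadline). Use `Inf` to disable.
#' @param excluded_phonemes onset phonemes removed because they image poorly.
#' @param drop_incorrect,drop_hesitation toggle those stages.
#' @param participant_subset optional allow-list of participant ids (used for
#'   image-quality / questionnaire control subsets); applied before the
#'   sequential stages and not counted in them.
#' @return list of class `artidelta_exclusion_config`.
#' @export
exclusion_config <- function(max_rt = 5,
                             excluded_phonemes = EXCLUDED_PHONEMES,
                             drop_incorrect = TRUE,
                             drop_hesitation = TRUE,
                             participant_subset = NULL) {
  if (max_rt <= 0) stop("configuration error: max_rt must be strictly positive")
  structure(list(max_rt = max_rt,
                 excluded_phonemes = excluded_phonemes,
                 drop_incorrect = drop_incorrect,
                 drop_hesitation = drop_hesitation,
                 participant_subset = participant_subset),
            class = "artidelta_exclusion_config")
}

#' Apply the sequential trial exclusions
#'
#' Removals are applied in the study's order, each stage reported against its
#' own denominator: (1) incorrect responses, including responses slower than
#' `max_rt` (denominator: all trials), (2) hesitations (denominator: correct
#' answers), (3) excluded onset phonemes (denominator: correct answers without
#' hesitations). The final kept set does not depend on the order; only the
#' reported denominators do.
#'
#' @param events trial-events table.
#' @param config an [exclusion_config()].
#' @return list with `kept` (filtered table) and `report` (one row per stage:
#'   `n_removed`, `n_denominator`, `pct`).
#' @export
filter_trials <- function(events, config = exclusion_config()) {
  validate_trial_events(events)
  if (anyNA(events$onset_phoneme))
    warning("missing onset phoneme label(s); affected trials retained")
  tab <- events
  if (!is.null(config$participant_subset))
    tab <- tab[tab$participant_id %in% config$participant_subset, , drop = FALSE]

  rt <- response_time(tab)
  bad1 <- (config$drop_incorrect & !tab$correct) | rt > config$max_rt
  n_all <- nrow(tab)
  tab1 <- tab[!bad1, , drop = FALSE]

  bad2 <- if (config$drop_hesitation) tab1$hesitation else rep(FALSE, nrow(tab1))
  tab2 <- tab1[!bad2, , drop = FALSE]

  bad3 <- tab2$onset_phoneme %in% config$excluded_phonemes
  kept <- tab2[!bad3, , drop = FALSE]

  report <- data.frame(
    stage = c("incorrect_or_timeout", "hesitation", "excluded_phoneme"),
    n_removed = c(sum(bad1), sum(bad2), sum(bad3)),
    n_denominator = c(n_all, nrow(tab1), nrow(tab2)),
    stringsAsFactors = FALSE
  )
  report$pct <- ifelse(report$n_denominator > 0,
                       100 * report$n_removed / report$n_denominator, 0)
  list(kept = kept, report = report)
}

#' Time-lock a Delta trace to a trial event
#'
#' Linearly interpolates the trace onto a uniform lock-relative grid with step
#' `1/frame_rate_hz`. Grid point k sits at `k * step` relative to the lock
#' time (question offset for TL1, critical-word onset for TL2, response onset
#' for TL3), so time 0 is always on the grid and grids from trials of
#' different lengths align by the integer index k. Points outside the recorded
#' span are marked invalid (`NA` values).
#'
#' @param trace an `artidelta_delta_trace` anchored to the trial clock.
#' @param events one-row trial-events table for the same trial.
#' @param lock `"TL1"`, `"TL2"` or `"TL3"`.
#' @return list of class `artidelta_epoch` with `k` (integer grid indices),
#'   `grid_times`, `values`, `valid`, `step` and `lock`.
#' @export
epoch_trace <- function(trace, events, lock = c("TL1", "TL2", "TL3")) {
  lock <- match.arg(lock)
  stopifnot(inherits(trace, "artidelta_delta_trace"))
  validate_trial_events(events)
  t_lock <- lock_time(events, lock)
  ts <- trace$timestamps
  step <- 1 / trace$frame_rate_hz
  if (t_lock < ts[1L] - step || t_lock > ts[length(ts)] + step)
    stop(lock, " lies more than one frame outside the trace span")
  rel <- ts - t_lock
  eps <- 1e-9
  kmin <- min(ceiling(rel[1L] / step - eps), 0L)
  kmax <- max(floor(rel[length(rel)] / step + eps), 0L)
  k <- kmin:kmax
  grid <- k * step
  # clamp grid points that fall a rounding error outside the sampled span
  tol <- step * 1e-6
  xq <- grid
  xq[xq < rel[1L] & xq > rel[1L] - tol] <- rel[1L]
  nr <- length(rel)
  xq[xq > rel[nr] & xq < rel[nr] + tol] <- rel[nr]
  vals <- stats::approx(rel, trace$values, xout = xq, rule = 1)$y
  valid <- !is.na(vals)
  structure(list(lock = lock, k = k, grid_times = grid, values = vals,
                 valid = valid, step = step,
                 participant_id = trace$participant_id,
                 item_id = trace$item_id,
                 condition = trace$condition),
            class = "artidelta_epoch")
}

#' Average epochs of one participant and condition
#'
#' Per-timepoint mean over the epochs that are valid there, together with the
#' per-timepoint count of contributing trials (trial lengths vary, so edges of
#' the lock-relative window are supported by fewer trials). Epochs must share
#' the grid step and lock; they align by integer grid index.
#'
#' @param epochs list of `artidelta_epoch` objects (>= 1).
#' @return list of class `artidelta_condition_average` with `k`, `grid_times`,
#'   `mean_values` (NA where no trial contributes) and `n_trials`.
#' @export
average_condition <- function(epochs) {
  stopifnot(length(epochs) >= 1L, all(vapply(epochs, inherits, TRUE, "artidelta_epoch")))
  steps <- vapply(epochs, `[[`, 0, "step")
  if (diff(range(steps)) > 1e-9) stop("grid mismatch: epochs have different grid steps")
  locks <- vapply(epochs, `[[`, "", "lock")
  if (length(unique(locks)) != 1L) stop("grid mismatch: epochs have different locks")
  kmin <- min(vapply(epochs, function(e) min(e$k), 0L))
  kmax <- max(vapply(epochs, function(e) max(e$k), 0L))
  k <- kmin:kmax
  sums <- numeric(length(k))
  counts <- integer(length(k))
  for (e in epochs) {
    idx <- e$k - kmin + 1L
    ok <- e$valid
    sums[idx[ok]] <- sums[idx[ok]] + e$values[ok]
    counts[idx[ok]] <- counts[idx[ok]] + 1L
  }
  means <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  structure(list(participant_id = epochs[[1L]]$participant_id,
                 condition = epochs[[1L]]$condition,
                 lock = locks[1L],
                 k = k,
                 grid_times = k * epochs[[1L]]$step,
                 mean_values = means,
                 n_trials = counts,
                 step = epochs[[1L]]$step),
            class = "artidelta_condition_average")
}

#' Build the participants x timepoints analysis matrices
#'
#' The analysis window is the set of grid timepoints at which every
#' participant's average, in both conditions, is supported by at least
#' `min_trials` trials (complete data, so the per-timepoint paired t-test has
#' constant degrees of freedom), optionally clipped to `clip_range`; the
#' maximal contiguous run (preferring the one containing time 0) is used.
#'
#' @param averages list of `artidelta_condition_average` objects covering both
#'   conditions for every participant at one lock.
#' @param min_trials minimum per-timepoint contributing-trial count.
#' @param clip_range optional `c(lo, hi)` window (s, lock-relative).
#' @return list with matrices `early_planning` and `late_planning` (P x T),
#'   `times` (length T) and `participants`.
#' @export
build_analysis_matrix <- function(averages, min_trials = 1L, clip_range = NULL) {
  stopifnot(length(averages) >= 2L,
            all(vapply(averages, inherits, TRUE, "artidelta_condition_average")))
  locks <- unique(vapply(averages, `[[`, "", "lock"))
  if (length(locks) != 1L) stop("averages mix locks: ", paste(locks, collapse = ", "))
  steps <- vapply(averages, `[[`, 0, "step")
  if (diff(range(steps)) > 1e-9) stop("grid mismatch across averages")
  step <- steps[1L]

  pids <- vapply(averages, `[[`, 0L, "participant_id")
  conds <- vapply(averages, `[[`, "", "condition")
  participants <- sort(unique(pids))
  for (p in participants) {
    if (!all(CONDITIONS %in% conds[pids == p]))
      stop("participant ", p, " lacks an average for one of the conditions")
  }

  valid_ks <- lapply(averages, function(a) a$k[a$n_trials >= min_trials])
  common <- Reduce(intersect, valid_ks)
  if (!is.null(clip_range))
    common <- common[common * step >= clip_range[1L] & common * step <= clip_range[2L]]
  if (length(common) == 0L)
    stop("empty common analysis window (min_trials = ", min_trials, ")")
  common <- sort(common)
  runs <- split(common, cumsum(c(1L, diff(common) != 1L)))
  has0 <- vapply(runs, function(r) any(r == 0L), TRUE)
  run <- if (any(has0)) runs[[which(has0)[1L]]] else runs[[which.max(lengths(runs))]]

  grab <- function(cond) {
    m <- matrix(NA_real_, length(participants), length(run))
    for (i in seq_along(participants)) {
      a <- averages[[which(pids == participants[i] & conds == cond)[1L]]]
      idx <- match(run, a$k)
      m[i, ] <- a$mean_values[idx]
    }
    m
  }
  list(early_planning = grab("early_planning"),
       late_planning = grab("late_planning"),
       times = run * step,
       participants = participants,
       lock = locks)
}

#' Per-participant condition averages for a whole dataset
#'
#' Convenience wrapper: time-locks every kept trial's Delta trace and averages
#' per participant and condition.
#'
#' @param traces named list of `artidelta_delta_trace` objects keyed
#'   `P<participant>_I<item>_<condition>` (as produced by the generator).
#' @param events kept trial-events table (after [filter_trials()]).
#' @param lock time-locking point.
#' @return list of `artidelta_condition_average`, one per participant x
#'   condition.
#' @export
average_dataset <- function(traces, events, lock) {
  validate_trial_events(events)
  averages <- list()
  for (p in sort(unique(events$participant_id))) {
    for (cond in CONDITIONS) {
      rows <- events[events$participant_id == p & events$condition == cond, , drop = FALSE]
      if (nrow(rows) == 0L) next
      epochs <- lapply(seq_len(nrow(rows)), function(i) {
        key <- sprintf("P%d_I%d_%s", rows$participant_id[i], rows$item_id[i], cond)
        tr <- traces[[key]]
        if (is.null(tr)) stop("no trace found for trial ", key)
        epoch_trace(tr, rows[i, , drop = FALSE], lock)
      })
      averages[[length(averages) + 1L]] <- average_condition(epochs)
    }
  }
  averages
}
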