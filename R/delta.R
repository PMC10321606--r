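# Delta technique: frame-to-frame Euclidean pixel distance, turning an
# ultrasound frame stack into a continuous tongue-movement magnitude trace.

#' Euclidean pixel distance between two frames
#'
#' Intensities are promoted to double before differencing (no unsigned
#' wraparound). With `normalization = "none"` this is the plain Euclidean
#' distance between the two frames' pixel vectors,
#' `sqrt(sum((a - b)^2))`; with `"per_pixel_rms"` it is divided by
#' `sqrt(H * W)` so traces are comparable across image sizes.
#'
#' @param frame_a,frame_b numeric/integer matrices of identical dimensions.
#' @param normalization `"per_pixel_rms"` (default) or `"none"`.
#' @return nonnegative scalar.
#' @export
frame_delta <- function(frame_a, frame_b, normalization = c("per_pixel_rms", "none")) {
  normalization <- match.arg(normalization)
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frame shape mismatch: ", paste(dim(frame_a), collapse = "x"),
         " vs ", paste(dim(frame_b), collapse = "x"))
  d <- sqrt(sum((as.numeric(frame_a) - as.numeric(frame_b))^2))
  if (normalization == "per_pixel_rms") d <- d / sqrt(length(frame_a))
  d
}

#' Construct a Delta trace object
#'
#' @param timestamps strictly increasing times (s), one per frame pair.
#' @param values nonnegative change magnitudes.
#' @param frame_rate_hz frame rate the trace was sampled at.
#' @param normalization normalization tag.
#' @param sync_time trial-clock time currently assigned to the sync pulse.
#' @param participant_id,item_id,condition optional trial identifiers.
#' @return list of class `artidelta_delta_trace`.
#' @export
delta_trace <- function(timestamps, values, frame_rate_hz,
                        normalization = "per_pixel_rms", sync_time = 0,
                        participant_id = NA_integer_, item_id = NA_integer_,
                        condition = NA_character_) {
  stopifnot(length(timestamps) == length(values), all(values >= 0),
            all(diff(timestamps) > 0))
  structure(list(
    timestamps = timestamps,
    values = values,
    frame_rate_hz = frame_rate_hz,
    normalization = normalization,
    sync_time = sync_time,
    participant_id = participant_id,
    item_id = item_id,
    condition = condition
  ), class = "artidelta_delta_trace")
}

#' Extract the Delta trace from a frame stack
#'
#' Value k is the Euclidean pixel distance between frames k and k+1; its
#' timestamp is the midpoint of the two frame times (the source material does
#' not fix whether a difference belongs to its first or second frame, and the
#' midpoint avoids a systematic half-frame lag). Times are initially on the
#' sync clock: the sync-pulse frame is at `stack$sync_time` (0 unless the
#' stack was rendered from a known trial); [align_to_events()] re-anchors the
#' trace to a trial's question onset.
#'
#' @param stack an `artidelta_frame_stack` with at least 2 frames.
#' @param normalization `"per_pixel_rms"` (default) or `"none"`.
#' @return an `artidelta_delta_trace` of length `n_frames - 1`.
#' @export
extract_delta_trace <- function(stack, normalization = c("per_pixel_rms", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(stack, "artidelta_frame_stack"))
  dm <- dim(stack$frames)
  n <- dm[3L]
  if (n < 2L) stop("frame stack must contain at least 2 frames")
  m <- matrix(as.numeric(stack$frames), dm[1L] * dm[2L], n)
  values <- sqrt(colSums((m[, -1L, drop = FALSE] - m[, -n, drop = FALSE])^2))
  if (normalization == "per_pixel_rms") values <- values / sqrt(dm[1L] * dm[2L])
  fps <- stack$frame_rate_hz
  # frame f sits at sync_time + (f - sync_index)/fps; value k at the midpoint
  timestamps <- stack$sync_time + (seq_len(n - 1L) - stack$sync_frame_index + 0.5) / fps
  delta_trace(timestamps, values, fps, normalization,
              sync_time = stack$sync_time,
              participant_id = stack$participant_id,
              item_id = stack$item_id,
              condition = stack$condition)
}

#' Anchor a Delta trace to a trial's event times
#'
#' Re-expresses the trace timestamps so that the sync-pulse time equals the
#' trial's question onset (the sync pulse is emitted at auditory stimulus
#' onset). Warns if any of the three time-locking points (question offset,
#' critical-word onset, response onset) falls outside the trace span by more
#' than one frame.
#'
#' @param trace an `artidelta_delta_trace`.
#' @param events one-row trial-events table for the same trial.
#' @return the trace with shifted `timestamps` and updated `sync_time`.
#' @export
align_to_events <- function(trace, events) {
  stopifnot(inherits(trace, "artidelta_delta_trace"))
  validate_trial_events(events)
  stopifnot(nrow(events) == 1L)
  if (!is.na(trace$participant_id) && trace$participant_id != events$participant_id)
    stop("participant mismatch between trace and events")
  if (!is.na(trace$item_id) && trace$item_id != events$item_id)
    stop("item mismatch between trace and events")
  shift <- events$question_onset - trace$sync_time
  trace$timestamps <- trace$timestamps + shift
  trace$sync_time <- events$question_onset
  locks <- c(TL1 = events$question_offset,
             TL2 = events$critical_word_onset,
             TL3 = events$response_onset)
  margin <- 1 / trace$frame_rate_hz
  outside <- locks < trace$timestamps[1L] - margin |
    locks > trace$timestamps[length(trace$timestamps)] + margin
  if (any(outside))
    warning("lock point(s) outside trace span: ", paste(names(locks)[outside], collapse = ", "))
  trace
}

#' Delta trace directly from latent kinematics (rendering-free observation)
#'
#' Fast observation path for simulation studies: the per-frame-pair movement
#' magnitude is taken as the midpoint average of the latent speed, bypassing
#' pixel rendering. On rendered noise-free stacks the true Delta trace is
#' monotonically related to the latent speed (ridge displacement is
#' proportional to it), so for rank-based and difference-based analyses the
#' two observation paths are interchangeable up to the measurement scale; the
#' pixel path additionally carries a speckle-induced noise floor.
#'
#' @param kin an `artidelta_kinematics` trace.
#' @return an `artidelta_delta_trace` anchored to the trial clock.
#' @export
delta_from_kinematics <- function(kin) {
  stopifnot(inherits(kin, "artidelta_kinematics"))
  n <- length(kin$speed)
  if (n < 2L) stop("kinematic trace must contain at least 2 frames")
  values <- (kin$speed[-1L] + kin$speed[-n]) / 2
  timestamps <- (kin$timestamps[-1L] + kin$timestamps[-n]) / 2
  delta_trace(timestamps, values, kin$frame_rate_hz, normalization = "kinematic",
              sync_time = kin$events$question_onset,
              participant_id = kin$events$participant_id,
              item_id = kin$events$item_id,
              condition = kin$events$condition)
}
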