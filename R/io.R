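# File formats: trial-events CSV and the raw binary frame-stack container
# (16-byte little-endian header: height, width, n_frames, frame_rate*1000 as
# 32-bit integers; then frames row-major, one byte per pixel).

EVENT_TIME_COLUMNS <- c("question_onset", "critical_word_onset", "question_offset",
                        "response_onset", "response_offset")

#' Write a trial-events table to CSV
#'
#' Times are serialized in seconds with 6 decimal places (microsecond
#' precision, far below the ~10.9 ms frame period).
#'
#' @param events trial-events table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_trial_events(events)
  out <- events
  for (col in EVENT_TIME_COLUMNS) out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial-events table from CSV
#'
#' Checks column completeness (a missing required column is an error naming
#' the column) and the event-ordering invariants; malformed rows are rejected
#' with their row numbers.
#'
#' @param path CSV path as written by [write_events()].
#' @return validated trial-events data.frame.
#' @export
read_events <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("participant_id", "item_id", "condition", EVENT_TIME_COLUMNS,
                "correct", "hesitation", "onset_phoneme")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0L)
    stop("events file is missing required column(s): ", paste(missing, collapse = ", "))
  for (col in EVENT_TIME_COLUMNS) {
    events[[col]] <- suppressWarnings(as.numeric(events[[col]]))
    bad <- which(is.na(events[[col]]))
    if (length(bad) > 0L)
      stop("non-numeric ", col, " in row(s): ", paste(bad, collapse = ", "))
  }
  events$correct <- as.logical(events$correct)
  events$hesitation <- as.logical(events$hesitation)
  validate_trial_events(events)
  events
}

#' Write a frame stack to the raw binary container
#'
#' Format: 16-byte little-endian header (`height`, `width`, `n_frames`,
#' `round(frame_rate_hz * 1000)` as signed 32-bit integers) followed by the
#' frames in order, each row-major, one unsigned byte per pixel.
#'
#' @param stack an `artidelta_frame_stack` (intensities must be in [0, 255]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "artidelta_frame_stack"))
  dm <- dim(stack$frames)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dm[1L], dm[2L], dm[3L], round(stack$frame_rate_hz * 1000))),
           con, size = 4L, endian = "little")
  # row-major per frame: transpose each H x W frame before flattening
  for (f in seq_len(dm[3L]))
    writeBin(as.raw(t(stack$frames[, , f])), con)
  invisible(path)
}

#' Read a frame stack from the raw binary container
#'
#' @param path file written by [write_frame_stack()].
#' @param sync_frame_index 1-based sync-pulse frame index (stored in the
#'   events table, not the container).
#' @param participant_id,item_id,condition optional trial identifiers.
#' @return an `artidelta_frame_stack`.
#' @export
read_frame_stack <- function(path, sync_frame_index = 1L,
                             participant_id = NA_integer_, item_id = NA_integer_,
                             condition = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
  H <- hdr[1L]; W <- hdr[2L]; n <- hdr[3L]
  if (H < 1L || W < 1L || n < 1L) stop("corrupt frame-stack header in ", path)
  raw <- readBin(con, "raw", n = H * W * n)
  if (length(raw) != H * W * n) stop("truncated frame-stack payload in ", path)
  # stored row-major per frame; R arrays are column-major
  frames <- aperm(array(as.integer(raw), dim = c(W, H, n)), c(2L, 1L, 3L))
  frame_stack(frames, hdr[4L] / 1000, sync_frame_index = sync_frame_index,
              participant_id = participant_id, item_id = item_id,
              condition = condition)
}
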