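#' Epoch-level accelerometer count series
#'
#' Container for one participant-measurement's count trace: an ordered vector
#' of non-negative integer activity counts accumulated over fixed epochs,
#' anchored to a clock time. Uniaxial waist-worn devices of the Actigraph
#' family report such counts; all downstream processing assumes counts per
#' 60-s epoch (cpm), shorter epochs are reintegrated first.
#'
#' @param participant_id character scalar identifying the participant.
#' @param start_clock POSIXct (or coercible) time of the first epoch's start.
#' @param counts numeric vector of non-negative integer counts, one per epoch.
#' @param epoch_length epoch duration in seconds; must divide 60 or equal 60.
#' @return An object of class `epoch_series`: a list with fields
#'   `participant_id`, `start_clock`, `epoch_length`, `counts`.
#' @examples
#' es <- epoch_series("P1", "2008-06-02 00:00:00", c(0, 0, 150, 4100), 60)
#' length(es$counts)
#' @export
epoch_series <- function(participant_id, start_clock, counts, epoch_length = 60L) {
  if (!is.numeric(counts)) stop("`counts` must be numeric")
  if (anyNA(counts)) stop("`counts` must not contain NA")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  if (any(counts != floor(counts))) stop("`counts` must be whole numbers")
  epoch_length <- as.integer(epoch_length)
  if (!(epoch_length == 60L || (epoch_length > 0L && 60L %% epoch_length == 0L)))
    stop("`epoch_length` must equal 60 or divide 60, got ", epoch_length)
  start_clock <- as.POSIXct(start_clock, tz = "UTC")
  if (length(start_clock) != 1L || is.na(start_clock))
    stop("`start_clock` must be a single valid date-time")
  structure(
    list(participant_id = as.character(participant_id),
         start_clock = start_clock,
         epoch_length = epoch_length,
         counts = as.integer(counts)),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  mins <- length(x$counts) * x$epoch_length / 60
  cat(sprintf("<epoch_series> %s: %d epochs of %ds (%.0f min) from %s\n",
              x$participant_id, length(x$counts), x$epoch_length, mins,
              format(x$start_clock, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Clock times of each epoch in a series
#'
#' @param series an [epoch_series()].
#' @return POSIXct vector of epoch start times.
#' @keywords internal
epoch_times <- function(series) {
  series$start_clock + (seq_along(series$counts) - 1L) * series$epoch_length
}

#' Split a multi-day series into per-calendar-day series
#'
#' Non-wear detection and day summaries operate on one calendar day at a time;
#' a bout spanning midnight is split at the day boundary and each part must
#' qualify on its own.
#'
#' @param series an [epoch_series()].
#' @return Named list of `epoch_series`, one per calendar day, names
#'   `YYYY-MM-DD`.
#' @export
split_days <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  tt <- epoch_times(series)
  day <- format(tt, "%Y-%m-%d")
  idx <- split(seq_along(day), day)
  lapply(idx, function(i)
    epoch_series(series$participant_id, tt[i[1L]], series$counts[i],
                 series$epoch_length))
}
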