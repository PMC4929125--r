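#' Processing rules for epoch-level count data
#'
#' Bundles every rule used to turn a count trace into wear time and intensity
#' minutes: the target epoch, the non-wear definition (60 min of consecutive
#' zeros allowing up to 2 min of nonzero interruptions), the daily wear window
#' (7 am to midnight), the valid-day and inclusion thresholds, and the Evenson
#' cut-points (sedentary < 100 cpm, moderate >= 2296 cpm, vigorous >= 4012 cpm).
#'
#' @param target_epoch target epoch length in seconds.
#' @param nonwear_min_bout minimum non-wear bout length, minutes.
#' @param nonwear_max_interrupt maximum number of single-epoch nonzero
#'   interruptions tolerated inside one bout (counted cumulatively).
#' @param wear_window numeric length-2, daily window in clock hours,
#'   half-open `[start, end)`.
#' @param valid_day_min_wear minimum wear minutes for a valid day (inclusive).
#' @param min_valid_days minimum number of valid days for inclusion.
#' @param sedentary_upper,moderate_lower,vigorous_lower intensity cut-points
#'   in counts per minute.
#' @param interrupt_max_cpm optional cap on the count an interruption epoch
#'   may carry and still be absorbed into a bout; `Inf` disables the cap
#'   (the published rule states no cap).
#' @return A list of class `processing_params`.
#' @examples
#' p <- processing_params()
#' p$vigorous_lower
#' @export
processing_params <- function(target_epoch = 60L,
                              nonwear_min_bout = 60,
                              nonwear_max_interrupt = 2L,
                              wear_window = c(7, 24),
                              valid_day_min_wear = 500,
                              min_valid_days = 1L,
                              sedentary_upper = 100,
                              moderate_lower = 2296,
                              vigorous_lower = 4012,
                              interrupt_max_cpm = Inf) {
  stopifnot(target_epoch > 0, nonwear_min_bout > 0, nonwear_max_interrupt >= 0,
            length(wear_window) == 2L, wear_window[1L] < wear_window[2L],
            valid_day_min_wear > 0, min_valid_days >= 1L)
  if (!(sedentary_upper > 0 && sedentary_upper <= moderate_lower &&
        moderate_lower < vigorous_lower))
    stop("cut-points must satisfy 0 < sedentary_upper <= moderate_lower < vigorous_lower")
  structure(
    list(target_epoch = as.integer(target_epoch),
         nonwear_min_bout = nonwear_min_bout,
         nonwear_max_interrupt = as.integer(nonwear_max_interrupt),
         wear_window = wear_window,
         valid_day_min_wear = valid_day_min_wear,
         min_valid_days = as.integer(min_valid_days),
         sedentary_upper = sedentary_upper,
         moderate_lower = moderate_lower,
         vigorous_lower = vigorous_lower,
         interrupt_max_cpm = interrupt_max_cpm),
    class = "processing_params")
}

#' Reintegrate a count series to a longer epoch
#'
#' Counts from consecutive short epochs are summed into blocks of the target
#' epoch length (e.g. 5-s to 60-s). A trailing partial block is dropped with a
#' warning, since an incomplete minute would bias counts-per-minute values.
#'
#' @param series an [epoch_series()].
#' @param target_epoch target epoch length in seconds; the input epoch length
#'   must divide it.
#' @return An `epoch_series` at the target epoch length.
#' @examples
#' es <- epoch_series("P1", "2008-06-02", rep(c(10, 0, 0, 50, 0, 0), 2), 5)
#' reintegrate(es, 60)$counts
#' @export
reintegrate <- function(series, target_epoch = 60L) {
  stopifnot(inherits(series, "epoch_series"))
  target_epoch <- as.integer(target_epoch)
  if (target_epoch %% series$epoch_length != 0L)
    stop(sprintf("input epoch length %d s does not divide target epoch %d s",
                 series$epoch_length, target_epoch))
  k <- target_epoch %/% series$epoch_length
  if (k == 1L) return(series)
  n <- length(series$counts)
  n_full <- n %/% k
  if (n %% k != 0L)
    warning(sprintf("dropping trailing partial block of %d epoch(s) during reintegration",
                    n %% k))
  if (n_full == 0L)
    return(epoch_series(series$participant_id, series$start_clock,
                        integer(0), target_epoch))
  x <- series$counts[seq_len(n_full * k)]
  out <- colSums(matrix(x, nrow = k))
  epoch_series(series$participant_id, series$start_clock, out, target_epoch)
}

#' Detect non-wear bouts in a 60-s epoch series
#'
#' A non-wear bout is a run of zero-count epochs at least
#' `nonwear_min_bout` minutes long, allowing at most
#' `nonwear_max_interrupt` nonzero interruption epochs. Interruptions are
#' single isolated epochs (two consecutive nonzero epochs always end a bout),
#' are counted cumulatively within a bout, and cannot be terminal: every bout
#' starts and ends on a zero epoch. An interruption beyond the allowance
#' terminates the bout at its last zero epoch; scanning is greedy from the
#' left.
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param params a [processing_params()].
#' @return data.frame with one row per qualifying bout: `start` (1-based index
#'   of the first epoch), `end` (exclusive, so `end - start` is the bout
#'   length in minutes) and `n_interruptions`.
#' @examples
#' es <- epoch_series("P1", "2008-06-02", c(rep(0, 59), 300, rep(0, 59)))
#' detect_nonwear(es, processing_params())
#' @export
detect_nonwear <- function(series, params = processing_params()) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_length != 60L)
    stop("detect_nonwear requires 60-s epochs; reintegrate first (epoch is ",
         series$epoch_length, " s)")
  x <- series$counts
  n <- length(x)
  res <- list()
  if (n == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      n_interruptions = integer(0)))
  r <- rle(x != 0L)
  len <- r$lengths
  nonzero <- r$values
  run_end <- cumsum(len)
  run_start <- run_end - len + 1L
  m <- length(len)
  # interruption epochs must not exceed the optional count cap
  interruptible <- !nonzero | (len == 1L & x[run_start] <= params$interrupt_max_cpm)

  i <- 1L
  while (i <= m) {
    if (nonzero[i]) { i <- i + 1L; next }
    bout_start <- run_start[i]
    bout_end <- run_end[i]          # inclusive index of last zero epoch
    interrupts <- 0L
    j <- i + 1L
    while (j + 1L <= m && !nonzero[j + 1L] &&
           len[j] == 1L && interruptible[j] &&
           interrupts < params$nonwear_max_interrupt) {
      interrupts <- interrupts + 1L
      bout_end <- run_end[j + 1L]
      j <- j + 2L
    }
    if (bout_end - bout_start + 1L >= params$nonwear_min_bout)
      res[[length(res) + 1L]] <- c(bout_start, bout_end + 1L, interrupts)
    i <- j
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      n_interruptions = integer(0)))
  out <- do.call(rbind, res)
  data.frame(start = out[, 1L], end = out[, 2L], n_interruptions = out[, 3L])
}

#' Classify 60-s epochs into intensity classes
#'
#' Applies the Evenson cut-points: counts below 100 cpm are sedentary,
#' `[100, 2296)` light, `[2296, 4012)` moderate and 4012 cpm or more vigorous.
#'
#' @param series an [epoch_series()] at 60-s epochs (or a bare count vector).
#' @param params a [processing_params()].
#' @return factor with levels `sedentary`, `light`, `moderate`, `vigorous`,
#'   one per epoch.
#' @examples
#' classify_epochs(c(0, 99, 100, 2295, 2296, 4011, 4012))
#' @export
classify_epochs <- function(series, params = processing_params()) {
  x <- if (inherits(series, "epoch_series")) {
    if (series$epoch_length != 60L)
      stop("classify_epochs requires 60-s epochs (epoch is ",
           series$epoch_length, " s)")
    series$counts
  } else series
  if (any(x < 0)) stop("negative counts are not valid")
  cut(x, breaks = c(-Inf, params$sedentary_upper, params$moderate_lower,
                    params$vigorous_lower, Inf),
      labels = c("sedentary", "light", "moderate", "vigorous"),
      right = FALSE)
}

#' Summarize one calendar day of 60-s epoch data
#'
#' Restricts to epochs whose clock time falls in the daily wear window
#' (default 07:00 to 24:00, half-open), removes epochs inside detected
#' non-wear bouts, and tallies minutes by intensity class over the remaining
#' wear epochs. A day is valid when wear time reaches
#' `valid_day_min_wear` minutes (inclusive).
#'
#' @param series an [epoch_series()] covering at most one calendar day.
#' @param params a [processing_params()].
#' @return One-row data.frame: `date`, `wear_minutes`, `sedentary_minutes`,
#'   `light_minutes`, `moderate_minutes`, `vigorous_minutes`, `valid`.
#'   The four class columns always sum to `wear_minutes`.
#' @export
summarize_day <- function(series, params = processing_params()) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_length != 60L)
    stop("summarize_day requires 60-s epochs")
  tt <- epoch_times(series)
  if (length(tt) && format(tt[1L], "%Y-%m-%d") != format(tt[length(tt)], "%Y-%m-%d"))
    stop("series spans more than one calendar day; use split_days() first")
  if (anyDuplicated(tt)) stop("duplicate epoch timestamps")

  hour <- as.numeric(difftime(tt, trunc(tt, "days"), units = "hours"))
  in_window <- hour >= params$wear_window[1L] & hour < params$wear_window[2L]

  bouts <- detect_nonwear(series, params)
  in_bout <- rep(FALSE, length(series$counts))
  if (nrow(bouts))
    for (b in seq_len(nrow(bouts)))
      in_bout[bouts$start[b]:(bouts$end[b] - 1L)] <- TRUE

  wear <- in_window & !in_bout
  cls <- classify_epochs(series, params)
  tab <- table(cls[wear])
  wear_min <- sum(wear)
  data.frame(
    date = if (length(tt)) as.Date(format(tt[1L], "%Y-%m-%d")) else as.Date(NA),
    wear_minutes = wear_min,
    sedentary_minutes = as.integer(tab[["sedentary"]]),
    light_minutes = as.integer(tab[["light"]]),
    moderate_minutes = as.integer(tab[["moderate"]]),
    vigorous_minutes = as.integer(tab[["vigorous"]]),
    valid = wear_min >= params$valid_day_min_wear)
}

#' Summarize a person-measurement from its day summaries
#'
#' Participants with at least `min_valid_days` valid days are included;
#' outcomes are unweighted means over valid days only. Exclusion is a return
#' state (`NULL`), not an error.
#'
#' @param day_summaries data.frame of rows as returned by [summarize_day()]
#'   (all days from one measurement of one participant).
#' @param params a [processing_params()].
#' @param participant_id identifier copied into the result.
#' @param measurement_date optional date of the measurement (defaults to the
#'   first day present).
#' @return One-row data.frame (`participant_id`, `measurement_date`,
#'   `n_valid_days`, `mean_wear_minutes`, `mean_sedentary_minutes`,
#'   `mean_mpa_minutes`, `mean_vpa_minutes`) or `NULL` when excluded.
#' @export
summarize_person <- function(day_summaries, params = processing_params(),
                             participant_id = NA_character_,
                             measurement_date = NULL) {
  v <- day_summaries[day_summaries$valid, , drop = FALSE]
  if (nrow(v) < params$min_valid_days) return(NULL)
  if (is.null(measurement_date)) measurement_date <- min(day_summaries$date)
  data.frame(
    participant_id = participant_id,
    measurement_date = as.Date(measurement_date),
    n_valid_days = nrow(v),
    mean_wear_minutes = mean(v$wear_minutes),
    mean_sedentary_minutes = mean(v$sedentary_minutes),
    mean_mpa_minutes = mean(v$moderate_minutes),
    mean_vpa_minutes = mean(v$vigorous_minutes))
}

#' Aggregate day-summary rows to person summaries
#'
#' Applies [summarize_person()] per participant to a data.frame of day rows
#' (as produced by [process_cohort()] or the day-level output of
#' [generate_cohort()]).
#'
#' @param days data.frame of day summaries with a `participant_id` column.
#' @param params a [processing_params()].
#' @return data.frame of person summaries (excluded participants omitted).
#' @export
summarize_persons <- function(days, params = processing_params()) {
  v <- days[days$valid, , drop = FALSE]
  g <- factor(v$participant_id)
  agg <- data.frame(
    participant_id = levels(g),
    measurement_date = as.Date(tapply(as.numeric(v$date), g, min),
                               origin = "1970-01-01"),
    n_valid_days = as.integer(table(g)),
    mean_wear_minutes = as.numeric(tapply(v$wear_minutes, g, mean)),
    mean_sedentary_minutes = as.numeric(tapply(v$sedentary_minutes, g, mean)),
    mean_mpa_minutes = as.numeric(tapply(v$moderate_minutes, g, mean)),
    mean_vpa_minutes = as.numeric(tapply(v$vigorous_minutes, g, mean)),
    row.names = NULL)
  agg[agg$n_valid_days >= params$min_valid_days, , drop = FALSE]
}

#' Process a list of epoch series into person summaries
#'
#' Full processing pipeline: reintegrate each trace to the target epoch,
#' split into calendar days, summarize each day, and aggregate to one
#' person-summary row per included participant.
#'
#' @param series_list list of [epoch_series()] (one per participant-measurement).
#' @param params a [processing_params()].
#' @return list with `persons` (data.frame, one row per included participant)
#'   and `days` (data.frame of all day summaries with `participant_id`).
#' @export
process_cohort <- function(series_list, params = processing_params()) {
  day_rows <- vector("list", length(series_list))
  person_rows <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    es <- reintegrate(series_list[[i]], params$target_epoch)
    dl <- split_days(es)
    ds <- do.call(rbind, lapply(dl, summarize_day, params = params))
    rownames(ds) <- NULL
    day_rows[[i]] <- cbind(participant_id = es$participant_id, ds)
    person_rows[[i]] <- summarize_person(ds, params,
                                         participant_id = es$participant_id)
  }
  list(persons = do.call(rbind, person_rows),
       days = do.call(rbind, day_rows))
}
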