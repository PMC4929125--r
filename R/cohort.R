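#' Configuration for the synthetic cohort generator
#'
#' Describes the generative world used to exercise the pipeline without
#' access to pooled consortium data: a multi-study sample of 5-18 year-olds
#' whose expected daily vigorous (VPA) and moderate (MPA) activity minutes
#' decline geometrically with age. A participant of age `a` has expected
#' VPA minutes per day `baseline_vpa_mean * annual_ratio_vpa^(a - 5)` times a
#' person-level log-normal factor; the same construction holds for MPA.
#' Default baselines (12.97 VPA, 41.32 MPA min/day at age 5-5.9) and ratios
#' (0.931, 0.940 per year), study/region shares, subgroup mixes, and the
#' wear-time distribution (mean 770, SD 88.6 min/day) are patterned on the
#' published pooled analysis this package emulates.
#'
#' @param n_participants number of participants.
#' @param age_range numeric length-2 within `[5, 18]`; ages drawn uniformly.
#' @param study_labels data.frame with columns `study_id`, `region`
#'   (`UK`, `Europe`, `North America`, `Brazil`, `Australia`) and sampling
#'   `weight`.
#' @param subgroup_mix named list of named probability vectors for `sex`,
#'   `ethnicity`, `maternal_education`, `weight_status`; each must sum to 1.
#' @param baseline_vpa_mean,baseline_mpa_mean expected min/day at age 5;
#'   either a scalar or a named vector over the levels of `ratio_moderator`.
#' @param annual_ratio_vpa,annual_ratio_mpa per-year geometric ratio (> 0);
#'   scalar or named vector over the levels of `ratio_moderator`.
#' @param ratio_moderator `NULL` for a common age trend, or the name of one
#'   subgroup variable (e.g. `"sex"`) whose levels index the baseline/ratio
#'   vectors.
#' @param person_sd_log SD of the person-level multiplicative noise on the
#'   log scale (one draw per person, shared by VPA and MPA).
#' @param days_per_person monitored days per participant.
#' @param day_jitter `"poisson"` for Poisson day-to-day variation of class
#'   minutes around the person's expectation, `"none"` for deterministic
#'   rounded targets.
#' @param wear_schedule list with `start_hour`, `mean_wear`, `sd_wear`,
#'   `min_wear`, `max_wear` (minutes). The wear block is anchored at
#'   `start_hour`; `max_wear` must keep the trailing gap to midnight at
#'   least 60 min so scheduled wear is exactly recoverable by the non-wear
#'   rule.
#' @param sedentary_mean expected sedentary min/day (remaining wear time is
#'   light intensity).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 1000L,
                          age_range = c(5, 18),
                          study_labels = default_study_labels(),
                          subgroup_mix = default_subgroup_mix(),
                          baseline_vpa_mean = 12.97,
                          baseline_mpa_mean = 41.32,
                          annual_ratio_vpa = 0.931,
                          annual_ratio_mpa = 0.940,
                          ratio_moderator = NULL,
                          person_sd_log = 0.5,
                          days_per_person = 7L,
                          day_jitter = c("poisson", "none"),
                          wear_schedule = list(start_hour = 7, mean_wear = 770,
                                               sd_wear = 88.6, min_wear = 500,
                                               max_wear = 960),
                          sedentary_mean = 349,
                          seed = 1L) {
  day_jitter <- match.arg(day_jitter)
  for (nm in names(subgroup_mix)) {
    p <- subgroup_mix[[nm]]
    if (abs(sum(p) - 1) > 1e-8)
      stop("subgroup proportions for `", nm, "` must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop("negative proportion in `", nm, "`")
  }
  if (any(c(annual_ratio_vpa, annual_ratio_mpa) <= 0))
    stop("annual ratios must be > 0")
  if (any(c(baseline_vpa_mean, baseline_mpa_mean) <= 0))
    stop("baseline means must be > 0")
  if (age_range[1L] < 5 || age_range[2L] > 18 || age_range[1L] >= age_range[2L])
    stop("age_range must be an increasing interval within [5, 18]")
  if (!is.null(ratio_moderator)) {
    lev <- names(subgroup_mix[[ratio_moderator]])
    for (v in list(baseline_vpa_mean, baseline_mpa_mean,
                   annual_ratio_vpa, annual_ratio_mpa))
      if (length(v) > 1L && !setequal(names(v), lev))
        stop("per-subgroup baselines/ratios must be named by the levels of `",
             ratio_moderator, "`")
  }
  if (1440 - (wear_schedule$start_hour * 60 + wear_schedule$max_wear) < 60)
    stop("wear schedule must leave >= 60 min of zeros before midnight")
  structure(
    list(n_participants = as.integer(n_participants), age_range = age_range,
         study_labels = study_labels, subgroup_mix = subgroup_mix,
         baseline_vpa_mean = baseline_vpa_mean,
         baseline_mpa_mean = baseline_mpa_mean,
         annual_ratio_vpa = annual_ratio_vpa,
         annual_ratio_mpa = annual_ratio_mpa,
         ratio_moderator = ratio_moderator,
         person_sd_log = person_sd_log,
         days_per_person = as.integer(days_per_person),
         day_jitter = day_jitter, wear_schedule = wear_schedule,
         sedentary_mean = sedentary_mean, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default study table: shares patterned on the pooled sample's regions
#' @return data.frame of study_id, region, sampling weight.
#' @export
default_study_labels <- function() {
  data.frame(
    study_id = c("UK-A", "UK-B", "EUR-A", "NA-A", "NA-B", "BR-A", "AUS-A"),
    region = c("UK", "UK", "Europe", "North America", "North America",
               "Brazil", "Australia"),
    weight = c(0.25, 0.157, 0.181, 0.15, 0.14, 0.019, 0.103))
}

#' Default subgroup category mix
#' @return named list of named probability vectors.
#' @export
default_subgroup_mix <- function() {
  list(sex = c(male = 0.447, female = 0.553),
       ethnicity = c(white = 0.523, black = 0.204, hispanic = 0.206,
                     other = 0.067),
       maternal_education = c("high school" = 0.526, college = 0.166,
                              university = 0.308),
       weight_status = c(normal = 0.898, "overweight/obese" = 0.102))
}

# expand a scalar-or-named generative parameter to one value per person
expand_param <- function(value, moderator_values) {
  if (length(value) == 1L) rep(unname(value), length(moderator_values))
  else unname(value[moderator_values])
}

#' Generate a synthetic cohort
#'
#' Draws participant metadata and per-day intensity-minute targets from the
#' generative model in [cohort_config()], optionally rendering full
#' epoch-level count traces. Day-level output is exact in the sense that the
#' rendered traces, when pushed through the processing rules, recover the
#' same day minutes.
#'
#' @param config a [cohort_config()].
#' @param traces logical; also render one multi-day 60-s [epoch_series()] per
#'   participant (slower).
#' @return list of class `vt_cohort` with elements `participants`
#'   (metadata data.frame), `days` (per-day class-minute targets shaped like
#'   [summarize_day()] output plus `participant_id`), `traces` (list of
#'   `epoch_series` or `NULL`) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 5, seed = 7))
#' head(coh$days)
#' @export
generate_cohort <- function(config, traces = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  empty_part <- data.frame(
    participant_id = character(0), study_id = character(0),
    region = character(0), age = numeric(0), sex = character(0),
    ethnicity = character(0), maternal_education = character(0),
    weight_status = character(0), measurement_date = as.Date(character(0)))
  if (n == 0L)
    return(structure(list(participants = empty_part,
                          days = NULL, traces = list(), config = config),
                     class = "vt_cohort"))

  st <- config$study_labels
  study_idx <- sample.int(nrow(st), n, replace = TRUE,
                          prob = st$weight / sum(st$weight))
  draw_cat <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  participants <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    study_id = st$study_id[study_idx],
    region = st$region[study_idx],
    age = stats::runif(n, config$age_range[1L], config$age_range[2L]),
    sex = draw_cat(config$subgroup_mix$sex),
    ethnicity = draw_cat(config$subgroup_mix$ethnicity),
    maternal_education = draw_cat(config$subgroup_mix$maternal_education),
    weight_status = draw_cat(config$subgroup_mix$weight_status),
    measurement_date = as.Date("2008-03-01") + seq_len(n) %/% 5L)

  mod_val <- if (is.null(config$ratio_moderator)) rep("", n)
             else participants[[config$ratio_moderator]]
  z <- stats::rnorm(n, 0, config$person_sd_log)    # one draw per person
  age0 <- participants$age - 5
  lambda_vpa <- expand_param(config$baseline_vpa_mean, mod_val) *
    expand_param(config$annual_ratio_vpa, mod_val)^age0 * exp(z)
  lambda_mpa <- expand_param(config$baseline_mpa_mean, mod_val) *
    expand_param(config$annual_ratio_mpa, mod_val)^age0 * exp(z)

  ws <- config$wear_schedule
  wear <- as.integer(round(pmin(pmax(stats::rnorm(n, ws$mean_wear, ws$sd_wear),
                                     ws$min_wear), ws$max_wear)))

  d <- config$days_per_person
  idx <- rep(seq_len(n), each = d)
  jit <- function(lambda) {
    if (config$day_jitter == "poisson") stats::rpois(n * d, lambda[idx])
    else as.integer(round(lambda[idx]))
  }
  vpa_d <- jit(lambda_vpa)
  mpa_d <- jit(lambda_mpa)
  sed_d <- jit(rep(config$sedentary_mean, n))
  wear_d <- wear[idx]
  # activity classes can never exceed the day's wear time; sedentary yields first
  over <- pmax(vpa_d + mpa_d + sed_d - wear_d, 0L)
  sed_d <- pmax(sed_d - over, 0L)
  over <- pmax(vpa_d + mpa_d + sed_d - wear_d, 0L)
  mpa_d <- pmax(mpa_d - over, 0L)
  vpa_d <- pmin(vpa_d, wear_d)
  light_d <- wear_d - sed_d - mpa_d - vpa_d

  days <- data.frame(
    participant_id = participants$participant_id[idx],
    date = rep(participants$measurement_date, each = d) + rep(seq_len(d) - 1L, n),
    wear_minutes = wear_d,
    sedentary_minutes = sed_d,
    light_minutes = light_d,
    moderate_minutes = mpa_d,
    vigorous_minutes = vpa_d,
    valid = wear_d >= 500)

  trace_list <- list()
  if (traces) {
    trace_list <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- which(idx == i)
      day_counts <- lapply(rows, function(r)
        render_day_counts(c(sedentary = sed_d[r], light = light_d[r],
                            moderate = mpa_d[r], vigorous = vpa_d[r]),
                          wear_start_min = ws$start_hour * 60,
                          wear_minutes = wear_d[r]))
      trace_list[[i]] <- epoch_series(
        participants$participant_id[i],
        as.POSIXct(paste(participants$measurement_date[i], "00:00:00"),
                   tz = "UTC"),
        unlist(day_counts), 60L)
    }
  }
  structure(list(participants = participants, days = days,
                 traces = trace_list, config = config),
            class = "vt_cohort")
}

#' @export
print.vt_cohort <- function(x, ...) {
  cat(sprintf("<vt_cohort> %d participants, %d day rows, %d traces (seed %d)\n",
              nrow(x$participants),
              if (is.null(x$days)) 0L else nrow(x$days),
              length(x$traces), x$config$seed))
  invisible(x)
}

# 1440 counts for one day: zeros outside the wear block, class-band draws inside
render_day_counts <- function(minutes, wear_start_min, wear_minutes) {
  counts <- integer(1440)
  if (wear_minutes == 0) return(counts)
  wear_pos <- wear_start_min + seq_len(wear_minutes)  # 1-based epoch indices
  lab <- rep(c("sedentary", "light", "moderate", "vigorous"), times = minutes)
  slack <- wear_minutes - length(lab)
  if (slack < 0) stop("class minutes exceed wear minutes")
  if (slack > 0) lab <- c(lab, rep("sedentary", slack))
  lab <- sample(lab)
  nlab <- length(lab)
  draw <- integer(nlab)
  # uniform draws within each cut-point band; zeros are reserved for non-wear
  draw[lab == "sedentary"] <- sample(1:99, sum(lab == "sedentary"), replace = TRUE)
  draw[lab == "light"] <- sample(100:2295, sum(lab == "light"), replace = TRUE)
  draw[lab == "moderate"] <- sample(2296:4011, sum(lab == "moderate"), replace = TRUE)
  draw[lab == "vigorous"] <- sample(4012:8000, sum(lab == "vigorous"), replace = TRUE)
  counts[wear_pos] <- draw
  counts
}

#' Generate one day's epoch trace with requested class minutes
#'
#' Builds a full-day (1440-epoch, 60-s) count trace whose wear block starts at
#' `wear_schedule$start_hour` and lasts `wear_schedule$wear_minutes`. Within
#' the wear block exactly the requested number of epochs carry counts drawn
#' uniformly inside each intensity band (sedentary `[1, 100)`, light
#' `[100, 2296)`, moderate `[2296, 4012)`, vigorous `[4012, 8000]`); any
#' unrequested wear minutes are filled with sedentary-band counts; all epochs
#' outside the block are zero.
#'
#' @param target_minutes named numeric vector with any of `sedentary`,
#'   `light`, `moderate`, `vigorous`; must sum to at most the scheduled wear
#'   minutes.
#' @param wear_schedule list with `start_hour` and `wear_minutes`
#'   (`start_hour * 60 + wear_minutes` must leave at least 60 min before
#'   midnight).
#' @param seed optional integer seed.
#' @param participant_id,date identity of the produced series.
#' @return An [epoch_series()] of 1440 60-s epochs.
#' @examples
#' es <- generate_day_trace(c(moderate = 30, vigorous = 10),
#'                          list(start_hour = 7, wear_minutes = 600), seed = 1)
#' table(classify_epochs(es))[c("moderate", "vigorous")]
#' @export
generate_day_trace <- function(target_minutes, wear_schedule, seed = NULL,
                               participant_id = "SYN", date = "2008-06-02") {
  if (!is.null(seed)) set.seed(seed)
  wm <- wear_schedule$wear_minutes
  full <- c(sedentary = 0, light = 0, moderate = 0, vigorous = 0)
  full[names(target_minutes)] <- target_minutes
  if (sum(full) > wm)
    stop(sprintf("requested class minutes (%d) exceed scheduled wear (%d)",
                 sum(full), wm))
  if (wear_schedule$start_hour * 60 + wm > 1380)
    stop("wear block must end by 23:00 to leave a detectable trailing gap")
  counts <- render_day_counts(full, wear_schedule$start_hour * 60, wm)
  epoch_series(participant_id,
               as.POSIXct(paste(date, "00:00:00"), tz = "UTC"), counts, 60L)
}

#' Inject non-wear bouts into an epoch series
#'
#' Zeroes the specified spans, optionally leaving isolated nonzero
#' interruption epochs inside each span so the result exercises the
#' interruption allowance of the non-wear rule. All epochs outside the spans
#' are untouched; a bout always starts and ends on a zero epoch.
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param bout_spec data.frame with columns `start` (1-based epoch index),
#'   `length` (epochs) and optionally `n_interruptions` (0-2, default 0) and
#'   `interrupt_count` (count value placed at interruption epochs,
#'   default 50).
#' @return The modified `epoch_series`.
#' @export
inject_nonwear <- function(series, bout_spec) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(bout_spec) || nrow(bout_spec) == 0L) return(series)
  if (is.null(bout_spec$n_interruptions)) bout_spec$n_interruptions <- 0L
  if (is.null(bout_spec$interrupt_count)) bout_spec$interrupt_count <- 50L
  ends <- bout_spec$start + bout_spec$length - 1L
  if (any(bout_spec$start < 1L) || any(ends > length(series$counts)))
    stop("bout positions fall outside the series")
  o <- order(bout_spec$start)
  if (any(bout_spec$start[o][-1L] <= ends[o][-length(o)]))
    stop("overlapping non-wear bouts")
  counts <- series$counts
  for (b in seq_len(nrow(bout_spec))) {
    s <- bout_spec$start[b]; L <- bout_spec$length[b]
    k <- bout_spec$n_interruptions[b]
    if (k > 0 && L < 2L * k + 1L)
      stop("bout too short for ", k, " isolated interruptions")
    counts[s:(s + L - 1L)] <- 0L
    if (k > 0) {
      # interior, pairwise non-adjacent interruption positions
      pos <- s + floor(L * seq_len(k) / (k + 1))
      counts[pos] <- bout_spec$interrupt_count[b]
    }
  }
  epoch_series(series$participant_id, series$start_clock, counts,
               series$epoch_length)
}
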