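#' Build the analysis dataset from person summaries and metadata
#'
#' Applies the cohort inclusion rules: one row per participant (the earliest
#' measurement when several are present) and age restricted to
#' `[age_range[1], age_range[2]]` (ages below 5.0 are excluded; the default
#' upper limit is 18.0). Participants present in the summaries but missing
#' from the metadata are reported, not silently dropped.
#'
#' @param person_summaries data.frame as returned by [process_cohort()]
#'   (or [generate_cohort()]'s day rows pushed through [summarize_person()]).
#' @param metadata participant metadata data.frame with `participant_id`,
#'   `age`, `study_id`, `region`, `sex`, `ethnicity`, `maternal_education`,
#'   `weight_status`.
#' @param age_range inclusive age limits.
#' @return data.frame with columns `participant_id`, `age`, `vpa_min`,
#'   `mpa_min`, `wear_min`, `sed_min`, `study_id`, `sex`, `ethnicity`,
#'   `maternal_education`, `weight_status`, `region`, plus attributes
#'   `log` (named counts at each filtering step) and `missing_metadata`
#'   (character vector of unmatched participant ids).
#' @export
build_analysis_dataset <- function(person_summaries, metadata,
                                   age_range = c(5, 18)) {
  empty <- data.frame(participant_id = character(0), age = numeric(0),
                      vpa_min = numeric(0), mpa_min = numeric(0),
                      wear_min = numeric(0), sed_min = numeric(0),
                      study_id = character(0), sex = character(0),
                      ethnicity = character(0),
                      maternal_education = character(0),
                      weight_status = character(0), region = character(0))
  n_in <- if (is.null(person_summaries)) 0L else nrow(person_summaries)
  if (n_in == 0L) {
    attr(empty, "log") <- c(summaries_in = 0L, first_measurement = 0L,
                            with_metadata = 0L, in_age_range = 0L)
    attr(empty, "missing_metadata") <- character(0)
    return(empty)
  }
  ps <- person_summaries[order(person_summaries$participant_id,
                               person_summaries$measurement_date), ]
  ps <- ps[!duplicated(ps$participant_id), ]          # first measurement only
  n_first <- nrow(ps)

  miss <- setdiff(ps$participant_id, metadata$participant_id)
  m <- merge(ps, metadata, by = "participant_id")
  n_meta <- nrow(m)
  keep <- m$age >= age_range[1L] & m$age <= age_range[2L]
  m <- m[keep, ]
  out <- data.frame(participant_id = m$participant_id, age = m$age,
                    vpa_min = m$mean_vpa_minutes, mpa_min = m$mean_mpa_minutes,
                    wear_min = m$mean_wear_minutes,
                    sed_min = m$mean_sedentary_minutes,
                    study_id = m$study_id, sex = m$sex,
                    ethnicity = m$ethnicity,
                    maternal_education = m$maternal_education,
                    weight_status = m$weight_status, region = m$region)
  rownames(out) <- NULL
  attr(out, "log") <- c(summaries_in = n_in, first_measurement = n_first,
                        with_metadata = n_meta, in_age_range = nrow(out))
  attr(out, "missing_metadata") <- miss
  out
}

#' Cap values above the sample 99th percentile
#'
#' Values above the 99th percentile are set to the 99th percentile value to
#' remove extreme observations; all other values are unchanged. The
#' percentile is computed by linear interpolation of order statistics
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector (at least 2 finite values).
#' @param probs percentile to cap at, default 0.99.
#' @return The capped vector, with attribute `threshold`.
#' @export
winsorize_p99 <- function(values, probs = 0.99) {
  if (sum(is.finite(values)) < 2L)
    stop("winsorization needs at least 2 finite values")
  q <- stats::quantile(values, probs, na.rm = TRUE, names = FALSE, type = 7)
  out <- pmin(values, q)
  attr(out, "threshold") <- q
  out
}

#' Natural-log transform with an additive zero offset
#'
#' @param values non-negative numeric vector.
#' @param zero_offset non-negative constant added before taking logs; must be
#'   positive when any value is zero.
#' @return `log(values + zero_offset)`.
#' @export
log_transform <- function(values, zero_offset = 0.5) {
  if (any(values < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  if (zero_offset < 0) stop("`zero_offset` must be non-negative")
  if (zero_offset == 0 && any(values == 0, na.rm = TRUE))
    stop("zero values present: set a positive `zero_offset` (e.g. 0.5)")
  log(values + zero_offset)
}

# shared model-frame construction for all age models
model_frame <- function(dataset, outcome = c("vpa", "mpa"),
                        adjust_for_mpa = FALSE, winsorize = (outcome == "vpa"),
                        zero_offset = 0.5) {
  outcome <- match.arg(outcome)
  y <- if (outcome == "vpa") dataset$vpa_min else dataset$mpa_min
  if (winsorize) y <- winsorize_p99(y)
  df <- data.frame(logy = log_transform(as.numeric(y), zero_offset),
                   age = dataset$age, wear = dataset$wear_min,
                   study = factor(dataset$study_id))
  if (adjust_for_mpa)
    df$log_mpa <- log_transform(dataset$mpa_min, zero_offset)
  df
}

wald_from_lm <- function(fit, term, conf_level = 0.95) {
  cf <- summary(fit)$coefficients
  if (!term %in% rownames(cf)) stop("term `", term, "` not estimable")
  beta <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(beta = beta, se = se,
       ci = c(beta - zq * se, beta + zq * se),
       p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Fit the log-linear geometric-mean-ratio age model
#'
#' Ordinary least squares of log(outcome + offset) on age, adjusted for mean
#' daily monitor wear time and study (fixed-effect indicators), optionally
#' additionally adjusted for log moderate-intensity minutes. The age
#' coefficient is back-transformed to the per-year ratio of geometric means;
#' confidence limits and p-values use the normal approximation.
#'
#' @param dataset an analysis dataset from [build_analysis_dataset()].
#' @param outcome `"vpa"` or `"mpa"`.
#' @param adjust_for_mpa also adjust for log MPA (used for the VPA model).
#' @param winsorize cap the outcome at its 99th percentile first (default:
#'   yes for VPA, no for MPA, mirroring the published analysis).
#' @param zero_offset additive offset before the log (see [log_transform()]).
#' @param conf_level confidence level.
#' @return list of class `vt_fit`: `beta_age`, `se_beta`, `ratio`,
#'   `ratio_ci`, `pct_change`, `pct_ci`, `p_value`, `n`, `outcome`,
#'   `covariates_used`, and the underlying `lm` object in `$fit`.
#' @export
fit_age_model <- function(dataset, outcome = c("vpa", "mpa"),
                          adjust_for_mpa = FALSE,
                          winsorize = NULL, zero_offset = 0.5,
                          conf_level = 0.95) {
  outcome <- match.arg(outcome)
  if (is.null(winsorize)) winsorize <- outcome == "vpa"
  if (length(unique(dataset$age)) < 2L)
    stop("cannot fit an age model with a single distinct age")
  df <- model_frame(dataset, outcome, adjust_for_mpa, winsorize, zero_offset)
  rhs <- c("age", "wear", if (nlevels(df$study) > 1L) "study",
           if (adjust_for_mpa) "log_mpa")
  fit <- stats::lm(stats::reformulate(rhs, response = "logy"), data = df)
  w <- wald_from_lm(fit, "age", conf_level)
  bt <- ratio_and_pct(w$beta, w$se, conf_level)
  structure(list(beta_age = w$beta, se_beta = w$se, ratio = bt$ratio,
                 ratio_ci = bt$ratio_ci, pct_change = bt$pct_change,
                 pct_ci = bt$pct_ci, p_value = w$p, n = nrow(df),
                 outcome = outcome, covariates_used = rhs, fit = fit),
            class = "vt_fit")
}

#' @export
print.vt_fit <- function(x, ...) {
  cat(sprintf(
    "<vt_fit> %s ~ age (n=%d): ratio %.3f (%.3f, %.3f), %+.1f%%/y, p=%.3g\n",
    toupper(x$outcome), x$n, x$ratio, x$ratio_ci[1L], x$ratio_ci[2L],
    x$pct_change, x$p_value))
  invisible(x)
}

#' Back-transform a log-scale age coefficient
#'
#' @param beta coefficient of age on the log(min/day) scale.
#' @param se standard error of `beta` (>= 0).
#' @param conf_level confidence level.
#' @return list with `ratio` (`exp(beta)`, the per-year geometric-mean
#'   ratio), `ratio_ci`, `pct_change` (`(ratio - 1) * 100`, signed) and
#'   `pct_ci`.
#' @examples
#' ratio_and_pct(log(0.931), 0)$pct_change  # -6.9% per year
#' @export
ratio_and_pct <- function(beta, se, conf_level = 0.95) {
  if (se < 0) stop("`se` must be non-negative")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ratio <- exp(beta)
  ci <- exp(c(beta - zq * se, beta + zq * se))
  list(ratio = ratio, ratio_ci = ci,
       pct_change = (ratio - 1) * 100, pct_ci = (ci - 1) * 100)
}

# reference levels mirroring the published stratified tables
vt_reference_levels <- c(sex = "male", ethnicity = "white",
                         maternal_education = "high school",
                         weight_status = "normal", region = "UK")

#' Test an age-by-subgroup interaction
#'
#' Augments the VPA age model with age-by-level interaction terms for one
#' moderator, reports a Wald p-value per non-reference level plus a joint
#' Wald test, and — when any of these is significant at `alpha` — refits the
#' model within each level (stratified fits). Reference levels are male,
#' white, high school, normal weight and UK.
#'
#' Note that when the moderator is `region` and studies are nested within
#' regions, the region main effects are aliased with the study indicators;
#' `lm` drops the aliased columns and the interaction terms remain estimable.
#'
#' @param dataset an analysis dataset from [build_analysis_dataset()].
#' @param moderator one of `sex`, `ethnicity`, `maternal_education`,
#'   `weight_status`, `region`.
#' @param outcome outcome variable, default `"vpa"`.
#' @param alpha significance threshold for proceeding to stratified fits.
#' @inheritParams fit_age_model
#' @return list of class `vt_interaction`: `moderator`, `reference`,
#'   `per_level_p` (named, non-reference levels), `joint_p`, `joint_df`,
#'   `significant`, `stratified` (named list of [fit_age_model()] results, or
#'   `NULL` when not significant).
#' @export
test_interaction <- function(dataset,
                             moderator = c("sex", "ethnicity",
                                           "maternal_education",
                                           "weight_status", "region"),
                             outcome = "vpa", alpha = 0.05,
                             winsorize = NULL, zero_offset = 0.5) {
  moderator <- match.arg(moderator)
  if (is.null(winsorize)) winsorize <- outcome == "vpa"
  mv <- factor(dataset[[moderator]])
  if (nlevels(mv) < 2L)
    stop("moderator `", moderator, "` has a single level")
  ref <- vt_reference_levels[[moderator]]
  if (ref %in% levels(mv)) mv <- stats::relevel(mv, ref)

  df <- model_frame(dataset, outcome, FALSE, winsorize, zero_offset)
  df$mod <- mv
  rhs <- c("age * mod", "wear", if (nlevels(df$study) > 1L) "study")
  fit <- stats::lm(stats::reformulate(rhs, response = "logy"), data = df)

  cf <- stats::coef(fit)
  int_terms <- grep("^age:mod", names(cf), value = TRUE)
  est <- int_terms[!is.na(cf[int_terms])]
  if (!length(est)) stop("no estimable interaction terms")
  sm <- summary(fit)$coefficients
  per_level_p <- 2 * stats::pnorm(-abs(sm[est, "Estimate"] / sm[est, "Std. Error"]))
  names(per_level_p) <- sub("^age:mod", "", est)

  V <- stats::vcov(fit)[est, est, drop = FALSE]
  b <- cf[est]
  W <- drop(t(b) %*% solve(V, b))
  joint_df <- length(est)
  joint_p <- stats::pchisq(W, df = joint_df, lower.tail = FALSE)

  significant <- any(per_level_p < alpha) || joint_p < alpha
  stratified <- NULL
  if (significant) {
    stratified <- lapply(levels(mv), function(lv) {
      sub <- dataset[mv == lv, , drop = FALSE]
      if (length(unique(sub$age)) < 2L) return(NULL)
      fit_age_model(sub, outcome, winsorize = winsorize,
                    zero_offset = zero_offset)
    })
    names(stratified) <- levels(mv)
  }
  structure(list(moderator = moderator, reference = levels(mv)[1L],
                 per_level_p = per_level_p, joint_p = joint_p,
                 joint_df = joint_df, joint_stat = W,
                 significant = significant, stratified = stratified,
                 fit = fit),
            class = "vt_interaction")
}

#' @export
print.vt_interaction <- function(x, ...) {
  cat(sprintf("<vt_interaction> age x %s (ref %s): joint p=%.3g on %d df%s\n",
              x$moderator, x$reference, x$joint_p, x$joint_df,
              if (x$significant) ", stratified fits attached" else ""))
  invisible(x)
}

#' Check log-linearity with 2-year age bands
#'
#' Refits the age model with 2-year age-band indicators
#' (`[5,7), [7,9), ..., [17,18]`) replacing linear age and returns the
#' differences between consecutive band coefficients. Under a log-linear
#' trend every difference between full-width adjacent bands is about
#' `2 * log(ratio)`.
#'
#' @param dataset an analysis dataset.
#' @param outcome `"vpa"` or `"mpa"`.
#' @inheritParams fit_age_model
#' @param band_breaks left edges plus final right edge of the bands.
#' @return list of class `vt_bands` with `coefficients` (per band, first band
#'   fixed at 0; `NA` for empty bands), `differences` (named
#'   `band2-band1`, ...), `band_n` and the `lm` fit.
#' @export
age_band_check <- function(dataset, outcome = c("vpa", "mpa"),
                           winsorize = NULL, zero_offset = 0.5,
                           band_breaks = c(5, 7, 9, 11, 13, 15, 17, 18)) {
  outcome <- match.arg(outcome)
  if (is.null(winsorize)) winsorize <- outcome == "vpa"
  df <- model_frame(dataset, outcome, FALSE, winsorize, zero_offset)
  band <- cut(dataset$age, breaks = band_breaks, right = FALSE,
              include.lowest = TRUE)
  band_n <- table(band)
  if (sum(band_n > 0) < 2L) stop("need at least 2 populated age bands")
  df$band <- band
  rhs <- c("band", "wear", if (nlevels(df$study) > 1L) "study")
  fit <- stats::lm(stats::reformulate(rhs, response = "logy"), data = df)
  cf <- stats::coef(fit)
  lv <- levels(band)
  co <- c(0, cf[paste0("band", lv[-1L])])
  names(co) <- lv
  co[band_n == 0L] <- NA_real_
  diffs <- diff(co)
  names(diffs) <- paste(lv[-1L], "-", lv[-length(lv)])
  structure(list(coefficients = co, differences = diffs,
                 band_n = band_n, fit = fit),
            class = "vt_bands")
}

#' Leave-one-study-out sensitivity analysis
#'
#' Refits the age model once per omitted study and flags refits whose age
#' coefficient changes sign relative to the full fit (the published analysis
#' used this to show one study drove the UK's positive age trend).
#'
#' @param dataset an analysis dataset with at least 2 studies.
#' @param outcome `"vpa"` or `"mpa"`.
#' @inheritParams fit_age_model
#' @return list of class `vt_loso`: `full` ([fit_age_model()] result),
#'   `by_study` (named list, one fit per omitted study) and `sign_flip`
#'   (named logical).
#' @export
leave_one_study_out <- function(dataset, outcome = c("vpa", "mpa"),
                                winsorize = NULL, zero_offset = 0.5) {
  outcome <- match.arg(outcome)
  studies <- unique(dataset$study_id)
  if (length(studies) < 2L) stop("leave-one-study-out needs at least 2 studies")
  full <- fit_age_model(dataset, outcome, winsorize = winsorize,
                        zero_offset = zero_offset)
  by_study <- lapply(studies, function(s)
    fit_age_model(dataset[dataset$study_id != s, , drop = FALSE], outcome,
                  winsorize = winsorize, zero_offset = zero_offset))
  names(by_study) <- studies
  flips <- vapply(by_study, function(f) sign(f$beta_age) != sign(full$beta_age),
                  logical(1))
  structure(list(full = full, by_study = by_study, sign_flip = flips),
            class = "vt_loso")
}
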