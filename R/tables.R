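fmt_mean_sd <- function(x, digits = 1)
  sprintf("%.*f (%.*f)", digits, mean(x), digits, stats::sd(x))

fmt_median_iqr <- function(x, digits = 1) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.*f [%.*f, %.*f]", digits, q[2L], digits, q[1L], digits, q[3L])
}

fmt_n_pct <- function(k, n) sprintf("%d (%.1f)", k, 100 * k / n)

#' Descriptive characteristics table
#'
#' One row per descriptive quantity in the layout of the published
#' characteristics table: N (%) per category of sex, region, weight status,
#' ethnicity and maternal education; mean (SD) age, wear and sedentary time;
#' median \[IQR\] daily VPA and MPA minutes.
#'
#' @param dataset an analysis dataset from [build_analysis_dataset()].
#' @return data.frame with columns `variable`, `level`, `value`.
#' @export
descriptives_table <- function(dataset) {
  n <- nrow(dataset)
  rows <- list(data.frame(variable = "N", level = "", value = as.character(n)))
  add <- function(variable, level, value)
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable,
                                             level = level, value = value)
  for (v in c("sex", "region", "weight_status", "ethnicity",
              "maternal_education")) {
    tab <- table(dataset[[v]])
    for (lv in names(tab)) add(v, lv, fmt_n_pct(as.integer(tab[[lv]]), n))
  }
  add("age_years", "mean_sd", fmt_mean_sd(dataset$age, 2))
  add("vpa_min_day", "median_iqr", fmt_median_iqr(dataset$vpa_min))
  add("mpa_min_day", "median_iqr", fmt_median_iqr(dataset$mpa_min))
  add("wear_min_day", "mean_sd", fmt_mean_sd(dataset$wear_min))
  add("sedentary_min_day", "mean_sd", fmt_mean_sd(dataset$sed_min))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_row <- function(fit, label) {
  data.frame(model = label, n = fit$n,
             beta = fit$beta_age, se = fit$se_beta,
             ratio = round(fit$ratio, 3),
             ci_low = round(fit$ratio_ci[1L], 3),
             ci_high = round(fit$ratio_ci[2L], 3),
             pct = round(fit$pct_change, 1),
             pct_low = round(fit$pct_ci[1L], 1),
             pct_high = round(fit$pct_ci[2L], 1),
             p = fit$p_value)
}

#' Assemble the report tables for one analysis run
#'
#' Renders the three standard outputs: a descriptives table, a single/adjusted
#' model table (per-year ratios with 95% CI, percent change, and the 13-year
#' extrapolated change anchored at the 5.0-5.9 y baseline mean), and
#' stratified panels for each significant interaction. Ratios are printed at
#' 3 dp, percents at 1 dp and extrapolated changes at 2 dp.
#'
#' @param dataset an analysis dataset.
#' @param fits named list of [fit_age_model()] results (e.g. `vpa`, `mpa`,
#'   `vpa_adjusted`).
#' @param interactions optional named list of [test_interaction()] results.
#' @param years extrapolation horizon.
#' @return list of class `vt_report`: `descriptives`, `models`, `stratified`
#'   (possibly `NULL`), `baselines`.
#' @export
build_tables <- function(dataset, fits, interactions = NULL, years = 13) {
  desc <- descriptives_table(dataset)

  base <- list(vpa = baseline_summary(dataset, "vpa"),
               mpa = baseline_summary(dataset, "mpa"))
  model_rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    r <- fit_row(f, nm)
    b <- base[[f$outcome]]
    if (!is.null(b) && !grepl("adjusted", nm)) {
      r$baseline_mean <- round(b$mean, 2)
      r$baseline_sd <- round(b$sd, 2)
      r$extrapolated_change <- extrapolate(f$ratio, b$mean, years)$change_2dp
    } else {
      r$baseline_mean <- r$baseline_sd <- r$extrapolated_change <- NA_real_
    }
    r
  })
  models <- do.call(rbind, model_rows)

  strat <- NULL
  if (!is.null(interactions)) {
    panels <- list()
    for (nm in names(interactions)) {
      ia <- interactions[[nm]]
      if (!ia$significant || is.null(ia$stratified)) {
        message("interaction `", nm, "` not significant; panel omitted")
        next
      }
      for (lv in names(ia$stratified)) {
        f <- ia$stratified[[lv]]
        if (is.null(f)) next
        sub <- dataset[dataset[[nm]] == lv, , drop = FALSE]
        r <- fit_row(f, paste(nm, lv, sep = ":"))
        r$moderator <- nm; r$level <- lv
        r$interaction_joint_p <- ia$joint_p
        bs <- tryCatch(baseline_summary(sub, f$outcome), error = function(e) NULL)
        if (!is.null(bs) && bs$n >= 10) {
          r$baseline_mean <- round(bs$mean, 2)
          r$baseline_sd <- round(bs$sd, 2)
          r$extrapolated_change <- extrapolate(f$ratio, bs$mean, years)$change_2dp
        } else {
          r$baseline_mean <- r$baseline_sd <- r$extrapolated_change <- NA_real_
        }
        panels[[length(panels) + 1L]] <- r
      }
    }
    if (length(panels)) strat <- do.call(rbind, panels)
  }
  structure(list(descriptives = desc, models = models, stratified = strat,
                 baselines = base),
            class = "vt_report")
}

#' Write a report to CSV files
#'
#' @param report a [build_tables()] result.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(descriptives = file.path(out_dir, "table1_descriptives.csv"),
             models = file.path(out_dir, "table2_models.csv"))
  utils::write.csv(report$descriptives, paths[["descriptives"]], row.names = FALSE)
  utils::write.csv(report$models, paths[["models"]], row.names = FALSE)
  if (!is.null(report$stratified)) {
    paths[["stratified"]] <- file.path(out_dir, "table3_stratified.csv")
    utils::write.csv(report$stratified, paths[["stratified"]], row.names = FALSE)
  }
  invisible(paths)
}
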