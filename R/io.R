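#' Write epoch series to a long-format CSV
#'
#' Columns: `participant_id`, `timestamp` (ISO-8601, UTC), `counts`.
#'
#' @param series_list list of [epoch_series()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_epochs_csv <- function(series_list, path) {
  dt <- data.table::rbindlist(lapply(series_list, function(es)
    data.table::data.table(
      participant_id = es$participant_id,
      timestamp = format(epoch_times(es), "%Y-%m-%dT%H:%M:%SZ"),
      counts = es$counts)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read epoch series from a long-format CSV
#'
#' Inverse of [write_epochs_csv()]. Epoch length is inferred from the
#' timestamp grid of each participant; timestamps must be regular.
#'
#' @param path CSV with columns `participant_id`, `timestamp`, `counts`.
#' @return list of [epoch_series()], one per participant.
#' @export
read_epochs_csv <- function(path) {
  dt <- data.table::fread(path)
  req <- c("participant_id", "timestamp", "counts")
  if (!all(req %in% names(dt)))
    stop("epoch CSV must have columns: ", paste(req, collapse = ", "))
  out <- lapply(split(dt, by = "participant_id", keep.by = TRUE), function(d) {
    tt <- as.POSIXct(d$timestamp, tz = "UTC",
                     format = "%Y-%m-%dT%H:%M:%SZ")
    if (anyNA(tt)) tt <- as.POSIXct(d$timestamp, tz = "UTC")
    o <- order(tt)
    tt <- tt[o]
    step <- if (length(tt) > 1L) unique(diff(as.numeric(tt))) else 60
    if (length(step) != 1L)
      stop("irregular timestamp grid for participant ", d$participant_id[1L])
    epoch_series(d$participant_id[1L], tt[1L], d$counts[o], step)
  })
  unname(out)
}

#' Write and read participant metadata CSV
#'
#' @param participants metadata data.frame as produced by [generate_cohort()].
#' @param path file path.
#' @return Invisibly `path` (write) / the data.frame (read).
#' @export
write_metadata_csv <- function(participants, path) {
  data.table::fwrite(participants, path)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  df$measurement_date <- as.Date(df$measurement_date)
  df
}

#' Load a cohort configuration from YAML
#'
#' Any field of [cohort_config()] may appear in the file; omitted fields keep
#' their defaults. `study_labels` is given as a list of
#' `{study_id, region, weight}` records; `subgroup_mix` as named maps.
#'
#' @param path YAML file.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$study_labels))
    y$study_labels <- do.call(rbind, lapply(y$study_labels, as.data.frame))
  if (!is.null(y$subgroup_mix))
    y$subgroup_mix <- lapply(y$subgroup_mix, unlist)
  for (nm in c("baseline_vpa_mean", "baseline_mpa_mean",
               "annual_ratio_vpa", "annual_ratio_mpa"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(cohort_config, y)
}

#' Load processing parameters from YAML
#'
#' @param path YAML file with any fields of [processing_params()].
#' @return A [processing_params()].
#' @export
read_processing_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(processing_params, y)
}
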