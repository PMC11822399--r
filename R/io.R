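# Serialization: raw streams as line-delimited JSON (one object per line,
# one file per stream per participant), tabular outputs as RFC-4180 CSV with
# "" as the null token.

STREAM_SCHEMAS <- list(
  hr = c("ts", "bpm"),
  sleep = c("seg_id", "start", "end", "is_main", "efficiency"),
  stages = c("seg_id", "stage", "start", "end"),
  steps = c("date", "steps"),
  gps = c("ts", "lat", "lon", "accuracy"),
  taps = c("ts", "in_game"),
  msgs = c("ts", "channel", "direction"),
  power = c("ts", "state"),
  light = c("hour")
)

ndjson_write <- function(df, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(df))
    jsonlite::stream_out(df, con, verbose = FALSE, digits = NA)
  invisible(path)
}

ndjson_read <- function(path, required) {
  if (!file.size(path)) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(required)),
                                 required))
    return(df)
  }
  df <- tryCatch(
    jsonlite::stream_in(file(path), verbose = FALSE),
    error = function(e) stop(sprintf("malformed record in %s: %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing required column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df[, required, drop = FALSE]
}

#' Write a cohort's raw streams to a directory
#'
#' One line-delimited JSON file per stream per participant
#' (`<id>_<stream>.ndjson`), a `<id>_meta.json` per participant, and
#' `clinical.csv`, `baseline_dates.csv`, `ground_truth.csv` for the cohort.
#'
#' @param cohort list as returned by [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in cohort$bundles) {
    id <- b$participant_id
    meta <- list(participant_id = id,
                 baseline_date = format(b$baseline_date),
                 n_days = b$n_days, tz_offset_hrs = b$tz_offset_hrs)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
               file.path(dir, paste0(id, "_meta.json")))
    for (s in c("hr", "sleep", "stages", "gps", "taps", "msgs", "power")) {
      ndjson_write(b[[s]], file.path(dir, paste0(id, "_", s, ".ndjson")))
    }
    steps <- b$steps
    if (nrow(steps)) steps$date <- format(steps$date)
    ndjson_write(steps, file.path(dir, paste0(id, "_steps.ndjson")))
    ndjson_write(data.frame(hour = b$light_hours),
                 file.path(dir, paste0(id, "_light.ndjson")))
  }
  write_table(cohort$profiles, file.path(dir, "clinical.csv"))
  bd <- data.frame(
    participant_id = vapply(cohort$bundles, `[[`, "", "participant_id"),
    baseline_date = vapply(cohort$bundles,
                           function(b) format(b$baseline_date), ""),
    stringsAsFactors = FALSE)
  write_table(bd, file.path(dir, "baseline_dates.csv"))
  if (!is.null(cohort$truth)) {
    write_table(cohort$truth$participants, file.path(dir, "ground_truth.csv"))
    write_table(cohort$truth$effects, file.path(dir, "planted_effects.csv"))
  }
  invisible(dir)
}

#' Read a cohort of raw streams back from a directory
#'
#' Inverse of [write_cohort()]: `read_streams(write_cohort(x))` reproduces
#' the bundles and profiles. An empty directory yields an empty cohort with
#' a warning; a malformed record or missing column is an error naming the
#' file.
#'
#' @param dir directory written by [write_cohort()]
#' @return list with `bundles` and `profiles` (no ground truth — that stays
#'   with the generator output)
#' @export
read_streams <- function(dir) {
  metas <- sort(list.files(dir, pattern = "_meta\\.json$", full.names = TRUE))
  if (!length(metas)) {
    warning(sprintf("no participant streams found in %s: empty cohort", dir))
    return(list(bundles = list(), profiles = NULL))
  }
  bundles <- lapply(metas, function(mf) {
    meta <- jsonlite::fromJSON(mf)
    id <- meta$participant_id
    pth <- function(s) file.path(dir, paste0(id, "_", s, ".ndjson"))
    streams <- empty_streams()
    for (s in c("hr", "sleep", "stages", "gps", "taps", "msgs", "power")) {
      df <- ndjson_read(pth(s), STREAM_SCHEMAS[[s]])
      if (nrow(df)) streams[[s]] <- df else
        streams[[s]] <- streams[[s]]
    }
    st <- ndjson_read(pth("steps"), STREAM_SCHEMAS$steps)
    if (nrow(st)) {
      st$date <- as.Date(st$date)
      st$steps <- as.integer(st$steps)
      streams$steps <- st
    }
    lh <- ndjson_read(pth("light"), STREAM_SCHEMAS$light)
    streams$light_hours <- as.integer(lh$hour)
    new_sensor_bundle(id, as.Date(meta$baseline_date), meta$n_days,
                      meta$tz_offset_hrs, streams)
  })
  prof_path <- file.path(dir, "clinical.csv")
  profiles <- if (file.exists(prof_path)) read_table(prof_path) else NULL
  list(bundles = bundles, profiles = profiles)
}

#' Write / read a tabular output with "" as the null token
#'
#' @param df data.frame
#' @param path CSV path
#' @return the path (write) or the data.frame (read)
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
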