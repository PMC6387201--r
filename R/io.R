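# All on-disk formats are plain delimiter-separated text with a header row.
# Malformed rows are reported with their file line number (header = line 1).

read_checked_csv <- function(path, required, numeric_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("%s: malformed '%s' value at line %d", path, col,
                   bad[1] + 1L))
    df[[col]] <- v
  }
  df
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Read / write a measurement stream file
#'
#' Columns `timestamp,beacon_id,rssi_dbm`. On read, rows from beacons outside
#' the supplied roster are kept but reported with a warning (the localizer
#' ignores them later).
#'
#' @param path file path.
#' @param roster optional beacon roster to check ids against.
#' @return data.frame `timestamp,beacon_id,rssi_dbm`.
#' @export
read_measurements <- function(path, roster = NULL) {
  df <- read_checked_csv(path, c("timestamp", "beacon_id", "rssi_dbm"),
                         c("timestamp", "rssi_dbm"))
  if (any(df$timestamp < 0))
    stop(sprintf("%s: negative timestamp at line %d", path,
                 which(df$timestamp < 0)[1] + 1L))
  if (!is.null(roster)) {
    unknown <- setdiff(unique(df$beacon_id), roster)
    if (length(unknown) > 0)
      warning(sprintf("%s: measurements from beacon(s) not in roster: %s",
                      path, paste(unknown, collapse = ", ")))
  }
  df[, c("timestamp", "beacon_id", "rssi_dbm")]
}

#' @rdname read_measurements
#' @param measurements data.frame `timestamp,beacon_id,rssi_dbm`.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements[, c("timestamp", "beacon_id", "rssi_dbm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a fingerprint database file
#'
#' First column `room_label`, then one column per roster beacon (the header
#' carries the roster order). Values round-trip at full double precision.
#'
#' @param path file path.
#' @return A [fingerprint_db()].
#' @export
read_fingerprint_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "room_label")
    stop(sprintf("%s: first column must be 'room_label'", path))
  roster <- names(df)[-1]
  if (length(roster) == 0) stop(sprintf("%s: no beacon columns", path))
  means <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(means)) stop(sprintf("%s: non-numeric fingerprint value", path))
  rownames(means) <- df$room_label
  fingerprint_db(roster, means)
}

#' @rdname read_fingerprint_db
#' @param db a [fingerprint_db()].
#' @export
write_fingerprint_db <- function(db, path) {
  stopifnot(inherits(db, "fingerprint_db"))
  header <- paste(c("room_label", db$roster), collapse = ",")
  rows <- vapply(seq_len(nrow(db$means)), function(i)
    paste(c(rownames(db$means)[i], fmt_num(db$means[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write a room-transition record file
#'
#' Columns `user_id,room,timestamp`. On read, each subject's timestamps must
#' be strictly increasing and consecutive rows must change room; violations
#' are rejected with their line number.
#'
#' @param path file path.
#' @return data.frame `user_id,room,timestamp`.
#' @export
read_transitions <- function(path) {
  df <- read_checked_csv(path, c("user_id", "room", "timestamp"), "timestamp")
  df$user_id <- as.character(df$user_id)
  for (u in unique(df$user_id)) {
    idx <- which(df$user_id == u)
    tt <- df$timestamp[idx]
    if (length(tt) > 1) {
      bad <- which(diff(tt) <= 0)
      if (length(bad) > 0)
        stop(sprintf("%s: non-increasing timestamp for user '%s' at line %d",
                     path, u, idx[bad[1] + 1L] + 1L))
      same <- which(df$room[idx][-1] == df$room[idx][-length(idx)])
      if (length(same) > 0)
        stop(sprintf("%s: repeated room for user '%s' at line %d",
                     path, u, idx[same[1] + 1L] + 1L))
    }
  }
  df[, c("user_id", "room", "timestamp")]
}

#' @rdname read_transitions
#' @param transitions data.frame `user_id,room,timestamp`.
#' @export
write_transitions <- function(transitions, path) {
  utils::write.csv(transitions[, c("user_id", "room", "timestamp")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a frailty label file
#'
#' Columns `user_id,frailty_status` with status in
#' `{non-frail, pre-frail, frail}`.
#'
#' @param path file path.
#' @return data.frame `user_id,frailty_status`.
#' @export
read_labels <- function(path) {
  df <- read_checked_csv(path, c("user_id", "frailty_status"), character(0))
  bad <- which(!df$frailty_status %in% c("non-frail", "pre-frail", "frail"))
  if (length(bad) > 0)
    stop(sprintf("%s: unknown frailty status '%s' at line %d", path,
                 df$frailty_status[bad[1]], bad[1] + 1L))
  df[, c("user_id", "frailty_status")]
}

#' @rdname read_labels
#' @param labels data.frame `user_id,frailty_status`.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[, c("user_id", "frailty_status")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a feature table file
#'
#' The nine segment features plus `user_id` and `label`, as written by
#' [extract_features()].
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_features <- function(path) {
  feat_cols <- c("n_transitions", "mean_duration", "sd_duration", "n_fast",
                 "n_slow", "pct_fast", "pct_slow", "norm_fast", "norm_slow")
  read_checked_csv(path, c("user_id", feat_cols, "label"), feat_cols)
}

#' @rdname read_features
#' @param features data.frame from [extract_features()].
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a plain-text evaluation report
#'
#' @param eval a `frailty_eval` from [cross_validate()].
#' @param path file path.
#' @export
write_report <- function(eval, path) {
  stopifnot(inherits(eval, "frailty_eval"))
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(eval)
  if (nrow(eval$metrics$breakdown) > 0) {
    cat("\nmisclassification breakdown:\n")
    print(eval$metrics$breakdown, row.names = FALSE)
  }
  sink()
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable constant of the pipeline in one serialisable list:
#' the online-localization constants, the segmentation and feature cutoffs,
#' the classifier choice and the seed.
#'
#' @param window,vote_length,vote_threshold,outside_timeout,impute see
#'   [localization_config()].
#' @param segment_threshold segmentation threshold in seconds.
#' @param fast_cutoff,slow_cutoff dwell bounds in seconds.
#' @param classifier classifier spec for [cross_validate()].
#' @param folds cross-validation folds.
#' @param seed integer seed for every stochastic stage.
#' @param users_per_class simulated subjects per frailty class.
#' @param hours_per_user simulated hours of behaviour per subject.
#' @return list of class `run_config`.
#' @export
run_config <- function(window = 10, vote_length = 800, vote_threshold = 0.8,
                       outside_timeout = 4, impute = -100,
                       segment_threshold = 1800, fast_cutoff = 15,
                       slow_cutoff = 600, classifier = "rf", folds = 10,
                       seed = 1, users_per_class = 5, hours_per_user = 12) {
  structure(list(window = window, vote_length = vote_length,
                 vote_threshold = vote_threshold,
                 outside_timeout = outside_timeout, impute = impute,
                 segment_threshold = segment_threshold,
                 fast_cutoff = fast_cutoff, slow_cutoff = slow_cutoff,
                 classifier = classifier, folds = folds, seed = seed,
                 users_per_class = users_per_class,
                 hours_per_user = hours_per_user),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
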