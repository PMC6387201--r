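#' Build the RSSI fingerprint of one room
#'
#' During setup a nurse walks the room for `duration` seconds while the phone
#' scans every beacon. Samples are binned per beacon into one-second half-open
#' bins `[t, t+1)`; each bin contributes its within-bin mean, and the
#' fingerprint entry for a beacon is the mean of its bin means. Bins with no
#' sample are skipped; a beacon heard in fewer than half of the bins makes the
#' walk unreliable and the whole walk is rejected, as is a beacon never heard
#' at all.
#'
#' @param measurements data.frame `timestamp,beacon_id,rssi_dbm` confined to
#'   one room. Timestamps may be epoch or 0-based seconds.
#' @param roster character vector of the M beacon ids of the house, in
#'   database order.
#' @param duration training duration in seconds (default 30).
#' @return Named numeric vector of length M: mean dBm per beacon.
#' @export
build_room_fingerprint <- function(measurements, roster, duration = 30) {
  stopifnot(length(roster) >= 1,
            all(c("timestamp", "beacon_id", "rssi_dbm") %in% names(measurements)))
  if (nrow(measurements) == 0L) stop("no measurements in training walk")
  t0 <- min(measurements$timestamp)
  if (max(measurements$timestamp) - t0 < duration - 1)
    stop(sprintf("training walk spans %.1f s, need %g s",
                 max(measurements$timestamp) - t0, duration))
  bin <- floor(measurements$timestamp - t0)
  keep <- bin < duration
  m <- measurements[keep, , drop = FALSE]
  bin <- bin[keep]
  out <- stats::setNames(numeric(length(roster)), roster)
  n_bins <- floor(duration)
  for (j in seq_along(roster)) {
    sel <- m$beacon_id == roster[j]
    if (!any(sel))
      stop(sprintf("beacon '%s' was never heard during the training walk",
                   roster[j]))
    bin_means <- tapply(m$rssi_dbm[sel], bin[sel], mean)
    if (length(bin_means) < n_bins / 2)
      stop(sprintf(
        "beacon '%s' heard in only %d of %d one-second bins; walk rejected",
        roster[j], length(bin_means), n_bins))
    out[j] <- mean(bin_means)
  }
  out
}

#' Fingerprint database constructor
#'
#' @param roster ordered character vector of the M beacon ids.
#' @param means numeric matrix, one row per room (rownames = room labels, in
#'   insertion order), one column per beacon.
#' @return An object of class `fingerprint_db`.
#' @export
fingerprint_db <- function(roster, means) {
  stopifnot(is.matrix(means), ncol(means) == length(roster),
            !is.null(rownames(means)), length(roster) >= 1)
  if (anyDuplicated(rownames(means))) stop("room labels must be unique")
  colnames(means) <- roster
  structure(list(roster = as.character(roster), means = means),
            class = "fingerprint_db")
}

#' @export
print.fingerprint_db <- function(x, ...) {
  cat(sprintf("fingerprint database: %d rooms x %d beacons (dBm)\n",
              nrow(x$means), length(x$roster)))
  print(round(x$means, 1))
  invisible(x)
}

#' Build a fingerprint database from per-room training walks
#'
#' @param walks named list: room label -> measurement data.frame (the order of
#'   the list fixes room insertion order, which breaks nearest-room ties).
#' @param roster ordered beacon ids.
#' @param duration per-room training duration in seconds.
#' @return A [fingerprint_db()].
#' @export
build_fingerprint_db <- function(walks, roster, duration = 30) {
  stopifnot(is.list(walks), length(walks) >= 1, !is.null(names(walks)))
  means <- t(vapply(walks, build_room_fingerprint, numeric(length(roster)),
                    roster = roster, duration = duration))
  rownames(means) <- names(walks)
  fingerprint_db(roster, means)
}

#' Validate a training walk with a step detector
#'
#' A step event fires whenever the deviation of the acceleration magnitude
#' from gravity crosses `step_threshold` upward, with a refractory period
#' suppressing re-fires. The walk is valid only if every one of the six
#' consecutive 5-second windows of the 30-second walk contains at least one
#' step: a nurse who stops walking (or never moves) must redo the room.
#'
#' @param accel data.frame `time,magnitude` covering `[0, total)` seconds
#'   (m/s^2 total acceleration).
#' @param step_threshold deviation from gravity that counts as a step, m/s^2.
#' @param refractory minimum seconds between step events.
#' @param total walk duration in seconds.
#' @param window step-check window in seconds.
#' @param gravity reference gravity, m/s^2.
#' @return `TRUE` if every window holds a step, else `FALSE`.
#' @export
validate_training_walk <- function(accel, step_threshold = 1.5,
                                   refractory = 0.3, total = 30, window = 5,
                                   gravity = 9.81) {
  if (is.null(accel) || nrow(accel) == 0L) return(FALSE)
  stopifnot(all(c("time", "magnitude") %in% names(accel)))
  o <- order(accel$time)
  tt <- accel$time[o]
  dev <- abs(accel$magnitude[o] - gravity)
  above <- dev > step_threshold
  # upward crossings
  cross <- which(above & !c(FALSE, above[-length(above)]))
  step_times <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (tt[i] - last >= refractory) {
      step_times <- c(step_times, tt[i])
      last <- tt[i]
    }
  }
  if (length(step_times) == 0L) return(FALSE)
  starts <- seq(0, total - window, by = window)
  all(vapply(starts, function(s)
    any(step_times >= s & step_times < s + window), logical(1)))
}
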