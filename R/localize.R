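#' Two-sigma filtered mean of a sliding window
#'
#' Computes the window mean and population standard deviation s, discards
#' values whose absolute deviation from the mean strictly exceeds 2s, and
#' returns the mean of the survivors. With s = 0 (all values equal), or in the
#' guarded case that nothing survives, the plain mean is returned.
#'
#' @param values numeric vector of recent dBm readings (non-empty).
#' @return Filtered mean in dBm.
#' @export
filtered_mean <- function(values) {
  if (length(values) == 0L) stop("empty window")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) return(m)
  keep <- abs(values - m) <= 2 * s
  if (!any(keep)) return(m)
  mean(values[keep])
}

#' Assemble the filtered measurement vector over the beacon roster
#'
#' @param windows named list of numeric vectors (recent readings per beacon).
#' @param roster ordered beacon ids defining the vector layout.
#' @param impute dBm sentinel for beacons with an empty window; the default
#'   sits below the practical BLE reception floor so silence reads as maximal
#'   distance.
#' @return Numeric vector of length M.
#' @export
assemble_filtered_vector <- function(windows, roster, impute = -100) {
  vapply(roster, function(b) {
    w <- windows[[b]]
    if (is.null(w) || length(w) == 0L) impute else filtered_mean(w)
  }, numeric(1))
}

#' Instantaneous nearest-fingerprint room estimate
#'
#' Returns the room whose stored fingerprint minimises the Euclidean distance
#' to the current filtered vector; ties break by database insertion order.
#'
#' @param current numeric vector of length M (filtered dBm per beacon).
#' @param db a [fingerprint_db()].
#' @return Room label.
#' @export
instant_room <- function(current, db) {
  stopifnot(inherits(db, "fingerprint_db"))
  if (length(current) != length(db$roster))
    stop(sprintf("vector length %d does not match roster length %d",
                 length(current), length(db$roster)))
  d2 <- rowSums(sweep(db$means, 2, current)^2)
  rownames(db$means)[which.min(d2)]
}

#' Majority-vote smoothing over recent room estimates
#'
#' The final room only changes when one room's count strictly exceeds
#' `threshold * capacity` in a full buffer of the most recent instantaneous
#' estimates; otherwise (including before the buffer first fills) the previous
#' final room is retained.
#'
#' @param estimates character vector of recent instantaneous room labels,
#'   oldest first (length <= capacity).
#' @param capacity the vote-window length L.
#' @param previous the current final room (returned when no room dominates).
#' @param threshold dominance fraction (default 0.8).
#' @param rooms room labels in database insertion order, used to break count
#'   ties deterministically; defaults to first appearance order.
#' @return Room label, or `previous`.
#' @export
vote_room <- function(estimates, capacity, previous = "Unknown",
                      threshold = 0.8, rooms = NULL) {
  stopifnot(capacity >= 1, threshold > 0, threshold <= 1)
  if (length(estimates) < capacity) return(previous)
  if (is.null(rooms)) rooms <- unique(estimates)
  counts <- vapply(rooms, function(r) sum(estimates == r), integer(1))
  if (max(counts) > threshold * capacity) rooms[which.max(counts)] else previous
}

#' Outside-the-house test
#'
#' The user is considered outside when no roster beacon has been heard for
#' strictly more than `timeout` seconds.
#'
#' @param last_heard numeric vector of the newest timestamp per roster beacon
#'   (`-Inf` or `NA` for beacons never heard).
#' @param now current time in seconds.
#' @param timeout seconds of collective silence (default 4).
#' @return `TRUE` if outside.
#' @export
is_outside <- function(last_heard, now, timeout = 4) {
  last_heard[is.na(last_heard)] <- -Inf
  newest <- max(last_heard)
  if (!is.finite(newest)) return(TRUE)
  (now - newest) > timeout
}

#' Localization configuration
#'
#' Collects the online-phase constants in one place.
#'
#' @param window per-beacon sliding-window length W in samples.
#' @param vote_length vote-window length L in time instants.
#' @param vote_threshold dominance fraction for a final room change.
#' @param outside_timeout seconds of beacon silence before Outside.
#' @param impute dBm sentinel for silent beacons.
#' @return A list of class `localization_config`.
#' @export
localization_config <- function(window = 10, vote_length = 800,
                                vote_threshold = 0.8, outside_timeout = 4,
                                impute = -100) {
  stopifnot(window >= 1, vote_length >= 1,
            vote_threshold > 0, vote_threshold <= 1, outside_timeout > 0)
  structure(list(window = as.integer(window),
                 vote_length = as.integer(vote_length),
                 vote_threshold = vote_threshold,
                 outside_timeout = outside_timeout, impute = impute),
            class = "localization_config")
}

#' Convert an online RSSI stream into room transitions
#'
#' Replays the stream one measurement at a time (a time instant is the arrival
#' of any measurement): the arriving beacon's window is updated, the filtered
#' vector re-assembled, the instantaneous nearest-fingerprint room pushed into
#' the vote buffer, and the smoothed final room re-evaluated. A transition
#' record is emitted whenever the final room changes. Collective beacon
#' silence longer than the outside timeout emits an `Outside` transition
#' (timestamped at silence start + timeout); re-entry clears all windows and
#' the vote buffer, so the state is re-established from scratch.
#'
#' @param measurements data.frame `timestamp,beacon_id,rssi_dbm`, time-ordered.
#'   Measurements from beacons not in the roster are ignored with one warning.
#' @param db a [fingerprint_db()].
#' @param config a [localization_config()].
#' @param user_id identifier written into the transition records.
#' @return data.frame `user_id,room,timestamp`, one row per final-room change
#'   (never two consecutive identical labels).
#' @export
process_stream <- function(measurements, db, config = localization_config(),
                           user_id = "u1") {
  stopifnot(inherits(db, "fingerprint_db"),
            inherits(config, "localization_config"))
  empty <- data.frame(user_id = character(0), room = character(0),
                      timestamp = numeric(0), stringsAsFactors = FALSE)
  if (is.null(measurements) || nrow(measurements) == 0L) return(empty)
  stopifnot(all(c("timestamp", "beacon_id", "rssi_dbm") %in% names(measurements)))
  if (is.unsorted(measurements$timestamp)) stop("measurements must be time-ordered")

  roster <- db$roster
  M <- length(roster)
  rooms <- rownames(db$means)
  R <- length(rooms)
  fp <- db$means
  fp2 <- rowSums(fp^2)
  W <- config$window
  L <- config$vote_length
  thr <- config$vote_threshold * L

  bidx <- match(measurements$beacon_id, roster)
  if (anyNA(bidx)) {
    unknown <- unique(measurements$beacon_id[is.na(bidx)])
    warning(sprintf("ignoring measurements from unknown beacon(s): %s",
                    paste(unknown, collapse = ", ")))
  }

  windows <- vector("list", M)
  filtered <- rep(config$impute, M)
  last_heard <- rep(-Inf, M)
  votebuf <- integer(L)    # 0 = empty slot
  vcount <- integer(R)
  vpos <- 1L; vfill <- 0L
  current <- "Unknown"

  out_room <- character(64); out_time <- numeric(64); n_out <- 0L
  emit <- function(room, t) {
    n_out <<- n_out + 1L
    if (n_out > length(out_room)) {
      out_room <<- c(out_room, character(length(out_room)))
      out_time <<- c(out_time, numeric(length(out_time)))
    }
    out_room[n_out] <<- room
    out_time[n_out] <<- t
  }

  for (i in seq_len(nrow(measurements))) {
    b <- bidx[i]
    if (is.na(b)) next
    t <- measurements$timestamp[i]

    # outside detection against the silence preceding this arrival
    newest <- max(last_heard)
    if (is.finite(newest) && (t - newest) > config$outside_timeout &&
        current != "Outside") {
      emit("Outside", newest + config$outside_timeout)
      current <- "Outside"
      windows <- vector("list", M)
      filtered <- rep(config$impute, M)
      votebuf <- integer(L); vcount <- integer(R); vpos <- 1L; vfill <- 0L
    }

    last_heard[b] <- t
    w <- windows[[b]]
    w <- if (length(w) >= W) c(w[-1L], measurements$rssi_dbm[i])
         else c(w, measurements$rssi_dbm[i])
    windows[[b]] <- w
    filtered[b] <- filtered_mean(w)

    est <- which.min(fp2 - 2 * drop(fp %*% filtered))

    old <- votebuf[vpos]
    if (old > 0L) vcount[old] <- vcount[old] - 1L
    votebuf[vpos] <- est
    vcount[est] <- vcount[est] + 1L
    vpos <- if (vpos == L) 1L else vpos + 1L
    if (vfill < L) vfill <- vfill + 1L

    if (vfill == L) {
      mx <- max(vcount)
      if (mx > thr) {
        winner <- rooms[which.max(vcount)]
        if (winner != current) {
          emit(winner, t)
          current <- winner
        }
      }
    }
  }
  data.frame(user_id = rep(user_id, n_out), room = out_room[seq_len(n_out)],
             timestamp = out_time[seq_len(n_out)], stringsAsFactors = FALSE)
}

#' Room-estimation accuracy over an evaluation grid
#'
#' For every grid position and heading a stationary dwell is simulated, the
#' full localization loop is run on the resulting stream, and the settled
#' final room is compared with the geometric truth. An undecided trial
#' (`Unknown`) counts as wrong.
#'
#' @param db a [fingerprint_db()].
#' @param points data.frame `x,y,heading,room` (see [grid_eval_points()]).
#' @param plan a [floorplan()].
#' @param beacons data.frame from [place_beacons()].
#' @param model a [propagation_model()].
#' @param dwell seconds spent standing at each point.
#' @param rate per-beacon sampling rate in Hz.
#' @param config a [localization_config()]; `NULL` scales the vote window to
#'   half the instants a dwell produces, so stationary trials can settle.
#' @param seed integer seed (one sub-stream per trial).
#' @return list: `accuracy` (fraction correct), `n_correct`, `n_trials`,
#'   `results` (per-trial data.frame).
#' @export
grid_accuracy <- function(db, points, plan, beacons, model, dwell = 20,
                          rate = 4, config = NULL, seed = 1) {
  stopifnot(inherits(db, "fingerprint_db"),
            all(c("x", "y", "heading", "room") %in% names(points)))
  if (is.null(config)) {
    L <- max(10L, floor(dwell * rate * length(db$roster) / 2))
    config <- localization_config(vote_length = L)
  }
  n <- nrow(points)
  settled <- character(n)
  for (i in seq_len(n)) {
    traj <- stationary_trajectory(points$x[i], points$y[i],
                                  points$heading[i], duration = dwell)
    sess <- simulate_tracking_session(plan, traj, beacons, model,
                                      rate = rate, seed = derive_seed(seed, i))
    trans <- process_stream(sess$measurements, db, config)
    settled[i] <- if (nrow(trans) > 0) trans$room[nrow(trans)] else "Unknown"
  }
  correct <- settled == points$room
  list(accuracy = mean(correct), n_correct = sum(correct), n_trials = n,
       results = data.frame(points, settled = settled, correct = correct,
                            stringsAsFactors = FALSE))
}
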