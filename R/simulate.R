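#' Stationary trajectory
#'
#' @param x,y position in metres.
#' @param heading heading in radians.
#' @param duration seconds.
#' @param dt trajectory sampling step in seconds.
#' @param t0 start time.
#' @return data.frame `time,x,y,heading`.
#' @export
stationary_trajectory <- function(x, y, heading = 0, duration = 60,
                                  dt = 0.25, t0 = 0) {
  tt <- seq(t0, t0 + duration, by = dt)
  data.frame(time = tt, x = x, y = y, heading = heading)
}

#' Piecewise-linear trajectory through waypoints
#'
#' Headings are the direction of motion on each leg (carried over on the last
#' sample).
#'
#' @param waypoints data.frame `time,x,y`, time strictly increasing.
#' @param dt sampling step in seconds.
#' @return data.frame `time,x,y,heading`.
#' @export
waypoint_trajectory <- function(waypoints, dt = 0.25) {
  stopifnot(all(c("time", "x", "y") %in% names(waypoints)),
            nrow(waypoints) >= 2, !is.unsorted(waypoints$time, strictly = TRUE))
  tt <- seq(min(waypoints$time), max(waypoints$time), by = dt)
  x <- stats::approx(waypoints$time, waypoints$x, tt)$y
  y <- stats::approx(waypoints$time, waypoints$y, tt)$y
  h <- atan2(c(diff(y), 0), c(diff(x), 0))
  if (length(h) > 1) h[length(h)] <- h[length(h) - 1]
  data.frame(time = tt, x = x, y = y, heading = h)
}

# interleaved per-beacon sampling times: beacon j advertises at `rate` Hz
# with phase offset j/(M*rate), so measurements from different beacons
# alternate the way asynchronous BLE advertising does
beacon_sample_times <- function(t_start, t_end, rate, n_beacons) {
  lapply(seq_len(n_beacons), function(j) {
    phase <- (j - 1) / (n_beacons * rate)
    tt <- seq(t_start + phase, t_end, by = 1 / rate)
    tt[tt <= t_end]
  })
}

# sample RSSI for every beacon along an interpolated trajectory
measure_along <- function(traj, beacons, model, plan, rate, offsets) {
  times <- beacon_sample_times(min(traj$time), max(traj$time), rate,
                               nrow(beacons))
  parts <- lapply(seq_len(nrow(beacons)), function(j) {
    tt <- times[[j]]
    if (length(tt) == 0L) return(NULL)
    x <- stats::approx(traj$time, traj$x, tt, rule = 2)$y
    y <- stats::approx(traj$time, traj$y, tt, rule = 2)$y
    h <- stats::approx(traj$time, traj$heading, tt, rule = 2)$y
    data.frame(timestamp = tt, beacon_id = beacons$beacon[j],
               rssi_dbm = rssi_at(x, y, h, beacons[j, , drop = FALSE],
                                  model, plan, offsets[j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-session interference offset (same for all beacons of the session)
session_interference <- function(model, n_beacons) {
  if (model$interference)
    rep(stats::runif(1, model$interference_range[1],
                     model$interference_range[2]), n_beacons)
  else rep(0, n_beacons)
}

#' Simulate the 30-second fingerprint training walk of one room
#'
#' A random-waypoint walk confined to the room's rectangle (0.3 m margin from
#' the walls), at walking speed, with RSSI sampled from every beacon at
#' `rate` Hz each and a synthetic accelerometer trace carrying periodic step
#' spikes at a normal walking cadence, so the trace passes
#' [validate_training_walk()] by construction.
#'
#' @param plan a [floorplan()].
#' @param room room label to train.
#' @param beacons data.frame from [place_beacons()].
#' @param model a [propagation_model()].
#' @param duration walk length in seconds (default 30).
#' @param rate per-beacon RSSI sampling rate in Hz.
#' @param speed walking speed in m/s.
#' @param seed integer seed; identical seeds give identical streams.
#' @return list with `measurements` (`timestamp,beacon_id,rssi_dbm`) and
#'   `accel` (`time,magnitude`).
#' @export
simulate_training_walk <- function(plan, room, beacons, model, duration = 30,
                                   rate = 4, speed = 0.5, seed = 1) {
  stopifnot(inherits(plan, "floorplan"))
  r <- plan$rooms[plan$rooms$room == room, , drop = FALSE]
  if (nrow(r) == 0L) stop(sprintf("unknown room '%s'", room))
  with_seed(seed, {
    margin <- min(0.3, (r$xmax - r$xmin) / 4, (r$ymax - r$ymin) / 4)
    n_wp <- max(2L, ceiling(duration * speed / 2) + 1L)
    wx <- stats::runif(n_wp, r$xmin + margin, r$xmax - margin)
    wy <- stats::runif(n_wp, r$ymin + margin, r$ymax - margin)
    leg <- sqrt(diff(wx)^2 + diff(wy)^2)
    wt <- cumsum(c(0, pmax(leg / speed, 0.5)))
    wt <- wt / max(wt) * duration            # rescale so the walk spans [0, duration]
    traj <- waypoint_trajectory(data.frame(time = wt, x = wx, y = wy), dt = 0.25)
    offsets <- session_interference(model, nrow(beacons))
    meas <- measure_along(traj, beacons, model, plan, rate, offsets)

    # accelerometer magnitude: gravity + sensor noise + a spike per step
    at <- seq(0, duration, by = 0.02)
    mag <- 9.81 + stats::rnorm(length(at), 0, 0.15)
    cadence <- 1.8                            # steps per second
    steps <- seq(0.3, duration, by = 1 / cadence)
    idx <- findInterval(steps, at)
    mag[idx] <- mag[idx] + stats::runif(length(idx), 3, 5)
    list(measurements = meas, accel = data.frame(time = at, magnitude = mag))
  })
}

#' Simulate a tracking session along a trajectory
#'
#' Produces the paired RSSI stream and per-sample ground-truth room labels
#' (from the floorplan geometry), the input an end-to-end localization
#' evaluation needs.
#'
#' @inheritParams simulate_training_walk
#' @param trajectory data.frame `time,x,y,heading` (see
#'   [stationary_trajectory()], [waypoint_trajectory()]).
#' @return list with `measurements` and `truth` (`time,room`).
#' @export
simulate_tracking_session <- function(plan, trajectory, beacons, model,
                                      rate = 4, seed = 1) {
  stopifnot(inherits(plan, "floorplan"),
            all(c("time", "x", "y", "heading") %in% names(trajectory)))
  with_seed(seed, {
    offsets <- session_interference(model, nrow(beacons))
    meas <- measure_along(trajectory, beacons, model, plan, rate, offsets)
    truth <- data.frame(time = trajectory$time,
                        room = room_at(plan, trajectory$x, trajectory$y),
                        stringsAsFactors = FALSE)
    list(measurements = meas, truth = truth)
  })
}

#' Behaviour profile of a frailty class
#'
#' Room dwell times follow a three-component mixture: a fast component
#' (dwell <= 15 s, uniform), a slow component (dwell > 600 s, shifted
#' lognormal) and a lognormal body with per-room median `mean_dwell`.
#' Successive rooms are drawn from a transition matrix with zero diagonal.
#'
#' @param class_label one of `"non-frail"`, `"pre-frail"`, `"frail"`.
#' @param mean_dwell mean of the lognormal body component in seconds; scalar
#'   or one value per room.
#' @param dwell_dispersion lognormal `sdlog` of the body component.
#' @param fast_prob probability of a fast dwell (<= 15 s).
#' @param slow_prob probability of a slow dwell (> 600 s).
#' @param transition_matrix optional row-stochastic matrix over rooms (zero
#'   diagonal); default uniform over the other rooms.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(class_label, mean_dwell, dwell_dispersion = 0.8,
                             fast_prob = 0.1, slow_prob = 0.05,
                             transition_matrix = NULL) {
  stopifnot(class_label %in% c("non-frail", "pre-frail", "frail"),
            all(mean_dwell > 0), dwell_dispersion >= 0,
            fast_prob >= 0, slow_prob >= 0, fast_prob + slow_prob <= 1)
  if (!is.null(transition_matrix)) {
    stopifnot(is.matrix(transition_matrix),
              nrow(transition_matrix) == ncol(transition_matrix),
              all(transition_matrix >= 0),
              all(abs(rowSums(transition_matrix) - 1) < 1e-8))
  }
  structure(list(class_label = class_label, mean_dwell = mean_dwell,
                 dwell_dispersion = dwell_dispersion, fast_prob = fast_prob,
                 slow_prob = slow_prob, transition_matrix = transition_matrix),
            class = "behavior_profile")
}

#' Default behaviour profiles for the three frailty classes
#'
#' Calibrated so that pooled >= 1800 s segments across the three classes show
#' on the order of 15-20 room transitions per segment, with non-frail subjects
#' moving much more than frail ones (short dwells, many fast transitions vs.
#' long sedentary dwells).
#'
#' @return Named list of three [behavior_profile()] objects.
#' @export
default_behavior_profiles <- function() {
  list(
    "non-frail" = behavior_profile("non-frail", mean_dwell = 70,
                                   dwell_dispersion = 0.8,
                                   fast_prob = 0.25, slow_prob = 0.01),
    "pre-frail" = behavior_profile("pre-frail", mean_dwell = 110,
                                   dwell_dispersion = 0.8,
                                   fast_prob = 0.15, slow_prob = 0.05),
    "frail"     = behavior_profile("frail", mean_dwell = 300,
                                   dwell_dispersion = 0.7,
                                   fast_prob = 0.03, slow_prob = 0.22)
  )
}

# one dwell draw from the profile's mixture, for the given room index
draw_dwell <- function(profile, room_idx) {
  u <- stats::runif(1)
  if (u < profile$fast_prob) {
    stats::runif(1, 2, 15)
  } else if (u < profile$fast_prob + profile$slow_prob) {
    600 + stats::rlnorm(1, meanlog = log(250) - 0.6^2 / 2, sdlog = 0.6)
  } else {
    m <- rep_len(profile$mean_dwell, max(room_idx, 1))[room_idx]
    stats::rlnorm(1, meanlog = log(m) - profile$dwell_dispersion^2 / 2,
                  sdlog = profile$dwell_dispersion)
  }
}

#' Simulate a room-transition record with a semi-Markov dwell model
#'
#' Repeatedly samples the next room from the profile's transition matrix and a
#' dwell duration from its mixture until `total_duration` is exhausted. Each
#' emitted row is a room entry: `(user_id, room, timestamp)`.
#'
#' @param profile a [behavior_profile()].
#' @param total_duration seconds of simulated behaviour.
#' @param rooms character vector of room labels (>= 2).
#' @param seed integer seed.
#' @param user_id identifier written into every row.
#' @param t0 timestamp of the first room entry.
#' @return data.frame `user_id,room,timestamp`.
#' @export
simulate_behavior <- function(profile, total_duration, rooms, seed = 1,
                              user_id = "u1", t0 = 0) {
  stopifnot(inherits(profile, "behavior_profile"), length(rooms) >= 2,
            total_duration > 0)
  n <- length(rooms)
  P <- profile$transition_matrix
  if (is.null(P)) {
    P <- matrix(1 / (n - 1), n, n)
    diag(P) <- 0
  }
  if (nrow(P) != n) stop("transition matrix dimension must match rooms")
  if (any(rowSums(P) == 0)) stop("degenerate transition matrix row")
  with_seed(seed, {
    cap <- ceiling(total_duration / 2) + 10L
    room_i <- integer(cap); times <- numeric(cap)
    i <- 1L
    room_i[1] <- sample.int(n, 1)
    times[1] <- t0
    t <- t0
    repeat {
      t <- t + draw_dwell(profile, room_i[i])
      if (t >= t0 + total_duration) break
      i <- i + 1L
      if (i > cap) break
      room_i[i] <- sample(n, 1, prob = P[room_i[i - 1L], ])
      times[i] <- t
    }
    data.frame(user_id = user_id, room = rooms[room_i[seq_len(i)]],
               timestamp = times[seq_len(i)], stringsAsFactors = FALSE)
  })
}

#' Evaluation grid over a floorplan
#'
#' Points on a regular lattice clipped to the rooms, each evaluated at four
#' headings (N/E/S/W), emulating a standing-user room-estimation survey.
#'
#' @param plan a [floorplan()].
#' @param n_points target number of distinct positions (default 48).
#' @param margin metres to keep from room edges.
#' @return data.frame `x,y,heading,room` with 4 rows per position.
#' @export
grid_eval_points <- function(plan, n_points = 48, margin = 0.4) {
  stopifnot(inherits(plan, "floorplan"))
  b <- plan$bounds
  # oversample a lattice, keep in-room points, thin to n_points
  k <- ceiling(sqrt(n_points * 2))
  gx <- seq(b["xmin"] + margin, b["xmax"] - margin, length.out = k)
  gy <- seq(b["ymin"] + margin, b["ymax"] - margin, length.out = k)
  g <- expand.grid(x = gx, y = gy)
  g$room <- room_at(plan, g$x, g$y)
  g <- g[!is.na(g$room), , drop = FALSE]
  keep_margin <- rep(TRUE, nrow(g))
  r <- plan$rooms
  for (i in seq_len(nrow(g))) {
    ri <- r[r$room == g$room[i], ]
    keep_margin[i] <- g$x[i] >= ri$xmin + margin && g$x[i] <= ri$xmax - margin &&
      g$y[i] >= ri$ymin + margin && g$y[i] <= ri$ymax - margin
  }
  g <- g[keep_margin, , drop = FALSE]
  if (nrow(g) > n_points)
    g <- g[round(seq(1, nrow(g), length.out = n_points)), , drop = FALSE]
  headings <- c(pi / 2, 0, -pi / 2, pi)   # N, E, S, W
  out <- g[rep(seq_len(nrow(g)), each = 4), , drop = FALSE]
  out$heading <- rep(headings, times = nrow(g))
  rownames(out) <- NULL
  out[, c("x", "y", "heading", "room")]
}
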