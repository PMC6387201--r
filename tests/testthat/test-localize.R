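test_that("two-sigma filtering matches hand-worked windows", {
  expect_equal(filtered_mean(rep(-60, 3)), -60)          # s = 0 short-circuit
  # -90 deviates 23.6 <= 2s (s ~ 11.84): nothing discarded, plain mean
  expect_equal(filtered_mean(c(-60, -62, -61, -90, -59)), -66.4)
  # one dominant outlier in n = 5 sits at |dev| ~ 0.8 * D < 2s: retained
  expect_equal(filtered_mean(c(-60, -62, -61, -120, -59)), -72.4)
  # in a longer window the same outlier exceeds 2s and is discarded
  expect_equal(filtered_mean(c(rep(-60, 9), -120)), -60)
  expect_error(filtered_mean(numeric(0)), "empty")
})

test_that("filtered mean equals the brute-force oracle on random windows", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    x <- round(runif(n, -100, -30), 1)
    if (runif(1) < 0.3) x[sample(n, 1)] <- -120   # inject an outlier
    if (runif(1) < 0.1) x <- rep(x[1], n)         # degenerate s = 0
    expect_equal(filtered_mean(x), oracle_filtered_mean(x))
  }
})

test_that("filtered vector assembly imputes silent beacons", {
  w <- list(b1 = rep(-55, 5), b2 = rep(-70, 5))
  expect_equal(assemble_filtered_vector(w, c("b1", "b2")), c(b1 = -55, b2 = -70))
  expect_equal(assemble_filtered_vector(w["b1"], c("b1", "b2")),
               c(b1 = -55, b2 = -100))
  expect_equal(assemble_filtered_vector(list(), c("b1", "b2"), impute = -95),
               c(b1 = -95, b2 = -95))
  v <- c(-60, -62, -61, -120, -59)
  expect_equal(unname(assemble_filtered_vector(list(b1 = v, b2 = v),
                                               c("b1", "b2"))),
               rep(filtered_mean(v), 2))
})

test_that("nearest fingerprint wins, ties break by insertion order", {
  db <- fingerprint_db(c("b1", "b2"),
                       matrix(c(-50, -70, -70, -50), 2, byrow = TRUE,
                              dimnames = list(c("A", "B"), NULL)))
  expect_equal(instant_room(db$means["A", ], db), "A")   # exact match
  expect_equal(instant_room(c(-55, -68), db), "A")       # sqrt(29) vs sqrt(549)
  dup <- fingerprint_db("b1", matrix(c(-60, -60), 2,
                                     dimnames = list(c("A", "B"), NULL)))
  expect_equal(instant_room(-60, dup), "A")
  expect_error(instant_room(c(-55, -68, -70), db), "length")
})

test_that("instant room agrees with exhaustive search on random databases", {
  set.seed(42)
  for (i in 1:200) {
    R <- sample(2:10, 1); M <- sample(1:10, 1)
    db <- fingerprint_db(paste0("b", 1:M),
                         matrix(round(runif(R * M, -100, -30)), R, M,
                                dimnames = list(paste0("r", 1:R), NULL)))
    cur <- runif(M, -100, -30)
    expect_identical(instant_room(cur, db), oracle_instant_room(cur, db))
  }
})

test_that("vote smoothing requires strict dominance in a full buffer", {
  est <- c(rep("kitchen", 641), rep("hall", 159))
  expect_equal(vote_room(sample(est), 800, previous = "bedroom"), "kitchen")
  est2 <- c(rep("kitchen", 640), rep("hall", 160))
  expect_equal(vote_room(sample(est2), 800, previous = "bedroom"), "bedroom")
  expect_equal(vote_room(rep("bath", 50), 50, previous = "hall"), "bath")
  # buffer not yet full: previous retained
  expect_equal(vote_room(rep("bath", 49), 50, previous = "hall"), "hall")
})

test_that("adding votes for the current winner never changes the decision", {
  set.seed(7)
  rooms <- c("A", "B", "C")
  for (i in 1:50) {
    L <- 40
    est <- sample(rooms, L, replace = TRUE, prob = c(0.9, 0.05, 0.05))
    dec <- vote_room(est, L, previous = "B", rooms = rooms)
    if (dec == "B") next                      # undecided: nothing to preserve
    more <- c(est[-seq_len(5)], rep(dec, 5))  # five more votes for the winner
    expect_identical(vote_room(more, L, previous = "B", rooms = rooms), dec)
  }
})

test_that("outside rule fires on strict collective 4-second silence", {
  expect_true(is_outside(c(0.9, 0.5), now = 5))      # newest 4.1 s ago
  expect_false(is_outside(c(0.9, 4.0), now = 5))     # one beacon 1 s ago
  expect_false(is_outside(c(1.0, 0.2), now = 5))     # exactly 4.0 s: strict >
  expect_true(is_outside(c(NA, -Inf), now = 5))      # never heard
})

test_that("a constant in-room stream yields a single transition record", {
  cfg <- localization_config(vote_length = 40)
  m <- constant_room_stream(tw_db0, "bedroom", duration = 10)
  tr <- process_stream(m, tw_db0, cfg, user_id = "u7")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$room, "bedroom")
  expect_equal(tr$user_id, "u7")
  # first decision once the vote buffer fills: 40 instants at 20 /s
  expect_equal(tr$timestamp, m$timestamp[40], tolerance = 1e-9)
})

test_that("a silence gap emits Outside at gap start + timeout, then re-enters", {
  cfg <- localization_config(vote_length = 40)
  m1 <- constant_room_stream(tw_db0, "kitchen", duration = 10)
  m2 <- m1
  m2$timestamp <- m2$timestamp + 20       # 10 s of silence from t ~ 10
  tr <- process_stream(rbind(m1, m2), tw_db0, cfg)
  expect_equal(tr$room, c("kitchen", "Outside", "kitchen"))
  expect_equal(tr$timestamp[2], max(m1$timestamp) + 4, tolerance = 1e-9)
  # re-entry restarts the vote buffer: 40 fresh instants before kitchen again
  expect_equal(tr$timestamp[3], m2$timestamp[40], tolerance = 1e-9)
  expect_true(all(diff(tr$timestamp) > 0))
})

test_that("emitted transitions never repeat a label consecutively", {
  cfg <- localization_config(vote_length = 30)
  for (s in 1:5) {
    traj <- waypoint_trajectory(data.frame(
      time = c(0, 40, 50, 90, 100, 140),
      x = c(2.1, 2.1, 6.4, 6.4, 6.4, 6.4),
      y = c(2.5, 2.5, 1.3, 1.3, 3.6, 3.6)))
    sess <- simulate_tracking_session(tw_plan, traj, tw_beacons, tw_model,
                                      seed = 60 + s)
    tr <- process_stream(sess$measurements, tw_db, cfg)
    if (nrow(tr) > 1) {
      expect_true(all(tr$room[-1] != tr$room[-nrow(tr)]))
      expect_true(all(diff(tr$timestamp) > 0))
    }
  }
})

test_that("unknown beacons are ignored with a warning, empty streams are empty", {
  cfg <- localization_config(vote_length = 10)
  m <- constant_room_stream(tw_db0, "hall", duration = 5)
  rogue <- data.frame(timestamp = 2.001, beacon_id = "intruder", rssi_dbm = -40)
  mm <- rbind(m, rogue)
  mm <- mm[order(mm$timestamp), ]
  expect_warning(tr <- process_stream(mm, tw_db0, cfg), "intruder")
  expect_equal(tr$room, "hall")
  expect_equal(nrow(process_stream(m[0, ], tw_db0, cfg)), 0L)
})
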