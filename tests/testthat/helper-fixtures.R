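# shared desk-scale world: default five-room house, one beacon per room,
# fingerprint databases trained under a deterministic and a noisy model

tw_plan <- default_floorplan()
tw_beacons <- place_beacons(tw_plan)
tw_rooms <- tw_plan$rooms$room

# deterministic propagation: no shadowing, no body term, no interference
tw_model0 <- propagation_model(shadow_sigma = 0, body_loss_max = 0)
tw_model <- propagation_model()   # defaults: sigma = 2 dB, body <= 6 dB

train_db <- function(model, seed0 = 100) {
  walks <- lapply(seq_along(tw_rooms), function(i)
    simulate_training_walk(tw_plan, tw_rooms[i], tw_beacons, model,
                           seed = seed0 + i))
  names(walks) <- tw_rooms
  build_fingerprint_db(lapply(walks, `[[`, "measurements"), tw_beacons$beacon)
}

tw_db0 <- train_db(tw_model0)
tw_db <- train_db(tw_model)

# brute-force re-statement of the 2-sigma filtered mean
oracle_filtered_mean <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / length(x))
  if (s == 0) return(m)
  kept <- x[abs(x - m) <= 2 * s]
  if (length(kept) == 0) m else sum(kept) / length(kept)
}

# exhaustive nearest-fingerprint search, first room wins ties
oracle_instant_room <- function(current, db) {
  best <- 1L
  best_d <- Inf
  for (i in seq_len(nrow(db$means))) {
    d <- sqrt(sum((current - db$means[i, ])^2))
    if (d < best_d) { best_d <- d; best <- i }
  }
  rownames(db$means)[best]
}

# a measurement stream whose instantaneous estimate is pinned to one room:
# every beacon repeats that room's stored fingerprint value
constant_room_stream <- function(db, room, duration, rate = 4) {
  fp <- db$means[room, ]
  times <- beacon_sample_times(0, duration, rate, length(db$roster))
  parts <- lapply(seq_along(db$roster), function(j)
    data.frame(timestamp = times[[j]], beacon_id = db$roster[j],
               rssi_dbm = unname(fp[j]), stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  out <- out[order(out$timestamp), ]
  rownames(out) <- NULL
  out
}

# behaviour profiles with strongly separated dwell statistics
# (frail body dwell 10x the non-frail one)
separated_profiles <- function() {
  list(
    "non-frail" = behavior_profile("non-frail", 50, 0.5,
                                   fast_prob = 0.35, slow_prob = 0.005),
    "pre-frail" = behavior_profile("pre-frail", 160, 0.5,
                                   fast_prob = 0.12, slow_prob = 0.05),
    "frail"     = behavior_profile("frail", 500, 0.5,
                                   fast_prob = 0.02, slow_prob = 0.30)
  )
}

# features for >= n_segments per class under the given profiles
simulate_feature_set <- function(profiles, seconds_per_user = 110000,
                                 users = 4, seed0 = 0) {
  parts <- lapply(names(profiles), function(cl) {
    beh <- lapply(seq_len(users), function(s)
      simulate_behavior(profiles[[cl]], seconds_per_user, tw_rooms,
                        seed = seed0 * 1000 + match(cl, names(profiles)) * 10 + s,
                        user_id = paste0(cl, "_", s)))
    trn <- do.call(rbind, beh)
    extract_features(trn, data.frame(user_id = unique(trn$user_id),
                                     frailty_status = cl),
                     n_rooms = length(tw_rooms))
  })
  do.call(rbind, parts)
}

feature_cols <- c("n_transitions", "mean_duration", "sd_duration", "n_fast",
                  "n_slow", "pct_fast", "pct_slow", "norm_fast", "norm_slow")

ref_confusion <- function(name) {
  df <- utils::read.csv(system.file("extdata", name, package = "frailhome"),
                        check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$true
  m
}
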