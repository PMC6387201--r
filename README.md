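# frailhome

Low-cost indoor activity monitoring for frailty assessment in older adults.

Clinically, frailty is graded on the Fried phenotype scale — non-frail,
pre-frail, frail — by in-person assessment. People at different points on
that scale also *move* differently at home: frail subjects dwell long in one
room, non-frail subjects transition often and quickly. `frailhome`
implements a monitoring pipeline that exploits this, built around
room-level indoor localization with Bluetooth Low Energy (BLE) beacons and a
smartphone in the subject's pocket:

1. **Fingerprinting (setup).** One beacon per room; a nurse walks each room
   for 30 s while the phone records the received signal strength (RSSI, dBm)
   from every beacon. The room fingerprint is the vector
   `f_i = (rss_{i,1}, …, rss_{i,M})` of per-beacon means over one-second
   bins, for the `M` beacons of the house. A threshold step detector on the
   accelerometer validates that the nurse actually kept walking (at least
   one step in every 5-s window).
2. **Online localization.** Each beacon keeps a sliding window of recent
   RSSI values; values deviating more than `2s` from the window mean
   (population standard deviation `s`) are discarded and the filtered means
   form the live vector `f_u`. The instantaneous room is
   `argmin_i ‖f_u − f_i‖`; a second sliding window of the last `L = 800`
   instantaneous estimates smooths this with a majority vote — the reported
   room changes only when one room holds strictly more than 80 % of the
   buffer. Collective beacon silence for more than 4 s means the subject is
   outside. The output is a log of room transitions
   `(user_id, room, timestamp)`.
3. **Frailty assessment.** Transition logs become dwell-interval signals,
   cut into segments of ≥ 1800 s by a running sum. Each segment yields nine
   mobility features (transition count, mean/SD dwell, counts, percentages
   and normalised counts of fast ≤ 15 s and slow > 600 s transitions), and
   classifiers (naive Bayes, 10-NN, neural network, decision tree, random
   forest) are evaluated with stratified 10-fold cross-validation on both
   the 3-class problem and the binary frail-identification problem.

Since the original hardware deployment and trial records are not available,
the package includes a first-class simulator: log-distance radio propagation
(`RSSI = P0 − 10 n log10 d`, plus per-wall attenuation, a heading-dependent
body-attenuation ramp, optional interference offsets and Gaussian
shadowing) over rectangular floorplans, and a semi-Markov behaviour model
with class-specific dwell mixtures. Every stage of the pipeline can
therefore be exercised, audited and tested at desk scale.

## Worked example

```r
library(frailhome)

plan    <- default_floorplan()          # 8.6 m x 9.35 m, five rooms
beacons <- place_beacons(plan)          # one beacon per room, >= 2 m apart
model   <- propagation_model()          # n = 2.2, 3 dB/wall, 2 dB shadowing

# --- setup phase: 30-s training walk per room -> fingerprint database
walks <- lapply(plan$rooms$room, function(r)
  simulate_training_walk(plan, r, beacons, model,
                         seed = 100 + match(r, plan$rooms$room)))
names(walks) <- plan$rooms$room
db <- build_fingerprint_db(lapply(walks, `[[`, "measurements"), beacons$beacon)
db
#> fingerprint database: 5 rooms x 5 beacons (dBm)
#>             b_kitchen b_living_room b_bedroom b_bathroom b_hall
#> kitchen         -56.9         -73.8     -75.8      -81.4  -84.1
#> living_room     -71.1         -58.4     -77.8      -74.1  -76.4
#> bedroom         -73.0         -78.4     -58.7      -72.2  -80.7
#> bathroom        -80.9         -76.1     -73.2      -54.0  -69.0
#> hall            -84.3         -76.2     -80.1      -68.4  -56.6
```

Each room is loudest on its own beacon (diagonal ≈ −55 to −59 dBm) and the
rooms are well separated — that is what makes nearest-fingerprint matching
work.

```r
# --- online phase: a walk from the living room into the hall
traj <- waypoint_trajectory(data.frame(time = c(0, 60, 70, 130),
                                       x = c(2.1, 2.1, 6.4, 6.4),
                                       y = c(2.5, 2.5, 1.3, 1.3)))
sess <- simulate_tracking_session(plan, traj, beacons, model, seed = 7)
process_stream(sess$measurements, db, localization_config(vote_length = 40))
#>   user_id        room timestamp
#> 1      u1 living_room      1.95
#> 2      u1        hall     67.30
```

The walker crosses the room boundary at t ≈ 65 s; the vote buffer reports
the change ~2 s later (the smoothing latency).

```r
# --- frailty phase: 36 h of simulated behaviour per class
profiles <- default_behavior_profiles()
trn <- do.call(rbind, lapply(names(profiles), function(cl)
  simulate_behavior(profiles[[cl]], 36 * 3600, plan$rooms$room,
                    seed = match(cl, names(profiles)), user_id = cl)))
labels <- data.frame(user_id = names(profiles), frailty_status = names(profiles))
feats  <- extract_features(trn, labels, n_rooms = 5)
cross_validate(feats[, 2:10], feats$label, "rf", k = 10, seed = 42)
#> 10-fold stratified cross-validation, classifier 'rf'
#> confusion matrix (rows = true, cols = predicted):
#>            predicted
#> true        frail non-frail pre-frail
#>   frail        60         0         2
#>   non-frail     1        57         9
#>   pre-frail     1         8        54
#> accuracy 89.06%  macro sensitivity 89.19%  macro PPV 89.18%
```

Misclassification concentrates between non-frail and pre-frail — the
adjacent classes with the most similar movement statistics — while frail
subjects separate almost perfectly, the same error structure the method
shows on field data.

`run_pipeline(run_config(seed = 1), "out/")` chains all of the above and
writes every intermediate file; `inst/cli/frailhome.R` exposes the stages as
shell subcommands (`simulate`, `fingerprint`, `localize`, `evaluate-grid`,
`features`, `classify`, `run-all`).

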