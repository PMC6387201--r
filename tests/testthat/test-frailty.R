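test_that("dwell intervals are successive timestamp differences", {
  rec <- data.frame(user_id = "u", room = c("a", "b", "a", "c"),
                    timestamp = c(0, 30, 100, 700))
  expect_equal(intervals_from_transitions(rec), list(c(30, 70, 600)))
  expect_equal(intervals_from_transitions(rec[1, ]), list())
  bad <- rec; bad$timestamp <- c(0, 30, 30, 700)
  expect_error(intervals_from_transitions(bad), "strictly increasing")
})

test_that("outside episodes split the signal and their dwell is dropped", {
  rec <- data.frame(user_id = "u",
                    room = c("a", "b", "Outside", "a", "b"),
                    timestamp = c(0, 50, 120, 400, 460))
  sig <- intervals_from_transitions(rec)
  expect_equal(sig, list(c(50, 70), 60))   # 280 s outside never appears
  # outside at the edges leaves a single sub-signal
  rec2 <- data.frame(user_id = "u", room = c("Outside", "a", "b", "Outside"),
                     timestamp = c(0, 10, 60, 200))
  expect_equal(intervals_from_transitions(rec2), list(c(50, 140)))
})

test_that("running-sum segmentation follows the worked traces", {
  s <- segment_intervals(c(1000, 500, 400, 50))
  expect_equal(s[[1]], c(1000, 500, 400))     # closes at 1900 >= 1800
  expect_length(s, 1)
  expect_equal(attr(s, "remainder"), 50)
  s2 <- segment_intervals(2500)
  expect_equal(s2[[1]], 2500)                  # one interval alone suffices
  s3 <- segment_intervals(c(900, 800))         # sums to 1700 < 1800
  expect_length(s3, 0)
  expect_equal(attr(s3, "remainder"), c(900, 800))
})

test_that("segments satisfy the threshold, minimality and losslessness", {
  set.seed(13)
  for (i in 1:100) {
    iv <- rlnorm(sample(5:120, 1), meanlog = runif(1, 3, 6), sdlog = 1)
    segs <- segment_intervals(iv)
    for (s in segs) {
      expect_gte(sum(s), 1800)
      expect_lt(sum(s) - s[length(s)], 1800)   # dropping the last falls short
    }
    rebuilt <- c(unlist(segs), attr(segs, "remainder"))
    expect_equal(rebuilt, iv)                   # reconstruction-lossless
    expect_lt(sum(attr(segs, "remainder")), 1800)
  }
})

test_that("segment features reproduce the hand-worked example", {
  f <- segment_features(c(10, 5, 700, 30, 650, 20), n_rooms = 4)
  expect_equal(f$n_transitions, 6L)
  expect_equal(f$mean_duration, 1415 / 6)
  expect_equal(f$sd_duration, sd(c(10, 5, 700, 30, 650, 20)))
  expect_equal(f$n_fast, 2L)
  expect_equal(f$n_slow, 2L)
  expect_equal(f$pct_fast, 1 / 3)
  expect_equal(f$pct_slow, 1 / 3)
  expect_equal(f$norm_fast, 2 / 24)
  expect_equal(f$norm_slow, 2 / 24)
})

test_that("feature edge cases: constant dwells, cutoffs, single interval", {
  f <- segment_features(rep(300, 7), n_rooms = 5)
  expect_equal(f$sd_duration, 0)
  expect_equal(f$n_fast + f$n_slow, 0L)
  expect_equal(f$pct_fast + f$pct_slow + f$norm_fast + f$norm_slow, 0)
  # 15 s counts fast (inclusive); 600 s does not count slow (exclusive)
  f2 <- segment_features(c(15, 600), n_rooms = 2)
  expect_equal(f2$n_fast, 1L)
  expect_equal(f2$n_slow, 0L)
  f3 <- segment_features(2000, n_rooms = 5)
  expect_equal(f3$sd_duration, 0)
  expect_equal(f3$n_transitions, 1L)
  expect_error(segment_features(numeric(0), 5), "empty")
})

test_that("feature invariants hold on randomised segments", {
  set.seed(14)
  for (i in 1:200) {
    iv <- rlnorm(sample(1:60, 1), meanlog = runif(1, 2, 7), sdlog = 1.2)
    n_rooms <- sample(1:10, 1)
    f <- segment_features(iv, n_rooms)
    expect_lte(f$n_fast + f$n_slow, f$n_transitions)
    expect_equal(f$pct_fast, f$n_fast / f$n_transitions)
    expect_equal(f$norm_fast, f$n_fast / (n_rooms * f$n_transitions))
    expect_true(all(unlist(f[c("pct_fast", "pct_slow",
                               "norm_fast", "norm_slow")]) >= 0))
    expect_true(all(unlist(f[c("pct_fast", "pct_slow",
                               "norm_fast", "norm_slow")]) <= 1))
    expect_lte(f$norm_fast, f$pct_fast)
  }
})

test_that("binary merge pools non-frail with pre-frail and keeps order", {
  x <- c("pre-frail", "frail", "non-frail", "frail")
  expect_equal(merge_binary(x),
               c("non-frail/pre-frail", "frail", "non-frail/pre-frail", "frail"))
  expect_error(merge_binary(c("frail", "robust")), "robust")
})

test_that("multi-user feature extraction stitches the stages together", {
  profs <- default_behavior_profiles()
  trn <- rbind(
    simulate_behavior(profs[["non-frail"]], 30000, tw_rooms, seed = 21,
                      user_id = "u1"),
    simulate_behavior(profs[["frail"]], 30000, tw_rooms, seed = 22,
                      user_id = "u2"))
  lab <- data.frame(user_id = c("u1", "u2"),
                    frailty_status = c("non-frail", "frail"))
  fe <- extract_features(trn, lab, n_rooms = 5)
  expect_true(all(feature_cols %in% names(fe)))
  expect_setequal(unique(fe$label), c("non-frail", "frail"))
  expect_true(all(fe$mean_duration > 0))
  expect_error(extract_features(trn, lab[1, , drop = FALSE], 5), "label")
})

test_that("confusion metrics reproduce reference-matrix arithmetic", {
  m <- confusion_metrics(matrix(c(435, 11, 0, 84), 2, byrow = TRUE,
                                dimnames = list(c("nfpf", "f"),
                                                c("nfpf", "f"))))
  expect_equal(m$accuracy, 519 / 530)
  expect_equal(unname(m$sensitivity), c(435 / 446, 1))
  expect_equal(unname(m$ppv), c(1, 84 / 95))
  # identity matrix: perfect accuracy, no breakdown rows
  id <- confusion_metrics(diag(3) * 5 + 0)
  expect_equal(id$accuracy, 1)
  expect_equal(nrow(id$breakdown), 0L)
  expect_error(confusion_metrics(matrix(0, 2, 2)), "all-zero")
  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
})

test_that("cross-validation separates well-separated clusters perfectly", {
  set.seed(31)
  n <- 30
  x <- data.frame(f1 = c(rnorm(n, 0), rnorm(n, 10)),
                  f2 = c(rnorm(n, 0), rnorm(n, 10)))
  y <- rep(c("a", "b"), each = n)
  for (clf in c("rf", "dt", "nb", "knn", "nn")) {
    ev <- cross_validate(x, y, clf, k = 10, seed = 2)
    expect_gte(ev$metrics$accuracy, 0.95)
  }
})

test_that("cross-validation is deterministic and validates its inputs", {
  set.seed(32)
  x <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
  y <- rep(c("a", "b", "c"), 20)
  e1 <- cross_validate(x, y, "rf", seed = 5)
  e2 <- cross_validate(x, y, "rf", seed = 5)
  expect_identical(e1$confusion, e2$confusion)
  expect_error(cross_validate(x, rep("a", 60), "rf"), "two classes")
  expect_error(cross_validate(x, c(rep("a", 55), rep("b", 5)), "rf", k = 10),
               "fewer than k")
  expect_error(cross_validate(data.frame(f = letters[1:60]), y, "rf"),
               "numeric")
  # pooled confusion matrix row sums equal the class counts
  expect_equal(unname(rowSums(e1$confusion)), rep(20, 3))
})
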