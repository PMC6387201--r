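#' Dwell intervals from a room-transition record
#'
#' The time-interval signal is the sequence of dwell durations between
#' successive transitions of one subject: `intervals[k] = t[k+1] - t[k]`.
#' Episodes spent outside the house break the signal: the outside dwell is
#' dropped and the signal splits into independent sub-signals, since the
#' system monitors indoor behaviour only.
#'
#' @param records data.frame `user_id,room,timestamp` for a single subject,
#'   sorted, timestamps strictly increasing.
#' @param outside_label label of the outside pseudo-room.
#' @return List of numeric vectors (sub-signals); empty list for < 2 records.
#' @export
intervals_from_transitions <- function(records, outside_label = "Outside") {
  if (is.null(records) || nrow(records) < 2L) return(list())
  stopifnot(all(c("room", "timestamp") %in% names(records)))
  if (is.unsorted(records$timestamp, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  iv <- diff(records$timestamp)
  room <- records$room[-nrow(records)]   # interval k is dwelt in room k
  keep <- room != outside_label
  if (!any(keep)) return(list())
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- lapply(which(runs$values), function(r) iv[starts[r]:ends[r]])
  out[lengths(out) > 0]
}

#' Segment a time-interval signal at a running-sum threshold
#'
#' Greedy left-to-right: intervals accumulate until the running sum reaches
#' the threshold; the segment closes including the last interval in full (so
#' actual segment durations overshoot the threshold by part of one dwell), and
#' the sum resets. A trailing remainder that never reaches the threshold is
#' discarded from the feature set but returned in the `remainder` attribute so
#' the segmentation stays reconstruction-lossless.
#'
#' @param intervals numeric vector of positive dwell durations (seconds).
#' @param threshold minimum segment duration in seconds (default 1800).
#' @return List of numeric vectors (segments), with attribute `remainder`.
#' @export
segment_intervals <- function(intervals, threshold = 1800) {
  stopifnot(all(intervals > 0))
  segments <- list()
  start <- 1L
  acc <- 0
  for (k in seq_along(intervals)) {
    acc <- acc + intervals[k]
    if (acc >= threshold) {
      segments[[length(segments) + 1L]] <- intervals[start:k]
      start <- k + 1L
      acc <- 0
    }
  }
  remainder <- if (start <= length(intervals))
    intervals[start:length(intervals)] else numeric(0)
  attr(segments, "remainder") <- remainder
  segments
}

#' Mobility features of one time-interval segment
#'
#' The nine features: transition count, mean and standard deviation of dwell
#' durations (sample convention, 0 for a single interval), counts of fast
#' (<= 15 s) and slow (> 600 s) transitions, their percentages of the
#' transition count, and their counts normalised by (number of rooms x number
#' of transitions).
#'
#' @param intervals numeric vector: one segment's dwell durations (non-empty).
#' @param n_rooms number of rooms registered for the house (a house property,
#'   not the rooms visited in the segment).
#' @param fast_cutoff fast-transition dwell bound in seconds (inclusive).
#' @param slow_cutoff slow-transition dwell bound in seconds (exclusive).
#' @return One-row data.frame with the nine feature columns.
#' @export
segment_features <- function(intervals, n_rooms, fast_cutoff = 15,
                             slow_cutoff = 600) {
  if (length(intervals) == 0L) stop("empty segment")
  stopifnot(n_rooms >= 1)
  n <- length(intervals)
  n_fast <- sum(intervals <= fast_cutoff)
  n_slow <- sum(intervals > slow_cutoff)
  data.frame(
    n_transitions = n,
    mean_duration = mean(intervals),
    sd_duration = if (n > 1) stats::sd(intervals) else 0,
    n_fast = n_fast,
    n_slow = n_slow,
    pct_fast = n_fast / n,
    pct_slow = n_slow / n,
    norm_fast = n_fast / (n_rooms * n),
    norm_slow = n_slow / (n_rooms * n)
  )
}

#' Feature table from multi-subject transition records
#'
#' Runs interval extraction, segmentation and feature extraction per subject
#' and stacks the result, attaching each subject's frailty label.
#'
#' @param transitions data.frame `user_id,room,timestamp` (all subjects).
#' @param labels data.frame `user_id,frailty_status`.
#' @param n_rooms rooms registered for the house(s).
#' @param threshold segmentation threshold in seconds.
#' @param fast_cutoff,slow_cutoff dwell bounds in seconds.
#' @return data.frame: `user_id`, the nine features, `label`.
#' @export
extract_features <- function(transitions, labels, n_rooms, threshold = 1800,
                             fast_cutoff = 15, slow_cutoff = 600) {
  stopifnot(all(c("user_id", "room", "timestamp") %in% names(transitions)),
            all(c("user_id", "frailty_status") %in% names(labels)))
  lab <- stats::setNames(as.character(labels$frailty_status),
                         as.character(labels$user_id))
  parts <- lapply(split(transitions, transitions$user_id), function(rec) {
    u <- rec$user_id[1]
    if (!u %in% names(lab)) stop(sprintf("no frailty label for user '%s'", u))
    rec <- rec[order(rec$timestamp), , drop = FALSE]
    segs <- unlist(lapply(intervals_from_transitions(rec),
                          segment_intervals, threshold = threshold),
                   recursive = FALSE)
    if (length(segs) == 0L) return(NULL)
    feats <- do.call(rbind, lapply(segs, segment_features, n_rooms = n_rooms,
                                   fast_cutoff = fast_cutoff,
                                   slow_cutoff = slow_cutoff))
    cbind(data.frame(user_id = u, stringsAsFactors = FALSE), feats,
          data.frame(label = unname(lab[u]), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Collapse frailty labels to the binary frail-identification problem
#'
#' @param labels character/factor vector over
#'   `{non-frail, pre-frail, frail}`.
#' @return Character vector over `{non-frail/pre-frail, frail}`, same length
#'   and order.
#' @export
merge_binary <- function(labels) {
  labels <- as.character(labels)
  ok <- labels %in% c("non-frail", "pre-frail", "frail")
  if (!all(ok))
    stop(sprintf("unknown frailty label(s): %s",
                 paste(unique(labels[!ok]), collapse = ", ")))
  ifelse(labels == "frail", "frail", "non-frail/pre-frail")
}

# the five classifier back-ends; x train/test are numeric data.frames
fit_predict <- function(classifier, x_train, y_train, x_test, inner_seed) {
  scale_pair <- function() {
    mu <- vapply(x_train, mean, numeric(1))
    sd <- vapply(x_train, stats::sd, numeric(1))
    sd[sd == 0 | is.na(sd)] <- 1
    list(train = scale(x_train, mu, sd), test = scale(x_test, mu, sd))
  }
  set.seed(inner_seed)
  switch(classifier,
    nb = {
      fit <- e1071::naiveBayes(x_train, y_train)
      as.character(stats::predict(fit, x_test, type = "class"))
    },
    knn = {
      sp <- scale_pair()
      as.character(class::knn(sp$train, sp$test, y_train, k = 10))
    },
    nn = {
      sp <- scale_pair()
      df <- data.frame(sp$train)
      df$.y <- y_train
      fit <- nnet::nnet(.y ~ ., data = df, size = 16, decay = 0.01,
                        maxit = 300, trace = FALSE, MaxNWts = 5000)
      as.character(stats::predict(fit, data.frame(sp$test), type = "class"))
    },
    dt = {
      df <- data.frame(x_train)
      df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(cp = 0.001))
      cp <- fit$cptable
      best <- cp[which.min(cp[, "xerror"]), "CP"]
      fit <- rpart::prune(fit, cp = best)
      as.character(stats::predict(fit, data.frame(x_test), type = "class"))
    },
    rf = {
      fit <- randomForest::randomForest(x_train, y_train, ntree = 100)
      as.character(stats::predict(fit, x_test))
    },
    stop(sprintf("unknown classifier '%s'", classifier))
  )
}

#' Stratified k-fold cross-validated classification
#'
#' Folds are stratified by label with a seeded shuffle; out-of-fold
#' predictions are pooled into a single confusion matrix from which accuracy,
#' per-class sensitivity and positive predictive value, and their macro
#' averages are computed. Deterministic given the seed.
#'
#' @param features numeric data.frame/matrix of predictors (one row per
#'   sample; non-numeric columns such as ids are rejected).
#' @param labels character/factor vector of class labels.
#' @param classifier one of `"nb"` (naive Bayes), `"knn"` (10-nearest
#'   neighbour), `"nn"` (single-hidden-layer neural network, 16 units),
#'   `"dt"` (information-gain decision tree with cost-complexity pruning),
#'   `"rf"` (random forest, 100 trees).
#' @param k number of folds (default 10). Every class needs >= k samples.
#' @param seed integer seed controlling folds and model randomness.
#' @return An object of class `frailty_eval`: list with `confusion` (rows =
#'   true, cols = predicted), `metrics` (see [confusion_metrics()]),
#'   `classifier`, `k`, `seed`.
#' @export
cross_validate <- function(features, labels,
                           classifier = c("rf", "nb", "knn", "nn", "dt"),
                           k = 10, seed = 1) {
  classifier <- match.arg(classifier)
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  y <- factor(as.character(labels))
  stopifnot(nrow(features) == length(y))
  if (nlevels(y) < 2) stop("need at least two classes")
  counts <- table(y)
  if (any(counts < k))
    stop(sprintf("class '%s' has %d samples, fewer than k = %d folds",
                 names(counts)[which.min(counts)], min(counts), k))
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pred <- character(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    pred[test] <- fit_predict(classifier, features[!test, , drop = FALSE],
                              droplevels(y[!test]),
                              features[test, , drop = FALSE],
                              inner_seed = derive_seed(seed, f))
  }
  cm <- table(true = y, predicted = factor(pred, levels = levels(y)))
  cm <- unclass(cm)
  structure(list(confusion = cm, metrics = confusion_metrics(cm),
                 classifier = classifier, k = k, seed = seed),
            class = "frailty_eval")
}

#' @export
print.frailty_eval <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation, classifier '%s'\n",
              x$k, x$classifier))
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.2f%%  macro sensitivity %.2f%%  macro PPV %.2f%%\n",
              100 * m$accuracy, 100 * m$macro_sensitivity, 100 * m$macro_ppv))
  invisible(x)
}

#' Metrics and misclassification breakdown of a confusion matrix
#'
#' Accuracy is trace/total; per-class sensitivity is the diagonal over the row
#' sum (recall), per-class PPV the diagonal over the column sum (precision);
#' macro averages are unweighted means over classes (classes absent from the
#' truth or the predictions are dropped from the respective average). The
#' breakdown lists every non-zero off-diagonal cell as a fraction of its true
#' class's errors and of all errors.
#'
#' @param mat square non-negative integer matrix, rows = true classes,
#'   columns = predicted classes, with dimnames.
#' @return list: `accuracy`, `sensitivity`, `ppv` (named per class),
#'   `macro_sensitivity`, `macro_ppv`, `n`, `n_errors`, `breakdown`
#'   (data.frame `true,predicted,count,frac_class_errors,frac_total_errors`).
#' @export
confusion_metrics <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("confusion matrix must be square")
  if (any(mat < 0) || any(mat != round(mat)))
    stop("confusion matrix entries must be non-negative integers")
  total <- sum(mat)
  if (total == 0) stop("all-zero confusion matrix")
  classes <- rownames(mat)
  if (is.null(classes)) classes <- colnames(mat)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(mat)))
  dg <- diag(mat)
  rs <- rowSums(mat)
  cs <- colSums(mat)
  sens <- stats::setNames(ifelse(rs > 0, dg / rs, NA_real_), classes)
  ppv <- stats::setNames(ifelse(cs > 0, dg / cs, NA_real_), classes)
  errs <- total - sum(dg)
  breakdown <- data.frame(true = character(0), predicted = character(0),
                          count = integer(0), frac_class_errors = numeric(0),
                          frac_total_errors = numeric(0))
  if (errs > 0) {
    for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
      if (i != j && mat[i, j] > 0) {
        class_errs <- rs[i] - dg[i]
        breakdown <- rbind(breakdown, data.frame(
          true = classes[i], predicted = classes[j], count = mat[i, j],
          frac_class_errors = mat[i, j] / class_errs,
          frac_total_errors = mat[i, j] / errs))
      }
    }
    rownames(breakdown) <- NULL
  }
  list(accuracy = sum(dg) / total, sensitivity = sens, ppv = ppv,
       macro_sensitivity = mean(sens, na.rm = TRUE),
       macro_ppv = mean(ppv, na.rm = TRUE),
       n = total, n_errors = errs, breakdown = breakdown)
}
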