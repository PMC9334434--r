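## k-nearest-neighbour decoding of stimulus class from peck coordinates:
## CC / CE / EE modes, shuffled-label null, paired-t significance across
## iterations, one-peck-per-trial control and peck-order analysis.

#' Classifier configuration
#'
#' Defaults follow the standard decoding protocol: `k = 15` neighbours (odd,
#' and close to the square root of the 250 training events), 250 training and
#' 250 test pecks, 10 iterations, a 500-event sufficiency gate for
#' error-trial analyses, and a Bonferroni-adjusted alpha of 0.05 / 8.
#'
#' @param k Number of neighbours (odd, `<= n_train`).
#' @param n_train,n_test Training/test events sampled per iteration.
#' @param iterations Number of decoding iterations (`>= 2`).
#' @param min_error_events Minimum error-pool size for CE/EE analyses.
#' @param one_peck_per_trial If `TRUE`, first keep one randomly chosen peck
#'   per trial before sampling (controls for within-trial peck dependence).
#' @param seed Optional integer seed for the decoding run.
#' @param alpha_adjusted Significance threshold for the verdict.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(k = 15L, n_train = 250L, n_test = 250L,
                              iterations = 10L, min_error_events = 500L,
                              one_peck_per_trial = FALSE, seed = NULL,
                              alpha_adjusted = 0.05 / 8) {
  k <- as.integer(k)
  stopifnot(k >= 1, k %% 2L == 1L, k <= n_train, iterations >= 2,
            n_train >= 1, n_test >= 1, min_error_events >= 0,
            alpha_adjusted > 0, alpha_adjusted < 1)
  structure(
    list(k = k, n_train = as.integer(n_train), n_test = as.integer(n_test),
         iterations = as.integer(iterations),
         min_error_events = as.integer(min_error_events),
         one_peck_per_trial = isTRUE(one_peck_per_trial),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         alpha_adjusted = alpha_adjusted),
    class = "classifier_config"
  )
}

#' k-nearest-neighbour prediction
#'
#' Labels each test point by the majority vote of its `k` Euclidean-nearest
#' training points. Distance ties are broken by training-point insertion
#' order (with continuous coordinates ties have measure zero); with odd `k`
#' and binary labels a vote tie cannot occur, but if labels are not binary a
#' vote tie falls to the tied label of the nearest neighbour.
#'
#' @param train_points Numeric n x 2 matrix of training coordinates.
#' @param train_labels Character vector of training labels, parallel to rows.
#' @param test_points Numeric m x 2 matrix of test coordinates.
#' @param k Number of neighbours (`<= n`).
#' @return Character vector of m predicted labels.
#' @export
knn_predict <- function(train_points, train_labels, test_points, k = 15L) {
  train_points <- as.matrix(train_points)
  test_points <- as.matrix(test_points)
  n <- nrow(train_points)
  stopifnot(ncol(train_points) == 2, ncol(test_points) == 2,
            length(train_labels) == n)
  if (n < k) stop(sprintf("training set has %d points, fewer than k = %d", n, k),
                  call. = FALSE)
  train_labels <- as.character(train_labels)
  tx <- train_points[, 1]; ty <- train_points[, 2]
  vapply(seq_len(nrow(test_points)), function(i) {
    d2 <- (tx - test_points[i, 1])^2 + (ty - test_points[i, 2])^2
    nn <- order(d2)[seq_len(k)]  # stable: equal distances by insertion order
    votes <- train_labels[nn]
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else votes[votes %in% top][1L]
  }, character(1))
}

# Reduce a pool to one uniformly chosen peck per trial.
one_peck_reduction <- function(events) {
  idx <- unlist(lapply(split(seq_len(nrow(events)), events$trial_index),
                       function(i) if (length(i) == 1L) i else sample(i, 1L)),
                use.names = FALSE)
  events[sort(idx), , drop = FALSE]
}

# Sample n row indices from events, class-balanced when both classes have
# enough events, else plain SRS without replacement. `exclude` rows are
# unavailable.
draw_events <- function(events, n, exclude = integer(0)) {
  avail <- setdiff(seq_len(nrow(events)), exclude)
  if (length(avail) < n)
    stop(sprintf("insufficient events: need %d, have %d (shortfall %d)",
                 n, length(avail), n - length(avail)), call. = FALSE)
  cls <- events$stimulus_class[avail]
  half <- n %/% 2L
  if (all(CLASSES %in% cls) && all(table(factor(cls, levels = CLASSES)) >= half)) {
    ix <- avail[cls == "X"]; iy <- avail[cls == "Y"]
    out <- c(sample(ix, half), sample(iy, half))
    if (n %% 2L == 1L)
      out <- c(out, sample(setdiff(avail, out), 1L))
    out
  } else {
    sample(avail, n)
  }
}

#' Sample disjoint training and test sets from a pool
#'
#' Draws `n_train + n_test` distinct events without replacement and splits
#' them disjointly. When both classes are sufficiently represented the draw
#' is class-balanced. With `one_peck_per_trial` the pool is first reduced to
#' one randomly chosen peck per trial. Uses R's global RNG stream.
#'
#' @param pool A [select_pool()] result.
#' @param config A [classifier_config()].
#' @return List with data frames `train` and `test`.
#' @export
sample_train_test <- function(pool, config = classifier_config()) {
  ev <- pool$events
  if (config$one_peck_per_trial) ev <- one_peck_reduction(ev)
  i_train <- draw_events(ev, config$n_train)
  i_test <- draw_events(ev, config$n_test, exclude = i_train)
  list(train = ev[i_train, , drop = FALSE], test = ev[i_test, , drop = FALSE])
}

decode_accuracy <- function(train, test, k, shuffle = FALSE) {
  train_labels <- train$stimulus_class
  test_labels <- test$stimulus_class
  if (shuffle) {
    # permute labels against coordinates within both samples
    train_labels <- sample(train_labels)
    test_labels <- sample(test_labels)
  }
  pred <- knn_predict(cbind(train$x, train$y), train_labels,
                      cbind(test$x, test$y), k)
  100 * mean(pred == test_labels)
}

#' Run CC / CE / EE decoding
#'
#' Decodes the presented stimulus class from peck coordinates with a kNN
#' classifier and quantifies significance against a shuffled-label null.
#' Per iteration: fresh training and test samples are drawn (disjointly from
#' one pool in CC/EE mode, or independently from the correct-trial training
#' pool and the error-trial test pool in CE mode); the empirical accuracy is
#' the percentage of test pecks whose predicted label matches the presented
#' class; the shuffled accuracy repeats the procedure after randomly
#' permuting labels against coordinates within both samples. A paired t test
#' across iterations (df = iterations - 1, two-sided) compares empirical and
#' shuffled accuracies, with `cohen_d = mean(diff) / sd(diff)`.
#'
#' Verdicts: `above_chance` (p below alpha, empirical mean above shuffled) is
#' class-consistent pecking; in CE mode `below_chance` indicates class
#' confusion (errors peck the other class's features) and `at_chance`
#' pecking unrelated to the learned locations.
#'
#' CE and EE modes require the error pool to hold at least
#' `min_error_events`; otherwise an object of class `decoder_insufficient`
#' describing the shortfall is returned instead of a report.
#'
#' @param train_pool Pool supplying training events (correct-trial pecks for
#'   CC/CE, error-trial pecks for EE).
#' @param test_pool Pool supplying test events; defaults to `train_pool`
#'   (CC/EE). For CE pass the error pool here.
#' @param mode `"CC"`, `"CE"` or `"EE"`.
#' @param config A [classifier_config()]; its `seed` (if non-NULL) makes the
#'   run deterministic.
#' @return An object of class `decoder_report`: mode, per-iteration
#'   accuracies, means, paired `t`, `df`, `p`, `cohen_d` and `verdict` —
#'   or a `decoder_insufficient` object.
#' @examples
#' s <- generate_session(make_archetype("two_class"), generator_config(seed = 7))
#' pool <- select_pool(s, outcomes = "correct")
#' run_decoding(pool, mode = "CC", config = classifier_config(seed = 7))
#' @export
run_decoding <- function(train_pool, test_pool = train_pool,
                         mode = c("CC", "CE", "EE"),
                         config = classifier_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(train_pool, "peck_pool"), inherits(test_pool, "peck_pool"))
  same_pool <- identical(train_pool$events, test_pool$events)

  if (mode %in% c("CE", "EE")) {
    err_pool <- if (mode == "CE") test_pool else train_pool
    n_err <- pool_size(err_pool)
    if (n_err < config$min_error_events)
      return(structure(
        list(mode = mode, reason = sprintf(
          "insufficient error events: %d < %d", n_err, config$min_error_events),
          available = n_err, required = config$min_error_events),
        class = "decoder_insufficient"))
  }

  run <- function() {
    emp <- shf <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      if (same_pool) {
        st <- sample_train_test(train_pool, config)
      } else {
        ev_tr <- train_pool$events
        ev_te <- test_pool$events
        if (config$one_peck_per_trial) {
          ev_tr <- one_peck_reduction(ev_tr)
          ev_te <- one_peck_reduction(ev_te)
        }
        st <- list(train = ev_tr[draw_events(ev_tr, config$n_train), , drop = FALSE],
                   test = ev_te[draw_events(ev_te, config$n_test), , drop = FALSE])
      }
      emp[it] <- decode_accuracy(st$train, st$test, config$k)
      shf[it] <- decode_accuracy(st$train, st$test, config$k, shuffle = TRUE)
    }
    build_decoder_report(mode, emp, shf, config,
                         trial_type = train_pool$selector$trial_type)
  }
  if (is.null(config$seed)) run() else with_seed(config$seed, run())
}

build_decoder_report <- function(mode, emp, shf, config, trial_type = NULL) {
  d <- emp - shf
  sd_d <- stats::sd(d)
  if (sd_d > 0) {
    tt <- stats::t.test(emp, shf, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
    cohen_d <- mean(d) / sd_d
  } else {
    # degenerate: identical differences every iteration
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    cohen_d <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  }
  verdict <- if (p < config$alpha_adjusted && mean(emp) > mean(shf)) {
    "above_chance"
  } else if (p < config$alpha_adjusted && mean(emp) < mean(shf)) {
    "below_chance"
  } else "at_chance"
  structure(
    list(mode = mode,
         trial_type = if (is.null(trial_type)) NA_character_ else trial_type,
         iterations = data.frame(accuracy_empirical = emp,
                                 accuracy_shuffled = shf),
         mean_accuracy = mean(emp), mean_shuffled = mean(shf),
         t = t_stat, df = config$iterations - 1L, p = p, cohen_d = cohen_d,
         verdict = verdict, config = config),
    class = "decoder_report"
  )
}

#' @export
print.decoder_report <- function(x, ...) {
  cat(sprintf("%s decoding: mean accuracy %.2f%% (shuffled %.2f%%) over %d iterations\n",
              x$mode, x$mean_accuracy, x$mean_shuffled, nrow(x$iterations)))
  cat(sprintf("  paired t(%d) = %.2f, p = %.4g, Cohen's d = %.2f -> %s\n",
              x$df, x$t, x$p, x$cohen_d, x$verdict))
  invisible(x)
}

#' @export
summary.decoder_report <- function(object, ...) {
  print(object)
  it <- object$iterations
  cat(sprintf("  empirical: min %.2f / median %.2f / max %.2f\n",
              min(it$accuracy_empirical), stats::median(it$accuracy_empirical),
              max(it$accuracy_empirical)))
  cat(sprintf("  shuffled:  min %.2f / median %.2f / max %.2f\n",
              min(it$accuracy_shuffled), stats::median(it$accuracy_shuffled),
              max(it$accuracy_shuffled)))
  invisible(object)
}

#' @export
print.decoder_insufficient <- function(x, ...) {
  cat(sprintf("%s decoding skipped: %s\n", x$mode, x$reason))
  invisible(x)
}

#' Decoding by peck order
#'
#' Runs a CC decoding separately for the i-th peck of each trial
#' (i in `ranks`), probing how quickly pecking settles on class-informative
#' locations: if early pecks are orienting pecks, rank-1 accuracy is lower
#' than later ranks. When a rank has fewer than `2 * n_train` events, the
#' sample sizes are reduced to `floor(available / 2)` each (minimum 50) and
#' the reduction is recorded; ranks with fewer than 100 events are skipped.
#'
#' @param pool Correct-trial peck pool.
#' @param config A [classifier_config()].
#' @param ranks Peck indices to analyze.
#' @return An object of class `peck_order_result`: list of per-rank entries,
#'   each either a `decoder_report` (with `rank` and `n_per_set` fields) or
#'   a skip notice.
#' @export
peck_order_decoding <- function(pool, config = classifier_config(),
                                ranks = 1:5) {
  stopifnot(inherits(pool, "peck_pool"))
  results <- lapply(ranks, function(r) {
    ev <- pool$events[pool$events$peck_index == r, , drop = FALSE]
    if (nrow(ev) < 100)
      return(list(rank = r, skipped = TRUE,
                  reason = sprintf("only %d events at peck rank %d (< 100)",
                                   nrow(ev), r)))
    cfg <- config
    if (nrow(ev) < config$n_train + config$n_test) {
      n_each <- max(50L, nrow(ev) %/% 2L)
      cfg <- classifier_config(
        k = config$k, n_train = n_each, n_test = n_each,
        iterations = config$iterations,
        min_error_events = config$min_error_events,
        one_peck_per_trial = FALSE, seed = config$seed,
        alpha_adjusted = config$alpha_adjusted)
    }
    sub <- pool
    sub$events <- ev
    rep <- run_decoding(sub, mode = "CC", config = cfg)
    rep$rank <- r
    rep$n_per_set <- c(train = cfg$n_train, test = cfg$n_test)
    rep$reduced <- cfg$n_train < config$n_train
    rep
  })
  structure(list(ranks = ranks, results = results), class = "peck_order_result")
}

#' @export
print.peck_order_result <- function(x, ...) {
  cat("CC decoding by peck order:\n")
  for (res in x$results) {
    if (isTRUE(res$skipped)) {
      cat(sprintf("  rank %d: skipped (%s)\n", res$rank, res$reason))
    } else {
      cat(sprintf("  rank %d: %.2f%% (shuffled %.2f%%)%s\n", res$rank,
                  res$mean_accuracy, res$mean_shuffled,
                  if (isTRUE(res$reduced))
                    sprintf(" [reduced to %d/%d]", res$n_per_set["train"],
                            res$n_per_set["test"]) else ""))
    }
  }
  invisible(x)
}
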