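# Shared fixtures: hand-built sessions and an independent brute-force kNN
# oracle used to validate the package implementation.

peck_df <- function(xs, ys) {
  data.frame(x = xs, y = ys, peck_index = seq_along(xs))
}

# n_trials per class, all pecks at fixed per-class locations
tiny_session <- function(n_per_class = 10, n_pecks = 5,
                         at_X = c(2.5, 2.5), at_Y = c(2.5, 2.5),
                         outcome = "correct", trial_type = "known",
                         subject = "t1") {
  mk <- function(i, cls, at) {
    choice <- if (outcome == "correct") cls else
      if (outcome == "error") setdiff(c("X", "Y"), cls) else "none"
    peck_trial(i, cls, peck_df(rep(at[1], n_pecks), rep(at[2], n_pecks)),
               phase = if (trial_type == "transfer") "transfer_test" else "learning",
               trial_type = trial_type, choice = choice, outcome = outcome)
  }
  trials <- c(lapply(seq_len(n_per_class), mk, cls = "X", at = at_X),
              lapply(n_per_class + seq_len(n_per_class), mk, cls = "Y",
                     at = at_Y))
  peck_session(subject, "s1", trials)
}

# Independent kNN oracle: literal per-point full sort over a data frame,
# deliberately structured differently from the package implementation.
brute_knn <- function(train_points, train_labels, test_points, k) {
  apply(test_points, 1, function(q) {
    d <- sqrt(rowSums(sweep(train_points, 2, q)^2))
    tab <- data.frame(d = d, i = seq_along(d), lab = train_labels)
    tab <- tab[order(tab$d, tab$i), ]
    votes <- tab$lab[1:k]
    counts <- sort(table(votes), decreasing = TRUE)
    winners <- names(counts)[counts == counts[1]]
    if (length(winners) == 1) winners else votes[votes %in% winners][1]
  })
}

# Pool built directly from an event data frame (bypasses session plumbing)
pool_from_events <- function(events, geometry = display_geometry()) {
  structure(list(events = events,
                 selector = list(phase = NULL, trial_type = NULL,
                                 outcomes = c("correct", "error"),
                                 classes = c("X", "Y")),
                 geometry = geometry),
            class = "peck_pool")
}

random_pool <- function(n, seed, labels_independent = TRUE) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 5), y = runif(n, 0, 5),
             trial_index = seq_len(n),
             stimulus_class = sample(c("X", "Y"), n, replace = TRUE),
             outcome = "correct", peck_index = 1L) |> pool_from_events()
}
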