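## Data model for per-peck behavioral logs: trials nested in sessions, with
## stimulus class, choice and outcome metadata, plus the CSV log format.

PHASES <- c("learning", "transfer_test")
TRIAL_TYPES <- c("known", "transfer")
CLASSES <- c("X", "Y")
CHOICES <- c("X", "Y", "none")
OUTCOMES <- c("correct", "error", "aborted", "no_choice")
REINFORCEMENTS <- c("differential", "nondifferential", "none")

LOG_COLUMNS <- c("subject_id", "session_id", "phase", "trial_index",
                 "trial_type", "stimulus_id", "stimulus_class",
                 "reinforcement", "choice", "outcome", "peck_index",
                 "x_cm", "y_cm", "timestamp_ms")

other_class <- function(cls) ifelse(cls == "X", "Y", "X")

check_enum <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0)
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

#' Construct a single trial
#'
#' A trial holds its metadata and an ordered data frame of pecks with columns
#' `x`, `y` (cm from the bottom-left corner of the registration region),
#' `peck_index` (1-based order within the trial) and optional `timestamp_ms`.
#'
#' Trials with fewer than 5 pecks but a recorded choice are accepted with a
#' validation warning (a conforming apparatus aborts such trials); the
#' `outcome` must be `"correct"` exactly when the choice matches the stimulus
#' class.
#'
#' @param trial_index Integer index, unique within a session.
#' @param stimulus_class `"X"` or `"Y"`.
#' @param pecks Data frame with columns `x`, `y`, `peck_index` and optionally
#'   `timestamp_ms`.
#' @param phase `"learning"` or `"transfer_test"`.
#' @param trial_type `"known"` or `"transfer"`.
#' @param stimulus_id Identifier of the presented exemplar.
#' @param choice `"X"`, `"Y"` or `"none"` (choice window elapsed).
#' @param outcome `"correct"`, `"error"`, `"aborted"` or `"no_choice"`.
#' @param reinforcement `"differential"`, `"nondifferential"` or `"none"`.
#' @return An object of class `peck_trial`.
#' @export
peck_trial <- function(trial_index, stimulus_class, pecks,
                       phase = "learning", trial_type = "known",
                       stimulus_id = NA_character_, choice = stimulus_class,
                       outcome = if (identical(choice, stimulus_class)) "correct" else "error",
                       reinforcement = "differential") {
  check_enum(phase, PHASES, "phase")
  check_enum(trial_type, TRIAL_TYPES, "trial_type")
  check_enum(stimulus_class, CLASSES, "stimulus_class")
  check_enum(choice, CHOICES, "choice")
  check_enum(outcome, OUTCOMES, "outcome")
  check_enum(reinforcement, REINFORCEMENTS, "reinforcement")
  stopifnot(is.data.frame(pecks), all(c("x", "y", "peck_index") %in% names(pecks)))
  if (!"timestamp_ms" %in% names(pecks)) pecks$timestamp_ms <- NA_integer_
  if (nrow(pecks) > 0) {
    if (any(pecks$peck_index < 1)) stop("peck_index must be >= 1")
    if (anyDuplicated(pecks$peck_index))
      stop(sprintf("duplicate peck_index in trial %s", trial_index))
    pecks <- pecks[order(pecks$peck_index), , drop = FALSE]
    rownames(pecks) <- NULL
  }
  consistent <- (outcome == "correct") == identical(choice, stimulus_class)
  if (outcome %in% c("correct", "error") && !consistent)
    stop(sprintf("trial %s: outcome '%s' inconsistent with choice '%s' for class '%s'",
                 trial_index, outcome, choice, stimulus_class))
  if (outcome != "aborted" && nrow(pecks) < 5)
    warning(sprintf("trial %s has %d pecks (< 5) but was not aborted",
                    trial_index, nrow(pecks)), call. = FALSE)
  structure(
    list(trial_index = as.integer(trial_index), phase = phase,
         trial_type = trial_type, stimulus_id = as.character(stimulus_id),
         stimulus_class = stimulus_class, choice = choice, outcome = outcome,
         reinforcement = reinforcement, pecks = pecks),
    class = "peck_trial"
  )
}

#' Construct a session
#'
#' @param subject_id,session_id Identifiers.
#' @param trials List of [peck_trial()] objects with unique trial indices.
#' @param geometry A [display_geometry()].
#' @return An object of class `peck_session`.
#' @export
peck_session <- function(subject_id, session_id, trials,
                         geometry = display_geometry()) {
  stopifnot(inherits(geometry, "display_geometry"), is.list(trials))
  idx <- vapply(trials, function(t) t$trial_index, integer(1))
  if (anyDuplicated(idx))
    stop(sprintf("duplicate trial_index in session %s: %s", session_id,
                 paste(idx[duplicated(idx)], collapse = ", ")))
  structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         geometry = geometry, trials = trials),
    class = "peck_session"
  )
}

#' @export
print.peck_session <- function(x, ...) {
  out <- table(factor(vapply(x$trials, `[[`, "", "outcome"), levels = OUTCOMES))
  npecks <- sum(vapply(x$trials, function(t) nrow(t$pecks), integer(1)))
  cat(sprintf("Peck session %s / subject %s: %d trials (%s), %d pecks\n",
              x$session_id, x$subject_id, length(x$trials),
              paste(sprintf("%d %s", out, names(out))[out > 0], collapse = ", "),
              npecks))
  invisible(x)
}

session_pecks_df <- function(session) {
  rows <- lapply(session$trials, function(tr) {
    n <- nrow(tr$pecks)
    if (n == 0) return(NULL)
    data.frame(x = tr$pecks$x, y = tr$pecks$y,
               trial_index = rep(tr$trial_index, n),
               stimulus_class = rep(tr$stimulus_class, n),
               outcome = rep(tr$outcome, n),
               peck_index = tr$pecks$peck_index,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0),
                      trial_index = integer(0), stimulus_class = character(0),
                      outcome = character(0), peck_index = integer(0))
  out
}

#' Read a peck log
#'
#' Reads a CSV peck log (one row per peck; trial-level fields repeated on
#' every row) into a list of sessions. The required header is
#' `subject_id,session_id,phase,trial_index,trial_type,stimulus_id,`
#' `stimulus_class,reinforcement,choice,outcome,peck_index,x_cm,y_cm,timestamp_ms`;
#' `timestamp_ms` may be empty. Enumerations are validated, pecks are ordered
#' by `peck_index` within trial, and duplicate `(trial, peck_index)` pairs are
#' an error. Non-aborted trials with fewer than 5 pecks raise a warning.
#'
#' @param source Path to a CSV file, or a connection.
#' @param geometry Geometry to attach to each session.
#' @return A list of [peck_session()] objects.
#' @seealso [write_peck_log()]
#' @export
read_peck_log <- function(source, geometry = display_geometry()) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(LOG_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("peck log is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in c("x_cm", "y_cm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(is.na(v)) && any(is.na(v)))
      bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric %s at data row(s) %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    df[[col]] <- v
  }
  df$trial_index <- as.integer(df$trial_index)
  df$peck_index <- as.integer(df$peck_index)
  df$timestamp_ms <- suppressWarnings(as.integer(df$timestamp_ms))
  check_enum(df$phase, PHASES, "phase")
  check_enum(df$trial_type, TRIAL_TYPES, "trial_type")
  check_enum(df$stimulus_class, CLASSES, "stimulus_class")
  check_enum(df$choice, CHOICES, "choice")
  check_enum(df$outcome, OUTCOMES, "outcome")
  check_enum(df$reinforcement, REINFORCEMENTS, "reinforcement")

  key <- paste(df$subject_id, df$session_id, df$trial_index, df$peck_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate (trial, peck_index): %s", d), call. = FALSE)
  }

  sess_key <- paste(df$subject_id, df$session_id, sep = "\r")
  sessions <- lapply(split(df, factor(sess_key, levels = unique(sess_key))),
    function(sdf) {
      trials <- lapply(split(sdf, factor(sdf$trial_index,
                                         levels = unique(sdf$trial_index))),
        function(tdf) {
          peck_trial(
            trial_index = tdf$trial_index[1],
            stimulus_class = tdf$stimulus_class[1],
            pecks = data.frame(x = tdf$x_cm, y = tdf$y_cm,
                               peck_index = tdf$peck_index,
                               timestamp_ms = tdf$timestamp_ms),
            phase = tdf$phase[1], trial_type = tdf$trial_type[1],
            stimulus_id = tdf$stimulus_id[1], choice = tdf$choice[1],
            outcome = tdf$outcome[1], reinforcement = tdf$reinforcement[1])
        })
      trials <- trials[order(vapply(trials, `[[`, integer(1), "trial_index"))]
      names(trials) <- NULL
      peck_session(sdf$subject_id[1], sdf$session_id[1], trials, geometry)
    })
  names(sessions) <- NULL
  sessions
}

#' Write a peck log
#'
#' Serializes sessions to the CSV peck-log format read by [read_peck_log()].
#'
#' @param sessions A single session or a list of [peck_session()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peck_log <- function(sessions, path) {
  if (inherits(sessions, "peck_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    do.call(rbind, lapply(s$trials, function(tr) {
      n <- nrow(tr$pecks)
      if (n == 0) return(NULL)
      data.frame(subject_id = s$subject_id, session_id = s$session_id,
                 phase = tr$phase, trial_index = tr$trial_index,
                 trial_type = tr$trial_type, stimulus_id = tr$stimulus_id,
                 stimulus_class = tr$stimulus_class,
                 reinforcement = tr$reinforcement, choice = tr$choice,
                 outcome = tr$outcome, peck_index = tr$pecks$peck_index,
                 x_cm = tr$pecks$x, y_cm = tr$pecks$y,
                 timestamp_ms = tr$pecks$timestamp_ms,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Discard pecks outside the registration region
#'
#' Pecks outside the stimulus/border area are discarded before any analysis.
#' Bounds are closed: a peck exactly on the region edge is retained.
#'
#' @param session A [peck_session()].
#' @return A list with elements `session` (the filtered session) and
#'   `discarded_count` (number of removed pecks).
#' @export
filter_pecks_in_bounds <- function(session) {
  stopifnot(inherits(session, "peck_session"))
  side <- session$geometry$region_side
  discarded <- 0L
  trials <- lapply(session$trials, function(tr) {
    keep <- tr$pecks$x >= 0 & tr$pecks$x <= side &
            tr$pecks$y >= 0 & tr$pecks$y <= side
    discarded <<- discarded + sum(!keep)
    tr$pecks <- tr$pecks[keep, , drop = FALSE]
    rownames(tr$pecks) <- NULL
    tr
  })
  out <- session
  out$trials <- trials
  list(session = out, discarded_count = discarded)
}

#' Pool pecks across trials matching a set of filters
#'
#' Collapses in-bounds pecks across all stimuli of the selected classes and
#' trial kinds into a single pool of events; this is the unit every spatial
#' and decoding analysis operates on. Aborted and no-choice trials are always
#' excluded.
#'
#' @param sessions A session or a list of sessions (all sharing a geometry).
#' @param phase Optional filter: `"learning"` or `"transfer_test"`.
#' @param trial_type Optional filter: `"known"` or `"transfer"`.
#' @param outcomes Outcomes to include; subset of `c("correct", "error")`.
#' @param classes Stimulus classes to include; subset of `c("X", "Y")`.
#' @return An object of class `peck_pool`: list with `events` (data frame with
#'   columns `x`, `y`, `trial_index`, `stimulus_class`, `outcome`,
#'   `peck_index`), `selector` (the filters applied) and `geometry`.
#' @export
select_pool <- function(sessions, phase = NULL, trial_type = NULL,
                        outcomes = c("correct", "error"),
                        classes = c("X", "Y")) {
  if (inherits(sessions, "peck_session")) sessions <- list(sessions)
  stopifnot(length(sessions) > 0)
  check_enum(outcomes, c("correct", "error"), "outcomes")
  check_enum(classes, CLASSES, "classes")
  if (!is.null(phase)) check_enum(phase, PHASES, "phase")
  if (!is.null(trial_type)) check_enum(trial_type, TRIAL_TYPES, "trial_type")
  geometry <- sessions[[1]]$geometry

  events <- do.call(rbind, lapply(sessions, function(s) {
    s <- filter_pecks_in_bounds(s)$session
    keep <- vapply(s$trials, function(tr) {
      tr$outcome %in% outcomes &&
        tr$stimulus_class %in% classes &&
        (is.null(phase) || tr$phase %in% phase) &&
        (is.null(trial_type) || tr$trial_type %in% trial_type)
    }, logical(1))
    s$trials <- s$trials[keep]
    session_pecks_df(s)
  }))
  structure(
    list(events = events,
         selector = list(phase = phase, trial_type = trial_type,
                         outcomes = outcomes, classes = classes),
         geometry = geometry),
    class = "peck_pool"
  )
}

#' @export
print.peck_pool <- function(x, ...) {
  sel <- x$selector
  cat(sprintf("Peck pool: %d events [phase=%s, trial_type=%s, outcomes={%s}, classes={%s}]\n",
              nrow(x$events),
              if (is.null(sel$phase)) "any" else paste(sel$phase, collapse = "/"),
              if (is.null(sel$trial_type)) "any" else paste(sel$trial_type, collapse = "/"),
              paste(sel$outcomes, collapse = ","),
              paste(sel$classes, collapse = ",")))
  invisible(x)
}

pool_size <- function(pool) nrow(pool$events)
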