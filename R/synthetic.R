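## Synthetic session generator: pecking-strategy archetypes with Gaussian
## class-specific peck clusters, orienting pecks and configurable error-trial
## models, so the full analysis pipeline can be validated without raw data.

ARCHETYPES <- c("two_class", "one_class", "lateralized", "confusion",
                "lapse", "random_error")
ERROR_MODELS <- c("none", "dispersed", "swapped", "uniform")
LEARNED <- c("both", "only_X", "neither")

#' Strategy profile for the synthetic generator
#'
#' A strategy profile is the generative description of a simulated subject:
#' where it pecks on each stimulus class when it responds correctly, how its
#' error-trial pecking differs, and the trial-level statistics of a session.
#' Correct-trial pecks are isotropic 2D Gaussians around a class-specific
#' center, truncated to the registration region by resampling; the first
#' `orienting_pecks` pecks of every trial are drawn from a broad Gaussian
#' around the region center instead (early pecks carry less class
#' information).
#'
#' Error-trial peck models:
#' \describe{
#'   \item{`none`}{errors peck the correct class's features (a choice lapse).}
#'   \item{`dispersed`}{same class center but spread `sd_error` (less focused).}
#'   \item{`swapped`}{the opposite class's center (class confusion).}
#'   \item{`uniform`}{uniform over the region (pecking unrelated to class).}
#' }
#'
#' @param center_X,center_Y Length-2 numeric peck centers (cm) for class X /
#'   class Y trials.
#' @param sd_correct Isotropic Gaussian sd (cm) of correct-trial pecks.
#' @param error_model One of `"none"`, `"dispersed"`, `"swapped"`, `"uniform"`.
#' @param sd_error Gaussian sd (cm) used by the `dispersed` error model.
#' @param learned_classes `"both"`, `"only_X"` (class-Y trials peck uniformly)
#'   or `"neither"` (one shared center regardless of class).
#' @param orienting_pecks Number of initial broad orienting pecks per trial.
#' @param orienting_sd Sd (cm) of orienting pecks around the region center.
#' @param p_correct Probability that a trial's choice is correct.
#' @param pecks_per_trial_mean Mean pecks per trial; realized counts are
#'   `5 + Poisson(mean - 5)` so every trial is valid.
#' @param n_trials Trials per generated session.
#' @param transfer_fraction Fraction of trials flagged as transfer trials.
#' @return An object of class `strategy_profile`.
#' @seealso [make_archetype()], [generate_session()]
#' @export
strategy_profile <- function(center_X = c(1.5, 2.5), center_Y = c(3.5, 2.5),
                             sd_correct = 0.4, error_model = "none",
                             sd_error = 1.2, learned_classes = "both",
                             orienting_pecks = 0L, orienting_sd = 1.5,
                             p_correct = 0.92, pecks_per_trial_mean = 8,
                             n_trials = 400L, transfer_fraction = 0.11) {
  check_enum(error_model, ERROR_MODELS, "error_model")
  check_enum(learned_classes, LEARNED, "learned_classes")
  stopifnot(length(center_X) == 2, length(center_Y) == 2,
            sd_correct > 0, sd_error > 0,
            p_correct >= 0, p_correct <= 1,
            pecks_per_trial_mean >= 5,
            orienting_pecks >= 0, orienting_sd > 0,
            n_trials >= 1,
            transfer_fraction >= 0, transfer_fraction <= 1)
  if (learned_classes == "neither") center_Y <- center_X
  structure(
    list(center_X = as.numeric(center_X), center_Y = as.numeric(center_Y),
         sd_correct = sd_correct, error_model = error_model,
         sd_error = sd_error, learned_classes = learned_classes,
         orienting_pecks = as.integer(orienting_pecks),
         orienting_sd = orienting_sd, p_correct = p_correct,
         pecks_per_trial_mean = pecks_per_trial_mean,
         n_trials = as.integer(n_trials),
         transfer_fraction = transfer_fraction),
    class = "strategy_profile"
  )
}

#' @export
print.strategy_profile <- function(x, ...) {
  cat(sprintf(
    "Strategy profile: centers X(%.2g, %.2g) / Y(%.2g, %.2g) cm, sd %.2g cm\n  learned: %s, error model: %s (sd %.2g), p_correct %.2f\n  %d trials, ~%.3g pecks/trial, %d orienting peck(s), transfer fraction %.2f\n",
    x$center_X[1], x$center_X[2], x$center_Y[1], x$center_Y[2], x$sd_correct,
    x$learned_classes, x$error_model, x$sd_error, x$p_correct,
    x$n_trials, x$pecks_per_trial_mean, x$orienting_pecks,
    x$transfer_fraction))
  invisible(x)
}

#' Named pecking-strategy archetypes
#'
#' Builds a fully specified [strategy_profile()] for one of the pecking
#' strategies a class decoder can distinguish:
#' \describe{
#'   \item{`two_class`}{distinct peck centers for both classes; errors are
#'     dispersed around the correct center (high CC decoding, EE above
#'     chance).}
#'   \item{`one_class`}{class-specific pecking only on class X; class-Y
#'     trials peck uniformly (intermediate CC decoding).}
#'   \item{`lateralized`}{one shared center regardless of class, e.g. always
#'     pecking the left side (CC decoding at chance).}
#'   \item{`confusion`}{errors peck the opposite class's features (CE
#'     decoding below chance).}
#'   \item{`lapse`}{errors peck the correct class's features, only the choice
#'     was wrong (CE above chance).}
#'   \item{`random_error`}{errors peck uniformly (CE and EE at chance).}
#' }
#'
#' @param name Archetype name.
#' @param ... Overrides passed to [strategy_profile()] (e.g. `n_trials`,
#'   `p_correct`, `seed`-independent settings).
#' @return A `strategy_profile`.
#' @examples
#' make_archetype("lateralized")$center_Y  # equals center_X
#' @export
make_archetype <- function(name, ...) {
  name <- match.arg(name, ARCHETYPES)
  base <- switch(name,
    two_class    = list(error_model = "dispersed"),
    one_class    = list(error_model = "dispersed", learned_classes = "only_X"),
    lateralized  = list(error_model = "none", learned_classes = "neither"),
    confusion    = list(error_model = "swapped"),
    lapse        = list(error_model = "none"),
    random_error = list(error_model = "uniform"))
  base$orienting_pecks <- 1L
  args <- utils::modifyList(base, list(...))
  do.call(strategy_profile, args)
}

#' Generator configuration
#'
#' @param seed Integer seed; identical (profile, config) pairs yield
#'   identical sessions.
#' @param geometry A [display_geometry()].
#' @param class_balance Probability that a trial shows class X.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, geometry = display_geometry(),
                             class_balance = 0.5) {
  stopifnot(inherits(geometry, "display_geometry"),
            class_balance >= 0, class_balance <= 1)
  structure(list(seed = as.integer(seed), geometry = geometry,
                 class_balance = class_balance),
            class = "generator_config")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# One truncated isotropic Gaussian draw inside [0, side]^2.
rnorm2_truncated <- function(center, sd, side, max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    p <- stats::rnorm(2, mean = center, sd = sd)
    if (p[1] >= 0 && p[1] <= side && p[2] >= 0 && p[2] <= side) return(p)
  }
  stop(sprintf("could not draw an in-bounds peck around (%.3g, %.3g) with sd %.3g after %d attempts",
               center[1], center[2], sd, max_attempts), call. = FALSE)
}

#' Draw one peck location under a strategy profile
#'
#' The sampling unit of [generate_session()]: draws a single in-bounds peck
#' for a trial of the given class and outcome. Uses R's global RNG stream.
#'
#' @param profile A [strategy_profile()].
#' @param class Stimulus class of the trial, `"X"` or `"Y"`.
#' @param outcome `"correct"` or `"error"`.
#' @param peck_index 1-based peck order; indices `<= orienting_pecks` are
#'   drawn from the broad orienting distribution.
#' @param geometry A [display_geometry()].
#' @return Numeric length-2 vector `(x, y)` in cm.
#' @export
sample_peck <- function(profile, class, outcome, peck_index,
                        geometry = display_geometry()) {
  check_enum(class, CLASSES, "class")
  side <- geometry$region_side
  if (peck_index <= profile$orienting_pecks)
    return(rnorm2_truncated(c(side / 2, side / 2), profile$orienting_sd, side))

  runif_region <- function() stats::runif(2, 0, side)
  center_of <- function(cls) if (cls == "X") profile$center_X else profile$center_Y

  if (outcome == "correct") {
    if (profile$learned_classes == "only_X" && class == "Y") return(runif_region())
    return(rnorm2_truncated(center_of(class), profile$sd_correct, side))
  }
  # error trial
  switch(profile$error_model,
    none      = rnorm2_truncated(center_of(class), profile$sd_correct, side),
    dispersed = rnorm2_truncated(center_of(class), profile$sd_error, side),
    swapped   = rnorm2_truncated(center_of(other_class(class)),
                                 profile$sd_correct, side),
    uniform   = runif_region())
}

#' Generate a synthetic session
#'
#' Simulates a full behavioral session under a strategy profile: class drawn
#' with `class_balance`, outcome correct with probability `p_correct`,
#' `5 + Poisson(mean - 5)` pecks per trial placed by [sample_peck()], choice
#' consistent with the outcome, and `transfer_fraction` of trials flagged as
#' transfer trials (non-differentially reinforced, `phase = "transfer_test"`).
#' Deterministic given `(profile, config)`.
#'
#' @param profile A [strategy_profile()].
#' @param config A [generator_config()].
#' @param subject_id,session_id Identifiers stored on the session.
#' @return A [peck_session()].
#' @examples
#' s <- generate_session(make_archetype("two_class"), generator_config(seed = 1))
#' length(s$trials)
#' @export
generate_session <- function(profile, config = generator_config(),
                             subject_id = "sim", session_id = "s1") {
  stopifnot(inherits(profile, "strategy_profile"),
            inherits(config, "generator_config"))
  geometry <- config$geometry
  with_seed(config$seed, {
    n <- profile$n_trials
    classes <- ifelse(stats::runif(n) < config$class_balance, "X", "Y")
    correct <- stats::runif(n) < profile$p_correct
    is_transfer <- stats::runif(n) < profile$transfer_fraction
    n_pecks <- 5L + stats::rpois(n, profile$pecks_per_trial_mean - 5)
    trials <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- classes[i]
      outc <- if (correct[i]) "correct" else "error"
      xy <- t(vapply(seq_len(n_pecks[i]), function(j)
        sample_peck(profile, cls, outc, j, geometry), numeric(2)))
      trials[[i]] <- peck_trial(
        trial_index = i, stimulus_class = cls,
        pecks = data.frame(x = xy[, 1], y = xy[, 2],
                           peck_index = seq_len(n_pecks[i])),
        phase = if (is_transfer[i]) "transfer_test" else "learning",
        trial_type = if (is_transfer[i]) "transfer" else "known",
        stimulus_id = sprintf("stim_%s_%02d", cls, 1L + (i %% 30L)),
        choice = if (correct[i]) cls else other_class(cls),
        outcome = outc,
        reinforcement = if (is_transfer[i]) "nondifferential" else "differential")
    }
    peck_session(subject_id, session_id, trials, geometry)
  })
}
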