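## Pre-experiment stimulus screen: pixelwise Pearson correlation between
## candidate grayscale renders, selection of the least cross-class-correlated
## exemplars, and a size / black-area confound check on the selected set.

#' Construct a stimulus image
#'
#' @param pixels Numeric H x W matrix of grayscale intensities in 0-255.
#' @param id Identifier.
#' @param class_label `"X"` or `"Y"`.
#' @return An object of class `stimulus_image`.
#' @export
stimulus_image <- function(pixels, id, class_label) {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            all(pixels >= 0), all(pixels <= 255))
  check_enum(class_label, CLASSES, "class_label")
  structure(list(id = as.character(id), class_label = class_label,
                 pixels = pixels),
            class = "stimulus_image")
}

#' Read a grayscale stimulus image
#'
#' Reads PNG (via the png package; RGB(A) channels are averaged to
#' grayscale) or plain-text PGM (P2). Intensities are returned on 0-255.
#'
#' @param path Image file path (`.png` or `.pgm`).
#' @param id Identifier; defaults to the file name without extension.
#' @param class_label `"X"` or `"Y"`.
#' @return A [stimulus_image()].
#' @export
read_stimulus_image <- function(path, id = NULL, class_label) {
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  pixels <- switch(ext,
    png = {
      a <- png::readPNG(path)
      m <- if (length(dim(a)) == 3) apply(a[, , seq_len(min(3, dim(a)[3])),
                                            drop = FALSE], c(1, 2), mean) else a
      m * 255
    },
    pgm = read_pgm_p2(path),
    stop(sprintf("unsupported image format: .%s (use .png or .pgm)", ext),
         call. = FALSE))
  stimulus_image(pixels, id, class_label)
}

# Plain-text (P2) PGM reader; rescales to 0-255 if maxval differs.
read_pgm_p2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- scan(text = paste(lines, collapse = " "), what = character(),
                 quiet = TRUE)
  if (tokens[1] != "P2") stop("only plain-text (P2) PGM is supported",
                              call. = FALSE)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.numeric(tokens[4])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count does not match header",
                                  call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval)
}

#' Pixelwise Pearson correlation between two images
#'
#' Pearson correlation over the flattened pixel vectors of two equally sized
#' grayscale images; symmetric and invariant to affine intensity rescaling.
#'
#' @param a,b [stimulus_image()] objects of equal dimensions, each with
#'   non-zero pixel variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pixelwise_correlation <- function(a, b) {
  stopifnot(inherits(a, "stimulus_image"), inherits(b, "stimulus_image"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop(sprintf("image dimensions differ: %s vs %s",
                 paste(dim(a$pixels), collapse = "x"),
                 paste(dim(b$pixels), collapse = "x")), call. = FALSE)
  va <- as.vector(a$pixels); vb <- as.vector(b$pixels)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant image: pixelwise correlation undefined", call. = FALSE)
  stats::cor(va, vb)
}

#' Select the least cross-class-correlated stimuli
#'
#' Scores each candidate by the aggregate (default: mean) of its pixelwise
#' correlations to all members of the other class, and keeps the `n_select`
#' lowest-scoring per class (ties broken by id). Low cross-class correlation
#' makes the two classes hard to separate by raw pixel overlap, so the
#' categorization must rely on class features. A size / black-area confound
#' check ([confound_check()]) is run on the selected set.
#'
#' @param class_a,class_b Lists of [stimulus_image()] (one class each),
#'   sharing dimensions.
#' @param n_select Number to keep per class.
#' @param aggregate `"mean"` (default) or `"max"` of cross-class
#'   correlations.
#' @param black_threshold Intensity at or below which a pixel counts as
#'   black background, passed to [confound_check()].
#' @return An object of class `selection_report`: `scores` (data frame with
#'   `id`, `class`, `score`, `selected`), `selected_a` / `selected_b`
#'   (lists of selected images), and `confound` (see [confound_check()]).
#' @export
select_stimuli <- function(class_a, class_b, n_select = 30,
                           aggregate = c("mean", "max"),
                           black_threshold = 10) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else max
  stopifnot(length(class_a) >= n_select, length(class_b) >= n_select)

  cross <- vapply(class_a, function(a)
    vapply(class_b, function(b) pixelwise_correlation(a, b), numeric(1)),
    numeric(length(class_b)))
  cross <- matrix(cross, nrow = length(class_b))
  # cross[j, i] = cor(class_a[[i]], class_b[[j]])
  score_a <- apply(cross, 2, agg)
  score_b <- apply(cross, 1, agg)

  pick <- function(images, scores, n) {
    ids <- vapply(images, `[[`, "", "id")
    ord <- order(scores, ids)
    sort(ord[seq_len(n)])
  }
  ia <- pick(class_a, score_a, n_select)
  ib <- pick(class_b, score_b, n_select)
  selected_a <- class_a[ia]
  selected_b <- class_b[ib]

  scores <- data.frame(
    id = c(vapply(class_a, `[[`, "", "id"), vapply(class_b, `[[`, "", "id")),
    class = c(vapply(class_a, `[[`, "", "class_label"),
              vapply(class_b, `[[`, "", "class_label")),
    score = c(score_a, score_b),
    selected = c(seq_along(class_a) %in% ia, seq_along(class_b) %in% ib),
    stringsAsFactors = FALSE)

  structure(
    list(scores = scores, selected_a = selected_a, selected_b = selected_b,
         n_select = n_select, aggregate = aggregate,
         confound = confound_check(c(selected_a, selected_b),
                                   black_threshold = black_threshold)),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Stimulus selection: %d per class kept (%s cross-class correlation)\n",
              x$n_select, x$aggregate))
  for (cls in CLASSES) {
    sc <- x$scores[x$scores$class == cls, ]
    cat(sprintf("  class %s: score range %.3f..%.3f, selected max %.3f\n",
                cls, min(sc$score), max(sc$score),
                max(sc$score[sc$selected])))
  }
  cat(sprintf("  confound: object size t(%s) = %.2f (p = %.3g); black area t(%s) = %.2f (p = %.3g)\n",
              format(x$confound$object_size$df, digits = 3),
              x$confound$object_size$t, x$confound$object_size$p,
              format(x$confound$black_area$df, digits = 3),
              x$confound$black_area$t, x$confound$black_area$p))
  invisible(x)
}

welch_t <- function(a, b) {
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    # both groups constant: t is 0 when means agree, infinite otherwise
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0, df = NA_real_))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Size / black-area confound check
#'
#' Verifies that the selected stimulus classes cannot be told apart by
#' trivial low-level cues: per image it counts object pixels (intensity
#' above `black_threshold`) and background black pixels (at or below), and
#' runs a two-sample t test between classes on each measure.
#'
#' @param selected List of [stimulus_image()] covering both classes.
#' @param black_threshold Intensity cut between black background and object.
#' @return List with `per_stimulus` (data frame: `id`, `class`,
#'   `object_pixels`, `black_pixels`) and t-test summaries `object_size`
#'   and `black_area` (each `t`, `p`, `df`).
#' @export
confound_check <- function(selected, black_threshold = 10) {
  per <- data.frame(
    id = vapply(selected, `[[`, "", "id"),
    class = vapply(selected, `[[`, "", "class_label"),
    object_pixels = vapply(selected, function(s)
      sum(s$pixels > black_threshold), numeric(1)),
    black_pixels = vapply(selected, function(s)
      sum(s$pixels <= black_threshold), numeric(1)),
    stringsAsFactors = FALSE)
  if (length(unique(per$class)) < 2)
    stop("confound check needs stimuli from both classes", call. = FALSE)
  a <- per$class == "X"
  list(per_stimulus = per,
       object_size = welch_t(per$object_pixels[a], per$object_pixels[!a]),
       black_area = welch_t(per$black_pixels[a], per$black_pixels[!a]),
       black_threshold = black_threshold)
}
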