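## Spatial peck statistics: grid binning, relative heatmaps (relPecks),
## difference maps, cumulative peck-concentration curves, and the
## Kolmogorov-Smirnov comparison of correct- vs error-trial concentration.

#' Bin pooled pecks into the spatial grid
#'
#' Sections the registration region into `grid_n` x `grid_n` equally sized
#' squares and counts the pecks in each. Cells are half-open
#' (`ix = floor(x / square_side)`) with the top/right region edge folded into
#' the last cell, so every in-bounds peck lands in exactly one square.
#'
#' @param pool A [select_pool()] result (events assumed in-bounds).
#' @param geometry A [display_geometry()]; defaults to the pool's.
#' @return An integer `grid_n` x `grid_n` matrix of counts; `m[ix, iy]` is
#'   the square with x-bin `ix` (left to right) and y-bin `iy` (bottom to
#'   top). The total equals the pool size.
#' @export
bin_pecks <- function(pool, geometry = pool$geometry) {
  stopifnot(inherits(pool, "peck_pool"), inherits(geometry, "display_geometry"))
  n <- geometry$grid_n
  delta <- geometry$region_side / n
  ix <- pmin(floor(pool$events$x / delta), n - 1) + 1L
  iy <- pmin(floor(pool$events$y / delta), n - 1) + 1L
  counts <- matrix(0L, n, n)
  if (length(ix) > 0) {
    tab <- table(factor(ix, levels = seq_len(n)), factor(iy, levels = seq_len(n)))
    counts <- matrix(as.integer(tab), n, n)
  }
  counts
}

#' Relative peck heatmap
#'
#' Converts a count grid to relative peck percentages,
#' `relPecks = (100 / allPecks) * pecks per square`, so heatmaps are
#' comparable between subjects with different peck totals. Values sum to 100
#' whenever there is at least one peck.
#'
#' @param counts Count matrix from [bin_pecks()].
#' @param geometry The [display_geometry()] of the grid.
#' @return An object of class `peck_heatmap`: list with `values` (percentage
#'   matrix), `total_pecks` and `geometry`.
#' @export
relative_heatmap <- function(counts, geometry = display_geometry()) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            nrow(counts) == geometry$grid_n, ncol(counts) == geometry$grid_n)
  total <- sum(counts)
  if (total == 0) {
    warning("no pecks: returning an all-zero heatmap", call. = FALSE)
    values <- matrix(0, nrow(counts), ncol(counts))
  } else {
    values <- 100 * counts / total
  }
  structure(list(values = values, total_pecks = as.integer(total),
                 geometry = geometry),
            class = "peck_heatmap")
}

#' @export
print.peck_heatmap <- function(x, ...) {
  peak <- which(x$values == max(x$values), arr.ind = TRUE)[1, ]
  cat(sprintf("Peck heatmap: %d x %d grid, %d pecks, peak %.2f%% at cell (%d, %d)\n",
              nrow(x$values), ncol(x$values), x$total_pecks,
              max(x$values), peak[1], peak[2]))
  invisible(x)
}

#' @export
plot.peck_heatmap <- function(x, main = "Relative pecks (%)", ...) {
  n <- x$geometry$grid_n
  mids <- (seq_len(n) - 0.5) * x$geometry$square_side
  graphics::image(mids, mids, x$values, xlab = "x (cm)", ylab = "y (cm)",
                  main = main, asp = 1, ...)
  invisible(x)
}

#' Difference between two heatmaps
#'
#' Elementwise subtraction `a - b` of two relative heatmaps on the same
#' geometry; reveals where pecks concentrate for one stimulus class (or
#' outcome) relative to another. Entries lie in `[-100, 100]` and sum to 0
#' when both grids contain pecks.
#'
#' @param a,b `peck_heatmap` objects with identical geometry.
#' @return A numeric matrix of percentage differences.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "peck_heatmap"), inherits(b, "peck_heatmap"))
  if (!same_geometry(a$geometry, b$geometry))
    stop("heatmaps have different geometries", call. = FALSE)
  a$values - b$values
}

#' Cumulative peck-concentration curve
#'
#' Ranks the grid squares by descending peck count (ties broken by cell
#' index) and accumulates the share of all pecks covered by the top `r`
#' squares, for `r = 1 .. grid_n^2`. A focused pecker reaches 1 within few
#' squares; a dispersed one climbs slowly.
#'
#' @param counts Count matrix from [bin_pecks()] with a positive total.
#' @return An object of class `cumulative_curve`: numeric vector of
#'   nondecreasing fractions ending at 1.
#' @export
cumulative_curve <- function(counts) {
  stopifnot(is.matrix(counts) || is.numeric(counts), all(counts >= 0))
  v <- as.vector(counts)
  total <- sum(v)
  if (total == 0) stop("cumulative_curve requires at least one peck", call. = FALSE)
  sorted <- v[order(-v)]  # order() is stable: ties fall back to cell index
  structure(cumsum(sorted) / total, class = "cumulative_curve")
}

#' @export
plot.cumulative_curve <- function(x, ...) {
  graphics::plot(seq_along(x), unclass(x), type = "s",
                 xlab = "squares (ranked by peck count)",
                 ylab = "cumulative fraction of pecks", ylim = c(0, 1), ...)
  invisible(x)
}

# Asymptotic two-sample Kolmogorov-Smirnov p-value for statistic D with
# sample sizes n and m.
ks_p_asymptotic <- function(D, n, m) {
  if (D <= 0) return(1)
  t <- sqrt(n * m / (n + m)) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Compare peck concentration between correct and error trials
#'
#' Computes the cumulative concentration curve ([cumulative_curve()]) of each
#' pool — each ranked by its own descending square counts — and takes
#' `D = max_r |C_correct(r) - C_error(r)|`. The p-value uses the asymptotic
#' two-sample Kolmogorov-Smirnov distribution with the `grid_n^2` ranked
#' squares of each curve as the sample sizes. Significance is judged at a
#' Bonferroni-adjusted alpha (default 0.05 / 8 = 0.00625 for a cohort of 8
#' subjects tested individually).
#'
#' @param pool_correct,pool_error Non-empty peck pools on the same geometry.
#' @param alpha_adjusted Adjusted significance threshold.
#' @return An object of class `ks_result` with fields `D`, `p`,
#'   `significant` and `alpha_adjusted`.
#' @export
compare_correct_error <- function(pool_correct, pool_error,
                                  alpha_adjusted = 0.05 / 8) {
  stopifnot(inherits(pool_correct, "peck_pool"), inherits(pool_error, "peck_pool"))
  if (pool_size(pool_correct) == 0 || pool_size(pool_error) == 0)
    stop("both pools must be non-empty", call. = FALSE)
  if (!same_geometry(pool_correct$geometry, pool_error$geometry))
    stop("pools have different geometries", call. = FALSE)
  cc <- cumulative_curve(bin_pecks(pool_correct))
  ce <- cumulative_curve(bin_pecks(pool_error))
  D <- max(abs(unclass(cc) - unclass(ce)))
  n <- length(cc)
  p <- ks_p_asymptotic(D, n, n)
  structure(list(D = D, p = p, significant = p < alpha_adjusted,
                 alpha_adjusted = alpha_adjusted),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS comparison of peck concentration: D = %.4f, p = %.4g (%s at alpha = %.5g)\n",
              x$D, x$p,
              if (x$significant) "significant" else "not significant",
              x$alpha_adjusted))
  invisible(x)
}
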