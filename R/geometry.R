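#' Display geometry of the pecking region
#'
#' Describes the square registration region on the touchscreen: the stimulus
#' itself plus the surrounding border on which pecks are still recorded, and
#' the grid used for spatial binning. The default matches a 4 x 4 cm stimulus
#' with a 0.5 cm border (5 x 5 cm region) sectioned into 15 x 15 squares.
#'
#' @param stimulus_side Side length of the (square) stimulus, in cm.
#' @param border Width of the border around the stimulus, in cm. Pecks on the
#'   border count as in-bounds.
#' @param grid_n Number of grid squares per side for heatmap binning.
#'
#' @return An object of class `display_geometry` with fields `stimulus_side`,
#'   `border`, `region_side`, `grid_n`, `square_side` and `square_area`
#'   (all lengths in cm, areas in cm^2).
#' @examples
#' g <- display_geometry()
#' g$region_side  # 5
#' round(g$square_area, 2)  # 0.11
#' @export
display_geometry <- function(stimulus_side = 4, border = 0.5, grid_n = 15L) {
  stopifnot(is.numeric(stimulus_side), stimulus_side > 0,
            is.numeric(border), border >= 0,
            is.numeric(grid_n), grid_n >= 1)
  grid_n <- as.integer(grid_n)
  region_side <- stimulus_side + 2 * border
  square_side <- region_side / grid_n
  structure(
    list(stimulus_side = stimulus_side,
         border = border,
         region_side = region_side,
         grid_n = grid_n,
         square_side = square_side,
         square_area = square_side^2),
    class = "display_geometry"
  )
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf(
    "Display geometry: %.3g x %.3g cm region (%.3g cm stimulus + %.3g cm border),\n  %d x %d grid, square side %.4g cm, square area %.4g cm^2\n",
    x$region_side, x$region_side, x$stimulus_side, x$border,
    x$grid_n, x$grid_n, x$square_side, x$square_area))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$region_side, b$region_side)) && a$grid_n == b$grid_n
}
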