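#' Rectangular simulation grid
#'
#' Node-centred uniform grid with x in `[0, Lx]` and y spanning exactly
#' one undulation wavelength `[0, lambda]`, with reflective (zero
#' normal flux) boundaries on all sides.  `Lx` and `lambda` must be
#' integer multiples of the spacing `dx`.
#'
#' @param dx Spacing (um).
#' @param Lx Domain extent in the propagation direction x (um).
#' @param lambda Domain extent in y = one undulation wavelength (um).
#' @return Object of class `ks_grid` with fields `dx`, `nx`, `ny`,
#'   `Lx`, `Ly`, and node coordinate vectors `x`, `y`.
#' @examples
#' make_grid(dx = 20, Lx = 6000, lambda = 800)
#' @export
make_grid <- function(dx, Lx, lambda) {
  stopifnot(dx > 0, Lx > 0, lambda > 0)
  if (abs(Lx / dx - round(Lx / dx)) > 1e-9 ||
      abs(lambda / dx - round(lambda / dx)) > 1e-9) {
    stop("Lx and lambda must be integer multiples of dx")
  }
  nx <- as.integer(round(Lx / dx)) + 1L
  ny <- as.integer(round(lambda / dx)) + 1L
  if (ny < 4L) stop("grid too narrow in y for the stencil (ny >= 4 required)")
  if (nx < 4L) stop("grid too narrow in x for the stencil (nx >= 4 required)")
  structure(list(dx = dx, nx = nx, ny = ny, Lx = Lx, Ly = lambda,
                 x = seq(0, Lx, by = dx), y = seq(0, lambda, by = dx)),
            class = "ks_grid")
}

#' @export
print.ks_grid <- function(x, ...) {
  cat(sprintf("ks_grid: %d x %d nodes, dx = %g um, Lx = %g um, Ly = %g um\n",
              x$nx, x$ny, x$dx, x$Lx, x$Ly))
  invisible(x)
}

#' Bundle density and nutrient fields at one time
#'
#' @param b Bacterial density field (cells/um^3), `nx` by `ny` matrix
#'   (rows index x, columns index y).
#' @param c Nutrient field (uM), same shape.
#' @param t Time (s).
#' @param grid The [make_grid()] the fields live on.
#' @return Object of class `field_state`.
#' @export
field_state <- function(b, c, t, grid) {
  check_field(b, grid)
  check_field(c, grid)
  if (min(b) < 0 || min(c) < 0) stop("fields must be non-negative")
  structure(list(t = t, b = b, c = c), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state at t = %g s: max b = %.4g cells/um^3, c range [%.4g, %.4g] uM\n",
              x$t, max(x$b), min(x$c), max(x$c)))
  invisible(x)
}

check_field <- function(field, grid) {
  if (!is.matrix(field) || nrow(field) != grid$nx || ncol(field) != grid$ny) {
    stop(sprintf("field must be a %d x %d matrix matching the grid",
                 grid$nx, grid$ny))
  }
  invisible(TRUE)
}
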