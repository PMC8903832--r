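#' Specification of a 3D-printed-like inoculum
#'
#' The initial bacterial distribution emulates an undulated cylinder of
#' densely packed cells: a Gaussian ridge of full width at half maximum
#' `fwhm` in x, peak density `b_peak`, whose centreline position
#' oscillates sinusoidally along y with amplitude `A0` and wavelength
#' `lambda`.
#'
#' @param lambda Undulation wavelength (um).
#' @param A0 Undulation amplitude (um); `A0 = 0` gives a flat ridge.
#' @param fwhm Ridge full width at half maximum (um).
#' @param b_peak Peak density (cells/um^3); default the packed inoculum
#'   density 0.95 (= 0.95e12 cells/mL).
#' @param x_center Mean centreline x position (um).
#' @param phase `"valley_at_0"` places the rearmost centreline point
#'   (valley) at y = 0 and the peak at y = lambda/2;
#'   `"peak_at_0"` inverts this.
#' @return Object of class `inoculum_spec`.
#' @export
inoculum_spec <- function(lambda, A0 = 300, fwhm = 100, b_peak = 0.95,
                          x_center, phase = c("valley_at_0", "peak_at_0")) {
  phase <- match.arg(phase)
  stopifnot(lambda > 0, A0 >= 0, fwhm > 0, b_peak > 0, x_center > 0)
  structure(list(lambda = lambda, A0 = A0, fwhm = fwhm, b_peak = b_peak,
                 x_center = x_center, phase = phase),
            class = "inoculum_spec")
}

#' Centreline position of the undulated inoculum
#'
#' `x0(y) = x_center -/+ A0 cos(2 pi y / lambda)` (minus for
#' `valley_at_0`): the centreline spans
#' `[x_center - A0, x_center + A0]`, so the peak-to-valley excursion is
#' `2 A0` and the extracted edge amplitude matches `A0`.
#'
#' @param y Lateral positions (um).
#' @param spec An [inoculum_spec()].
#' @return Centreline x positions (um).
#' @export
inoculum_centerline <- function(y, spec) {
  s <- if (spec$phase == "valley_at_0") -1 else 1
  spec$x_center + s * spec$A0 * cos(2 * pi * y / spec$lambda)
}

#' Generate the undulated inoculum density field
#'
#' `b(x, y) = b_peak exp(-(x - x0(y))^2 / (2 sigma^2))` with
#' `sigma = fwhm / (2 sqrt(2 log 2))` and centreline
#' [inoculum_centerline()].
#'
#' @param spec An [inoculum_spec()].
#' @param grid A [make_grid()] object; `grid$Ly` must equal the spec
#'   wavelength, and the ridge (centreline +- a few widths) must fit
#'   inside `[0, Lx]`.
#' @return `nx` by `ny` density matrix (cells/um^3).
#' @export
make_undulated_inoculum <- function(spec, grid) {
  if (abs(grid$Ly - spec$lambda) > 1e-9) {
    stop("grid y extent must equal the undulation wavelength")
  }
  sigma <- spec$fwhm / (2 * sqrt(2 * log(2)))
  margin <- spec$A0 + 4 * sigma
  if (spec$x_center - margin < 0 || spec$x_center + margin > grid$Lx) {
    stop("inoculum does not fit inside the grid in x")
  }
  x0 <- inoculum_centerline(grid$y, spec)
  b <- outer(grid$x, x0, function(x, x0) exp(-(x - x0)^2 / (2 * sigma^2)))
  spec$b_peak * b
}

#' Generate the uniform initial nutrient field
#'
#' @param c0 Initial nutrient concentration (uM); the standard condition
#'   is 1e4 uM (10 mM), the low-nutrient robustness variant 10 uM.
#' @param grid A [make_grid()] object.
#' @return `nx` by `ny` nutrient matrix (uM).
#' @export
make_uniform_nutrient <- function(c0, grid) {
  if (c0 < 0) stop("c0 must be non-negative")
  matrix(c0, grid$nx, grid$ny)
}

#' Synthetic undulation-amplitude time series
#'
#' Piecewise model used to exercise the smoothing-time fitter in
#' isolation: `A(t) = A0` for `t < t0`, `A0 exp(-(t - t0)/tau)` after,
#' plus optional seeded Gaussian noise.  `tau = Inf` encodes a
#' non-smoothing (flat) series.
#'
#' @param A0 Initial amplitude (um).
#' @param tau Decay constant (s); may be `Inf`.
#' @param t0 Smoothing initiation time (s).
#' @param duration Series length (s).
#' @param sampling Sampling interval (s).
#' @param noise_sd Gaussian noise standard deviation (um).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return Data frame with columns `t` (s) and `A` (um).
#' @export
synth_amplitude_series <- function(A0, tau, t0, duration, sampling,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(tau > 0, sampling > 0, duration > 0, A0 > 0)
  if (noise_sd > 0 && is.null(seed)) {
    stop("seed must be set for a noisy series")
  }
  t <- seq(0, duration, by = sampling)
  A <- ifelse(t < t0, A0, A0 * exp(-(t - t0) / tau))
  if (noise_sd > 0) {
    A <- A + withr::with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  data.frame(t = t, A = A)
}

#' Render snapshots as a fluorescence-like image stack
#'
#' Maps density snapshots (optionally after the starvation-signal
#' correction, see [apply_starvation_signal()]) to log-scaled grayscale
#' frames, mimicking maximum-intensity projections displayed with
#' logarithmic intensities.  The transform is
#' `I = log10(1 + signal/b_ref) / log10(1 + s_max/b_ref)`, quantized to
#' 16 bits; `b_ref` and the overall maximum `s_max` are recorded so the
#' map is invertible up to quantization.
#'
#' @param snapshots List of density matrices (e.g. `run$b` or the
#'   starvation-corrected signal).
#' @param file Optional path; if given, frames are written as a
#'   multi-page 16-bit TIFF.
#' @param b_ref Reference density of the log transform (cells/um^3).
#' @return Invisibly, a list with `frames` (list of matrices in
#'   `[0, 1]`), `b_ref`, `s_max`, and `file`.
#' @export
render_image_stack <- function(snapshots, file = NULL, b_ref = 1e-4) {
  if (length(snapshots) == 0L) stop("empty snapshot list")
  s_max <- max(vapply(snapshots, max, 0))
  if (s_max <= 0) s_max <- b_ref
  denom <- log10(1 + s_max / b_ref)
  frames <- lapply(snapshots, function(s) {
    log10(1 + pmax(s, 0) / b_ref) / denom
  })
  # quantize exactly as the TIFF writer will, so frames round-trip
  frames <- lapply(frames, function(f) round(f * 65535) / 65535)
  if (!is.null(file)) {
    tiff::writeTIFF(frames, file, bits.per.sample = 16L)
  }
  invisible(list(frames = frames, b_ref = b_ref, s_max = s_max,
                 file = file))
}

#' Invert the image-stack intensity transform
#'
#' @param frame Matrix of intensities in `[0, 1]`.
#' @param b_ref,s_max Transform constants from [render_image_stack()].
#' @return Density matrix (cells/um^3), up to 16-bit quantization.
#' @export
unrender_image <- function(frame, b_ref, s_max) {
  b_ref * (10^(frame * log10(1 + s_max / b_ref)) - 1)
}
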