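#' Michaelis-Menten nutrient availability factor
#'
#' `g(c) = c / (c + c_half)` modulates both per-cell consumption and
#' proliferation; it is 1/2 at the Monod constant and saturates at 1.
#'
#' @param c Nutrient concentration (uM), scalar or array; must be
#'   non-negative.
#' @param params A [model_params()] object.
#' @return Dimensionless fraction in `[0, 1)`, same shape as `c`.
#' @export
monod_g <- function(c, params) {
  if (any(c < 0)) stop("negative nutrient concentration")
  c / (c + params$c_half)
}

#' Nutrient sensing function
#'
#' In logarithmic mode (the receptor-saturation model),
#' `f(c) = log[(1 + c/c_minus) / (1 + c/c_plus)]` (natural log): linear
#' in `c` below `c_minus`, saturating at `log(c_plus/c_minus)` above
#' `c_plus`.  In linear mode, `f(c) = c / c_lin` with
#' `c_lin = (1/c_minus - 1/c_plus)^-1`, which matches the logarithmic
#' form at small `c` but never saturates.
#'
#' @inheritParams monod_g
#' @return Dimensionless sensed signal, same shape as `c`.
#' @seealso [sensing_fprime()]
#' @export
sensing_f <- function(c, params) {
  if (any(c < 0)) stop("negative nutrient concentration")
  if (params$sensing_mode == "linear") return(c / params$c_lin)
  log1p(c / params$c_minus) - log1p(c / params$c_plus)
}

#' Chemotactic response function f'(c)
#'
#' Analytic derivative of [sensing_f()]: in logarithmic mode
#' `1/(c + c_minus) - 1/(c + c_plus)`, strictly positive and strictly
#' decreasing (receptor saturation weakens the response at high
#' nutrient); in linear mode the constant `1/c_lin`.
#'
#' @inheritParams monod_g
#' @return Response per concentration (1/uM), same shape as `c`.
#' @export
sensing_fprime <- function(c, params) {
  if (any(c < 0)) stop("negative nutrient concentration")
  if (params$sensing_mode == "linear") {
    return(c * 0 + 1 / params$c_lin)  # constant, shape-preserving
  }
  1 / (c + params$c_minus) - 1 / (c + params$c_plus)
}

#' Mean separation between neighbouring cells
#'
#' `l_cell = (3 f_pore / (4 pi b))^(1/3) - d_cell`: the mean surface
#' separation of cells at local density `b` sharing the pore-space
#' volume fraction `f_pore`.  Negative values mean cells are jammed.
#' Non-positive densities return `+Inf` (no crowding).
#'
#' @param b Local bacterial density (cells/um^3), scalar or array.
#' @param medium A [porous_medium()] object.
#' @param params A [model_params()] object (supplies `d_cell`).
#' @return Length (um), same shape as `b`; may be negative.
#' @export
mean_cell_separation <- function(b, medium, params) {
  out <- rep_len(Inf, length(b))
  pos <- b > 0
  out[pos] <- (3 * medium$f_pore / (4 * pi * b[pos]))^(1 / 3) - params$d_cell
  dim(out) <- dim(b)
  out
}

#' Density-dependent motility correction
#'
#' Cell-cell collisions truncate the random-walk step length once the
#' mean cell separation `l_cell` falls below the mean chord length
#' `l_c`; both `Db` and `chi` are then multiplied by `(l_cell/l_c)^2`.
#' Where cells are jammed (`l_cell <= 0`) both coefficients vanish.
#'
#' @inheritParams mean_cell_separation
#' @return Dimensionless factor in `[0, 1]`, same shape as `b`.
#' @export
motility_correction <- function(b, medium, params) {
  lc <- mean_cell_separation(b, medium, params)
  out <- ifelse(lc >= medium$l_c, 1,
                ifelse(lc <= 0, 0, (lc / medium$l_c)^2))
  dim(out) <- dim(b)
  out
}

#' Pointwise reaction terms of the model
#'
#' Consumption (`dc/dt` contribution) `-b * kappa * g(c)` and net
#' proliferation (`db/dt` contribution) `+b * gamma * g(c)`.  The growth
#' knockout (`gamma = 0`) zeroes the growth term exactly.
#'
#' @param b,c Density and nutrient fields of identical shape.
#' @param params A [model_params()] object.
#' @return List with fields `consumption` (uM/s, non-positive) and
#'   `growth` (cells/um^3/s, non-negative).
#' @export
reaction_terms <- function(b, c, params) {
  if (!identical(dim(b), dim(c)) || length(b) != length(c)) {
    stop("b and c fields must have identical shape")
  }
  if (any(b < 0)) stop("negative density")
  g <- monod_g(c, params)
  list(consumption = -b * params$kappa * g,
       growth = b * params$gamma * g)
}

#' Back-of-envelope smoothing time scales
#'
#' The two passive mechanisms that could in principle flatten an
#' undulated front: diffusive smoothing of a perturbation of wavelength
#' `lambda` takes `lambda^2 / Db`, and proliferative spreading over the
#' amplitude `A0` by end-to-end growth of cells of body length
#' `l_cell_body` takes `gamma^-1 log2(A0 / l_cell_body)`.  Both are
#' returned in hours for comparison with measured smoothing times.
#'
#' @param lambda Undulation wavelength (um).
#' @param Db Cellular diffusivity (um^2/s).
#' @param gamma Maximal proliferation rate (1/s).
#' @param A0 Undulation amplitude (um).
#' @param l_cell_body Cell body length (um).
#' @return List with `diffusive_hr` and `proliferative_hr`.
#' @examples
#' scale_estimates(1000, 2.32, 1 / 3600, 300, 2)
#' @export
scale_estimates <- function(lambda, Db, gamma, A0, l_cell_body) {
  stopifnot(lambda > 0, Db > 0, gamma > 0, l_cell_body > 0)
  if (A0 <= l_cell_body) {
    stop("A0 must exceed the cell body length for the growth estimate")
  }
  list(diffusive_hr = (lambda^2 / Db) / 3600,
       proliferative_hr = (log2(A0 / l_cell_body) / gamma) / 3600)
}
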