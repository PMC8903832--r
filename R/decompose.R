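#' Decompose the chemotactic velocity along the leading edge
#'
#' The x component of the chemotactic velocity,
#' `v_cx = chi f'(c) dc/dx`, is evaluated at each edge point: the
#' driving force `dc/dx` (node-centred central difference of the
#' nutrient field, bilinearly interpolated to the off-node edge
#' position), the response function `f'(c)` at the interpolated
#' concentration, and their product times `chi`.  `chi` is taken at its
#' uncorrected (constant per-medium) value `chi0`, as in the velocity
#' decomposition itself: edge thresholds sit orders of magnitude below
#' the jamming density, which is asserted; the local correction values
#' are returned in `corr_edge` so the approximation can be inspected.
#'
#' @param b,c Density and nutrient matrices of one snapshot.
#' @param edge An `edge_profile` from [extract_leading_edge()],
#'   time-matched to the snapshot.
#' @param grid A [make_grid()] object.
#' @param params A [model_params()] object.
#' @param medium A [porous_medium()] object.
#' @return Object of class `decomposition_profile`: list with `t`, `y`,
#'   `x_edge`, `c_edge` (uM), `dcdx_edge` (uM/um), `fprime_edge`
#'   (1/uM), `vcx_edge` (um/s), `corr_edge` (motility correction at the
#'   edge, for inspection), `j_peak`, `j_valley` (row indices of the
#'   leading-most and rearmost edge points), and `flagged` (rows
#'   omitted for lack of an edge).
#' @export
decompose_at_edge <- function(b, c, edge, grid, params, medium) {
  check_field(b, grid); check_field(c, grid)
  valid <- which(!is.na(edge$x_edge))
  if (length(valid) < 2L) stop("edge has fewer than 2 valid rows")

  dcdx_nodes <- dfdx(c, grid)
  n <- length(valid)
  c_e <- dcdx_e <- b_e <- numeric(n)
  for (kk in seq_len(n)) {
    j <- valid[kk]
    xe <- edge$x_edge[j]
    c_e[kk] <- interp_x(c, grid, xe, j)
    dcdx_e[kk] <- interp_x(dcdx_nodes, grid, xe, j)
    b_e[kk] <- interp_x(b, grid, xe, j)
  }
  # chi is taken at its uncorrected (constant per-medium) value along
  # the edge; assert the edge is nowhere near jamming, where that
  # approximation would break down entirely
  corr_e <- motility_correction(pmax(b_e, 1e-300), medium, params)
  if (any(corr_e <= 0)) {
    stop("edge density reaches the jamming regime; constant chi is invalid there")
  }
  fp_e <- sensing_fprime(pmax(c_e, 0), params)
  vcx <- medium$chi0 * fp_e * dcdx_e
  xe_v <- edge$x_edge[valid]
  structure(list(t = edge$t, y = grid$y[valid], x_edge = xe_v,
                 c_edge = c_e, dcdx_edge = dcdx_e, fprime_edge = fp_e,
                 vcx_edge = vcx, corr_edge = corr_e,
                 j_peak = which.max(xe_v), j_valley = which.min(xe_v),
                 flagged = setdiff(seq_len(grid$ny), valid)),
            class = "decomposition_profile")
}

# node-centred central-difference x derivative with one-sided stencils
# at the x boundaries
dfdx <- function(field, grid) {
  nx <- grid$nx
  out <- (shift_x(field, 1L) - shift_x(field, -1L)) / (2 * grid$dx)
  out[1L, ] <- (field[2L, ] - field[1L, ]) / grid$dx
  out[nx, ] <- (field[nx, ] - field[nx - 1L, ]) / grid$dx
  out
}

# linear interpolation of a nodal field along x at fixed row j
interp_x <- function(field, grid, x, j) {
  i <- findInterval(x, grid$x)
  i <- min(max(i, 1L), grid$nx - 1L)
  w <- (x - grid$x[i]) / grid$dx
  (1 - w) * field[i, j] + w * field[i + 1L, j]
}

#' @export
print.decomposition_profile <- function(x, ...) {
  cat(sprintf("decomposition_profile at t = %g s (%d edge rows)\n",
              x$t, length(x$y)))
  cat(sprintf("  vcx: peak %.4g um/s, valley %.4g um/s\n",
              x$vcx_edge[x$j_peak], x$vcx_edge[x$j_valley]))
  invisible(x)
}

#' Valley-minus-peak chemotactic velocity gap
#'
#' `Delta v_cx = v_cx(valley) - v_cx(peak)`.  Positive values mean
#' valleys outrun peaks, i.e. the undulation is being smoothed out;
#' negative values mean the profile is inverted (amplification).
#'
#' @param profile A `decomposition_profile`.
#' @return List with `dvcx` (um/s) and `degenerate` (TRUE when the edge
#'   is flat so peak and valley coincide and the gap is 0 by fiat).
#' @export
velocity_gap <- function(profile) {
  if (profile$j_peak == profile$j_valley ||
      abs(profile$x_edge[profile$j_peak] -
          profile$x_edge[profile$j_valley]) < 1e-9) {
    return(list(dvcx = 0, degenerate = TRUE))
  }
  list(dvcx = profile$vcx_edge[profile$j_valley] -
         profile$vcx_edge[profile$j_peak],
       degenerate = FALSE)
}

#' Catch-up time of valleys on peaks
#'
#' Trapezoidal cumulative integral of the velocity gap series; the
#' catch-up time `tau'` is the first elapsed time at which
#' `integral(Delta v_cx) dt` reaches the initial amplitude `A0`,
#' linearly interpolated between samples.
#'
#' @param dt_series Elapsed times since smoothing initiation (s),
#'   starting at 0.
#' @param dvcx_series Velocity gap at each elapsed time (um/s).
#' @param A0 Initial undulation amplitude (um).
#' @return List with `attained` (logical), `tau_prime` (s, `NA` when
#'   not attained) and `integral_end` (um, total displacement gap).
#' @export
catch_up_time <- function(dt_series, dvcx_series, A0) {
  stopifnot(length(dt_series) == length(dvcx_series))
  if (length(dt_series) == 0L) stop("empty velocity-gap series")
  if (A0 <= 0) stop("A0 must be strictly positive")
  if (abs(dt_series[1L]) > 1e-9) stop("series must start at elapsed time 0")
  cum <- pracma::cumtrapz(dt_series, dvcx_series)[, 1L]
  hit <- which(cum >= A0)
  if (length(hit) == 0L) {
    return(list(attained = FALSE, tau_prime = NA_real_,
                integral_end = cum[length(cum)]))
  }
  k <- hit[1L]
  if (k == 1L) return(list(attained = TRUE, tau_prime = dt_series[1L],
                           integral_end = cum[length(cum)]))
  frac <- (A0 - cum[k - 1L]) / (cum[k] - cum[k - 1L])
  list(attained = TRUE,
       tau_prime = dt_series[k - 1L] +
         frac * (dt_series[k] - dt_series[k - 1L]),
       integral_end = cum[length(cum)])
}

#' Iso-concentration contours of the nutrient field
#'
#' Marching-squares contours (via [grDevices::contourLines()]) of the
#' nutrient field, typically at the sensing limits `c_minus` and
#' `c_plus`.  Levels outside the field range yield empty, flagged
#' entries.
#'
#' @param c Nutrient matrix.
#' @param levels Contour levels (uM).
#' @param grid A [make_grid()] object.
#' @return List (one element per level) with `level`, `lines` (list of
#'   data frames with `x`, `y`) and `empty` flag.
#' @export
nutrient_contours <- function(c, levels, grid) {
  check_field(c, grid)
  lapply(levels, function(lv) {
    if (lv < min(c) || lv > max(c)) {
      return(list(level = lv, lines = list(), empty = TRUE))
    }
    cl <- grDevices::contourLines(grid$x, grid$y, c, levels = lv)
    list(level = lv,
         lines = lapply(cl, function(l) data.frame(x = l$x, y = l$y)),
         empty = length(cl) == 0L)
  })
}

#' Row-wise x positions of a nutrient level
#'
#' Interpolated x position at which the nutrient field crosses `level`
#' along a given y row, scanning from +x inward (the outermost
#' crossing).  Used to compare the spacing of the `c_minus`/`c_plus`
#' contours at peak and valley rows.
#'
#' @param c Nutrient matrix.
#' @param level Level (uM).
#' @param grid A [make_grid()] object.
#' @param j Row index.
#' @return x position (um) or `NA` when the row never crosses.
#' @export
level_crossing_x <- function(c, level, grid, j) {
  col <- c[, j]
  below <- which(col <= level)
  if (length(below) == 0L || max(below) == grid$nx) return(NA_real_)
  i <- max(below)  # outermost node still below the level
  frac <- (level - col[i]) / (col[i + 1L] - col[i])
  grid$x[i] + frac * grid$dx
}
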