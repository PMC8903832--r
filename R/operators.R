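# Reference (pure R) spatial operators.  These define the
# discretization; the compiled integrator core implements the identical
# stencils and is cross-checked against these in the tests.

# reflect a matrix index outside [1, n] back inside (ghost-node mirror,
# zero normal derivative)
shift_x <- function(m, by) {
  nx <- nrow(m)
  idx <- seq_len(nx) + by
  idx[idx < 1L] <- 2L - idx[idx < 1L]
  idx[idx > nx] <- 2L * nx - idx[idx > nx]
  m[idx, , drop = FALSE]
}

shift_y <- function(m, by) {
  ny <- ncol(m)
  idx <- seq_len(ny) + by
  idx[idx < 1L] <- 2L - idx[idx < 1L]
  idx[idx > ny] <- 2L * ny - idx[idx > ny]
  m[, idx, drop = FALSE]
}

#' Five-point Laplacian with reflective boundaries
#'
#' Central second differences on the interior; boundary rows/columns use
#' ghost-node reflection, which implements zero normal flux (a uniform
#' field has identically zero Laplacian, including at the boundary).
#'
#' @param field `nx` by `ny` matrix.
#' @param grid A [make_grid()] object.
#' @return Matrix of the same shape (units of field / um^2).
#' @export
laplacian <- function(field, grid) {
  check_field(field, grid)
  (shift_x(field, 1L) + shift_x(field, -1L) +
   shift_y(field, 1L) + shift_y(field, -1L) - 4 * field) / grid$dx^2
}

#' Divergence of the bacterial flux (transport term of db/dt)
#'
#' Computes `-div(J_b)` with `J_b = -Db(b) grad b + b chi(b) grad f(c)`
#' in conservative (flux) form: fluxes are evaluated on cell faces, with
#' face coefficients taken as arithmetic means of the adjacent node
#' values of `Db0 * motility_correction(b)` and
#' `chi0 * motility_correction(b)`, and face density as the mean of the
#' adjacent `b`.  Boundary faces carry zero flux, so the field sums to
#' zero over the grid to round-off (discrete mass conservation).
#'
#' Knockout flags on `params` zero `Db0` or `chi0`.
#'
#' @param b,c Density and nutrient fields (`nx` by `ny`).
#' @param grid A [make_grid()] object.
#' @param params A [model_params()] object.
#' @param medium A [porous_medium()] object.
#' @return Matrix: the transport contribution to `db/dt` (cells/um^3/s).
#' @export
flux_divergence <- function(b, c, grid, params, medium) {
  check_field(b, grid)
  check_field(c, grid)
  if (any(!is.finite(b)) || any(!is.finite(c))) {
    bad <- which(!is.finite(b) | !is.finite(c))[1L]
    stop(sprintf("non-finite input at node [%d, %d]",
                 (bad - 1L) %% grid$nx + 1L, (bad - 1L) %/% grid$nx + 1L))
  }
  eff <- .effective_coeffs(params, medium)
  corr <- motility_correction(pmax(b, 0), medium, params)
  fc <- sensing_f(pmax(c, 0), params)
  dx <- grid$dx
  nx <- grid$nx; ny <- grid$ny

  # x faces between rows i and i+1 (matrix of nx-1 rows)
  i1 <- seq_len(nx - 1L); i2 <- i1 + 1L
  Df <- eff$Db0 * (corr[i1, , drop = FALSE] + corr[i2, , drop = FALSE]) / 2
  Xf <- eff$chi0 * (corr[i1, , drop = FALSE] + corr[i2, , drop = FALSE]) / 2
  bf <- (b[i1, , drop = FALSE] + b[i2, , drop = FALSE]) / 2
  Fx <- -Df * (b[i2, , drop = FALSE] - b[i1, , drop = FALSE]) / dx +
    bf * Xf * (fc[i2, , drop = FALSE] - fc[i1, , drop = FALSE]) / dx
  # y faces between columns j and j+1
  j1 <- seq_len(ny - 1L); j2 <- j1 + 1L
  Dg <- eff$Db0 * (corr[, j1, drop = FALSE] + corr[, j2, drop = FALSE]) / 2
  Xg <- eff$chi0 * (corr[, j1, drop = FALSE] + corr[, j2, drop = FALSE]) / 2
  bg <- (b[, j1, drop = FALSE] + b[, j2, drop = FALSE]) / 2
  Fy <- -Dg * (b[, j2, drop = FALSE] - b[, j1, drop = FALSE]) / dx +
    bg * Xg * (fc[, j2, drop = FALSE] - fc[, j1, drop = FALSE]) / dx

  out <- matrix(0, nx, ny)
  # -d(Fx)/dx: flux in through the left face, out through the right
  out[i1, ] <- out[i1, , drop = FALSE] - Fx / dx
  out[i2, ] <- out[i2, , drop = FALSE] + Fx / dx
  out[, j1] <- out[, j1, drop = FALSE] - Fy / dx
  out[, j2] <- out[, j2, drop = FALSE] + Fy / dx
  out
}

#' Full right-hand side of the model equations
#'
#' `dc/dt = Dc lap(c) - b kappa g(c)` and
#' `db/dt = -div(J_b) + b gamma g(c)`.  Set `include_consumption =
#' FALSE` to obtain the transport-plus-growth part only (the part the
#' multistep integrator advances explicitly; consumption is handled by a
#' stiff split step, see [run_simulation()]).
#'
#' @inheritParams flux_divergence
#' @param include_consumption Include the `-b kappa g(c)` sink in
#'   `dcdt`?
#' @return List with matrices `dbdt` and `dcdt`.
#' @export
ks_rhs <- function(b, c, grid, params, medium, include_consumption = TRUE) {
  g <- monod_g(pmax(c, 0), params)
  dcdt <- params$Dc * laplacian(c, grid)
  if (include_consumption) dcdt <- dcdt - pmax(b, 0) * params$kappa * g
  dbdt <- flux_divergence(b, c, grid, params, medium) +
    pmax(b, 0) * params$gamma * g
  list(dbdt = dbdt, dcdt = dcdt)
}
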