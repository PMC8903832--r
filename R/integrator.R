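#' Integrator configuration
#'
#' Settings of the multistep time stepper.  The explicit diffusion
#' stability number `Dc dt / dx^2` is checked at the start of every run:
#' above 0.5 the run refuses to start, above 0.25 it warns.
#'
#' @param dt Time step (s).
#' @param output_interval Interval between stored snapshots (s).
#' @param max_time Total simulated time (s).
#' @param starter Single-step method used to generate the two back
#'   values the order-3 predictor needs: `"rk4"` (classical Runge-Kutta,
#'   order 4).
#' @param positivity_tol_b,positivity_tol_c Abort thresholds: the run
#'   stops if any density drops below `-positivity_tol_b` (cells/um^3)
#'   or any concentration below `-positivity_tol_c` (uM).  The defaults
#'   (1e-3 of the packed density; 1e-3 of the standard 10 mM nutrient
#'   level) sit comfortably above the saturated undershoot of the
#'   central scheme (measured at ~3e-4 of the packed density for the
#'   strongest-chemotaxis preset on the coarse grid, and far smaller
#'   elsewhere) while still catching genuine instability, which grows
#'   without bound.
#' @return Object of class `ks_integrator_config`.
#' @export
integrator_config <- function(dt = 0.05, output_interval = 300,
                              max_time = 6 * 3600, starter = "rk4",
                              positivity_tol_b = 1e-3 * 0.95,
                              positivity_tol_c = 1e-3 * 1e4) {
  stopifnot(dt > 0, output_interval > 0, max_time >= 0)
  starter <- match.arg(starter, "rk4")
  structure(list(dt = dt, output_interval = output_interval,
                 max_time = max_time, starter = starter,
                 predictor_order = 3L, corrector_order = 2L,
                 positivity_tol_b = positivity_tol_b,
                 positivity_tol_c = positivity_tol_c),
            class = "ks_integrator_config")
}

#' Build the startup history for the multistep scheme
#'
#' The order-3 Adams-Bashforth predictor needs the right-hand side at
#' the two steps preceding the current one.  A classical fourth-order
#' Runge-Kutta starter (order >= 3, sufficient for an order-3 predictor)
#' advances the first two steps and records the RHS along the way.
#' Works on any flat numeric state, so scalar test problems exercise the
#' same code path as the PDE fields.
#'
#' @param y0 Initial state (numeric vector).
#' @param t0 Initial time.
#' @param rhs Function `rhs(t, y)` returning `dy/dt`.
#' @param dt Time step.
#' @return List with `ys` (list of the 3 states), `fs` (list of the 3
#'   RHS evaluations) and `t` (time of the newest state).
#' @examples
#' h <- start_history(1, 0, function(t, y) -y, 0.01)
#' h$ys[[3]]  # e^-0.02 to ~1e-10
#' @export
start_history <- function(y0, t0, rhs, dt) {
  ys <- vector("list", 3L)
  fs <- vector("list", 3L)
  ys[[1L]] <- y0
  fs[[1L]] <- rhs(t0, y0)
  t <- t0
  for (k in 2:3) {
    y <- ys[[k - 1L]]
    k1 <- fs[[k - 1L]]
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
    k4 <- rhs(t + dt, y + dt * k3)
    ys[[k]] <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    fs[[k]] <- rhs(t, ys[[k]])
    if (any(!is.finite(ys[[k]]))) stop("non-finite state during startup")
  }
  list(ys = ys, fs = fs, t = t)
}

#' One Adams-Bashforth-Moulton predictor-corrector step
#'
#' PECE scheme: order-3 Adams-Bashforth predictor
#' `y* = y_n + dt/12 (23 f_n - 16 f_{n-1} + 5 f_{n-2})`, one RHS
#' evaluation at the prediction, order-2 Adams-Moulton (trapezoidal)
#' corrector `y_{n+1} = y_n + dt/2 (f(y*) + f_n)`, and a final RHS
#' evaluation at the corrected state that becomes the newest history
#' entry.
#'
#' @param history As returned by [start_history()] or a previous
#'   `abm_step()`.
#' @inheritParams start_history
#' @return Updated history (newest state in `ys[[3]]`, time in `t`).
#' @export
abm_step <- function(history, rhs, dt) {
  yn <- history$ys[[3L]]
  fn <- history$fs[[3L]]
  pred <- yn + dt / 12 * (23 * fn - 16 * history$fs[[2L]] +
                            5 * history$fs[[1L]])
  tn1 <- history$t + dt
  fp <- rhs(tn1, pred)
  ycorr <- yn + dt / 2 * (fp + fn)
  list(ys = list(history$ys[[2L]], yn, ycorr),
       fs = list(history$fs[[2L]], fn, rhs(tn1, ycorr)),
       t = tn1)
}

#' Stiff split update of the Monod consumption term
#'
#' At packed densities the consumption sink `-b kappa g(c)` relaxes `c`
#' on a ~1e-4 s time scale, far below any affordable time step, so it is
#' integrated by a pointwise backward-Euler step with a closed-form
#' solution: `c_new` solves
#' `c = c_old - dt b kappa c/(c + c_half)`, a quadratic whose positive
#' root is taken.  The update is unconditionally stable, strictly
#' positivity-preserving, and reduces to the explicit step when
#' `dt b kappa g' << 1`.
#'
#' @param c Nutrient field (uM).
#' @param b Density field (cells/um^3); negative values are treated
#'   as 0.
#' @param dt Time step (s).
#' @param params A [model_params()] object.
#' @return Updated nutrient field, in `[0, c]` elementwise.
#' @export
deplete_nutrient <- function(c, b, dt, params) {
  S <- dt * params$kappa * pmax(b, 0)
  B <- params$c_half + S - c
  (-B + sqrt(B^2 + 4 * params$c_half * c)) / 2
}

#' Integrate the model equations
#'
#' Advances an initial [field_state()] to `cfg$max_time`, storing
#' snapshots every `cfg$output_interval`.  Each step is a Lie split:
#' an Adams-Bashforth-Moulton PECE step (see [abm_step()]) of the
#' transport-plus-growth system, followed by the pointwise implicit
#' consumption update ([deplete_nutrient()]); the trailing RHS
#' evaluation of the PECE step is taken at the post-split state so the
#' multistep history stays consistent.  The solver is deterministic:
#' identical inputs give identical outputs.
#'
#' The default `engine = "cpp"` runs the compiled core; `engine = "r"`
#' composes [start_history()]/[abm_step()] in R (identical scheme, used
#' for cross-checking on small grids).
#'
#' @param state0 Initial [field_state()].
#' @param grid A [make_grid()] object.
#' @param params A [model_params()] object.
#' @param medium A [porous_medium()] object.
#' @param cfg An [integrator_config()] object.
#' @param engine `"cpp"` or `"r"`.
#' @return Object of class `ks_run`: list with `times` (s), `b` and `c`
#'   (lists of matrices), plus the grid/params/medium/cfg used.
#' @export
run_simulation <- function(state0, grid, params, medium,
                           cfg = integrator_config(),
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_field(state0$b, grid)
  check_field(state0$c, grid)
  stab <- params$Dc * cfg$dt / grid$dx^2
  if (stab >= 0.5) {
    stop(sprintf("explicit diffusion stability violated: Dc dt/dx^2 = %.3g >= 0.5", stab))
  }
  if (stab > 0.25) {
    warning(sprintf("diffusion stability number %.3g > 0.25; dt is aggressive", stab))
  }
  n_steps <- as.integer(round(cfg$max_time / cfg$dt))
  out_every <- max(1L, as.integer(round(cfg$output_interval / cfg$dt)))

  if (engine == "cpp") {
    eff <- .effective_coeffs(params, medium)
    res <- cpp_integrate(state0$b, state0$c, grid$dx, cfg$dt,
                         n_steps, out_every,
                         params$Dc, params$kappa, params$c_half, eff$gamma,
                         params$c_minus, params$c_plus,
                         params$sensing_mode == "linear", params$c_lin,
                         eff$Db0, eff$chi0, medium$f_pore, medium$l_c,
                         params$d_cell, cfg$positivity_tol_b,
                         cfg$positivity_tol_c)
    run <- list(times = res$times,
                b = lapply(res$b, matrix, nrow = grid$nx, ncol = grid$ny),
                c = lapply(res$c, matrix, nrow = grid$nx, ncol = grid$ny))
  } else {
    run <- .integrate_r(state0, grid, params, medium, cfg, n_steps, out_every)
  }
  run$grid <- grid; run$params <- params; run$medium <- medium; run$cfg <- cfg
  class(run) <- "ks_run"
  run
}

# Pure-R engine: same split scheme as the compiled core.
.integrate_r <- function(state0, grid, params, medium, cfg, n_steps,
                         out_every) {
  nx <- grid$nx; ny <- grid$ny; nfield <- nx * ny
  pack <- function(b, c) c(as.numeric(b), as.numeric(c))
  unpack_b <- function(y) matrix(y[seq_len(nfield)], nx, ny)
  unpack_c <- function(y) matrix(y[nfield + seq_len(nfield)], nx, ny)
  rhs <- function(t, y) {
    r <- ks_rhs(unpack_b(y), unpack_c(y), grid, params, medium,
                include_consumption = FALSE)
    pack(r$dbdt, r$dcdt)
  }
  deplete_state <- function(y, dt) {
    b <- unpack_b(y)
    cc <- deplete_nutrient(unpack_c(y), b, dt, params)
    pack(b, cc)
  }
  check_pos <- function(y, t) {
    if (any(!is.finite(y))) stop(sprintf("non-finite state at t = %g s", t))
    mb <- min(y[seq_len(nfield)])
    mc <- min(y[nfield + seq_len(nfield)])
    if (mb < -cfg$positivity_tol_b || mc < -cfg$positivity_tol_c) {
      stop(sprintf("positivity violated at t = %g s (min b = %.3g, min c = %.3g)",
                   t, mb, mc))
    }
  }

  times <- c(); bs <- list(); cs <- list()
  store <- function(t, y) {
    times <<- c(times, t)
    bs[[length(bs) + 1L]] <<- unpack_b(y)
    cs[[length(cs) + 1L]] <<- unpack_c(y)
  }
  y <- pack(state0$b, state0$c)
  store(state0$t, y)
  if (n_steps == 0L) return(list(times = times, b = bs, c = cs))

  # startup: single RK4 steps, each followed by the consumption split
  rk4_step <- function(t, y, dt) {
    k1 <- rhs(t, y)
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
    k4 <- rhs(t + dt, y + dt * k3)
    y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  ys <- list(y); fs <- list(rhs(state0$t, y)); t <- state0$t
  for (k in 1:2) {
    ynew <- deplete_state(rk4_step(t, ys[[k]], cfg$dt), cfg$dt)
    t <- t + cfg$dt
    check_pos(ynew, t)
    ys[[k + 1L]] <- ynew
    fs[[k + 1L]] <- rhs(t, ynew)
    if ((k %% out_every) == 0L) store(t, ynew)
  }
  hist <- list(ys = ys, fs = fs, t = t)

  for (step in 3:n_steps) {
    stepped <- abm_step_split(hist, rhs, cfg$dt,
                              function(y) deplete_state(y, cfg$dt))
    hist <- stepped
    if ((step %% 200L) == 0L || step == n_steps) check_pos(hist$ys[[3L]], hist$t)
    if ((step %% out_every) == 0L) store(hist$t, hist$ys[[3L]])
  }
  list(times = times, b = bs, c = cs)
}

# ABM PECE step with the consumption split applied before the trailing
# history evaluation.
abm_step_split <- function(history, rhs, dt, split_fn) {
  yn <- history$ys[[3L]]
  fn <- history$fs[[3L]]
  pred <- yn + dt / 12 * (23 * fn - 16 * history$fs[[2L]] +
                            5 * history$fs[[1L]])
  tn1 <- history$t + dt
  fp <- rhs(tn1, pred)
  ycorr <- split_fn(yn + dt / 2 * (fp + fn))
  list(ys = list(history$ys[[2L]], yn, ycorr),
       fs = list(history$fs[[2L]], fn, rhs(tn1, ycorr)),
       t = tn1)
}

#' @export
print.ks_run <- function(x, ...) {
  cat(sprintf("ks_run: %d snapshots, t in [%g, %g] s, grid %d x %d (dx = %g um)\n",
              length(x$times), min(x$times), max(x$times),
              x$grid$nx, x$grid$ny, x$grid$dx))
  invisible(x)
}

#' Total cell number and nutrient content of a snapshot
#'
#' Discrete integrals `sum(field) * dx^2` used by the conservation
#' diagnostics.
#'
#' @param run A `ks_run`.
#' @return Data frame with columns `t`, `cells`, `nutrient`.
#' @export
run_totals <- function(run) {
  dx2 <- run$grid$dx^2
  data.frame(t = run$times,
             cells = vapply(run$b, function(m) sum(m) * dx2, 0),
             nutrient = vapply(run$c, function(m) sum(m) * dx2, 0))
}
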