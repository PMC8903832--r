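#' Configuration of one in-silico experiment
#'
#' Collects every knob of a single simulation case.  Resolution presets:
#' `"desk"` (dx = 20 um, dt = 0.05 s, Lx = 6 mm) is the default
#' workhorse; `"coarse"` (dx = 40 um, dt = 0.2 s) is used for parameter
#' sweeps; `"paper"` (dx = 10 um, dt = 0.01 s, Lx = 3.5e4 um,
#' centred inoculum) reproduces the full-chamber geometry and is
#' correspondingly expensive.  In the desk/coarse presets the inoculum
#' centreline sits at `x = 0.2 Lx` so the analysed +x front has most of
#' the domain to propagate into.
#'
#' @param lambda_mm Undulation wavelength (mm).
#' @param xi Porous-medium preset label (um): 1.2, 1.7 or 2.2.
#' @param A0 Undulation amplitude (um); 0 gives a flat front.
#' @param sensing `"log"` or `"linear"`.
#' @param knockout `NULL`, `"diffusion"`, `"growth"` or `"chemotaxis"`.
#' @param c0_mM Initial nutrient concentration (mM).
#' @param preset `"desk"`, `"coarse"` or `"paper"`.
#' @param t_max_hr Simulated duration (hours).
#' @param output_interval Snapshot interval (s).
#' @param c_plus Upper sensing limit (uM); override for the
#'   reduced-c-plus variant.
#' @param chi0 Optional chemotactic-coefficient override (um^2/s),
#'   used by [calibrate_chi()].
#' @param signal Apply the starvation signal model when rendering?
#' @param dx,dt,Lx,x_frac Optional explicit overrides of the preset.
#' @param tol_b,tol_c Optional positivity-tolerance overrides passed to
#'   [integrator_config()]; used e.g. by the advection-dominated linear
#'   sensing variant, where central differencing produces larger (but
#'   bounded) oscillatory undershoot.
#' @return Object of class `case_config` (a list).
#' @export
case_config <- function(lambda_mm = 0.8, xi = 1.7, A0 = 300,
                        sensing = c("log", "linear"), knockout = NULL,
                        c0_mM = 10, preset = c("desk", "coarse", "paper"),
                        t_max_hr = 8, output_interval = 300,
                        c_plus = 30, chi0 = NULL, signal = TRUE,
                        dx = NULL, dt = NULL, Lx = NULL, x_frac = NULL,
                        tol_b = NULL, tol_c = NULL) {
  sensing <- match.arg(sensing)
  preset <- match.arg(preset)
  res <- switch(preset,
    desk   = list(dx = 20, dt = 0.05, Lx = 6000, x_frac = 0.2),
    coarse = list(dx = 40, dt = 0.2, Lx = 6000, x_frac = 0.2),
    paper  = list(dx = 10, dt = 0.01, Lx = 3.5e4, x_frac = 0.5))
  if (!is.null(dx)) res$dx <- dx
  if (!is.null(dt)) res$dt <- dt
  if (!is.null(Lx)) res$Lx <- Lx
  if (!is.null(x_frac)) res$x_frac <- x_frac
  structure(list(lambda = lambda_mm * 1000, xi = xi, A0 = A0,
                 sensing = sensing, knockout = knockout,
                 c0 = c0_mM * 1000, preset = preset,
                 t_max = t_max_hr * 3600,
                 output_interval = output_interval, c_plus = c_plus,
                 chi0 = chi0, signal = signal,
                 dx = res$dx, dt = res$dt, Lx = res$Lx,
                 x_frac = res$x_frac, tol_b = tol_b, tol_c = tol_c),
            class = "case_config")
}

#' @export
print.case_config <- function(x, ...) {
  cat(sprintf("case_config: lambda = %g mm, xi = %g um, A0 = %g um, %s sensing%s\n",
              x$lambda / 1000, x$xi, x$A0, x$sensing,
              if (is.null(x$knockout)) "" else paste0(", knockout = ", x$knockout)))
  cat(sprintf("  c0 = %g mM, preset %s (dx = %g um, dt = %g s, Lx = %g um), t_max = %g hr\n",
              x$c0 / 1000, x$preset, x$dx, x$dt, x$Lx, x$t_max / 3600))
  invisible(x)
}

#' Passive spreading scale of a non-chemotactic population
#'
#' How far the threshold crossing of the inoculum's Gaussian fringe
#' advances under diffusion and proliferation alone: the fringe widens
#' diffusively (`sigma(t)^2 = sigma0^2 + 2 Db t`) while exponential
#' growth lifts the whole profile, pushing the crossing at density
#' `threshold` outward.  For a Gaussian of peak `b_peak`,
#' `x_thr(t) = sigma(t) sqrt(2 log(b_peak e^(gamma t)/threshold))`, and
#' the creep scale is `x_thr(t_max) - x_thr(0)`.  A population whose
#' leading edge advances no more than about this scale has not formed a
#' migrating front — it merely "spreads via diffusion and
#' proliferation"; the drivers classify a run as front-forming when the
#' measured advance exceeds twice this scale.
#'
#' @param t_max Run duration (s).
#' @param Db0 Cellular diffusivity (um^2/s).
#' @param gamma Maximal proliferation rate (1/s).
#' @param b_peak Peak inoculum density (cells/um^3).
#' @param threshold Edge-detection threshold (cells/um^3).
#' @param sigma0 Initial Gaussian ridge width (um).
#' @return Creep distance (um).
#' @export
creep_scale <- function(t_max, Db0, gamma, b_peak, threshold, sigma0) {
  L0 <- log(b_peak / threshold)
  Lt <- L0 + gamma * t_max
  sqrt(sigma0^2 + 2 * Db0 * t_max) * sqrt(2 * Lt) - sigma0 * sqrt(2 * L0)
}

# resolve a case_config into concrete model objects
resolve_case <- function(config) {
  params <- model_params(c0 = config$c0, sensing_mode = config$sensing,
                         knockout = config$knockout,
                         c_plus = config$c_plus)
  medium <- porous_medium(config$xi)
  if (!is.null(config$chi0)) {
    medium <- porous_medium(config$xi, Db0 = medium$Db0,
                            chi0 = config$chi0, f_pore = medium$f_pore,
                            l_c = medium$l_c)
  }
  grid <- make_grid(config$dx, config$Lx, config$lambda)
  spec <- inoculum_spec(lambda = config$lambda, A0 = config$A0,
                        b_peak = params$b_pack,
                        x_center = config$x_frac * config$Lx)
  b0 <- make_undulated_inoculum(spec, grid)
  c0 <- make_uniform_nutrient(config$c0, grid)
  list(params = params, medium = medium, grid = grid, spec = spec,
       state0 = field_state(b0, c0, 0, grid))
}

#' Run one complete simulation-and-analysis case
#'
#' Composes the full pipeline: synthetic inoculum and nutrient field,
#' PDE integration, leading-edge extraction, amplitude/position trace,
#' exponential smoothing fit, and (for undulated smoothing fronts) the
#' chemotactic velocity decomposition with the catch-up time `tau'`.
#' Deterministic: identical configs give identical results.
#'
#' @param config A [case_config()].
#' @param decompose Compute the velocity-gap series and `tau'`?
#' @param keep_run Keep the full snapshot history in the result?
#' @return Object of class `ks_case`: list with `config`, `trace`,
#'   `fit`, `front_formed`, `Rf_advance`, `creep_scale`, `speed`
#'   (flat fronts, um/s), `decomp` (`dt`, `dvcx`, `tau_prime`,
#'   `attained`), `summary` (flat named list), and optionally `run`.
#' @export
run_case <- function(config, decompose = TRUE, keep_run = TRUE) {
  rc <- resolve_case(config)
  cfg <- integrator_config(dt = config$dt,
                           output_interval = config$output_interval,
                           max_time = config$t_max)
  if (!is.null(config$tol_b)) cfg$positivity_tol_b <- config$tol_b
  if (!is.null(config$tol_c)) cfg$positivity_tol_c <- config$tol_c
  run <- run_simulation(rc$state0, rc$grid, rc$params, rc$medium, cfg)
  analyze_case(config, rc, run, decompose = decompose,
               keep_run = keep_run)
}

analyze_case <- function(config, rc, run, decompose = TRUE,
                         keep_run = TRUE) {
  thr_mig <- edge_threshold(rc$medium, config$lambda, "migration",
                            b_peak = rc$params$b_pack)
  trace <- front_trace(run, threshold = thr_mig,
                       x_ref = rc$spec$x_center)
  valid <- is.finite(trace$Rf)
  Rf_advance <- if (any(valid)) {
    max(trace$Rf[valid]) - trace$Rf[valid][1L]
  } else 0
  eff <- .effective_coeffs(rc$params, rc$medium)
  creep <- creep_scale(config$t_max, eff$Db0, eff$gamma,
                       rc$params$b_pack, thr_mig,
                       rc$spec$fwhm / (2 * sqrt(2 * log(2))))
  front_formed <- config$t_max > 0 && Rf_advance >= 2 * creep

  fit <- NULL; speed <- NA_real_
  if (config$A0 == 0) {
    speed <- front_speed(trace)
  } else if (sum(valid) >= 6L) {
    fit <- fit_smoothing_time(trace$t[valid], trace$A[valid])
  }

  decomp <- NULL
  if (decompose && config$A0 > 0 && !is.null(fit) && fit$smoothing &&
      front_formed) {
    decomp <- velocity_gap_series(run, rc, config, fit)
  }

  summary <- list(
    lambda_mm = config$lambda / 1000, xi = config$xi,
    A0_um = config$A0, sensing = config$sensing,
    knockout = if (is.null(config$knockout)) NA_character_ else config$knockout,
    c0_mM = config$c0 / 1000, preset = config$preset,
    t_max_hr = config$t_max / 3600,
    front_formed = front_formed, Rf_advance_um = Rf_advance,
    creep_scale_um = creep,
    smoothing = !is.null(fit) && fit$smoothing,
    t0_hr = if (!is.null(fit) && fit$smoothing) fit$t0 / 3600 else NA_real_,
    A0_fit_um = if (!is.null(fit) && fit$smoothing) fit$A0 else NA_real_,
    tau_hr = if (!is.null(fit) && fit$smoothing) fit$tau / 3600 else NA_real_,
    tau_prime_hr = if (!is.null(decomp) && decomp$attained) {
      decomp$tau_prime / 3600
    } else NA_real_,
    speed_um_s = speed)

  out <- list(config = config, trace = trace, fit = fit,
              front_formed = front_formed, Rf_advance = Rf_advance,
              creep_scale = creep, speed = speed,
              decomp = decomp, summary = summary)
  if (keep_run) out$run <- run
  structure(out, class = "ks_case")
}

#' @export
print.ks_case <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ks_case: lambda = %g mm, xi = %g um%s, %s sensing\n",
              s$lambda_mm, s$xi,
              if (is.na(s$knockout)) "" else paste0(", knockout = ", s$knockout),
              s$sensing))
  cat(sprintf("  front formed: %s (Rf advance %.0f um vs passive creep scale %.0f um)\n",
              s$front_formed, s$Rf_advance_um, s$creep_scale_um))
  if (isTRUE(s$smoothing)) {
    cat(sprintf("  smoothing: t0 = %.2f hr, tau = %.2f hr%s\n",
                s$t0_hr, s$tau_hr,
                if (is.na(s$tau_prime_hr)) "" else
                  sprintf(", tau' = %.2f hr", s$tau_prime_hr)))
  } else if (s$A0_um > 0) {
    cat("  no exponential amplitude decay detected\n")
  }
  if (!is.na(s$speed_um_s)) {
    cat(sprintf("  flat-front speed: %.4g um/s\n", s$speed_um_s))
  }
  invisible(x)
}

# velocity-gap series from t0 onward, at the decomposition threshold,
# plus the catch-up time
velocity_gap_series <- function(run, rc, config, fit) {
  thr <- edge_threshold(rc$medium, config$lambda, "decomposition")
  ks <- which(run$times >= fit$t0 - 1e-9)
  dts <- dvcx <- numeric(0)
  for (k in ks) {
    edge <- extract_leading_edge(run$b[[k]], thr, run$grid,
                                 t = run$times[k])
    if (sum(!is.na(edge$x_edge)) < 2L) next
    prof <- decompose_at_edge(run$b[[k]], run$c[[k]], edge, run$grid,
                              rc$params, rc$medium)
    gap <- velocity_gap(prof)
    dts <- c(dts, run$times[k] - fit$t0)
    dvcx <- c(dvcx, gap$dvcx)
  }
  if (length(dts) < 2L) {
    return(list(dt = dts, dvcx = dvcx, attained = FALSE,
                tau_prime = NA_real_))
  }
  cu <- catch_up_time(dts - dts[1L], dvcx, fit$A0)
  list(dt = dts, dvcx = dvcx, attained = cu$attained,
       tau_prime = cu$tau_prime, integral_end = cu$integral_end)
}

# long-time flat-front speed: linear fit of Rf(t) over the final third
front_speed <- function(trace) {
  ok <- is.finite(trace$Rf)
  t <- trace$t[ok]; Rf <- trace$Rf[ok]
  if (length(t) < 4L) return(NA_real_)
  t_start <- t[length(t)] - (t[length(t)] - t[1L]) / 3
  sel <- t >= t_start
  if (sum(sel) < 3L) return(NA_real_)
  unname(stats::coef(stats::lm(Rf[sel] ~ t[sel]))[2L])
}

#' Knockout experiment
#'
#' Re-runs a base configuration with exactly one mechanism disabled:
#' `"diffusion"` (Db = 0), `"growth"` (gamma = 0) or `"chemotaxis"`
#' (chi = 0).  Fronts lacking diffusion or growth still smooth (finite
#' tau); fronts lacking chemotaxis do not form at all, which is
#' reported through the quantitative no-front criterion: the
#' leading-edge advance must exceed twice what diffusion and
#' proliferation alone could produce (see [creep_scale()]).
#'
#' @param config A [case_config()] (its `knockout` field is replaced).
#' @param which `"diffusion"`, `"growth"` or `"chemotaxis"`.
#' @param ... Passed to [run_case()].
#' @return A `ks_case`.
#' @export
run_knockout <- function(config, which, ...) {
  which <- match.arg(which, c("diffusion", "growth", "chemotaxis"))
  config$knockout <- which
  run_case(config, ...)
}

#' Wavelength and pore-size sweep
#'
#' Runs one case per (lambda, xi) combination and tabulates the
#' smoothing results, together with ordering diagnostics: tau should
#' increase with lambda at fixed xi and decrease with xi (easier
#' migration) at fixed lambda.  Failures of individual cases are
#' recorded and the sweep continues.
#'
#' @param lambdas_mm Wavelengths (mm).
#' @param xis Medium labels (um).
#' @param base_config Template [case_config()].
#' @param ... Passed to [run_case()].
#' @return Data frame with one row per combination (class `ks_sweep`,
#'   cases in attribute `"cases"`).
#' @export
run_sweep <- function(lambdas_mm, xis, base_config = case_config(), ...) {
  stopifnot(length(lambdas_mm) > 0, length(xis) > 0)
  combos <- expand.grid(lambda_mm = lambdas_mm, xi = xis,
                        KEEP.OUT.ATTRS = FALSE)
  cases <- vector("list", nrow(combos))
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    cfg <- base_config
    cfg$lambda <- combos$lambda_mm[k] * 1000
    cfg$xi <- combos$xi[k]
    res <- tryCatch(run_case(cfg, keep_run = FALSE, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(lambda_mm = combos$lambda_mm[k], xi = combos$xi[k],
                        tau_hr = NA_real_, tau_prime_hr = NA_real_,
                        t0_hr = NA_real_, error = conditionMessage(res)))
    }
    cases[[k]] <<- res
    s <- res$summary
    data.frame(lambda_mm = s$lambda_mm, xi = s$xi, tau_hr = s$tau_hr,
               tau_prime_hr = s$tau_prime_hr, t0_hr = s$t0_hr,
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  attr(out, "cases") <- cases
  class(out) <- c("ks_sweep", class(out))
  out
}

#' Low-nutrient robustness case
#'
#' Runs the base geometry with the initial nutrient lowered to a value
#' between the sensing limits `c_minus` and `c_plus` (default 10 uM).
#' Under these conditions nutrient consumption — and with it the
#' self-generated gradient — is so weak that no travelling front forms
#' within the experimental window; the quantitative no-front criterion
#' reports this.  The starvation-signal correction is disabled for this
#' case, which only affects rendering.
#'
#' @param config A [case_config()]; its `c0` is replaced.
#' @param c0_uM Initial nutrient (uM), default 10.
#' @param ... Passed to [run_case()].
#' @return A `ks_case`.
#' @export
run_low_nutrient <- function(config = case_config(), c0_uM = 10, ...) {
  params_check <- model_params()
  if (c0_uM <= params_check$c_minus || c0_uM >= params_check$c_plus) {
    stop("c0_uM must lie strictly between c_minus and c_plus")
  }
  config$c0 <- c0_uM
  config$signal <- FALSE
  run_case(config, decompose = FALSE, ...)
}

#' Calibrate the chemotactic coefficient against a front speed
#'
#' Bisection on `chi0` until the long-time flat-front propagation speed
#' (linear fit of `Rf(t)` over the final third of the run) matches a
#' target speed within `tol` (relative).  The measured speed increases
#' monotonically with `chi0` over any physical bracket, which the
#' routine verifies at the bracket ends.
#'
#' @param xi Porous-medium preset label.
#' @param target_speed Target long-time front speed (um/s).
#' @param bracket Length-2 numeric, chi0 search interval (um^2/s).
#' @param config Flat-front template config (A0 is forced to 0).
#' @param tol Relative speed tolerance (default 0.02).
#' @param max_iter Maximum bisection iterations.
#' @return List with `chi0`, `speed`, `target_speed`, `iterations`,
#'   `history` (data frame of trials).
#' @export
calibrate_chi <- function(xi, target_speed, bracket,
                          config = case_config(xi = xi, A0 = 0,
                                               preset = "coarse",
                                               t_max_hr = 4),
                          tol = 0.02, max_iter = 20L) {
  stopifnot(length(bracket) == 2L, bracket[1L] > 0,
            bracket[2L] > bracket[1L])
  if (target_speed <= 0) stop("target_speed must be strictly positive")
  config$A0 <- 0
  config$xi <- xi
  speed_of <- function(chi) {
    cfg <- config
    cfg$chi0 <- chi
    res <- run_case(cfg, decompose = FALSE, keep_run = FALSE)
    res$speed
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  s_lo <- speed_of(lo); s_hi <- speed_of(hi)
  hist <- data.frame(chi0 = c(lo, hi), speed = c(s_lo, s_hi))
  if (is.na(s_lo) || is.na(s_hi) || s_lo > target_speed ||
      s_hi < target_speed) {
    stop(sprintf(
      "bracket does not straddle the target: speed(%g) = %.4g, speed(%g) = %.4g, target %.4g um/s",
      lo, s_lo, hi, s_hi, target_speed))
  }
  best <- if (abs(s_lo - target_speed) < abs(s_hi - target_speed)) {
    list(chi0 = lo, speed = s_lo)
  } else list(chi0 = hi, speed = s_hi)
  iter <- 0L
  while (abs(best$speed - target_speed) > tol * target_speed &&
         iter < max_iter) {
    iter <- iter + 1L
    mid <- sqrt(lo * hi)  # geometric bisection: speed is closer to
    s_mid <- speed_of(mid)  # linear on log(chi)
    hist <- rbind(hist, data.frame(chi0 = mid, speed = s_mid))
    if (abs(s_mid - target_speed) < abs(best$speed - target_speed)) {
      best <- list(chi0 = mid, speed = s_mid)
    }
    if (s_mid < target_speed) lo <- mid else hi <- mid
  }
  list(chi0 = best$chi0, speed = best$speed, target_speed = target_speed,
       iterations = iter, history = hist)
}

#' Write the analysis outputs of a case to a directory
#'
#' Writes `trace.csv` (t_s, A_um, Rf_um), `summary.json`, and, when
#' present, `velocity_gap.csv` (dt_s, dvcx_um_s) and `fit.json`.
#'
#' @param case A `ks_case`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- data.frame(t_s = case$trace$t, A_um = case$trace$A,
                   Rf_um = case$trace$Rf)
  utils::write.csv(tr, file.path(dir, "trace.csv"), row.names = FALSE)
  jsonlite::write_json(case$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(case$fit)) {
    jsonlite::write_json(unclass(case$fit), file.path(dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(case$decomp)) {
    utils::write.csv(data.frame(dt_s = case$decomp$dt,
                                dvcx_um_s = case$decomp$dvcx),
                     file.path(dir, "velocity_gap.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read/write a case configuration as YAML
#'
#' @param config A [case_config()].
#' @param file Path.
#' @return `read_config` returns a [case_config()].
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  cfg <- case_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg
}
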