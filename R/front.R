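#' Extract the leading edge of the +x front
#'
#' The leading edge is the locus of positions at which the density falls
#' below a threshold.  Each y-row is scanned from the +x boundary
#' inward to the first node with `b >= threshold`; the crossing position
#' is linearly interpolated between that node and its outward
#' neighbour.  Rows that never reach the threshold are flagged `NA`
#' (no-front), not silently filled.
#'
#' @param b Density matrix (`nx` by `ny`).
#' @param threshold Edge threshold (cells/um^3).  For migration traces
#'   the convention is `1e-4 * max(b initial)`; see [edge_threshold()]
#'   for the per-condition values used in the velocity-decomposition
#'   analysis.
#' @param grid A [make_grid()] object.
#' @param t Time of the snapshot (s), carried through for bookkeeping.
#' @return Object of class `edge_profile`: list with `t`, `y`, `x_edge`
#'   (um, `NA` where no crossing), `threshold`.
#' @export
extract_leading_edge <- function(b, threshold, grid, t = NA_real_) {
  check_field(b, grid)
  if (threshold <= 0) stop("threshold must be strictly positive")
  nx <- grid$nx
  x_edge <- rep(NA_real_, grid$ny)
  for (j in seq_len(grid$ny)) {
    col <- b[, j]
    above <- which(col >= threshold)
    if (length(above) == 0L) next
    i <- max(above)                     # innermost from +x: last node >= threshold
    if (i == nx) {                      # front touches the boundary
      x_edge[j] <- grid$x[nx]
    } else {
      # linear interpolation between node i (>= thr) and i+1 (< thr)
      frac <- (col[i] - threshold) / (col[i] - col[i + 1L])
      x_edge[j] <- grid$x[i] + frac * grid$dx
    }
  }
  structure(list(t = t, y = grid$y, x_edge = x_edge, threshold = threshold),
            class = "edge_profile")
}

#' @export
print.edge_profile <- function(x, ...) {
  ok <- sum(!is.na(x$x_edge))
  cat(sprintf("edge_profile at t = %g s: %d/%d rows cross threshold %.3g\n",
              x$t, ok, length(x$x_edge), x$threshold))
  invisible(x)
}

#' Per-condition edge thresholds for the decomposition analysis
#'
#' Migration traces use `1e-4` times the peak of the initial
#' distribution.  The velocity-decomposition analysis uses a fixed
#' per-condition threshold: 0.003 cells/um^3 for the prototypical
#' (xi = 1.7 um, lambda = 0.8 mm) case and all xi = 2.2 um cases;
#' 0.002 for xi = 1.7 um at lambda = 2.0 and 3.2 mm; 0.001 for
#' xi = 1.2 um at lambda = 0.8 mm.
#'
#' @param medium A [porous_medium()] object.
#' @param lambda Undulation wavelength (um).
#' @param purpose `"migration"` or `"decomposition"`.
#' @param b_peak Peak initial density (cells/um^3), used by the
#'   migration threshold.
#' @return Threshold density (cells/um^3).
#' @export
edge_threshold <- function(medium, lambda,
                           purpose = c("migration", "decomposition"),
                           b_peak = 0.95) {
  purpose <- match.arg(purpose)
  if (purpose == "migration") return(1e-4 * b_peak)
  if (medium$xi >= 2.2) return(0.003)
  if (medium$xi >= 1.7) {
    if (lambda > 1.5e3) return(0.002)
    return(0.003)
  }
  0.001
}

#' Undulation amplitude and front position of an edge profile
#'
#' The amplitude is half the peak-to-valley excursion of the edge,
#' `A = (max x_edge - min x_edge) / 2` (matching the sinusoid-amplitude
#' convention of the inoculum generator), and the front position is the
#' leading-most point, `Rf = max x_edge - x_ref`.
#'
#' @param edge An `edge_profile`.
#' @param x_ref Reference x for `Rf` (the inoculum centreline); default
#'   0 returns the absolute edge position.
#' @return List with `A` (um) and `Rf` (um).
#' @export
amplitude_and_position <- function(edge, x_ref = 0) {
  xe <- edge$x_edge[!is.na(edge$x_edge)]
  if (length(xe) < 2L) stop("edge profile has fewer than 2 valid rows")
  list(A = (max(xe) - min(xe)) / 2, Rf = max(xe) - x_ref)
}

#' Build the A(t), Rf(t) trace of a run
#'
#' Applies [extract_leading_edge()] and [amplitude_and_position()] to
#' every snapshot of a run.
#'
#' @param run A `ks_run` from [run_simulation()].
#' @param threshold Edge threshold (cells/um^3); default the migration
#'   convention `1e-4 * max(b initial)`.
#' @param x_ref Reference x for `Rf` (um).
#' @return Object of class `front_trace`: data frame with columns `t`,
#'   `A`, `Rf` (`NA` on snapshots with no front), with the threshold in
#'   attribute `"threshold"`.
#' @export
front_trace <- function(run, threshold = NULL, x_ref = 0) {
  if (is.null(threshold)) threshold <- 1e-4 * max(run$b[[1L]])
  rows <- lapply(seq_along(run$times), function(k) {
    edge <- extract_leading_edge(run$b[[k]], threshold, run$grid,
                                 t = run$times[k])
    n_ok <- sum(!is.na(edge$x_edge))
    if (n_ok < 2L) {
      return(data.frame(t = run$times[k], A = NA_real_, Rf = NA_real_))
    }
    ap <- amplitude_and_position(edge, x_ref = x_ref)
    data.frame(t = run$times[k], A = ap$A, Rf = ap$Rf)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("front_trace", class(out))
  out
}

#' Fit the exponential smoothing law to an amplitude series
#'
#' For every candidate initiation time `t0` on the sampling grid, the
#' model `A = A(t0) exp(-(t - t0)/tau)` is least-squares fitted (over
#' `tau` only; `A0` is pinned to the observed `A(t0)`) to the points
#' with `t >= t0`.  The fit error of each candidate is the RMSE
#' normalized by `A(t0)`, which makes candidates at different stages of
#' the decay comparable; the reported `t0` is the earliest candidate
#' whose normalized error is within `rmse_tol` (default 5%) of the
#' global minimum, quantifying "the earliest time at which the fit
#' error is minimized" on the otherwise flat error basin.  The spread
#' of candidates inside the tolerance is reported as the `t0`
#' uncertainty band.
#'
#' A series is classified as non-smoothing when its amplitude never
#' decays appreciably (`A` non-decreasing overall, or best-fit `tau`
#' longer than 50 times the fitted window).
#'
#' @param t Times (s).
#' @param A Amplitudes (um); `NA` rows are dropped.
#' @param rmse_tol Relative tolerance on the minimum RMSE used to pick
#'   the earliest acceptable `t0`.
#' @param min_points Minimum points required after `t0` (default 4).
#' @return Object of class `smoothing_fit`: list with `smoothing`
#'   (logical), `t0`, `A0`, `tau` (s; `Inf` when non-smoothing),
#'   `rmse`, `t0_lo`, `t0_hi` (uncertainty band), `n_points`.
#' @export
fit_smoothing_time <- function(t, A, rmse_tol = 0.05, min_points = 4L) {
  keep <- is.finite(t) & is.finite(A)
  t <- t[keep]; A <- A[keep]
  if (length(t) < 6L) stop("need at least 6 time points")
  o <- order(t); t <- t[o]; A <- A[o]

  nonsmooth <- function() {
    structure(list(smoothing = FALSE, t0 = NA_real_, A0 = NA_real_,
                   tau = Inf, rmse = NA_real_, t0_lo = NA_real_,
                   t0_hi = NA_real_, n_points = length(t)),
              class = "smoothing_fit")
  }
  if (A[length(A)] >= max(A) * (1 - 1e-9)) return(nonsmooth())

  duration <- t[length(t)] - t[1L]
  fit_one <- function(i0) {
    tt <- t[i0:length(t)] - t[i0]
    AA <- A[i0:length(t)]
    A0 <- A[i0]
    if (A0 <= 0) return(NULL)
    sse <- function(log_tau) {
      sum((AA - A0 * exp(-tt / exp(log_tau)))^2)
    }
    opt <- stats::optimize(sse, c(log(1), log(500 * duration)), tol = 1e-8)
    list(tau = exp(opt$minimum),
         rmse = sqrt(opt$objective / length(AA)),
         rel = sqrt(opt$objective / length(AA)) / A0)
  }
  # candidate initiation times lie on the amplitude plateau: smoothing
  # initiates while the undulation is still of order its original size,
  # so windows that start after most of the decay (which fit trivially
  # well) are not admissible
  idx <- which(seq_along(t) <= length(t) - (min_points - 1L) &
                 A >= 0.5 * max(A))
  fits <- lapply(idx, fit_one)
  ok <- !vapply(fits, is.null, TRUE)
  idx <- idx[ok]; fits <- fits[ok]
  if (length(idx) == 0L) stop("no candidate t0 leaves enough points to fit")
  rel <- vapply(fits, function(f) f$rel, 0)
  best <- min(rel)
  # the 1e-4 floor makes all essentially-perfect fits (normalized error
  # below 0.01%) equivalent, so the earliest-t0 rule is well defined on
  # noiseless series
  within <- rel <= best * (1 + rmse_tol) + 1e-4
  pick <- which(within)[1L]
  fit <- fits[[pick]]
  if (!is.finite(fit$tau) || fit$tau > 50 * duration) return(nonsmooth())
  structure(list(smoothing = TRUE,
                 t0 = t[idx[pick]], A0 = A[idx[pick]], tau = fit$tau,
                 rmse = fit$rmse,
                 t0_lo = t[idx[which(within)[1L]]],
                 t0_hi = t[idx[utils::tail(which(within), 1L)]],
                 n_points = length(t) - idx[pick] + 1L),
            class = "smoothing_fit")
}

#' @export
print.smoothing_fit <- function(x, ...) {
  if (!x$smoothing) {
    cat("smoothing_fit: non-smoothing (no exponential amplitude decay)\n")
  } else {
    cat(sprintf("smoothing_fit: t0 = %.0f s, A0 = %.1f um, tau = %.0f s (%.2f hr), rmse = %.3g um\n",
                x$t0, x$A0, x$tau, x$tau / 3600, x$rmse))
    cat(sprintf("  t0 uncertainty band: [%.0f, %.0f] s\n", x$t0_lo, x$t0_hi))
  }
  invisible(x)
}

#' Starvation-corrected cellular signal
#'
#' Converts density snapshots into the observable "cellular signal":
#' wherever the nutrient first dropped below `c_star` at time `t'`, the
#' density at all later times `t > t' + tau_delay` is multiplied by
#' `exp(-(t - t')/tau_starve)`, emulating the loss of fluorescence of
#' oxygen/nutrient-starved cells.  Nodes never depleted pass through
#' unchanged.
#'
#' @param run A `ks_run` (supplies time-aligned `b` and `c` histories).
#' @param params A [model_params()] object (supplies `c_star`,
#'   `tau_delay`, `tau_starve`); defaults to the run's own.
#' @return List of signal matrices, one per snapshot.
#' @export
apply_starvation_signal <- function(run, params = run$params) {
  nt <- length(run$times)
  if (length(run$b) != nt || length(run$c) != nt) {
    stop("misaligned b/c histories")
  }
  t_dep <- matrix(Inf, nrow(run$b[[1L]]), ncol(run$b[[1L]]))
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    tk <- run$times[k]
    newly <- run$c[[k]] < params$c_star & !is.finite(t_dep)
    t_dep[newly] <- tk
    sig <- run$b[[k]]
    act <- is.finite(t_dep) & (tk > t_dep + params$tau_delay)
    sig[act] <- sig[act] * exp(-(tk - t_dep[act]) / params$tau_starve)
    out[[k]] <- sig
  }
  out
}
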