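#' Model parameters for the chemotactic migration model
#'
#' Collects every biochemical/biophysical constant of the coupled
#' nutrient/bacteria equations
#' \deqn{\partial_t c = D_c \nabla^2 c - b\,\kappa\, g(c)}
#' \deqn{\partial_t b = -\nabla\cdot J_b + b\,\gamma\, g(c), \qquad
#'       J_b = -D_b \nabla b + b\,\chi \nabla f(c)}
#' in a fixed internal unit system: micrometres, seconds, micromolar
#' (uM), and cells per cubic micrometre.  All printed literature values
#' (mM, cells/mL, minutes, hours) are converted once, here, at
#' construction.
#'
#' @param Dc Nutrient diffusivity (um^2/s).
#' @param kappa_printed Maximal consumption rate per cell in the units in
#'   which it is usually reported, mM (cell/mL)^-1 s^-1.  Stored
#'   internally as uM um^3 cell^-1 s^-1 (multiply by 1e15).
#' @param c_half Monod (Michaelis-Menten) constant of `g(c) = c/(c +
#'   c_half)` (uM).
#' @param gamma Maximal proliferation rate (1/s); default one doubling
#'   per hour, `log(2)/3600`.
#' @param c_minus,c_plus Lower/upper receptor dissociation constants of
#'   the logarithmic sensing function (uM).
#' @param d_cell Characteristic cell size (um).
#' @param b_pack Packed (3D-printed) inoculum density (cells/um^3);
#'   0.95 corresponds to 0.95e12 cells/mL.
#' @param c0 Initial nutrient concentration (uM); default 1e4 uM = 10 mM.
#' @param sensing_mode `"log"` for the saturating logarithmic sensing
#'   function, `"linear"` for the non-saturating linear variant.
#' @param c_lin Scale of the linear sensing variant (uM).  Defaults to
#'   `(1/c_minus - 1/c_plus)^-1` so that linear and logarithmic sensing
#'   agree at small concentrations.
#' @param knockout `NULL`, or one of `"diffusion"`, `"growth"`,
#'   `"chemotaxis"`: zeroes Db, gamma, or chi respectively.
#' @param tau_delay Delay before starvation-induced signal loss begins
#'   after local nutrient depletion (s).
#' @param tau_starve Exponential decay constant of the cellular signal
#'   after the delay elapses (s); 1782 s = 29.7 min.
#' @param c_star Nutrient concentration below which a location counts as
#'   depleted for the signal model (uM).  The kinetic scale `c_half` is
#'   the default.
#'
#' @return An object of class `ks_params`.
#' @examples
#' p <- model_params()
#' monod_g(p$c_half, p)  # 0.5 by construction
#' @export
model_params <- function(Dc = 800,
                         kappa_printed = 1.6e-11,
                         c_half = 1,
                         gamma = log(2) / 3600,
                         c_minus = 1,
                         c_plus = 30,
                         d_cell = 1,
                         b_pack = 0.95,
                         c0 = 1e4,
                         sensing_mode = c("log", "linear"),
                         c_lin = NULL,
                         knockout = NULL,
                         tau_delay = 7200,
                         tau_starve = 1782,
                         c_star = c_half) {
  sensing_mode <- match.arg(sensing_mode)
  kappa <- kappa_to_internal(kappa_printed)
  pos <- c(Dc = Dc, kappa = kappa, c_half = c_half, c_minus = c_minus,
           c_plus = c_plus, d_cell = d_cell, b_pack = b_pack,
           tau_delay = tau_delay, tau_starve = tau_starve, c_star = c_star)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all rates, concentrations and lengths must be strictly positive; ",
         "offending: ", paste(names(pos)[!is.finite(pos) | pos <= 0],
                              collapse = ", "))
  }
  if (gamma < 0) stop("gamma must be non-negative")
  if (c0 < 0) stop("c0 must be non-negative")
  if (c_minus >= c_plus) stop("c_minus must be smaller than c_plus")
  if (is.null(c_lin)) c_lin <- 1 / (1 / c_minus - 1 / c_plus)
  if (c_lin <= 0) stop("c_lin must be strictly positive")
  if (!is.null(knockout)) {
    knockout <- match.arg(knockout, c("diffusion", "growth", "chemotaxis"))
    if (knockout == "growth") gamma <- 0
  }
  structure(
    list(Dc = Dc, kappa = kappa, kappa_printed = kappa_printed,
         c_half = c_half, gamma = gamma, c_minus = c_minus, c_plus = c_plus,
         d_cell = d_cell, b_pack = b_pack, c0 = c0,
         sensing_mode = sensing_mode, c_lin = c_lin, knockout = knockout,
         tau_delay = tau_delay, tau_starve = tau_starve, c_star = c_star),
    class = "ks_params")
}

#' @export
print.ks_params <- function(x, ...) {
  cat("Keller-Segel model parameters (internal units: um, s, uM, cells/um^3)\n")
  cat(sprintf("  Dc = %g um^2/s, kappa = %g uM um^3/cell/s (%.3g mM (cell/mL)^-1 s^-1)\n",
              x$Dc, x$kappa, x$kappa_printed))
  cat(sprintf("  c_half = %g uM, gamma = %.3g 1/s, c- = %g uM, c+ = %g uM\n",
              x$c_half, x$gamma, x$c_minus, x$c_plus))
  cat(sprintf("  sensing: %s (c_lin = %.4g uM), c0 = %g uM, b_pack = %g cells/um^3\n",
              x$sensing_mode, x$c_lin, x$c0, x$b_pack))
  cat(sprintf("  starvation signal: tau_delay = %g s, tau_starve = %g s, c* = %g uM\n",
              x$tau_delay, x$tau_starve, x$c_star))
  if (!is.null(x$knockout)) cat(sprintf("  knockout: %s\n", x$knockout))
  invisible(x)
}

#' Unit conversion for the per-cell consumption rate
#'
#' The consumption rate is usually reported in mM (cell/mL)^-1 s^-1;
#' internally it is carried in uM um^3 cell^-1 s^-1.  The factor is
#' 1e3 (mM to uM) times 1e12 (a density of 1 cell/um^3 is 1e12
#' cells/mL).
#'
#' @param kappa_printed Rate in mM (cell/mL)^-1 s^-1.
#' @return Rate in uM um^3 cell^-1 s^-1.
#' @export
kappa_to_internal <- function(kappa_printed) kappa_printed * 1e15

#' @rdname kappa_to_internal
#' @param kappa_internal Rate in uM um^3 cell^-1 s^-1.
#' @export
kappa_to_printed <- function(kappa_internal) kappa_internal * 1e-15

.medium_presets <- data.frame(
  xi     = c(2.2, 1.7, 1.2),
  Db0    = c(2.32, 0.93, 0.42),
  chi0   = c(145, 9, 5),
  f_pore = c(0.36, 0.17, 0.04),
  l_c    = c(4.6, 3.1, 2.4)
)

#' Porous-medium motility parameters
#'
#' Per-medium motility preset: the cellular diffusivity `Db0` and
#' chemotactic coefficient `chi0` measured in packings of mean pore size
#' `xi`, together with the pore-space volume fraction `f_pore` and mean
#' chord length `l_c` that control the density-dependent motility
#' correction.  The three shipped presets (`xi` = 2.2, 1.7, 1.2 um)
#' carry directly measured values; custom media can be constructed by
#' passing all fields.
#'
#' @param xi Mean pore size label (um).  If one of 2.2, 1.7, 1.2 and no
#'   other argument is given, the corresponding preset is returned.
#' @param Db0 Cellular diffusivity (um^2/s).
#' @param chi0 Chemotactic coefficient (um^2/s).
#' @param f_pore Pore-space volume fraction, in (0, 1).
#' @param l_c Mean chord length of the pore space (um).
#' @return An object of class `ks_medium`.
#' @examples
#' porous_medium(1.7)
#' @export
porous_medium <- function(xi, Db0 = NULL, chi0 = NULL, f_pore = NULL,
                          l_c = NULL) {
  if (is.null(Db0) && is.null(chi0) && is.null(f_pore) && is.null(l_c)) {
    row <- .medium_presets[abs(.medium_presets$xi - xi) < 1e-9, ]
    if (nrow(row) != 1L) {
      stop("no preset for xi = ", xi,
           "; available: ", paste(.medium_presets$xi, collapse = ", "),
           " um (or supply Db0, chi0, f_pore, l_c explicitly)")
    }
    Db0 <- row$Db0; chi0 <- row$chi0; f_pore <- row$f_pore; l_c <- row$l_c
  }
  if (any(c(Db0, chi0, l_c) < 0)) stop("Db0, chi0, l_c must be non-negative")
  if (f_pore <= 0 || f_pore >= 1) stop("f_pore must lie in (0, 1)")
  structure(list(xi = xi, Db0 = Db0, chi0 = chi0, f_pore = f_pore, l_c = l_c),
            class = "ks_medium")
}

#' @export
print.ks_medium <- function(x, ...) {
  cat(sprintf("Porous medium xi = %g um: Db = %g um^2/s, chi = %g um^2/s, f = %g, l_c = %g um\n",
              x$xi, x$Db0, x$chi0, x$f_pore, x$l_c))
  invisible(x)
}

#' @rdname porous_medium
#' @return `medium_presets()` returns the table of shipped presets.
#' @export
medium_presets <- function() .medium_presets

# effective coefficients after knockout flags
.effective_coeffs <- function(params, medium) {
  Db0 <- medium$Db0
  chi0 <- medium$chi0
  if (!is.null(params$knockout)) {
    if (params$knockout == "diffusion") Db0 <- 0
    if (params$knockout == "chemotaxis") chi0 <- 0
  }
  list(Db0 = Db0, chi0 = chi0, gamma = params$gamma)
}
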