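# First-passage engine: injection points, splitting probabilities and
# conditional mean first-passage times of the 1-D Smoluchowski process
#   dx = -D U'(x) dt + sqrt(2 D) dW,   U in kBT,
# with absorbing boundaries at x = 0 (retraction) and x = L (translocation),
# or absorbing at 0 / reflecting at L for a tethered polymer.
#
# All observables are spatial integrals of exp(+/- U); they are accumulated in
# log space (see integrals.R) so arbitrarily steep potentials cannot overflow
# and additive constants in U cancel exactly.

#' Injection point: potential minimum within a range
#'
#' Returns the grid position of the minimal potential within the closed range
#' `[range[1], range[2]]` — the most stable initial position of the polymer.
#' Ties are broken toward the smallest x. A degenerate range that contains no
#' grid point (e.g. `c(a, a)`) forces the injection point to the grid point
#' nearest the range centre, so the initial position can be pinned anywhere.
#'
#' @param U a `potential_profile`.
#' @param range numeric length-2, search window in nm (default the whole grid).
#' @return injection position x0 in nm (a grid point).
#' @export
find_injection_point <- function(U, range = NULL) {
  stopifnot(inherits(U, "potential_profile"))
  x <- U$x
  if (is.null(range)) range <- c(x[1], x[length(x)])
  stopifnot(is.numeric(range), length(range) == 2L)
  if (range[1] > range[2]) stop("injection range must have xmin <= xmax")
  if (range[2] < x[1] || range[1] > x[length(x)])
    stop("injection range does not intersect the grid")
  idx <- which(x >= range[1] & x <= range[2])
  if (length(idx) == 0L) {
    mid <- mean(range)
    return(x[which.min(abs(x - mid))])
  }
  x[idx[which.min(U$U[idx])]]
}

# Index of the grid point nearest x0 (x0 is snapped to the grid).
grid_index <- function(x, x0) {
  if (x0 < x[1] - 1e-9 || x0 > x[length(x)] + 1e-9)
    stop("x0 outside the grid domain [",
         format(x[1]), ", ", format(x[length(x)]), "]")
  which.min(abs(x - x0))
}

#' Splitting probabilities of retraction and translocation
#'
#' For both boundaries absorbing, the probability of exiting at x = L before
#' x = 0 starting from x0 is
#' `piL = int_0^x0 exp(U) dy / int_0^L exp(U) dy`, and `pi0 = 1 - piL`.
#' Integrals are trapezoidal on the profile grid, evaluated in log space.
#'
#' @param U a `potential_profile` with finite values.
#' @param x0 injection position in nm (snapped to the nearest grid point).
#' @return named numeric `c(pi0, piL)`.
#' @export
splitting_probabilities <- function(U, x0) {
  stopifnot(inherits(U, "potential_profile"))
  if (!all(is.finite(U$U))) stop("potential has non-finite values")
  i0 <- grid_index(U$x, x0)
  logPhi <- log_cumtrapz(U$x, U$U)
  n <- length(U$x)
  piL <- exp(logPhi[i0] - logPhi[n])
  c(pi0 = 1 - piL, piL = piL)
}

# pi_L(x0) * tau_L(x0) from the backward-equation double integral:
#   g(x) = [ J(L) Phi(x) / Phi(L) - J(x) ] / (D Phi(L)),
# with Phi(x) = int_0^x e^U, I(z) = int_0^z e^{-U(y)} Phi(y) dy,
# J(x) = int_0^x e^{U(z)} I(z) dz. Satisfies g(0) = g(L) = 0.
g_occupation <- function(x, Uv, D, i0) {
  n <- length(x)
  logPhi <- log_cumtrapz(x, Uv)
  logI <- log_cumtrapz(x, -Uv + logPhi)
  logJ <- log_cumtrapz(x, Uv + logI)
  a <- exp(logJ[n] + logPhi[i0] - 2 * logPhi[n] - log(D))
  b <- exp(logJ[i0] - logPhi[n] - log(D))
  max(a - b, 0)
}

#' Conditional mean first-passage times (untethered)
#'
#' Mean escape times of the drift-diffusion process with both boundaries
#' absorbing: `tau0` conditional on retraction (exit at 0), `tauL` conditional
#' on translocation (exit at L), and the unconditional mean escape time
#' `tau = pi0 tau0 + piL tauL`. Computed from the stationary backward-equation
#' double-integral solutions by cumulative trapezoids in a single O(n) pass;
#' the retraction branch is obtained by reflecting the potential about L/2.
#'
#' @inheritParams splitting_probabilities
#' @param D diffusion constant in nm^2/s.
#' @return named numeric `c(tau0, tauL, tau, pi0, piL)`, times in seconds.
#'   When a splitting probability is below 1e-12 the corresponding conditional
#'   time is reported as `NaN` with a warning.
#' @export
conditional_mfpt <- function(U, D, x0) {
  stopifnot(inherits(U, "potential_profile"))
  if (!all(is.finite(U$U))) stop("potential has non-finite values")
  if (!is.numeric(D) || D <= 0) stop("diffusion constant D must be positive")
  x <- U$x
  n <- length(x)
  i0 <- grid_index(x, x0)
  pis <- splitting_probabilities(U, x0)
  gL <- g_occupation(x, U$U, D, i0)                 # piL * tauL
  g0 <- g_occupation(x, rev(U$U), D, n + 1L - i0)   # pi0 * tau0 (reflected)
  tau <- g0 + gL
  tau0 <- if (pis[["pi0"]] < 1e-12) {
    warning("pi0 below 1e-12: tau0 is undefined (NaN)")
    NaN
  } else g0 / pis[["pi0"]]
  tauL <- if (pis[["piL"]] < 1e-12) {
    warning("piL below 1e-12: tauL is undefined (NaN)")
    NaN
  } else gL / pis[["piL"]]
  c(tau0 = tau0, tauL = tauL, tau = tau,
    pi0 = pis[["pi0"]], piL = pis[["piL"]])
}

#' Mean first-passage time of a tethered polymer
#'
#' One chain end is anchored, so translocation is impossible: the boundary at
#' x = L is reflecting and only retraction (absorption at x = 0) occurs. The
#' mean escape time is
#' `tau = (1/D) int_0^x0 exp(U(y)) [ int_y^L exp(-U(z)) dz ] dy`.
#'
#' @inheritParams conditional_mfpt
#' @return named numeric `c(tau, pi0, piL)` with `pi0 = 1`, `piL = 0` exactly.
#' @export
mfpt_tethered <- function(U, D, x0) {
  stopifnot(inherits(U, "potential_profile"))
  if (!all(is.finite(U$U))) stop("potential has non-finite values")
  if (!is.numeric(D) || D <= 0) stop("diffusion constant D must be positive")
  x <- U$x
  n <- length(x)
  i0 <- grid_index(x, x0)
  logM <- log_cumtrapz(x, -U$U)          # log int_0^y e^{-U}
  logK <- log_sub(logM[n], logM)         # log int_y^L e^{-U}
  logT <- log_cumtrapz(x, U$U + logK)
  c(tau = exp(logT[i0] - log(D)), pi0 = 1, piL = 0)
}

#' Per-voltage first-passage results for a nanopore system
#'
#' For each voltage: assembles the total potential (electrokinetic + entropy +
#' auxiliary terms), locates the injection point within `injection_range`, and
#' computes splitting probabilities and mean first-passage times (conditional
#' ones for a free polymer; the absorbing/reflecting escape time for a tethered
#' one, for which `piL = 0` by construction).
#'
#' This is the computational core behind [nanopore_fpt()]; use that entry point
#' unless you are composing the pieces yourself.
#'
#' @param eff effective (EOF-corrected) `charge_profile`.
#' @param static_terms list of voltage-independent `potential_profile`s
#'   (entropy, auxiliary forces) on the same grid; may be empty.
#' @param voltages numeric vector of transmembrane potentials in mV.
#' @param D diffusion constant in um^2/s (nanopore convention; converted to
#'   nm^2/s internally).
#' @param injection_range length-2 numeric in nm, or `NULL` for the full grid.
#' @param tethered logical; tethered (absorbing/reflecting) dynamics?
#' @param thermal_voltage kBT/e in mV.
#' @return a data.frame with one row per voltage and columns `voltage_mV`,
#'   `x0_nm`, `pi0`, `piL`, `tau0_s`, `tauL_s`, `tau_s`.
#' @export
voltage_sweep <- function(eff, static_terms, voltages, D,
                          injection_range = NULL, tethered = FALSE,
                          thermal_voltage = THERMAL_VOLTAGE_MV) {
  stopifnot(inherits(eff, "charge_profile"))
  D_nm <- D * 1e6                        # um^2/s -> nm^2/s
  rows <- lapply(voltages, function(v) {
    terms <- c(list(electrokinetic_term(eff, v, thermal_voltage)),
               static_terms)
    U <- total_potential(terms)
    x0 <- find_injection_point(U, injection_range)
    if (tethered) {
      r <- mfpt_tethered(U, D_nm, x0)
      data.frame(voltage_mV = v, x0_nm = x0, pi0 = r[["pi0"]],
                 piL = r[["piL"]], tau0_s = r[["tau"]], tauL_s = NA_real_,
                 tau_s = r[["tau"]])
    } else {
      r <- conditional_mfpt(U, D_nm, x0)
      data.frame(voltage_mV = v, x0_nm = x0, pi0 = r[["pi0"]],
                 piL = r[["piL"]], tau0_s = r[["tau0"]],
                 tauL_s = r[["tauL"]], tau_s = r[["tau"]])
    }
  })
  if (length(rows) == 0L)
    return(data.frame(voltage_mV = numeric(0), x0_nm = numeric(0),
                      pi0 = numeric(0), piL = numeric(0),
                      tau0_s = numeric(0), tauL_s = numeric(0),
                      tau_s = numeric(0)))
  do.call(rbind, rows)
}
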