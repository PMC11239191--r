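# Interaction-potential terms. Every term is a potential_profile: U(x) in kBT
# on the shared laa/2 grid; the total potential is their pointwise sum.

new_potential_profile <- function(x, U, voltage = NA_real_) {
  structure(list(x = x, U = U, voltage = voltage),
            class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  v <- if (is.na(x$voltage)) "voltage-independent" else
    sprintf("V = %g mV", x$voltage)
  cat(sprintf("potential profile on [%g, %g] nm (%d points), %s\n",
              min(x$x), max(x$x), length(x$x), v))
  cat(sprintf("  range [%.4g, %.4g] kBT\n", min(x$U), max(x$U)))
  invisible(x)
}

#' Electrokinetic potential term
#'
#' The work done by the transmembrane field on the polymer charge that has
#' crossed the pore: `UE(x) = (V / V_T) * integral_0^x sigma(y) dy`, with
#' `sigma` the EOF-corrected effective charge density in e/nm, `V` the applied
#' potential in mV and `V_T = kBT/e` the thermal voltage in mV, so that UE is
#' in kBT. `UE(0) = 0`.
#'
#' @param eff a `charge_profile` of kind `"effective"`.
#' @param V applied transmembrane potential in mV.
#' @param thermal_voltage kBT/e in mV (default 25.693, i.e. 25 C).
#' @return a `potential_profile` carrying `voltage = V`.
#' @export
electrokinetic_term <- function(eff, V, thermal_voltage = THERMAL_VOLTAGE_MV) {
  stopifnot(inherits(eff, "charge_profile"))
  if (!identical(eff$kind, "effective"))
    stop("electrokinetic_term() expects an effective (EOF-corrected) profile")
  if (!is.numeric(thermal_voltage) || thermal_voltage <= 0)
    stop("thermal_voltage must be positive")
  U <- (V / thermal_voltage) * cumtrapz(eff$x, eff$sigma)
  new_potential_profile(eff$x, U, voltage = V)
}

#' Entropic potential of a free (untethered) chain
#'
#' Confinement entropy of the two free tails of a self-avoiding chain with x nm
#' threaded: `US(x) = nu * (ln(x/L) + ln(1 - x/L))` in kBT, with `nu` the Flory
#' exponent. The term diverges logarithmically at both boundaries; the endpoint
#' values are replaced by the value a half grid spacing inside, which keeps the
#' first-passage integrands finite while preserving the shape of the
#' logarithmic wells.
#'
#' @param grid positions in nm spanning `[0, L]`.
#' @param L contour length in nm.
#' @param nu Flory exponent (default 0.59, self-avoiding chain).
#' @return a voltage-independent `potential_profile`.
#' @export
entropy_free_term <- function(grid, L, nu = 0.59) {
  stopifnot(is.numeric(grid), length(grid) >= 2L, L > 0)
  us <- function(x) nu * (log(x / L) + log(1 - x / L))
  U <- numeric(length(grid))
  inner <- grid > 0 & grid < L
  U[inner] <- us(grid[inner])
  h <- grid[2] - grid[1]
  U[grid <= 0] <- us(h / 2)
  U[grid >= L] <- us(L - h / 2)
  new_potential_profile(grid, U)
}

#' Entropic potential of a tethered Gaussian chain
#'
#' Confinement entropy when one chain end is anchored a distance `lt` above the
#' pore mouth, from the propagator of a non-self-avoiding Gaussian chain. With
#' `nC = (x - Lp/2)/b` Kuhn segments translocated and `nT = (L - x - Lp/2)/b`
#' not yet translocated,
#' `US(x) = -ln[ (2 pi nC b^2 / 3)^(-3/2) *
#'   (exp(-3 (lt - delta)^2 / (2 nC b^2)) - exp(-3 (lt + delta)^2 / (2 nC b^2)))
#'   * erf(sqrt(3 / (2 nT)) delta / b) ]`
#' in kBT, defined up to an additive constant; the returned profile is shifted
#' so its minimum over the valid region is 0. Outside the valid region
#' `Lp/2 < x < L - Lp/2` the term diverges, making the region inaccessible; the
#' profile there is clamped to the nearest valid value plus 25 kBT, which acts
#' as a reflecting wall.
#'
#' @inheritParams entropy_free_term
#' @param Lp pore length in nm.
#' @param lt tether distance above the pore in nm.
#' @param b Kuhn length in nm (default 0.6).
#' @param delta regularisation distance in nm (default 1e-3).
#' @return a voltage-independent `potential_profile`.
#' @export
entropy_tethered_term <- function(grid, L, Lp, lt = 0, b = 0.6, delta = 1e-3) {
  stopifnot(is.numeric(grid), length(grid) >= 2L, L > 0, Lp > 0,
            b > 0, delta > 0, lt >= 0)
  if (L <= Lp)
    stop("tethered entropy requires L > Lp (no valid interior otherwise)")
  nC <- (grid - Lp / 2) / b
  nT <- (L - grid - Lp / 2) / b
  valid <- nC > 0 & nT > 0
  if (!any(valid))
    stop("no grid points in the valid region (Lp/2, L - Lp/2)")
  U <- rep(NA_real_, length(grid))
  ncv <- nC[valid]
  ntv <- nT[valid]
  # log w(x), evaluated stably: near the pore wall (nC -> 0) the propagator
  # prefactor diverges and the Gaussian difference underflows, so work with
  # a(x) = 3 / (2 nC b^2) in log space throughout. The Gaussian difference
  # exp(-a (lt-delta)^2) - exp(-a (lt+delta)^2) = exp(-a (lt-delta)^2) *
  # (1 - exp(-4 a delta lt)); at lt = 0 it vanishes identically and the
  # x-dependent part of its lt -> 0 limit, a exp(-a delta^2), is used instead
  # (the dropped factor 4 delta lt is an additive constant in U).
  a <- 3 / (2 * ncv * b^2)
  log_pref <- -1.5 * log(2 * pi * ncv * b^2 / 3)
  log_gauss <- if (lt == 0) {
    -a * delta^2 + log(a)
  } else {
    -a * (lt - delta)^2 + log1p(-exp(-4 * a * delta * lt))
  }
  erf_arg <- sqrt(3 / (2 * ntv)) * delta / b
  U[valid] <- -(log_pref + log_gauss + log(erf(erf_arg)))
  U[valid] <- U[valid] - min(U[valid])
  iv <- which(valid)
  lo <- iv[1]; hi <- iv[length(iv)]
  if (lo > 1L) U[seq_len(lo - 1L)] <- U[lo] + 25
  if (hi < length(grid)) U[(hi + 1L):length(grid)] <- U[hi] + 25
  new_potential_profile(grid, U)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Constant-force potential term
#'
#' `UF(x) = F * x`, for a position-independent force such as hydrodynamic drag
#' from an osmotic or pressure gradient across the membrane.
#'
#' @inheritParams entropy_free_term
#' @param F force in kBT/nm; use [pn_to_kbt_nm()] to convert from pN.
#' @return a voltage-independent `potential_profile`.
#' @export
constant_force_term <- function(grid, F) {
  stopifnot(is.numeric(grid), is.numeric(F), length(F) == 1L, is.finite(F))
  new_potential_profile(grid, F * grid)
}

#' Convert a force from pN to kBT/nm
#'
#' Uses 1 kBT = 4.114 pN nm (298.15 K).
#'
#' @param f_pn force in pN.
#' @return force in kBT/nm.
#' @export
pn_to_kbt_nm <- function(f_pn) f_pn / KBT_PN_NM

#' Gaussian potential term
#'
#' `UG(x) = EG * exp(-(x - xG)^2 / (2 sG^2))`: a localised, voltage-independent
#' feature tied to a position on the polymer, e.g. a bulky side chain (EG > 0)
#' or a site-specific attraction to the channel interior (EG < 0).
#'
#' @inheritParams entropy_free_term
#' @param EG amplitude in kBT (either sign).
#' @param xG centre in nm.
#' @param sG width (standard deviation) in nm, > 0.
#' @return a voltage-independent `potential_profile`.
#' @export
gaussian_term <- function(grid, EG, xG, sG) {
  if (!is.numeric(sG) || sG <= 0) stop("Gaussian width sG must be positive")
  new_potential_profile(grid, EG * exp(-(grid - xG)^2 / (2 * sG^2)))
}

#' Barrier (error-function step) potential term
#'
#' `UB(x) = EB * erf((x - xB) / (sB sqrt(2)))`: a smoothed step of height 2 EB
#' centred at xB, e.g. the energetics of a membrane-binding region. Two barrier
#' terms of opposite amplitude offset in xB make a smoothed box potential.
#'
#' @inheritParams entropy_free_term
#' @param EB half-step amplitude in kBT (either sign).
#' @param xB centre in nm.
#' @param sB width in nm, > 0.
#' @return a voltage-independent `potential_profile`.
#' @export
barrier_term <- function(grid, EB, xB, sB) {
  if (!is.numeric(sB) || sB <= 0) stop("barrier width sB must be positive")
  new_potential_profile(grid, EB * erf((grid - xB) / (sB * sqrt(2))))
}

#' Sum potential terms on a shared grid
#'
#' @param terms list of `potential_profile` objects on one common grid. An
#'   empty list with `grid` supplied gives the zero potential.
#' @param grid grid to use when `terms` is empty.
#' @return a `potential_profile`; its `voltage` is taken from the unique
#'   non-`NA` voltage among the terms (or `NA` if none).
#' @export
total_potential <- function(terms, grid = NULL) {
  if (length(terms) == 0L) {
    if (is.null(grid)) stop("empty term list needs an explicit grid")
    return(new_potential_profile(grid, numeric(length(grid))))
  }
  stopifnot(all(vapply(terms, inherits, logical(1), "potential_profile")))
  x <- terms[[1]]$x
  for (t in terms[-1])
    if (!same_grid(x, t$x)) stop("potential terms live on different grids")
  U <- Reduce(`+`, lapply(terms, `[[`, "U"))
  volts <- unique(stats::na.omit(vapply(terms, `[[`, numeric(1), "voltage")))
  v <- if (length(volts) == 1L) volts else NA_real_
  new_potential_profile(x, U, voltage = v)
}

#' Export potential profiles as tab-separated text
#'
#' One `x_nm` column, then one `U_kT@<V>mV` column per profile.
#'
#' @param profiles list of `potential_profile`s on a shared grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_potentials <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  x <- profiles[[1]]$x
  cols <- list(x_nm = fmt_full(x))
  for (p in profiles) {
    if (!same_grid(x, p$x)) stop("profiles live on different grids")
    nm <- if (is.na(p$voltage)) "U_kT" else sprintf("U_kT@%gmV", p$voltage)
    cols[[nm]] <- fmt_full(p$U)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
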