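# Validation oracles: closed forms for the zero-potential special cases and a
# brute-force Euler-Maruyama trajectory simulator. These are independent of the
# spatial-integration engine in fpt.R and are used to validate it.

#' Closed-form first-passage moments for a free polymer at zero potential
#'
#' For U = 0 with both boundaries absorbing, with u = x0/L:
#' `pi0 = 1 - u`, `piL = u`, `tau0 = (L^2/2D) u (2 - u) / 3`,
#' `tauL = (L^2/2D) (1 - u)(1 + u) / 3`, `tau = (L^2/2D) u (1 - u)`.
#'
#' @param x0 injection position in nm, in `[0, L]`.
#' @param L domain length in nm.
#' @param D diffusion constant in nm^2/s.
#' @return named numeric `c(pi0, piL, tau0, tauL, tau)`, times in seconds.
#' @export
analytic_free <- function(x0, L, D) {
  stopifnot(x0 >= 0, x0 <= L, L > 0, D > 0)
  u <- x0 / L
  s <- L^2 / (2 * D)
  c(pi0 = 1 - u, piL = u,
    tau0 = s * u * (2 - u) / 3,
    tauL = s * (1 - u) * (1 + u) / 3,
    tau = s * u * (1 - u))
}

#' Closed-form mean first-passage time for a tethered polymer at zero potential
#'
#' Absorbing boundary at 0, reflecting at L, U = 0:
#' `tau = (L^2/2D) (x0/L) (2 - x0/L)`.
#'
#' @inheritParams analytic_free
#' @return mean escape time in seconds.
#' @export
analytic_tethered <- function(x0, L, D) {
  stopifnot(x0 >= 0, x0 <= L, L > 0, D > 0)
  u <- x0 / L
  (L^2 / (2 * D)) * u * (2 - u)
}

#' Euler-Maruyama first-passage simulator
#'
#' Brute-force overdamped Langevin trajectories
#' `x <- x - D U'(x) dt + sqrt(2 D dt) xi` with `U'` from central differences
#' on the profile grid and linear interpolation between grid points.
#' Trajectories are absorbed when a step lands at or beyond a boundary, or by a
#' Brownian-bridge within-step crossing test (which removes the leading
#' O(sqrt(dt)) first-passage bias of end-of-step detection); in
#' `"absorb0_reflectL"` mode, steps beyond L are specularly reflected (the
#' reflecting wall keeps end-of-step handling, with a small O(sqrt(dt)) bias
#' toward longer times). Empirical
#' splitting probabilities and (conditional) mean escape times are returned
#' with standard errors. Reproducible under `set.seed()`.
#'
#' @param U a `potential_profile`.
#' @param D diffusion constant in nm^2/s.
#' @param x0 starting position in nm.
#' @param n_traj number of trajectories.
#' @param dt time step in s; must satisfy `sqrt(2 D dt)` < grid spacing.
#' @param max_steps per-trajectory step cap; capped trajectories are excluded
#'   from the moments with a warning.
#' @param boundary_mode `"both_absorbing"` or `"absorb0_reflectL"`.
#' @return a list with `pi0`, `piL`, `tau0`, `tauL`, `tau`, their standard
#'   errors (`se_pi0`, `se_tau0`, ...), `n_used` and `n_capped`.
#' @export
simulate_langevin <- function(U, D, x0, n_traj = 10000, dt,
                              max_steps = 1e7,
                              boundary_mode = c("both_absorbing",
                                                "absorb0_reflectL")) {
  stopifnot(inherits(U, "potential_profile"), D > 0, n_traj >= 1)
  boundary_mode <- match.arg(boundary_mode)
  x <- U$x
  h <- x[2] - x[1]
  if (sqrt(2 * D * dt) >= h)
    stop("time step too large: sqrt(2 D dt) must be below the grid spacing ",
         format(h), " nm")
  L <- x[length(x)]
  drift <- -D * central_diff(x, U$U)
  res <- langevin_paths(x0, L, h, drift, D, dt, as.integer(n_traj),
                        max_steps, boundary_mode == "absorb0_reflectL")
  side <- res$side
  time <- res$time
  capped <- is.na(side)
  if (any(capped))
    warning(sum(capped), " trajectories hit max_steps and were excluded")
  side <- side[!capped]
  time <- time[!capped]
  n <- length(side)
  if (n == 0L) stop("all trajectories hit max_steps")
  piL <- mean(side == 1L)
  pi0 <- 1 - piL
  t0 <- time[side == 0L]
  tL <- time[side == 1L]
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  list(pi0 = pi0, piL = piL,
       tau0 = if (length(t0)) mean(t0) else NaN,
       tauL = if (length(tL)) mean(tL) else NaN,
       tau = mean(time),
       se_pi0 = sqrt(pi0 * piL / n), se_piL = sqrt(pi0 * piL / n),
       se_tau0 = sem(t0), se_tauL = sem(tL), se_tau = sem(time),
       n_used = n, n_capped = sum(capped))
}

# Central-difference derivative on a uniform grid (one-sided at the ends).
central_diff <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L)
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

#' Engine self-validation against the zero-potential closed forms
#'
#' Runs the spatial-integration engine on a flat potential (the configuration
#' with entropy off and EOF slope/intercept zero, where closed-form solutions
#' exist) and reports the maximum relative error of every first-passage
#' quantity against [analytic_free()] (both boundaries absorbing) and
#' [analytic_tethered()] (absorbing/reflecting), over a sweep of injection
#' points.
#'
#' @param n_residues chain length in residues (default 100).
#' @param laa length per residue in nm (default 1, so L = 100 nm).
#' @param D diffusion constant in nm^2/s (default 1).
#' @param x0_frac injection points as fractions of L
#'   (default `seq(0.05, 0.95, by = 0.05)`).
#' @return list with `free` and `tethered`: the maximum relative errors
#'   (fractions, not percent) over the sweep, and `details`, a data.frame of
#'   per-point errors.
#' @export
validate_engine <- function(n_residues = 100, laa = 1, D = 1,
                            x0_frac = seq(0.05, 0.95, by = 0.05)) {
  L <- n_residues * laa
  grid <- seq.int(0, 2L * n_residues) * (laa / 2)
  U <- new_potential_profile(grid, numeric(length(grid)))
  rel <- function(a, b) abs(a - b) / abs(b)
  rows <- lapply(x0_frac, function(u) {
    x0 <- u * L
    num <- conditional_mfpt(U, D, x0)
    ref <- analytic_free(x0, L, D)
    tet <- mfpt_tethered(U, D, x0)[["tau"]]
    tet_ref <- analytic_tethered(x0, L, D)
    data.frame(
      x0_frac = u,
      err_pi0 = rel(num[["pi0"]], ref[["pi0"]]),
      err_piL = rel(num[["piL"]], ref[["piL"]]),
      err_tau0 = rel(num[["tau0"]], ref[["tau0"]]),
      err_tauL = rel(num[["tauL"]], ref[["tauL"]]),
      err_tau = rel(num[["tau"]], ref[["tau"]]),
      err_tau_tethered = rel(tet, tet_ref))
  })
  details <- do.call(rbind, rows)
  list(free = max(details$err_pi0, details$err_piL, details$err_tau0,
                  details$err_tauL, details$err_tau),
       tethered = max(details$err_tau_tethered),
       details = details)
}
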