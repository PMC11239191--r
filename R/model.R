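#' Nanopore first-passage model of polymer translocation
#'
#' The main entry point. Builds the full one-dimensional interaction potential
#' for a charged polymer threading a nanopore — electrokinetic term from the
#' sequence-derived, EOF-corrected charge density; free or tethered chain
#' entropy; optional auxiliary force terms — and computes, for each applied
#' voltage, the injection point (potential minimum within `injection_range`),
#' the splitting probabilities of retraction (`pi0`) and translocation (`piL`),
#' and the conditional and unconditional mean escape times. For a tethered
#' polymer translocation is impossible (`piL = 0` by construction) and only the
#' mean escape time is reported.
#'
#' @param sequence single-letter residue string (see [parse_sequence()]), or a
#'   `polymer_sequence`.
#' @param voltages transmembrane potentials in mV.
#' @param D effective diffusion constant of the chain in the pore, in um^2/s
#'   (typically 0.1 to 10).
#' @param data optional experimental escape-time table (see
#'   [load_experiment()]) with columns `voltage_mV`, `tau_s` and optionally
#'   `tau_err_s`; enables [residuals.nanopore_fpt()] and the overlay in
#'   [plot.nanopore_fpt()].
#' @param direction,laa sequence direction and length per residue (nm); see
#'   [parse_sequence()].
#' @param Lp pore length in nm (charge-smoothing FWHM; default 3.5, a
#'   VDAC-like biological pore).
#' @param m_eof,b_eof electroosmotic slope (dimensionless) and intercept
#'   (e/nm); see [effective_charge_density()].
#' @param use_entropy include the chain-entropy term?
#' @param tethered is one chain end anchored above the pore? Switches both the
#'   entropy term and the boundary condition at x = L (reflecting).
#' @param lt tether distance above the pore in nm (tethered entropy only).
#' @param kuhn Kuhn length b in nm (default 0.6).
#' @param nu Flory exponent (default 0.59).
#' @param forces list of auxiliary force terms, each a list with `form` one of
#'   `"constant"` (field `F`, kBT/nm), `"gaussian"` (`EG` kBT, `xG` nm, `sG`
#'   nm) or `"barrier"` (`EB` kBT, `xB` nm, `sB` nm).
#' @param injection_range length-2 numeric (nm) restricting the injection-point
#'   search; `NULL` for the full `[0, L]`. A degenerate range `c(a, a)` pins
#'   the injection point at the grid point nearest `a`.
#' @param thermal_voltage kBT/e in mV (default 25.693, 25 C).
#' @param config a `porefpt_config` (see [run_config()]); when supplied it
#'   provides every parameter above and the other arguments are ignored.
#' @return an object of class `nanopore_fpt` with components `config`,
#'   `sequence`, `native` and `effective` (charge profiles), `results` (one
#'   row per voltage) and `data`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`, `residuals`, `as.data.frame`.
#' @examples
#' fit <- nanopore_fpt("GSGSGSKKKK", voltages = c(-40, 40), D = 1,
#'                     Lp = 3.5, use_entropy = FALSE)
#' fit
#' @export
nanopore_fpt <- function(sequence = NULL, voltages = numeric(0), D = 1,
                         data = NULL, direction = "N_to_C", laa = 0.4,
                         Lp = 3.5, m_eof = 0.654, b_eof = -0.21,
                         use_entropy = TRUE, tethered = FALSE, lt = 0,
                         kuhn = 0.6, nu = 0.59, forces = list(),
                         injection_range = NULL,
                         thermal_voltage = THERMAL_VOLTAGE_MV,
                         config = NULL) {
  if (is.null(config)) {
    seqtext <- if (inherits(sequence, "polymer_sequence"))
      paste(sequence$codes, collapse = "") else sequence
    if (inherits(sequence, "polymer_sequence")) {
      direction <- sequence$direction
      laa <- sequence$laa
    }
    config <- run_config(
      sequence = seqtext, direction = direction, laa = laa, Lp = Lp,
      m_eof = m_eof, b_eof = b_eof, use_entropy = use_entropy,
      tethered = tethered, lt = lt, b = kuhn, nu = nu, forces = forces,
      voltages = voltages, D = D, injection_range = injection_range,
      thermal_voltage = thermal_voltage)
  }
  sys <- assemble_system(config)
  results <- voltage_sweep(sys$effective, sys$static_terms,
                           config$calc$voltages, config$calc$D,
                           injection_range = config$calc$injection_range,
                           tethered = config$entropy$tethered,
                           thermal_voltage = config$thermal$thermal_voltage)
  structure(list(config = config, sequence = sys$sequence,
                 native = sys$native, effective = sys$effective,
                 static_terms = sys$static_terms,
                 results = results, data = data),
            class = "nanopore_fpt")
}

# Build the voltage-independent pieces of the model from a config.
assemble_system <- function(config) {
  seq <- parse_sequence(config$sequence$text,
                        direction = config$sequence$direction,
                        laa = config$sequence$laa)
  grid <- sequence_grid(seq)
  native <- native_charge_density(seq, config$pore$Lp, grid)
  eff <- effective_charge_density(native, config$pore$m_eof,
                                  config$pore$b_eof)
  static_terms <- list()
  ent <- config$entropy
  if (isTRUE(ent$use_entropy)) {
    static_terms <- c(static_terms, list(
      if (isTRUE(ent$tethered))
        entropy_tethered_term(grid, seq$L, config$pore$Lp,
                              lt = ent$lt, b = ent$b, delta = ent$delta)
      else
        entropy_free_term(grid, seq$L, nu = ent$nu)))
  }
  for (f in config$forces)
    static_terms <- c(static_terms, list(auxiliary_term(f, grid)))
  list(sequence = seq, grid = grid, native = native, effective = eff,
       static_terms = static_terms)
}

auxiliary_term <- function(f, grid) {
  switch(f$form,
         constant = constant_force_term(grid, f$F),
         gaussian = gaussian_term(grid, f$EG, f$xG, f$sG),
         barrier  = barrier_term(grid, f$EB, f$xB, f$sB),
         stop("unknown auxiliary force form: ", f$form))
}

#' Total interaction potential(s) of a fitted model
#'
#' @param object a `nanopore_fpt`.
#' @param voltages voltages in mV; defaults to the model's.
#' @return list of `potential_profile`s, one per voltage.
#' @export
potential_profiles <- function(object, voltages = NULL) {
  stopifnot(inherits(object, "nanopore_fpt"))
  if (is.null(voltages)) voltages <- object$config$calc$voltages
  lapply(voltages, function(v)
    total_potential(c(list(electrokinetic_term(
      object$effective, v, object$config$thermal$thermal_voltage)),
      object$static_terms)))
}

#' @export
print.nanopore_fpt <- function(x, ...) {
  cfg <- x$config
  cat("Nanopore first-passage model\n")
  cat(sprintf("  polymer: %d residues, L = %g nm (laa = %g nm, %s)%s\n",
              x$sequence$N, x$sequence$L, cfg$sequence$laa,
              cfg$sequence$direction,
              if (cfg$entropy$tethered) ", tethered" else ""))
  cat(sprintf("  pore: Lp = %g nm, mEOF = %g, bEOF = %g e/nm\n",
              cfg$pore$Lp, cfg$pore$m_eof, cfg$pore$b_eof))
  cat(sprintf("  D = %g um^2/s; entropy %s; %d auxiliary term(s)\n",
              cfg$calc$D, if (cfg$entropy$use_entropy) "on" else "off",
              length(cfg$forces)))
  if (nrow(x$results) > 0) {
    cat("Results:\n")
    print(format(x$results, digits = 4), row.names = FALSE)
  } else cat("No voltages requested.\n")
  invisible(x)
}

#' @export
summary.nanopore_fpt <- function(object, ...) {
  out <- list(model = object, coef = coef(object),
              results = object$results, n_data = NROW(object$data))
  class(out) <- "summary.nanopore_fpt"
  out
}

#' @export
print.summary.nanopore_fpt <- function(x, ...) {
  print(x$model)
  cat("Derived quantities:\n")
  co <- x$coef
  for (nm in names(co)) cat(sprintf("  %-24s %g\n", nm, co[[nm]]))
  if (x$n_data > 0) cat(sprintf("Experimental rows attached: %d\n", x$n_data))
  invisible(x)
}

#' @export
coef.nanopore_fpt <- function(object, ...) {
  c(N_residues = object$sequence$N,
    L_nm = object$sequence$L,
    net_charge_e = sum(object$sequence$z),
    total_native_charge_e = total_charge(object$native),
    total_effective_charge_e = total_charge(object$effective),
    mean_effective_density_e_nm =
      total_charge(object$effective) / object$sequence$L,
    D_um2_s = object$config$calc$D)
}

#' @export
as.data.frame.nanopore_fpt <- function(x, ...) x$results

#' Recompute first-passage results at new voltages
#'
#' @param object a `nanopore_fpt`.
#' @param voltages voltages in mV (default: the model's own).
#' @param ... unused.
#' @return data.frame as in the model's `results`.
#' @export
predict.nanopore_fpt <- function(object, voltages = NULL, ...) {
  cfg <- object$config
  if (is.null(voltages)) return(object$results)
  voltage_sweep(object$effective, object$static_terms, voltages,
                cfg$calc$D, injection_range = cfg$calc$injection_range,
                tethered = cfg$entropy$tethered,
                thermal_voltage = cfg$thermal$thermal_voltage)
}

#' Residuals against an attached experimental escape-time table
#'
#' Computes the model's mean escape time at each experimental voltage and
#' returns residuals on the log scale, `log(tau_obs) - log(tau_model)`, the
#' natural scale for escape times that vary over decades.
#'
#' @param object a `nanopore_fpt` built with `data =`.
#' @param ... unused.
#' @return numeric vector of log-scale residuals, one per data row.
#' @export
residuals.nanopore_fpt <- function(object, ...) {
  if (is.null(object$data))
    stop("no experimental data attached; pass `data =` to nanopore_fpt()")
  pred <- predict(object, voltages = object$data$voltage_mV)
  log(object$data$tau_s) - log(pred$tau_s)
}

#' Plot escape time versus voltage
#'
#' Mean escape time tau against applied voltage on a log time axis, with the
#' attached experimental table (if any) overlaid as points with error bars.
#'
#' @param x a `nanopore_fpt`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nanopore_fpt <- function(x, ...) {
  r <- x$results
  if (nrow(r) == 0) stop("no results to plot (no voltages)")
  yl <- range(c(r$tau_s, x$data$tau_s), finite = TRUE)
  if (yl[1] == yl[2]) yl <- yl * c(0.5, 2)
  graphics::plot(r$voltage_mV, r$tau_s, type = "l", log = "y",
                 xlab = "applied voltage (mV)", ylab = "mean escape time (s)",
                 ylim = yl, ...)
  if (!is.null(x$data)) {
    graphics::points(x$data$voltage_mV, x$data$tau_s, pch = 19)
    if (!is.null(x$data$tau_err_s))
      graphics::arrows(x$data$voltage_mV, x$data$tau_s - x$data$tau_err_s,
                       x$data$voltage_mV, x$data$tau_s + x$data$tau_err_s,
                       angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

#' Stochastic simulation of a fitted model
#'
#' Runs the Euler-Maruyama oracle at one of the model's voltages, starting from
#' that voltage's injection point, and returns the empirical first-passage
#' moments with standard errors — a brute-force cross-check of the
#' spatial-integration results.
#'
#' @param object a `nanopore_fpt`.
#' @param nsim number of trajectories.
#' @param seed optional RNG seed.
#' @param voltage which voltage (mV); default the first in the model.
#' @param dt time step in s; default `h^2 / (8 D)` with h the grid spacing,
#'   i.e. an r.m.s. step of half a grid spacing.
#' @param ... passed to [simulate_langevin()].
#' @return see [simulate_langevin()].
#' @export
simulate.nanopore_fpt <- function(object, nsim = 1000, seed = NULL,
                                  voltage = NULL, dt = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$config
  if (is.null(voltage)) {
    if (length(cfg$calc$voltages) == 0) stop("model has no voltages")
    voltage <- cfg$calc$voltages[1]
  }
  U <- potential_profiles(object, voltage)[[1]]
  x0 <- find_injection_point(U, cfg$calc$injection_range)
  D_nm <- cfg$calc$D * 1e6
  h <- U$x[2] - U$x[1]
  if (is.null(dt)) dt <- h^2 / (8 * D_nm)
  mode <- if (cfg$entropy$tethered) "absorb0_reflectL" else "both_absorbing"
  simulate_langevin(U, D_nm, x0, n_traj = nsim, dt = dt,
                    boundary_mode = mode, ...)
}

#' @importFrom stats coef predict residuals simulate
NULL
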