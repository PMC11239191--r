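test_that("injection point is the potential minimum, ties to smallest x", {
  L <- 100
  U0 <- zero_potential(L)
  expect_equal(find_injection_point(U0), 0)               # all-tie case
  grid <- U0$x
  Uw <- total_potential(list(gaussian_term(grid, -5, 30, 4)))
  expect_equal(find_injection_point(Uw), 30)
  # restricted range
  expect_equal(find_injection_point(Uw, c(50, 80)), 50)
  # degenerate range pins the point to the nearest grid node
  expect_equal(find_injection_point(Uw, c(49.9, 50.1)), 50)
  expect_equal(find_injection_point(Uw, c(49.76, 49.76)), 50)
  # disjoint range errors
  expect_error(find_injection_point(Uw, c(200, 300)), "intersect")
  expect_error(find_injection_point(Uw, c(80, 50)), "xmin")
})

test_that("splitting probabilities reduce to x0/L at zero potential", {
  L <- 100
  U0 <- zero_potential(L)
  p <- splitting_probabilities(U0, 25)
  expect_equal(p[["piL"]], 0.25, tolerance = 1e-12)
  expect_equal(p[["pi0"]] + p[["piL"]], 1, tolerance = 1e-12)
  expect_equal(splitting_probabilities(U0, 0)[["pi0"]], 1)
  expect_equal(splitting_probabilities(U0, L)[["piL"]], 1)
})

test_that("zero-potential moments match the closed forms to well under 1%", {
  v <- validate_engine()          # 100 residues at 1 nm, D = 1 nm^2/s
  expect_lt(v$free, 0.01)
  expect_lt(v$tethered, 0.01)
  # midpoint spot check: everything equals L^2/(8D) * 2 = 1250 s
  U0 <- zero_potential(100)
  r <- conditional_mfpt(U0, D = 1, x0 = 50)
  expect_equal(r[["tau0"]], 1250, tolerance = 1e-6)
  expect_equal(r[["tauL"]], 1250, tolerance = 1e-6)
  expect_equal(r[["tau"]], 1250, tolerance = 1e-6)
})

test_that("tau decomposes as pi0 tau0 + piL tauL on arbitrary potentials", {
  set.seed(3)
  for (i in 1:10) {
    U <- random_potential(L = 50)
    x0 <- sample(U$x[U$x > 5 & U$x < 45], 1)
    r <- conditional_mfpt(U, D = 100, x0 = x0)
    expect_equal(r[["pi0"]] + r[["piL"]], 1, tolerance = 1e-6)
    expect_lt(abs(r[["pi0"]] * r[["tau0"]] + r[["piL"]] * r[["tauL"]] -
                    r[["tau"]]) / r[["tau"]], 1e-3)
  }
})

test_that("results are exactly invariant to additive constants in U", {
  set.seed(4)
  U <- random_potential(L = 50)
  x0 <- 20
  base <- conditional_mfpt(U, D = 10, x0 = x0)
  for (c0 in c(-300, 1e4)) {
    Uc <- make_potential(U$x, U$U + c0)
    shifted <- conditional_mfpt(Uc, D = 10, x0 = x0)
    expect_equal(shifted, base, tolerance = 1e-10)
    expect_equal(mfpt_tethered(Uc, 10, x0), mfpt_tethered(U, 10, x0),
                 tolerance = 1e-10)
  }
})

test_that("reflecting the potential swaps retraction and translocation", {
  set.seed(5)
  U <- random_potential(L = 50)
  x0 <- 15
  fwd <- conditional_mfpt(U, D = 10, x0 = x0)
  Ur <- make_potential(U$x, rev(U$U))
  bwd <- conditional_mfpt(Ur, D = 10, x0 = 50 - x0)
  expect_equal(bwd[["pi0"]], fwd[["piL"]], tolerance = 1e-10)
  expect_equal(bwd[["piL"]], fwd[["pi0"]], tolerance = 1e-10)
  expect_equal(bwd[["tau0"]], fwd[["tauL"]], tolerance = 1e-10)
  expect_equal(bwd[["tauL"]], fwd[["tau0"]], tolerance = 1e-10)
  expect_equal(bwd[["tau"]], fwd[["tau"]], tolerance = 1e-10)
})

test_that("escape times scale as 1/D and as L^2 at zero potential", {
  r1 <- conditional_mfpt(zero_potential(100), D = 1, x0 = 30)
  r2 <- conditional_mfpt(zero_potential(100), D = 8, x0 = 30)
  expect_equal(r1[["tau"]] / r2[["tau"]], 8, tolerance = 1e-9)
  r3 <- conditional_mfpt(zero_potential(200), D = 1, x0 = 60)
  expect_equal(r3[["tau"]] / r1[["tau"]], 4, tolerance = 1e-6)
})

test_that("steep potentials (hundreds of kBT) do not overflow", {
  grid <- seq(0, 100, by = 0.5)
  U <- make_potential(grid, -15 * grid)        # 1500 kBT across the domain
  r <- suppressWarnings(conditional_mfpt(U, D = 1e6, x0 = 50))
  expect_true(all(is.finite(unlist(r[c("pi0", "piL", "tau")]))))
  expect_gt(r[["piL"]], 1 - 1e-12)
  expect_gt(r[["tau"]], 0)
  # drift-dominated limit: tau ~ distance / (D |U'|)
  expect_equal(r[["tau"]], 50 / (1e6 * 15), tolerance = 0.05)
})

test_that("tethered escape matches the reflecting-boundary closed form", {
  U0 <- zero_potential(100)
  expect_equal(mfpt_tethered(U0, 1, 100)[["tau"]], 5000, tolerance = 1e-9)
  expect_equal(mfpt_tethered(U0, 1, 0)[["tau"]], 0)
  for (u in seq(0.1, 0.9, by = 0.2)) {
    tau <- mfpt_tethered(U0, 1, 100 * u)[["tau"]]
    expect_equal(tau, analytic_tethered(100 * u, 100, 1), tolerance = 1e-2)
    # reflection lengthens paths relative to two open exits
    expect_gt(tau, conditional_mfpt(U0, 1, 100 * u)[["tau"]])
  }
  expect_identical(mfpt_tethered(U0, 1, 50)[["piL"]], 0)
})

test_that("conditional times at an absorbing start are flagged undefined", {
  U0 <- zero_potential(100)
  expect_warning(r <- conditional_mfpt(U0, 1, 0), "tauL")
  expect_true(is.nan(r[["tauL"]]))
  expect_equal(r[["pi0"]], 1)
})

test_that("voltage_sweep reproduces the flat-potential limit per voltage", {
  # 100 arbitrary residues at 1 nm/residue, entropy off, EOF slope and
  # intercept zero: U = 0, so voltage has no effect
  set.seed(6)
  s <- parse_sequence(random_sequence_text(100), laa = 1)
  nat <- native_charge_density(s, Lp = 3.5)
  eff <- effective_charge_density(nat, m_eof = 0, b_eof = 0)
  res <- voltage_sweep(eff, list(), voltages = c(0, 75, -120), D = 1e-6,
                       injection_range = c(50, 50))
  expect_equal(nrow(res), 3L)
  for (i in 1:3) {
    expect_equal(res$x0_nm[i], 50)
    expect_equal(res$tau_s[i], 1250, tolerance = 1e-6)
    expect_equal(res$pi0[i], 0.5, tolerance = 1e-9)
  }
  # empty voltage list -> empty results, stable columns
  empty <- voltage_sweep(eff, list(), numeric(0), D = 1)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("voltage_mV", "tau_s", "pi0", "piL") %in% names(empty)))
  # tethered sweeps report piL = 0 and no translocation time
  rt <- voltage_sweep(eff, list(), voltages = 50, D = 1e-6,
                      injection_range = c(50, 50), tethered = TRUE)
  expect_identical(rt$piL, 0)
  expect_true(is.na(rt$tauL_s))
  expect_equal(rt$tau_s, analytic_tethered(50, 100, 1), tolerance = 1e-6)
})
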