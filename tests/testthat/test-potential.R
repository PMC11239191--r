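test_that("electrokinetic term integrates the effective charge density", {
  s <- parse_sequence(random_sequence_text(50))
  nat <- native_charge_density(s, Lp = 3.5)
  # uniform density +1 e/nm via slope 0, intercept 1
  eff <- effective_charge_density(nat, 0, 1)
  U <- electrokinetic_term(eff, V = 25.693)
  expect_equal(U$U[1], 0)
  expect_equal(U$U, eff$x, tolerance = 1e-12)   # slope 1 kBT/nm at V = V_T
  # V = 0 kills the term
  expect_true(all(electrokinetic_term(eff, 0)$U == 0))
  # bilinearity: flipping both sigma and V leaves UE unchanged
  effm <- effective_charge_density(nat, 0, -1)
  expect_equal(electrokinetic_term(effm, -25.693)$U, U$U)
  # requires an EOF-corrected profile
  expect_error(electrokinetic_term(nat, 10), "effective")
})

test_that("free-chain entropy has the log-well shape with regularised ends", {
  L <- 40
  grid <- seq(0, L, by = 0.2)
  U <- entropy_free_term(grid, L, nu = 0.59)
  # direct evaluation at the midpoint
  expect_equal(U$U[grid == L / 2], 2 * 0.59 * log(0.5), tolerance = 1e-12)
  # symmetry about L/2
  expect_equal(U$U, rev(U$U), tolerance = 1e-12)
  # nu = 0 switches the term off
  expect_true(all(entropy_free_term(grid, L, nu = 0)$U == 0))
  # endpoints take the half-spacing value and stay finite
  h <- 0.2
  ref <- 0.59 * (log(h / 2 / L) + log(1 - h / 2 / L))
  expect_equal(U$U[1], ref)
  expect_equal(U$U[length(grid)], ref)
  expect_true(all(is.finite(U$U)))
})

test_that("exp(+/-US) stays integrable as the grid is refined", {
  # 500 residues at 0.4 nm; the e^{-US} integrand has x^{-nu} endpoint
  # singularities, so convergence there is O(h^{1-nu}) — slow but convergent
  L <- 500 * 0.4
  for (sgn in c(1, -1)) {
    g1 <- seq(0, L, by = 0.2)           # laa/2
    g2 <- seq(0, L, by = 0.1)           # laa/4
    i1 <- porefpt:::trapz(g1, exp(sgn * entropy_free_term(g1, L)$U))
    i2 <- porefpt:::trapz(g2, exp(sgn * entropy_free_term(g2, L)$U))
    expect_lt(abs(i1 - i2) / i2, 0.01)
  }
})

test_that("tethered entropy is finite inside, divergent toward the pore wall", {
  L <- 60; Lp <- 4; b <- 0.6
  grid <- seq(0, L, by = 0.02)   # fine enough to resolve the wall divergence
  # lt = 0: regularised by delta, still finite everywhere valid
  U0 <- entropy_tethered_term(grid, L, Lp, lt = 0, b = b)
  expect_true(all(is.finite(U0$U)))
  # lt > delta: climbs monotonically approaching x = Lp/2 from above
  U1 <- entropy_tethered_term(grid, L, Lp, lt = 1, b = b)
  valid <- which(grid > Lp / 2 & grid < L - Lp / 2)
  first10 <- U1$U[valid[1:10]]
  expect_true(all(diff(first10) < 0))   # decreasing away from the wall
  # minimum over the valid region is shifted to zero
  expect_equal(min(U1$U[valid]), 0)
  # clamped regions sit 25 kBT above the nearest valid value
  expect_equal(U1$U[valid[1] - 1], U1$U[valid[1]] + 25)
  expect_equal(U1$U[valid[length(valid)] + 1],
               U1$U[valid[length(valid)]] + 25)
  # doubling b moves values smoothly but not the clamp domain
  U2 <- entropy_tethered_term(grid, L, Lp, lt = 1, b = 2 * b)
  expect_identical(which(is.finite(U2$U)), seq_along(grid))
  # no valid interior without L > Lp
  expect_error(entropy_tethered_term(seq(0, 3, 0.1), 3, Lp = 4), "L > Lp")
})

test_that("auxiliary force terms have their stated functional forms", {
  grid <- seq(0, 100, by = 0.5)
  # constant force
  UF <- constant_force_term(grid, 0.1)
  expect_equal(UF$U[grid == 50], 5)
  expect_equal(UF$U[length(grid)] - UF$U[1], 0.1 * 100)
  expect_true(all(constant_force_term(grid, 0)$U == 0))
  expect_equal(pn_to_kbt_nm(4.114), 1)
  # gaussian: peak EG, half-maximum at xG +/- sG sqrt(2 ln 2)
  UG <- gaussian_term(grid, EG = 3, xG = 40, sG = 5)
  expect_equal(UG$U[grid == 40], 3)
  xh <- 40 + 5 * sqrt(2 * log(2))
  expect_equal(stats::approx(grid, UG$U, xout = xh)$y, 1.5, tolerance = 1e-3)
  expect_lt(min(gaussian_term(grid, -4, 40, 5)$U), 0)  # attractive allowed
  expect_error(gaussian_term(grid, 1, 40, 0), "positive")
  # barrier: odd step through xB with asymptotes +/- EB
  UB <- barrier_term(grid, EB = 2, xB = 50, sB = 3)
  expect_equal(UB$U[grid == 50], 0)
  expect_equal(UB$U[length(grid)], 2, tolerance = 1e-9)
  expect_equal(UB$U[1], -2, tolerance = 1e-9)
  expect_error(barrier_term(grid, 1, 50, -1), "positive")
  # opposite barriers offset in xB make a smoothed box
  box <- total_potential(list(barrier_term(grid, 2, 30, 2),
                              barrier_term(grid, -2, 70, 2)))
  expect_equal(box$U[grid == 50], 4, tolerance = 1e-6)
  expect_equal(box$U[1], 0, tolerance = 1e-6)
  expect_equal(box$U[length(grid)], 0, tolerance = 1e-6)
})

test_that("total_potential sums pointwise on a shared grid", {
  grid <- seq(0, 20, by = 0.5)
  a <- gaussian_term(grid, 2, 8, 2)
  b <- barrier_term(grid, 1, 12, 1)
  cst <- constant_force_term(grid, 0.05)
  # empty list with a grid is the zero potential
  z <- total_potential(list(), grid = grid)
  expect_true(all(z$U == 0))
  # single term is the identity
  expect_equal(total_potential(list(a))$U, a$U)
  # order independence
  expect_equal(total_potential(list(a, b, cst))$U,
               total_potential(list(cst, a, b))$U)
  # exact cancellation
  expect_true(all(total_potential(list(a, gaussian_term(grid, -2, 8, 2)))$U == 0))
  # grid mismatch is an error
  other <- gaussian_term(seq(0, 20, by = 0.25), 1, 8, 2)
  expect_error(total_potential(list(a, other)), "grid")
})

test_that("potential profiles export one column per voltage", {
  s <- parse_sequence("KKKDDDEEE")
  fit <- suppressWarnings(
    nanopore_fpt(s, voltages = c(-25, 50), D = 1, use_entropy = FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_potentials(potential_profiles(fit), f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("x_nm", "U_kT@-25mV", "U_kT@50mV"))
  back <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(back), length(sequence_grid(s)))
})
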