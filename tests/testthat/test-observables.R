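const <- thermo_constants()

test_that("log P converts a Gibbs energy gap into decadic log units", {
  expect_equal(log_p(-10, -10), 0)
  expect_equal(log_p(-10 + const$RTln10, -10), 1.0)
  expect_equal(log_p(-3, -8), -log_p(-8, -3))  # phase-exchange antisymmetry
  # a compound much more stable in water partitions into water
  expect_lt(log_p(-20, -5), 0)
  expect_error(log_p(NaN, 0), "finite")
})

test_that("log D applies the acid/base ionization shift at pH 7.4", {
  expect_equal(log_d(1.3, "base", pKa = 7.4), 1.3 - log10(2))
  expect_equal(log_d(2.0, "acid", pKa = 6.4), 2.0 - log10(1 + 10^1.0))
  expect_equal(log_d(2.0, "acid", pKa = 6.4), 0.9586, tolerance = 1e-4)
  expect_equal(log_d(0.7, "base", pKa = -5), 0.7, tolerance = 1e-6)  # never protonated
  expect_equal(log_d(0.7, "none"), 0.7)
  expect_error(log_d(1, "acid"), "missing pKa")
  # vectorized with per-compound types
  out <- log_d(c(1, 1, 1), c("acid", "base", "none"), pKa = c(7.4, 7.4, NA))
  expect_equal(out, c(1 - log10(2), 1 - log10(2), 1))
})

test_that("log D never exceeds log P and pH is overridable", {
  set.seed(31)
  logp <- runif(50, -5, 5)
  pka <- runif(50, 0, 14)
  type <- sample(c("acid", "base"), 50, replace = TRUE)
  expect_true(all(log_d(logp, type, pka) <= logp + 1e-12))
  # at pH = pKa the shift is exactly log10(2) regardless of site type
  expect_equal(log_d(0, "acid", pKa = 3, pH = 3), -log10(2))
})

test_that("the two-parameter pKa model is affine in the Gibbs gap", {
  p <- pka_params(a = 1 / const$RTln10, b = 0)
  expect_equal(pka_from_gibbs(0, const$RTln10, p), 1.0)
  expect_equal(pka_from_gibbs(-40, -40, pka_params(0.5, 2)), 2)  # dG = 0
  expect_equal(pka_from_gibbs(0, 10, suppressWarnings(pka_params(0, 3))), 3)  # degenerate slope
  # doubling the slope doubles pKa - b
  p2 <- pka_params(2 / const$RTln10, 5)
  expect_equal(pka_from_gibbs(0, 3, p2) - 5,
               2 * (pka_from_gibbs(0, 3, pka_params(1 / const$RTln10, 5)) - 5))
  expect_warning(pka_params(-1, 0), "not physically oriented")
})

two_species <- function(g_a, g_b, phase = "water") {
  sol <- rbind(
    data.frame(compound_id = "1", tautomer_id = "A", conformer_id = "C1",
               phase = phase, E_sol = g_a, mu_ex = 0, V_m = 0, q = 0),
    data.frame(compound_id = "1", tautomer_id = "B", conformer_id = "C1",
               phase = phase, E_sol = g_b, mu_ex = 0, V_m = 0, q = 0))
  validate_states(sol)
}

test_that("direct tautomerization free energy is G_b - G_a", {
  st <- two_species(-10, -14.8)
  idw <- identity_params("water")
  ens_a <- species_ensemble(st, "1", "water", "single-tautomer", "A")
  ens_b <- species_ensemble(st, "1", "water", "single-tautomer", "B")
  r <- tautomer_dg_direct(ens_a, ens_b, idw)
  expect_equal(r$dG, -4.8)
  expect_equal(tautomer_dg_direct(ens_b, ens_a, idw)$dG, 4.8)  # antisymmetry
  # isoenergetic tautomers react with dG = 0
  st_eq <- two_species(-10, -10)
  eq_a <- species_ensemble(st_eq, "1", "water", "single-tautomer", "A")
  eq_b <- species_ensemble(st_eq, "1", "water", "single-tautomer", "B")
  expect_equal(tautomer_dg_direct(eq_a, eq_b, idw)$dG, 0)
  expect_error(tautomer_dg_direct(ens_a, ens_a, idw), "must differ")
  st_c <- two_species(-10, -14.8, phase = "cyclohexane")
  ens_c <- species_ensemble(st_c, "1", "cyclohexane", "single-tautomer", "B")
  expect_error(tautomer_dg_direct(ens_a, ens_c, idw), "phase mismatch")
})

cycle_states <- function(E_sol, E_gas, E_hl, therm, tautomer_id) {
  validate_states(rbind(
    data.frame(compound_id = "1", tautomer_id = tautomer_id, conformer_id = "C1",
               phase = "water", E_sol = E_sol, mu_ex = 0, V_m = 0, q = 0,
               E_gas = E_gas, G_thermal_gas = therm, E_gas_highlevel = E_hl),
    data.frame(compound_id = "1", tautomer_id = tautomer_id, conformer_id = "C1",
               phase = "gas", E_sol = E_gas, mu_ex = 0, V_m = 0, q = 0,
               E_gas = E_gas, G_thermal_gas = therm, E_gas_highlevel = E_hl)))
}

test_that("the thermodynamic cycle closes onto the direct route", {
  idw <- identity_params("water")
  make_pair <- function(E_sol, E_gas, E_hl, therm, t) {
    st <- cycle_states(E_sol, E_gas, E_hl, therm, t)
    list(sol = species_ensemble(st, "1", "water", "single-tautomer", t),
         gas = species_ensemble(st, "1", "gas", "single-tautomer", t))
  }
  a <- make_pair(-20, -18, -18, 0, "A")
  b <- make_pair(-24, -21, -21, 0, "B")
  cyc <- tautomer_dg_cycle(a$gas, a$sol, b$gas, b$sol, idw)
  dir <- tautomer_dg_direct(a$sol, b$sol, idw)
  expect_equal(cyc$dG, dir$dG, tolerance = 1e-9)

  # stated cycle legs: dE_gas = -3, d(thermal) = +0.5, ddG_hyd = -1
  a2 <- make_pair(-15, -10, -30, 1.0, "A")   # dG_hyd(a) = -5
  b2 <- make_pair(-16, -10, -33, 1.5, "B")   # dG_hyd(b) = -6
  cyc2 <- tautomer_dg_cycle(a2$gas, a2$sol, b2$gas, b2$sol, idw)
  expect_equal(cyc2$dG, -3 + 0.5 - 1)
  cyc2r <- tautomer_dg_cycle(b2$gas, b2$sol, a2$gas, a2$sol, idw)
  expect_equal(cyc2r$dG, -cyc2$dG)

  # missing high-level fields are reported with the offending state
  bad <- cycle_states(-15, -10, NA, 1.0, "A")
  bad_gas <- species_ensemble(bad, "1", "gas", "single-tautomer", "A")
  expect_error(tautomer_dg_cycle(bad_gas, a2$sol, b2$gas, b2$sol, idw),
               "E_gas_highlevel.*1, A, C1")
})

test_that("tautomerization free energies are additive around a cycle", {
  idw <- identity_params("water")
  g <- c(A = -10, B = -12.5, C = -9.1)
  st <- validate_states(do.call(rbind, lapply(names(g), function(t) {
    data.frame(compound_id = "1", tautomer_id = t, conformer_id = "C1",
               phase = "water", E_sol = g[[t]], mu_ex = 0, V_m = 0, q = 0)
  })))
  ens <- lapply(names(g), function(t)
    species_ensemble(st, "1", "water", "single-tautomer", t))
  names(ens) <- names(g)
  ab <- tautomer_dg_direct(ens$A, ens$B, idw)$dG
  bc <- tautomer_dg_direct(ens$B, ens$C, idw)$dG
  ac <- tautomer_dg_direct(ens$A, ens$C, idw)$dG
  expect_equal(ab + bc, ac, tolerance = 1e-9)
})
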