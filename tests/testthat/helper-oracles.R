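# Independent oracles and small fixture builders shared across tests.

# direct-summation Boltzmann free energy (no shift stabilization)
naive_boltzmann <- function(g, const = thermo_constants()) {
  -const$RT * log(sum(exp(-g / const$RT)))
}

# build a one-phase state table from vectors; gas rows added when E_gas given
make_states <- function(E_sol, mu_ex, V_m = 100, q = 0, E_gas = NULL,
                        phase = "cyclohexane", compound_id = "X",
                        tautomer_id = "T1",
                        G_thermal_gas = NULL, E_gas_highlevel = NULL) {
  n <- length(E_sol)
  sol <- data.frame(
    compound_id = compound_id, tautomer_id = tautomer_id,
    conformer_id = paste0("C", seq_len(n)), phase = phase,
    E_sol = E_sol, mu_ex = mu_ex,
    V_m = rep_len(V_m, n), q = rep_len(q, n),
    E_gas = if (is.null(E_gas)) NA_real_ else rep_len(E_gas, n),
    stringsAsFactors = FALSE)
  if (!is.null(G_thermal_gas)) sol$G_thermal_gas <- rep_len(G_thermal_gas, n)
  if (!is.null(E_gas_highlevel)) sol$E_gas_highlevel <- rep_len(E_gas_highlevel, n)
  if (!is.null(E_gas)) {
    gas <- sol
    gas$phase <- "gas"
    gas$E_sol <- gas$E_gas
    gas$mu_ex <- 0
    sol <- rbind(sol, gas)
  }
  validate_states(sol)
}

ensemble_of <- function(states, phase, compound_id = "X", ...) {
  species_ensemble(states, compound_id, phase, ...)
}

# identity correction: corrected mu equals raw mu
identity_params <- function(phase = "cyclohexane") {
  correction_params("1-par", c_V = 0, phase = phase)
}

# Euler-angle rotation matrix
rot3 <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# brute-force minimal RMSD over rotations: multi-start numerical minimization
rmsd_rotmin_oracle <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  obj <- function(p) {
    d <- a - b %*% rot3(p[1], p[2], p[3])
    sqrt(sum(d * d) / nrow(a))
  }
  starts <- as.matrix(expand.grid(c(0, pi / 2, pi, 3 * pi / 2),
                                  c(0, pi / 2, pi), c(0, pi)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

# ground-truth correction parameter sets used by recovery tests
truth_for <- function(variant, phase = "cyclohexane") {
  switch(variant,
    "1-par" = correction_params("1-par", c_V = -0.149, phase = phase),
    "2-par" = correction_params("2-par", c_mu = 2.02, c_V = -0.178, phase = phase),
    "2-par-I" = correction_params("2-par-I", c_V = -0.109, d = -1.66, phase = phase),
    "3-par" = correction_params("3-par", c_mu = 1.85, c_V = -0.147, d = -1.08,
                                phase = phase),
    "water-3-par-q" = correction_params("water-3-par-q", c_mu = 0.95,
                                        c_V = -0.11, c_q = -3.1, phase = "water")
  )
}

gen_for <- function(variant, n = 40, noise = 0, seed = 1, ...) {
  phase <- if (variant == "water-3-par-q") "water" else "cyclohexane"
  cfg <- generator_config(
    n_compounds = n, true_params = truth_for(variant, phase),
    noise_sd = noise, seed = seed,
    fraction_anions = if (variant == "water-3-par-q") 0.2 else 0,
    fraction_cations = if (variant == "water-3-par-q") 0.2 else 0, ...)
  generate_states(cfg)
}

# deterministic displaced geometry at an exact Kabsch RMSD from `base`
scale_to_rmsd_test <- function(base, target, seed) {
  set.seed(seed)
  delta <- matrix(rnorm(length(base)), ncol = 3)
  f <- function(s) kabsch_rmsd(base, base + s * delta) - target
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  s <- uniroot(f, c(0, hi), tol = 1e-12)$root
  base + s * delta
}

random_prediction_table <- function(n, seed) {
  set.seed(seed)
  prediction_table(paste0("id", seq_len(n)),
                   stats::rnorm(n, 0, 2),
                   stats::rnorm(n, 0, 2),
                   group = sample(c("g1", "g2"), n, replace = TRUE))
}
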