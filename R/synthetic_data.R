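# run expr under a private RNG stream; the caller's global seed is untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

#' Configuration of the synthetic-data generator
#'
#' Collects the ground-truth model and the sampling conditions from which
#' synthetic per-state datasets are drawn. The default energy scales mimic
#' the regimes of quantum-chemical solvation pipelines: excess chemical
#' potentials in [-80, 20] kcal/mol, partial molar volumes in [50, 400]
#' cubic Angstrom (shared within 2 percent across conformers of a species),
#' conformer spreads within 5 kcal/mol.
#'
#' @param n_compounds Number of compounds to generate.
#' @param tautomers_per_compound Integer range (length-2) of tautomer counts.
#' @param conformers_per_state Integer range of conformer counts per
#'   tautomer.
#' @param true_params Ground-truth [correction_params()] used to construct
#'   reference solvation free energies.
#' @param true_pka_params Ground-truth [pka_params()] for titratable
#'   compounds.
#' @param noise_sd Gaussian noise added to reference observables, kcal/mol.
#' @param fraction_acids,fraction_bases Fractions of titratable compounds
#'   (must sum to at most 1).
#' @param fraction_anions,fraction_cations Fractions of ionic species in the
#'   solvation training set (nonzero only for water-type models with a
#'   charge term).
#' @param pka_range Range the true pKa values are drawn from.
#' @param seed Integer seed of the generator's private random stream.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 100L,
                             tautomers_per_compound = c(1L, 1L),
                             conformers_per_state = c(1L, 1L),
                             true_params = correction_params(
                               "3-par", c_mu = 1.85, c_V = -0.147,
                               d = -1.08, phase = "cyclohexane"),
                             true_pka_params = pka_params(
                               a = 1 / thermo_constants()$RTln10, b = -190),
                             noise_sd = 0,
                             fraction_acids = 0.3, fraction_bases = 0.5,
                             fraction_anions = 0, fraction_cations = 0,
                             pka_range = c(2, 12),
                             seed = 1L) {
  stopifnot(n_compounds >= 1L, noise_sd >= 0,
            length(tautomers_per_compound) == 2L,
            length(conformers_per_state) == 2L,
            all(tautomers_per_compound >= 1L),
            all(conformers_per_state >= 1L),
            inherits(true_params, "correction_params"),
            inherits(true_pka_params, "pka_params"))
  for (f in c(fraction_acids, fraction_bases, fraction_anions, fraction_cations)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (fraction_acids + fraction_bases > 1) {
    stop("fraction_acids + fraction_bases must not exceed 1")
  }
  if (fraction_anions + fraction_cations > 1) {
    stop("fraction_anions + fraction_cations must not exceed 1")
  }
  structure(
    list(n_compounds = as.integer(n_compounds),
         tautomers_per_compound = as.integer(tautomers_per_compound),
         conformers_per_state = as.integer(conformers_per_state),
         true_params = true_params, true_pka_params = true_pka_params,
         noise_sd = noise_sd,
         fraction_acids = fraction_acids, fraction_bases = fraction_bases,
         fraction_anions = fraction_anions, fraction_cations = fraction_cations,
         pka_range = pka_range, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic per-state solvation dataset with known ground truth
#'
#' Draws per-state electronic energies, excess chemical potentials, partial
#' molar volumes and charges for every compound/tautomer/conformer, then
#' computes the *exact* ensemble solvation free energy implied by the
#' ground-truth correction model (solution partition function with corrected
#' excess chemical potentials, minus the gas-phase partition function over
#' `E_gas`) and adds Gaussian noise of sd `noise_sd` to form the reference
#' values. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with `states` (a validated `state_table` holding solution
#'   and gas rows), `reference` (data frame `compound_id`, `phase`,
#'   `dG_ref`, `dG_true`, `subset`), and `truth` (the generating
#'   [correction_params()]).
#' @export
generate_states <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  params <- config$true_params
  const <- thermo_constants()
  with_local_seed(config$seed, {
    n <- config$n_compounds
    subset <- rep("neutral", n)
    n_an <- round(config$fraction_anions * n)
    n_ca <- round(config$fraction_cations * n)
    if (n_an + n_ca > 0L) {
      subset[seq_len(n_an)] <- "anion"
      if (n_ca > 0L) subset[n_an + seq_len(n_ca)] <- "cation"
    }
    rows <- list()
    for (i in seq_len(n)) {
      cid <- sprintf("CMP_%04d", i)
      q <- switch(subset[i], neutral = 0, anion = -1, cation = 1)
      n_taut <- sample(seq(config$tautomers_per_compound[1L],
                           config$tautomers_per_compound[2L]), 1L)
      V_base <- runif1(50, 400)
      mu_base <- runif1(-80, 20)
      for (t in seq_len(n_taut)) {
        tid <- paste0("T", t)
        n_conf <- sample(seq(config$conformers_per_state[1L],
                             config$conformers_per_state[2L]), 1L)
        E_gas_base <- runif1(-30, 0) + (t - 1) * runif1(0, 3)
        for (c in seq_len(n_conf)) {
          cfid <- paste0("C", c)
          E_gas <- E_gas_base + if (c == 1L) 0 else runif1(0, 5)
          E_sol <- E_gas + runif1(-6, 2)
          mu_ex <- mu_base + runif1(-2, 2)
          V_m <- V_base * (1 + runif1(-0.02, 0.02))
          rows[[length(rows) + 1L]] <- data.frame(
            compound_id = cid, tautomer_id = tid, conformer_id = cfid,
            phase = c(params$phase, "gas"),
            E_sol = c(E_sol, NA_real_), E_gas = E_gas,
            mu_ex = c(mu_ex, 0), V_m = V_m, q = q,
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    # gas rows carry no solution-phase energy; keep E_sol finite-but-unused
    tab$E_sol[tab$phase == "gas"] <- tab$E_gas[tab$phase == "gas"]
    states <- validate_states(tab)
    dG_true <- predict_dg_solv(states, params, const)
    noise <- stats::rnorm(length(dG_true), 0, config$noise_sd)
    reference <- data.frame(
      compound_id = names(dG_true), phase = params$phase,
      dG_true = unname(dG_true), dG_ref = unname(dG_true) + noise,
      subset = subset, stringsAsFactors = FALSE)
    list(states = states, reference = reference, truth = params)
  })
}

#' Single-representative training rows from a generated dataset
#'
#' Convenience bridge from [generate_states()] to [fit_correction()]: joins
#' the lowest-free-energy representative state of each compound with its
#' reference solvation free energy.
#'
#' @param dataset A list as returned by [generate_states()].
#' @return Data frame with the columns [fit_correction()] expects.
#' @export
training_rows <- function(dataset) {
  reps <- representative_rows(dataset$states, dataset$truth$phase)
  merge(reps, dataset$reference[c("compound_id", "dG_ref")], by = "compound_id")
}

#' Generate titratable species with known pKa, log P and log D
#'
#' Constructs, per compound, the water-phase Gibbs energies of the
#' protonated and deprotonated forms so that the ground-truth pKa model maps
#' the deprotonation Gibbs energy difference exactly onto the drawn true
#' pKa, plus a consistent pair of water/organic Gibbs energies reproducing a
#' drawn true log P. Acid/base site types are assigned by the configured
#' fractions. Observed columns (`dG_deprot_obs`) carry Gaussian noise of sd
#' `noise_sd`; truth columns are exact.
#'
#' @param config A [generator_config()] with
#'   `fraction_acids + fraction_bases > 0`.
#' @param pH pH at which the true log D is evaluated (default 7.4).
#' @return Data frame with one row per compound: `compound_id`,
#'   `site_type`, `pka_true`, `dG_deprot`, `dG_deprot_obs`,
#'   `G_protonated_W`, `G_deprotonated_W`, `logp_true`, `G_water`,
#'   `G_organic`, `logd_true`.
#' @export
generate_titratable <- function(config, pH = 7.4) {
  stopifnot(inherits(config, "generator_config"))
  if (config$fraction_acids + config$fraction_bases <= 0) {
    stop("no titratable compounds: fractions are zero")
  }
  pk <- config$true_pka_params
  const <- thermo_constants()
  with_local_seed(config$seed + 1L, {
    n <- config$n_compounds
    u <- stats::runif(n)
    site <- ifelse(u < config$fraction_acids, "acid",
                   ifelse(u < config$fraction_acids + config$fraction_bases,
                          "base", "none"))
    pka_true <- stats::runif(n, config$pka_range[1L], config$pka_range[2L])
    pka_true[site == "none"] <- NA_real_
    dG <- (pka_true - pk$b) / pk$a
    G_prot <- stats::runif(n, -120, -80)
    G_deprot <- G_prot + dG
    logp_true <- stats::runif(n, -4, 6)
    G_water <- stats::runif(n, -40, -10)
    G_org <- G_water - logp_true * const$RTln10
    noise <- stats::rnorm(n, 0, config$noise_sd)
    data.frame(
      compound_id = sprintf("TIT_%04d", seq_len(n)),
      site_type = site, pka_true = pka_true,
      dG_deprot = dG, dG_deprot_obs = dG + noise,
      G_protonated_W = G_prot, G_deprotonated_W = G_deprot,
      logp_true = logp_true, G_water = G_water, G_organic = G_org,
      logd_true = log_d(logp_true, site, pka_true, pH = pH),
      stringsAsFactors = FALSE)
  })
}

# rescale a perturbation so the Kabsch RMSD from `base` hits `target`
scale_to_rmsd <- function(base, delta, target) {
  if (target <= 0) return(base)
  f <- function(s) kabsch_rmsd(base, base + s * delta) - target
  hi <- 1
  while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
  s <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  base + s * delta
}

#' Generate a planted-cluster conformer set
#'
#' Builds a random base geometry and plants `n_clusters` well-separated
#' cluster centers (pairwise Kabsch RMSD at least 0.8 by construction when
#' `between >= 1`), each surrounded by members within `within` Angstrom, so
#' the true clustering at a 0.5 Angstrom radius is known exactly. Energies
#' increase with cluster index and member index, so the first planted
#' cluster holds the global minimum and each center is its cluster's
#' lowest-energy member. Deterministic given `seed`.
#'
#' @param n_clusters Number of planted clusters.
#' @param members Conformers per cluster (center included).
#' @param n_atoms Number of atoms (at least 3).
#' @param within Max member-to-center RMSD, Angstrom (default 0.15).
#' @param between Center-to-base RMSD, Angstrom (default 1.2); `0` collapses
#'   all centers onto the base geometry (one true cluster).
#' @param energy_spread Energy gap between successive clusters, kcal/mol.
#' @param seed Integer seed.
#' @return List with `set` (a [conformer_set()] in generation order) and
#'   `truth` (integer vector of planted cluster memberships).
#' @export
generate_conformers <- function(n_clusters = 3L, members = 4L, n_atoms = 8L,
                                within = 0.15, between = 1.2,
                                energy_spread = 1.0, seed = 1L) {
  if (n_atoms < 3L) stop("n_atoms must be at least 3")
  if (n_clusters < 1L || members < 1L) stop("counts must be at least 1")
  if (within < 0 || between < 0) stop("spreads must be non-negative")
  with_local_seed(seed, {
    base <- matrix(stats::runif(3L * n_atoms, -3, 3), ncol = 3L)
    centers <- vector("list", n_clusters)
    centers[[1L]] <- base
    k <- 2L
    while (k <= n_clusters) {
      cand <- scale_to_rmsd(base, matrix(stats::rnorm(3L * n_atoms), ncol = 3L),
                            between)
      sep <- vapply(centers[seq_len(k - 1L)],
                    function(m) kabsch_rmsd(m, cand), numeric(1L))
      if (between == 0 || all(sep >= 0.8 * between)) {
        centers[[k]] <- cand
        k <- k + 1L
      }
    }
    coords <- list(); energy <- numeric(); truth <- integer()
    for (cl in seq_len(n_clusters)) {
      for (m in seq_len(members)) {
        if (m == 1L) {
          geom <- centers[[cl]]
        } else {
          r <- within * stats::runif(1L, 0.3, 1)
          geom <- scale_to_rmsd(centers[[cl]],
                                matrix(stats::rnorm(3L * n_atoms), ncol = 3L), r)
        }
        coords[[length(coords) + 1L]] <- geom
        energy <- c(energy, (cl - 1L) * energy_spread +
                      (m - 1L) * 0.1 * energy_spread)
        truth <- c(truth, cl)
      }
    }
    atoms <- rep("C", n_atoms)
    list(set = conformer_set(coords, energy, atoms), truth = truth)
  })
}
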