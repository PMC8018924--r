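#' Corrected excess chemical potential
#'
#' Applies the linear, solvent-specific correction
#' `mu_corr = c_mu * mu_ex + c_V * V_m + c_q * q + d` to each state of a
#' state table. The correction maps the raw integral-equation excess chemical
#' potential onto experimental solvation free energy scales using the partial
#' molar volume and (for ionic species in water) the net charge.
#'
#' @param states A `state_table` or `species_ensemble` whose rows all belong
#'   to `params$phase`.
#' @param params A [correction_params()] object.
#' @return Numeric vector of corrected excess chemical potentials, kcal/mol,
#'   one per row of `states`.
#' @export
corrected_mu_ex <- function(states, params) {
  stopifnot(inherits(states, "state_table"), inherits(params, "correction_params"))
  if (any(states$phase != params$phase)) {
    stop("phase mismatch: states in {",
         paste(unique(states$phase), collapse = ", "),
         "} but parameters are for \"", params$phase, "\"")
  }
  params$c_mu * states$mu_ex + params$c_V * states$V_m +
    params$c_q * states$q + params$d
}

#' Per-state free energy in solution
#'
#' The per-state quantity entering the Boltzmann sum of [ensemble_gibbs()]:
#' solution-phase electronic energy plus the corrected excess chemical
#' potential.
#'
#' @inheritParams corrected_mu_ex
#' @return Numeric vector, kcal/mol.
#' @export
state_free_energy <- function(states, params) {
  states$E_sol + corrected_mu_ex(states, params)
}

#' Shift-stable Boltzmann free energy of a set of state energies
#'
#' Computes `G = -RT * log(sum(exp(-g/RT)))` by max-subtraction so that the
#' result is exact under adding any constant to all `g` (naive exponentiation
#' would overflow once |g| exceeds a few hundred times RT).
#'
#' @param g Numeric vector of per-state free energies, kcal/mol.
#' @param const A [thermo_constants()] object.
#' @return An object of class `gibbs_result`: list with `G` (kcal/mol),
#'   `n_states`, and `weights` (Boltzmann populations summing to 1).
#' @examples
#' boltzmann_gibbs(c(0, 0), thermo_constants())$G  # -RT*log(2)
#' @export
boltzmann_gibbs <- function(g, const = thermo_constants()) {
  stopifnot(inherits(const, "thermo_constants"))
  if (length(g) == 0L) stop("empty ensemble: no states")
  if (any(!is.finite(g))) stop("non-finite state free energy")
  x <- -g / const$RT
  xmax <- max(x)
  w <- exp(x - xmax)
  Z <- sum(w)
  structure(
    list(G = -const$RT * (xmax + log(Z)), n_states = length(g), weights = w / Z),
    class = "gibbs_result"
  )
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat(sprintf("gibbs_result: G = %.6f kcal/mol over %d state(s)\n",
              x$G, x$n_states))
  invisible(x)
}

#' Partition-function Gibbs energy of a species ensemble
#'
#' Boltzmann-weighted free energy over all tautomer/conformer states of a
#' species in one solvent:
#' `G = -RT * log( sum_tc exp(-(E_sol_tc + mu_corr_tc)/RT) )`.
#' For the reserved `"gas"` phase the per-state energy is the uncorrected
#' gas-phase electronic energy `E_gas` (no excess chemical potential exists
#' in vacuum), and `params` may be `NULL`.
#'
#' @param ensemble A `species_ensemble` (or any `state_table` whose rows form
#'   the desired ensemble in a single phase).
#' @param params A [correction_params()] for the ensemble's phase; ignored
#'   (may be `NULL`) for gas-phase ensembles.
#' @param const A [thermo_constants()] object.
#' @return A `gibbs_result` (see [boltzmann_gibbs()]).
#' @export
ensemble_gibbs <- function(ensemble, params = NULL, const = thermo_constants()) {
  stopifnot(inherits(ensemble, "state_table"))
  if (nrow(ensemble) == 0L) stop("empty ensemble: no states")
  phase <- unique(ensemble$phase)
  if (length(phase) != 1L) {
    stop("ensemble spans multiple phases: ", paste(phase, collapse = ", "))
  }
  if (identical(phase, "gas")) {
    if (anyNA(ensemble$E_gas)) {
      bad <- ensemble[is.na(ensemble$E_gas), STATE_KEY_COLS][1L, ]
      stop("missing E_gas on gas-phase state (",
           paste(unlist(bad), collapse = ", "), ")")
    }
    g <- ensemble$E_gas
  } else {
    if (is.null(params)) stop("correction parameters required for phase \"", phase, "\"")
    g <- state_free_energy(ensemble, params)
  }
  boltzmann_gibbs(g, const)
}

#' Solvation free energy of a species
#'
#' Difference between the solution-phase ensemble Gibbs energy (corrected
#' excess chemical potentials included) and the gas-phase ensemble Gibbs
#' energy computed from uncorrected gas-phase electronic energies, ignoring
#' thermal corrections. Both ensembles are partition-function averages over
#' their own states.
#'
#' @param ensemble_sol Solution-phase `species_ensemble`.
#' @param ensemble_gas Gas-phase `species_ensemble` (phase `"gas"`); every
#'   state must carry `E_gas`.
#' @param params A [correction_params()] matching the solution phase.
#' @param const A [thermo_constants()] object.
#' @return Solvation free energy, kcal/mol.
#' @export
solvation_free_energy <- function(ensemble_sol, ensemble_gas, params,
                                  const = thermo_constants()) {
  if (!all(ensemble_gas$phase == "gas")) {
    stop("`ensemble_gas` must contain gas-phase states")
  }
  G_sol <- ensemble_gibbs(ensemble_sol, params, const)$G
  G_gas <- ensemble_gibbs(ensemble_gas, NULL, const)$G
  G_sol - G_gas
}
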