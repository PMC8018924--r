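#' Partition coefficient from two ensemble Gibbs energies
#'
#' `log P = (G_water - G_organic) / (RT * ln 10)` for the neutral species,
#' with both Gibbs energies taken over all tautomers and conformers in the
#' respective phase. A compound more stable in water (`G_water` well below
#' `G_organic`) gets a negative log P; swapping the phases negates the value.
#'
#' @param G_water Ensemble Gibbs energy in water, kcal/mol.
#' @param G_organic Ensemble Gibbs energy in the organic phase, kcal/mol.
#' @param const A [thermo_constants()] object.
#' @return log P (decadic), vectorized over its inputs.
#' @export
log_p <- function(G_water, G_organic, const = thermo_constants()) {
  stopifnot(is.numeric(G_water), is.numeric(G_organic))
  if (any(!is.finite(G_water)) || any(!is.finite(G_organic))) {
    stop("Gibbs energies must be finite")
  }
  (G_water - G_organic) / const$RTln10
}

#' Distribution coefficient at a given pH
#'
#' Reduces a partition coefficient by the ionized fraction in water:
#' `log D = log P - log10(1 + 10^(pKa - pH))` for bases and
#' `log D = log P - log10(1 + 10^(pH - pKa))` for acids; compounds without an
#' ionizable site keep `log D = log P`. The ionized species is assumed unable
#' to enter the organic phase, so log D never exceeds log P.
#'
#' @param logP Partition coefficient(s).
#' @param ion An [ionization_info()] object, or a character vector of site
#'   types (`"acid"`, `"base"`, `"none"`) parallel to `logP`.
#' @param pKa Acidity constants parallel to `logP`; ignored when `ion` is an
#'   `ionization_info` (which carries its own), required where
#'   `ion != "none"` otherwise.
#' @param pH The pH of the aqueous phase (default 7.4).
#' @return log D at the given pH, vectorized.
#' @examples
#' log_d(2.0, "acid", pKa = 6.4)  # 2 - log10(1 + 10) = 0.9586
#' @export
log_d <- function(logP, ion = "none", pKa = NULL, pH = 7.4) {
  if (inherits(ion, "ionization_info")) {
    pKa <- ion$pKa
    ion <- ion$site_type
  }
  ion <- as.character(ion)
  if (!all(ion %in% c("acid", "base", "none"))) {
    stop("site types must be \"acid\", \"base\" or \"none\"")
  }
  n <- max(length(logP), length(ion))
  logP <- rep_len(as.numeric(logP), n)
  ion <- rep_len(ion, n)
  if (is.null(pKa)) pKa <- rep(NA_real_, n) else pKa <- rep_len(as.numeric(pKa), n)
  need <- ion != "none"
  if (any(need & !is.finite(pKa))) {
    stop("missing pKa for ionizable compound(s) at position(s) ",
         paste(which(need & !is.finite(pKa)), collapse = ", "))
  }
  shift <- numeric(n)
  # log1p-based form keeps the shift accurate when the exponent is large
  shift[ion == "base"] <- log1p(10^(pKa[ion == "base"] - pH)) / log(10)
  shift[ion == "acid"] <- log1p(10^(pH - pKa[ion == "acid"])) / log(10)
  logP - shift
}

#' Two-parameter linear pKa model
#'
#' Parameters of the affine map from a deprotonation Gibbs energy difference
#' in water to a pKa: one slope scaling the free energy difference between
#' protonated and deprotonated forms, one intercept representing the free
#' proton contribution.
#'
#' @param a Slope, pK units per kcal/mol; warns (physically disoriented
#'   model) when not positive.
#' @param b Intercept, pK units.
#' @return An object of class `pka_params`.
#' @export
pka_params <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop("pKa model parameters must be finite")
  if (a <= 0) warning("slope a <= 0: pKa model is not physically oriented")
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "pka_params")
}

#' @export
print.pka_params <- function(x, ...) {
  cat(sprintf("pka_params: pKa = %g * dG_deprot + %g\n", x$a, x$b))
  invisible(x)
}

#' Predict a pKa from protonated/deprotonated Gibbs energies
#'
#' `pKa = a * (G_deprotonated - G_protonated) + b`, with both Gibbs energies
#' taken in water over the tautomers/conformers of the respective protonation
#' state (see [ensemble_gibbs()]).
#'
#' @param G_protonated,G_deprotonated Gibbs energies in water, kcal/mol.
#' @param params A [pka_params()] object.
#' @return Predicted pKa(s), vectorized.
#' @export
pka_from_gibbs <- function(G_protonated, G_deprotonated, params) {
  stopifnot(inherits(params, "pka_params"))
  dG <- as.numeric(G_deprotonated) - as.numeric(G_protonated)
  if (any(!is.finite(dG))) stop("Gibbs energies must be finite")
  params$a * dG + params$b
}

new_tautomer_reaction <- function(reaction_id, species_a, species_b, dG) {
  if (identical(species_a, species_b)) stop("species_a and species_b must differ")
  structure(list(reaction_id = reaction_id, species_a = species_a,
                 species_b = species_b, dG = dG),
            class = "tautomer_reaction")
}

#' @export
print.tautomer_reaction <- function(x, ...) {
  cat(sprintf("tautomer_reaction %s: %s -> %s, dG = %.4f kcal/mol\n",
              x$reaction_id, x$species_a, x$species_b, x$dG))
  invisible(x)
}

#' Tautomerization free energy, direct route
#'
#' Standard reaction Gibbs energy in water for the state change a -> b,
#' `dG0 = G_b(W) - G_a(W)`, with each species' Gibbs energy taken as the
#' partition-function average over its own conformers/rotamers in solution.
#' Antisymmetric under swapping the species.
#'
#' @param ens_a,ens_b Single-tautomer `species_ensemble`s in the same
#'   solvent phase.
#' @param params A [correction_params()] for that phase.
#' @param const A [thermo_constants()] object.
#' @param reaction_id Optional reaction label; defaults to "a -> b" built
#'   from the ensemble tautomer labels.
#' @return A `tautomer_reaction` with fields `reaction_id`, `species_a`,
#'   `species_b`, `dG` (kcal/mol).
#' @export
tautomer_dg_direct <- function(ens_a, ens_b, params, const = thermo_constants(),
                               reaction_id = NULL) {
  pa <- attr(ens_a, "phase"); pb <- attr(ens_b, "phase")
  if (!identical(pa, pb)) {
    stop("phase mismatch between species: \"", pa, "\" vs \"", pb, "\"")
  }
  la <- species_label(ens_a); lb <- species_label(ens_b)
  if (is.null(reaction_id)) reaction_id <- paste(la, "->", lb)
  dG <- ensemble_gibbs(ens_b, params, const)$G -
    ensemble_gibbs(ens_a, params, const)$G
  new_tautomer_reaction(reaction_id, la, lb, dG)
}

species_label <- function(ens) {
  t <- attr(ens, "tautomer_id")
  if (is.null(t)) t <- paste(unique(ens$tautomer_id), collapse = "+")
  paste0(attr(ens, "compound_id"), "/", t)
}

#' Tautomerization free energy, thermodynamic-cycle route
#'
#' Combines a high-level gas-phase reaction free energy with the difference
#' of explicit solvation free energies:
#' `dG0 = [G_gas(b) - G_gas(a)] + [dG_solv(b) - dG_solv(a)]`.
#' The gas-phase leg is a partition-function average over each species'
#' rotamers using the high-level gas electronic energy plus the thermal
#' correction; the solvation legs use [solvation_free_energy()] (standard
#' gas energies, corrected solution free energies). When the high-level gas
#' energies coincide with the standard ones and the thermal terms vanish,
#' the cycle closes onto [tautomer_dg_direct()].
#'
#' @param ens_a_gas,ens_b_gas Gas-phase `species_ensemble`s carrying
#'   `E_gas_highlevel` and `G_thermal_gas` on every state.
#' @param ens_a_sol,ens_b_sol Solution-phase `species_ensemble`s.
#' @param params A [correction_params()] for the solution phase.
#' @param const A [thermo_constants()] object.
#' @param reaction_id Optional reaction label.
#' @return A `tautomer_reaction` (kcal/mol).
#' @export
tautomer_dg_cycle <- function(ens_a_gas, ens_a_sol, ens_b_gas, ens_b_sol,
                              params, const = thermo_constants(),
                              reaction_id = NULL) {
  gas_high_g <- function(ens) {
    need <- c("E_gas_highlevel", "G_thermal_gas")
    for (col in need) {
      bad <- is.na(ens[[col]])
      if (any(bad)) {
        k <- ens[which(bad)[1L], STATE_KEY_COLS]
        stop("missing ", col, " on state (", paste(unlist(k), collapse = ", "), ")")
      }
    }
    boltzmann_gibbs(ens$E_gas_highlevel + ens$G_thermal_gas, const)$G
  }
  la <- species_label(ens_a_sol); lb <- species_label(ens_b_sol)
  if (is.null(reaction_id)) reaction_id <- paste(la, "->", lb)
  d_gas <- gas_high_g(ens_b_gas) - gas_high_g(ens_a_gas)
  d_hyd <- solvation_free_energy(ens_b_sol, ens_b_gas, params, const) -
    solvation_free_energy(ens_a_sol, ens_a_gas, params, const)
  new_tautomer_reaction(reaction_id, la, lb, d_gas + d_hyd)
}
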