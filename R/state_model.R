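#' Physical constants for ensemble thermodynamics
#'
#' Bundles the molar gas constant and absolute temperature used by all
#' partition-function operations. Defaults correspond to 25 degrees C and the
#' gas constant in kcal/(mol K), so that `RT*ln(10)` is about 1.3643 kcal/mol.
#'
#' @param R Molar gas constant in kcal/(mol K).
#' @param T Absolute temperature in K.
#' @return An object of class `thermo_constants` with elements `R`, `T`,
#'   `RT` and `RTln10`.
#' @examples
#' const <- thermo_constants()
#' const$RTln10
#' @export
thermo_constants <- function(R = 1.987204e-3, T = 298.15) {
  stopifnot(is.numeric(R), is.numeric(T), R > 0, T > 0)
  structure(
    list(R = R, T = T, RT = R * T, RTln10 = R * T * log(10)),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat(sprintf("thermo_constants: R = %g kcal/(mol K), T = %g K, RT = %.6f kcal/mol\n",
              x$R, x$T, x$RT))
  invisible(x)
}

# conversion used when state tables are declared in hartree
HARTREE_TO_KCALMOL <- 627.5095

# column contract of the per-state thermodynamic table
STATE_KEY_COLS <- c("compound_id", "tautomer_id", "conformer_id", "phase")
STATE_REQUIRED_NUM <- c("E_sol", "mu_ex", "V_m", "q")
STATE_OPTIONAL_NUM <- c("E_gas", "G_thermal_gas", "E_gas_highlevel")
STATE_ENERGY_COLS <- c("E_sol", "E_gas", "mu_ex", "G_thermal_gas", "E_gas_highlevel")

#' Validate a per-state thermodynamic table
#'
#' Checks a data frame of per-state records (one row per compound, tautomer,
#' conformer and solvent phase) against the dataset contract: all required
#' columns present, energies and partial molar volumes finite, net charges
#' integer-valued within 1e-6, and the (compound, tautomer, conformer, phase)
#' key unique. Optional columns (`E_gas`, `G_thermal_gas`, `E_gas_highlevel`)
#' may contain `NA` for absent values but must be finite where present.
#'
#' @param records A data frame with columns `compound_id`, `tautomer_id`,
#'   `conformer_id`, `phase`, `E_sol`, `mu_ex`, `V_m`, `q` and optionally
#'   `E_gas`, `G_thermal_gas`, `E_gas_highlevel`. Energies in kcal/mol,
#'   volumes in cubic Angstrom, charges in elementary units.
#' @return The validated table with class `state_table`.
#' @export
validate_states <- function(records) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  missing_cols <- setdiff(c(STATE_KEY_COLS, STATE_REQUIRED_NUM), names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in STATE_OPTIONAL_NUM) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }

  for (col in STATE_KEY_COLS) {
    records[[col]] <- as.character(records[[col]])
    if (anyNA(records[[col]]) || any(!nzchar(records[[col]]))) {
      stop("empty or missing values in key column `", col, "`")
    }
  }
  for (col in c(STATE_REQUIRED_NUM, STATE_OPTIONAL_NUM)) {
    records[[col]] <- as.numeric(records[[col]])
  }
  for (col in STATE_REQUIRED_NUM) {
    bad <- !is.finite(records[[col]])
    if (any(bad)) {
      stop("non-finite values in required column `", col, "` (row ",
           paste(which(bad), collapse = ", "), ")")
    }
  }
  for (col in STATE_OPTIONAL_NUM) {
    bad <- !is.na(records[[col]]) & !is.finite(records[[col]])
    if (any(bad)) {
      stop("non-finite values in optional column `", col, "`")
    }
  }

  off <- abs(records$q - round(records$q))
  if (any(off > 1e-6)) {
    stop("net charge `q` not integer-valued within 1e-6 (row ",
         which.max(off), ")")
  }

  key <- do.call(paste, c(records[STATE_KEY_COLS], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    k <- records[which(dup)[1L], STATE_KEY_COLS]
    stop("duplicate state key: (", paste(unlist(k), collapse = ", "), ")")
  }

  class(records) <- c("state_table", "data.frame")
  records
}

#' Read a per-state thermodynamic table from delimited text
#'
#' Reads a comma- or tab-delimited table (delimiter auto-detected from the
#' header line), normalizes typographic minus signs (U+2212) to ASCII hyphens,
#' optionally converts energy columns from hartree to kcal/mol, and validates
#' the result with [validate_states()]. Empty cells in optional columns denote
#' absent fields.
#'
#' @param path Path to the delimited text file.
#' @param energy_unit Unit of the energy columns in the file; `"kcal/mol"`
#'   (default) or `"hartree"` (converted with 1 hartree = 627.5095 kcal/mol).
#' @return A validated `state_table`.
#' @export
read_state_table <- function(path, energy_unit = c("kcal/mol", "hartree")) {
  energy_unit <- match.arg(energy_unit)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), strip.white = TRUE)
  num_cols <- intersect(c(STATE_REQUIRED_NUM, STATE_OPTIONAL_NUM), names(raw))
  for (col in num_cols) {
    raw[[col]] <- as.numeric(gsub("−", "-", raw[[col]]))
  }
  if (energy_unit == "hartree") {
    for (col in intersect(STATE_ENERGY_COLS, names(raw))) {
      raw[[col]] <- raw[[col]] * HARTREE_TO_KCALMOL
    }
  }
  validate_states(raw)
}

#' Write a per-state thermodynamic table to delimited text
#'
#' Writes a validated state table so that a subsequent [read_state_table()]
#' round-trips every numeric field to at least 12 significant digits. Absent
#' optional fields are written as empty cells.
#'
#' @param x A `state_table` (see [validate_states()]).
#' @param path Output path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "state_table"))
  out <- as.data.frame(x)
  for (col in c(STATE_REQUIRED_NUM, STATE_OPTIONAL_NUM)) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 15, format = "g"))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Correction-model parameter sets
#'
#' Constructs the parameter vector of the linear excess chemical potential
#' correction `mu_corr = c_mu * mu_ex + c_V * V_m + c_q * q + d` for one
#' solvent. The `variant` tag fixes which entries are adjustable:
#' \describe{
#'   \item{`"1-par"`}{`c_mu = 1`, `c_q = 0`, `d = 0`; only `c_V` free.}
#'   \item{`"2-par"`}{`c_q = 0`, `d = 0`; `c_mu` and `c_V` free.}
#'   \item{`"2-par-I"`}{`c_mu = 1`, `c_q = 0`; `c_V` and `d` free.}
#'   \item{`"3-par"`}{`c_q = 0`; `c_mu`, `c_V` and `d` free.}
#'   \item{`"water-3-par-q"`}{`d = 0`; `c_mu`, `c_V` and `c_q` free (net
#'     charge term used for ionic species in water).}
#' }
#'
#' @param variant One of `"1-par"`, `"2-par"`, `"2-par-I"`, `"3-par"`,
#'   `"water-3-par-q"`.
#' @param c_mu Dimensionless scale on the excess chemical potential.
#' @param c_V Coefficient on the partial molar volume, kcal/(mol A^3).
#' @param c_q Coefficient on the net charge, kcal/(mol e).
#' @param d Intercept, kcal/mol.
#' @param phase Solvent phase label (e.g. `"water"`, `"cyclohexane"`); the
#'   reserved phase `"gas"` carries no correction parameters.
#' @param label Optional display label (e.g. a model code such as
#'   `"2-par-I(5)"`); defaults to `variant`.
#' @return An object of class `correction_params`.
#' @examples
#' correction_params("3-par", c_mu = 1.8516, c_V = -0.14692, d = -1.0842,
#'                   phase = "cyclohexane")
#' @export
correction_params <- function(variant, c_mu = 1, c_V = 0, c_q = 0, d = 0,
                              phase = "water", label = variant) {
  variants <- c("1-par", "2-par", "2-par-I", "3-par", "water-3-par-q")
  if (!is.character(variant) || length(variant) != 1L || !variant %in% variants) {
    stop("unknown variant; must be one of: ", paste(variants, collapse = ", "))
  }
  phase <- check_phase(phase)
  if (identical(phase, "gas")) {
    stop("the reserved phase \"gas\" has no correction parameters")
  }
  p <- c(c_mu = as.numeric(c_mu), c_V = as.numeric(c_V),
         c_q = as.numeric(c_q), d = as.numeric(d))
  if (any(!is.finite(p))) stop("correction parameters must be finite")

  fixed <- switch(variant,
    "1-par"         = c(c_mu = 1, c_q = 0, d = 0),
    "2-par"         = c(c_q = 0, d = 0),
    "2-par-I"       = c(c_mu = 1, c_q = 0),
    "3-par"         = c(c_q = 0),
    "water-3-par-q" = c(d = 0)
  )
  for (nm in names(fixed)) {
    if (abs(p[[nm]] - fixed[[nm]]) > 1e-12) {
      stop("variant \"", variant, "\" fixes ", nm, " = ", fixed[[nm]],
           " but ", nm, " = ", p[[nm]], " was supplied")
    }
    p[[nm]] <- fixed[[nm]]
  }
  structure(
    list(variant = variant, c_mu = p[["c_mu"]], c_V = p[["c_V"]],
         c_q = p[["c_q"]], d = p[["d"]], phase = phase, label = label),
    class = "correction_params"
  )
}

#' @export
print.correction_params <- function(x, ...) {
  cat(sprintf("correction_params [%s, %s]: c_mu = %g, c_V = %g, c_q = %g, d = %g\n",
              x$label, x$phase, x$c_mu, x$c_V, x$c_q, x$d))
  invisible(x)
}

# names of the adjustable parameters of a variant
free_params <- function(variant) {
  switch(variant,
    "1-par"         = "c_V",
    "2-par"         = c("c_mu", "c_V"),
    "2-par-I"       = c("c_V", "d"),
    "3-par"         = c("c_mu", "c_V", "d"),
    "water-3-par-q" = c("c_mu", "c_V", "c_q"),
    stop("unknown variant: ", variant)
  )
}

check_phase <- function(phase) {
  if (!is.character(phase) || length(phase) != 1L || !nzchar(phase)) {
    stop("phase must be a non-empty character scalar")
  }
  phase
}

#' Ionization annotation for a compound
#'
#' Records whether a compound is treated as an acid or a base when converting
#' a partition coefficient into a distribution coefficient, together with its
#' (macroscopic) pKa. Site typing is an input annotation, not computed.
#'
#' @param compound_id Compound label.
#' @param site_type `"acid"`, `"base"`, or `"none"`.
#' @param pKa Acidity constant; required unless `site_type = "none"`.
#' @return An object of class `ionization_info`.
#' @export
ionization_info <- function(compound_id, site_type = c("none", "acid", "base"),
                            pKa = NULL) {
  site_type <- match.arg(site_type)
  if (site_type == "none") {
    if (!is.null(pKa)) stop("pKa must be absent when site_type = \"none\"")
  } else {
    if (is.null(pKa) || !is.finite(pKa)) {
      stop("finite pKa required for site_type = \"", site_type, "\"")
    }
  }
  structure(list(compound_id = as.character(compound_id),
                 site_type = site_type,
                 pKa = if (is.null(pKa)) NA_real_ else as.numeric(pKa)),
            class = "ionization_info")
}

#' Extract a species ensemble from a state table
#'
#' Collects the per-state records of one chemical species in one solvent
#' phase: either a single tautomer (`scope = "single-tautomer"`, the species
#' entering pKa and tautomerization free energies) or all tautomers of a
#' compound (`scope = "all-tautomers"`, the species entering log P and log D).
#'
#' @param states A `state_table`.
#' @param compound_id Compound label to select.
#' @param phase Solvent phase label to select (`"gas"` for gas-phase states).
#' @param scope `"all-tautomers"` (default) or `"single-tautomer"`.
#' @param tautomer_id Tautomer label; required when
#'   `scope = "single-tautomer"`.
#' @return An object of class `species_ensemble`: the selected rows with
#'   attributes `compound_id`, `phase` and `scope`.
#' @export
species_ensemble <- function(states, compound_id, phase,
                             scope = c("all-tautomers", "single-tautomer"),
                             tautomer_id = NULL) {
  stopifnot(inherits(states, "state_table"))
  scope <- match.arg(scope)
  phase <- check_phase(phase)
  keep <- states$compound_id == compound_id & states$phase == phase
  if (scope == "single-tautomer") {
    if (is.null(tautomer_id)) {
      stop("tautomer_id required for scope = \"single-tautomer\"")
    }
    keep <- keep & states$tautomer_id == tautomer_id
  }
  sel <- states[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no states for compound \"", compound_id, "\" in phase \"", phase,
         "\"", if (!is.null(tautomer_id)) paste0(", tautomer \"", tautomer_id, "\""))
  }
  structure(sel,
            compound_id = compound_id, phase = phase, scope = scope,
            tautomer_id = tautomer_id,
            class = c("species_ensemble", "state_table", "data.frame"))
}

#' @export
print.species_ensemble <- function(x, ...) {
  cat(sprintf("species_ensemble: %s in %s (%s), %d state(s)\n",
              attr(x, "compound_id"), attr(x, "phase"), attr(x, "scope"),
              nrow(x)))
  invisible(x)
}
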