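#' Fit report accessors
#'
#' Calibration functions return a `fit_report`: the fitted parameter object
#' plus training metrics (RMSE, MAE, mean signed error, descriptive
#' regression slope/intercept/R^2, all in the model's units, population
#' convention).
#'
#' @name fit_report
NULL

new_fit_report <- function(params, observed, predicted, residual_cols = NULL) {
  tab <- prediction_table(seq_along(observed), observed, predicted)
  ms <- prediction_metrics(tab)
  structure(
    list(params = params, rmse = ms$rmse, mae = ms$mae, mse = ms$mse,
         m_prime = ms$m_prime, b_prime = ms$b_prime, r2 = ms$r2, n = ms$n,
         residuals = predicted - observed, residual_cols = residual_cols),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report (n = %d): RMSE %.4f, MAE %.4f, MSE %+.4f\n",
              x$n, x$rmse, x$mae, x$mse))
  print(x$params)
  invisible(x)
}

# design matrix of the free parameters of a correction variant
correction_design <- function(data, variant) {
  free <- free_params(variant)
  cols <- list(c_mu = data$mu_ex, c_V = data$V_m, c_q = data$q,
               d = rep(1, nrow(data)))
  X <- do.call(cbind, cols[free])
  colnames(X) <- free
  X
}

# response after removing the uncorrectable part and the fixed terms
correction_offset <- function(data, variant) {
  base <- data$E_sol - data$E_gas
  if (!"c_mu" %in% free_params(variant)) base <- base + data$mu_ex  # c_mu fixed at 1
  base
}

check_rank <- function(X, n) {
  if (n < ncol(X)) {
    stop("fewer records (", n, ") than free parameters (", ncol(X), ")")
  }
  if (qr(X)$rank < ncol(X)) {
    sds <- apply(X, 2L, stats::sd)
    flat <- colnames(X)[sds == 0 & colnames(X) != "d"]
    if (length(flat) > 0L) {
      stop("rank-deficient design: column `",
           switch(flat[1L], c_mu = "mu_ex", c_V = "V_m", c_q = "q", flat[1L]),
           "` has no spread")
    }
    stop("rank-deficient design: free-parameter columns are collinear")
  }
  invisible(TRUE)
}

#' Calibrate a correction-model variant against reference solvation data
#'
#' Ordinary least squares for the free parameters of a correction variant,
#' minimizing the squared residuals of the predicted single-state solvation
#' free energy `E_sol - E_gas + c_mu*mu_ex + c_V*V_m + c_q*q + d` against a
#' reference value per training compound. Parameters fixed by the variant
#' (see [correction_params()]) are honored exactly.
#'
#' @param data Data frame with one representative state per training
#'   compound: numeric columns `E_sol`, `E_gas`, `mu_ex`, `V_m`, `q`, and the
#'   reference `dG_ref` (kcal/mol).
#' @param variant Correction variant tag (see [correction_params()]).
#' @param phase Solvent phase the model is trained for.
#' @return A `fit_report` whose `params` element is the fitted
#'   [correction_params()].
#' @export
fit_correction <- function(data, variant, phase = "cyclohexane") {
  need <- c("E_sol", "E_gas", "mu_ex", "V_m", "q", "dG_ref")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(data[need])))) stop("non-finite training data")
  X <- correction_design(data, variant)
  y <- data$dG_ref - correction_offset(data, variant)
  check_rank(X, nrow(data))
  beta <- qr.coef(qr(X), y)
  full <- c(c_mu = 1, c_V = 0, c_q = 0, d = 0)
  full[names(beta)] <- beta
  params <- correction_params(variant, c_mu = full[["c_mu"]],
                              c_V = full[["c_V"]], c_q = full[["c_q"]],
                              d = full[["d"]], phase = phase)
  predicted <- correction_offset(data, variant) + drop(X %*% beta)
  new_fit_report(params, data$dG_ref, predicted, residual_cols = X)
}

#' Calibrate the two-parameter pKa model
#'
#' Ordinary least squares for slope and intercept of
#' `pKa = a * dG_deprot + b` over reference (Gibbs energy difference, pKa)
#' pairs.
#'
#' @param dG_deprot Deprotonation Gibbs energy differences in water,
#'   kcal/mol.
#' @param pKa_ref Reference pKa values.
#' @return A `fit_report` whose `params` element is the fitted
#'   [pka_params()].
#' @export
fit_pka <- function(dG_deprot, pKa_ref) {
  dG_deprot <- as.numeric(dG_deprot); pKa_ref <- as.numeric(pKa_ref)
  if (length(dG_deprot) != length(pKa_ref)) stop("input lengths differ")
  if (length(dG_deprot) < 2L) stop("at least 2 reference pairs required")
  if (any(!is.finite(dG_deprot)) || any(!is.finite(pKa_ref))) {
    stop("non-finite training data")
  }
  if (stats::sd(dG_deprot) == 0) {
    stop("degenerate training set: all dG_deprot values equal")
  }
  X <- cbind(d = 1, a = dG_deprot)
  beta <- qr.coef(qr(X), pKa_ref)
  params <- suppressWarnings(pka_params(a = beta[["a"]], b = beta[["d"]]))
  new_fit_report(params, pKa_ref, drop(X %*% beta), residual_cols = X)
}

# split a state table into per-compound solution/gas ensembles for `phase`
split_compound_ensembles <- function(states, phase) {
  comps <- unique(states$compound_id)
  lapply(stats::setNames(comps, comps), function(id) {
    list(sol = states[states$compound_id == id & states$phase == phase, , drop = FALSE],
         gas = states[states$compound_id == id & states$phase == "gas", , drop = FALSE])
  })
}

#' Predict ensemble solvation free energies for a parameter set
#'
#' Boltzmann-averaged solvation free energy per compound: the
#' partition-function Gibbs energy over the compound's solution states
#' (with corrected excess chemical potentials) minus the gas-phase
#' partition-function Gibbs energy over `E_gas`.
#'
#' @param states A `state_table` containing, for each compound, its states
#'   in `params$phase` and in the reserved `"gas"` phase.
#' @param params A [correction_params()] object.
#' @param const A [thermo_constants()] object.
#' @return Named numeric vector of solvation free energies, kcal/mol.
#' @export
predict_dg_solv <- function(states, params, const = thermo_constants()) {
  stopifnot(inherits(states, "state_table"))
  ens <- split_compound_ensembles(states, params$phase)
  vapply(ens, function(e) {
    if (nrow(e$sol) == 0L || nrow(e$gas) == 0L) {
      stop("compound without both solution and gas states")
    }
    class(e$sol) <- class(e$gas) <- c("state_table", "data.frame")
    solvation_free_energy(e$sol, e$gas, params, const)
  }, numeric(1L))
}

# lowest-free-energy representative row per compound (identity correction)
representative_rows <- function(states, phase) {
  ens <- split_compound_ensembles(states, phase)
  rows <- lapply(ens, function(e) {
    sol <- e$sol[which.min(e$sol$E_sol + e$sol$mu_ex), , drop = FALSE]
    sol$E_gas <- min(e$gas$E_gas)
    sol
  })
  do.call(rbind, rows)
}

#' Ensemble-aware calibration of a correction variant
#'
#' Nonlinear least squares for the free parameters of a correction variant
#' where the predicted solvation free energy is the Boltzmann-weighted
#' ensemble value of [predict_dg_solv()] rather than a single-state
#' expression (the correction parameters sit inside the partition function,
#' so the problem is no longer linear). Initialized from the linear
#' single-representative fit; iterations stop when the relative parameter
#' step falls below 1e-8.
#'
#' @param states A `state_table` with solution-phase and gas-phase states
#'   for every training compound.
#' @param reference Data frame with columns `compound_id` and `dG_ref`
#'   (kcal/mol).
#' @param variant Correction variant tag.
#' @param phase Solvent phase being calibrated.
#' @param const A [thermo_constants()] object.
#' @param init Optional named numeric vector of starting values for the free
#'   parameters; defaults to the linear single-representative fit.
#' @param max_iter Maximum number of Levenberg-Marquardt iterations.
#' @return A `fit_report` whose `params` element is the fitted
#'   [correction_params()] and which carries the iteration count in
#'   `$iterations`.
#' @export
fit_correction_ensemble <- function(states, reference, variant,
                                    phase = "cyclohexane",
                                    const = thermo_constants(),
                                    init = NULL, max_iter = 100L) {
  stopifnot(inherits(states, "state_table"), is.data.frame(reference))
  if (!all(c("compound_id", "dG_ref") %in% names(reference))) {
    stop("`reference` needs columns compound_id and dG_ref")
  }
  free <- free_params(variant)
  if (nrow(reference) < length(free)) {
    stop("fewer records (", nrow(reference), ") than free parameters (",
         length(free), ")")
  }
  keep <- states$compound_id %in% reference$compound_id
  states <- states[keep, , drop = FALSE]
  class(states) <- c("state_table", "data.frame")

  if (is.null(init)) {
    rep_data <- representative_rows(states, phase)
    rep_data <- merge(rep_data, reference, by = "compound_id")
    lin <- fit_correction(rep_data, variant, phase)
    init <- unlist(lin$params[free])
  } else {
    if (!all(free %in% names(init))) {
      stop("`init` must name every free parameter: ", paste(free, collapse = ", "))
    }
    init <- init[free]
  }

  as_params <- function(p) {
    full <- c(c_mu = 1, c_V = 0, c_q = 0, d = 0)
    full[free] <- p
    correction_params(variant, c_mu = full[["c_mu"]], c_V = full[["c_V"]],
                      c_q = full[["c_q"]], d = full[["d"]], phase = phase)
  }
  resid_fn <- function(p) {
    pred <- predict_dg_solv(states, as_params(p), const)
    pred[reference$compound_id] - reference$dG_ref
  }
  fit <- minpack.lm::nls.lm(
    par = init, fn = resid_fn,
    control = minpack.lm::nls.lm.control(ptol = 1e-8, ftol = 1e-12,
                                         maxiter = as.integer(max_iter))
  )
  if (!fit$info %in% 1:4) {
    stop("ensemble fit did not converge after ", fit$niter,
         " iterations (last iterate: ",
         paste(sprintf("%s = %.6g", names(fit$par), fit$par), collapse = ", "),
         ")")
  }
  params <- as_params(fit$par)
  pred <- predict_dg_solv(states, params, const)[reference$compound_id]
  report <- new_fit_report(params, reference$dG_ref, pred)
  report$iterations <- fit$niter
  report
}

#' Write fitted correction parameters to a plain-text config
#'
#' One `key = value` line per parameter under a `[phase/variant]` header, the
#' format read back by [read_correction_config()].
#'
#' @param params A [correction_params()] object.
#' @param path Output path; the section is appended if the file exists.
#' @return `path`, invisibly.
#' @export
write_correction_config <- function(params, path) {
  stopifnot(inherits(params, "correction_params"))
  lines <- c(sprintf("[%s/%s]", params$phase, params$variant),
             sprintf("c_mu = %.12g", params$c_mu),
             sprintf("c_V = %.12g", params$c_V),
             sprintf("c_q = %.12g", params$c_q),
             sprintf("d = %.12g", params$d), "")
  cat(paste0(lines, collapse = "\n"),
      file = path, append = file.exists(path))
  invisible(path)
}

#' Read correction parameters from a plain-text config
#'
#' @param path Config file written by [write_correction_config()].
#' @return Named list of [correction_params()], one per `[phase/variant]`
#'   section, named `phase/variant`.
#' @export
read_correction_config <- function(path) {
  lines <- trimws(readLines(path))
  out <- list(); current <- NULL; vals <- list()
  flush <- function(out, current, vals) {
    if (is.null(current)) return(out)
    parts <- strsplit(current, "/", fixed = TRUE)[[1L]]
    out[[current]] <- correction_params(
      parts[2L], c_mu = vals$c_mu, c_V = vals$c_V, c_q = vals$c_q,
      d = vals$d, phase = parts[1L])
    out
  }
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      out <- flush(out, current, vals)
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      vals <- list(c_mu = 1, c_V = 0, c_q = 0, d = 0)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      vals[[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
    }
  }
  flush(out, current, vals)
}
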