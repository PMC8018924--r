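#' Paired experimental/calculated prediction table
#'
#' Container for challenge-style evaluation: compound (or reaction) ids, the
#' experimental observable, the calculated observable, and an optional group
#' label per id (e.g. a dataset batch, or obscure/explanatory). Missing
#' predictions must be flagged explicitly (`flagged = TRUE` with `y_calc`
#' `NA`); they are carried along, reported, and excluded from metrics rather
#' than silently dropped.
#'
#' @param ids Character vector of unique identifiers.
#' @param y_exp Experimental values.
#' @param y_calc Calculated values; `NA` only where `flagged`.
#' @param group Optional group label per id.
#' @param units Observable unit label (metadata only).
#' @param flagged Logical vector marking ids with no prediction.
#' @return A data frame of class `prediction_table` with attribute `units`.
#' @export
prediction_table <- function(ids, y_exp, y_calc, group = NULL, units = "",
                             flagged = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in prediction table")
  if (length(y_exp) != n || length(y_calc) != n) {
    stop("ids, y_exp and y_calc must have equal length")
  }
  if (is.null(flagged)) flagged <- is.na(y_calc)
  flagged <- rep_len(as.logical(flagged), n)
  if (any(is.na(y_calc) & !flagged)) {
    stop("unflagged missing prediction for id(s): ",
         paste(ids[is.na(y_calc) & !flagged], collapse = ", "))
  }
  if (any(!is.finite(y_exp))) stop("y_exp must be finite")
  if (is.null(group)) group <- rep("all", n)
  out <- data.frame(id = ids, y_exp = as.numeric(y_exp),
                    y_calc = as.numeric(y_calc),
                    group = as.character(rep_len(group, n)),
                    flagged = flagged, stringsAsFactors = FALSE)
  structure(out, units = units, class = c("prediction_table", "data.frame"))
}

#' Challenge evaluation metrics
#'
#' Error statistics and descriptive regression for a prediction table, with
#' errors defined as calculated minus experimental: RMSE, MAE, the mean
#' *signed* error MSE (bias, the field's convention), the least-squares line
#' `y_calc = m' * y_exp + b'`, and `R^2` as the squared Pearson correlation.
#' All means use the population (divide-by-n) convention. Flagged-missing
#' rows are excluded first. With zero variance in `y_exp` the regression
#' diagnostics are returned as `NA` and the result carries
#' `regression_undefined = TRUE`.
#'
#' @param table A [prediction_table()].
#' @return An object of class `metric_set`: list with `rmse`, `mae`, `mse`,
#'   `m_prime`, `b_prime`, `r2`, `n`, and `regression_undefined`.
#' @export
prediction_metrics <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  use <- table[!table$flagged, , drop = FALSE]
  if (nrow(use) == 0L) stop("no unflagged predictions to evaluate")
  e <- use$y_calc - use$y_exp
  out <- list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), mse = mean(e),
              m_prime = NA_real_, b_prime = NA_real_, r2 = NA_real_,
              n = nrow(use), regression_undefined = TRUE)
  if (nrow(use) >= 2L && stats::var(use$y_exp) > 0) {
    fit <- stats::lm.fit(cbind(1, use$y_exp), use$y_calc)
    out$b_prime <- unname(fit$coefficients[1L])
    out$m_prime <- unname(fit$coefficients[2L])
    r <- suppressWarnings(stats::cor(use$y_exp, use$y_calc))
    out$r2 <- if (is.na(r)) NA_real_ else r^2
    out$regression_undefined <- is.na(out$r2)
  }
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  cat(sprintf("metric_set (n = %d): RMSE %.*f, MAE %.*f, MSE %+.*f",
              x$n, digits, x$rmse, digits, x$mae, digits, x$mse))
  if (!x$regression_undefined) {
    cat(sprintf(", m' %.*f, b' %+.*f, R2 %.*f",
                digits, x$m_prime, digits, x$b_prime, digits, x$r2))
  }
  cat("\n")
  invisible(x)
}

as_df_metric <- function(ms) {
  data.frame(n = ms$n, rmse = ms$rmse, mae = ms$mae, mse = ms$mse,
             m_prime = ms$m_prime, b_prime = ms$b_prime, r2 = ms$r2)
}

#' Remove listed ids from a prediction table
#'
#' Drops the given ids (e.g. outliers under a stated exclusion rule) and
#' records them in the table's `excluded` attribute for provenance. Unknown
#' ids produce a warning; excluding every row is an error.
#'
#' @param table A [prediction_table()].
#' @param ids Ids to remove.
#' @return The reduced `prediction_table`.
#' @export
exclude_ids <- function(table, ids) {
  stopifnot(inherits(table, "prediction_table"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, table$id)
  if (length(unknown) > 0L) {
    warning("unknown id(s) not in table: ", paste(unknown, collapse = ", "))
  }
  keep <- !(table$id %in% ids)
  if (!any(keep)) stop("exclusion would remove every row")
  out <- table[keep, , drop = FALSE]
  attr(out, "units") <- attr(table, "units")
  attr(out, "excluded") <- c(attr(table, "excluded"), intersect(ids, table$id))
  class(out) <- class(table)
  out
}

#' Consensus of two prediction tables
#'
#' Averages the calculated values of two methods over their common ids
#' (a hypothetical consensus prediction) and quantifies inter-method
#' agreement by evaluating method `a` against method `b` as if `b` were the
#' reference. Flagged rows in either table are dropped from the
#' intersection.
#'
#' @param a,b [prediction_table()]s for the same observable.
#' @return List with `consensus` (a `prediction_table` of the averaged
#'   predictions over the common ids) and `cross` (a `metric_set` of a
#'   versus b; its RMSE/MAE are symmetric in the two methods).
#' @export
consensus_tables <- function(a, b) {
  stopifnot(inherits(a, "prediction_table"), inherits(b, "prediction_table"))
  a <- a[!a$flagged, , drop = FALSE]
  b <- b[!b$flagged, , drop = FALSE]
  common <- intersect(a$id, b$id)
  if (length(common) == 0L) stop("no common ids between the two tables")
  ia <- match(common, a$id); ib <- match(common, b$id)
  if (any(abs(a$y_exp[ia] - b$y_exp[ib]) > 1e-9)) {
    warning("experimental values differ between tables for some common ids")
  }
  consensus <- prediction_table(common, a$y_exp[ia],
                                (a$y_calc[ia] + b$y_calc[ib]) / 2,
                                group = a$group[ia], units = attr(a, "units"))
  cross <- prediction_metrics(
    prediction_table(common, b$y_calc[ib], a$y_calc[ia])
  )
  list(consensus = consensus, cross = cross)
}

#' Per-group and pooled evaluation metrics
#'
#' One [prediction_metrics()] summary per group label plus a pooled summary
#' over the union of all groups. Groups left empty after removing flagged
#' rows are skipped with a warning.
#'
#' @param table A [prediction_table()] with group labels.
#' @param pooled_label Label used for the pooled row (default `"all"`).
#' @return Data frame with one row per group and a final pooled row; columns
#'   `group`, `n`, `rmse`, `mae`, `mse`, `m_prime`, `b_prime`, `r2`.
#' @export
grouped_metrics <- function(table, pooled_label = "all") {
  stopifnot(inherits(table, "prediction_table"))
  groups <- unique(table$group)
  rows <- list()
  for (g in groups) {
    sub <- table[table$group == g, , drop = FALSE]
    class(sub) <- class(table)
    if (all(sub$flagged)) {
      warning("group \"", g, "\" has no unflagged predictions; skipped")
      next
    }
    rows[[g]] <- cbind(group = g, as_df_metric(prediction_metrics(sub)))
  }
  rows[[length(rows) + 1L]] <- cbind(group = pooled_label,
                                     as_df_metric(prediction_metrics(table)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
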