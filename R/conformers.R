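#' Conformer sets
#'
#' A `conformer_set` holds the Cartesian geometries of the conformers of one
#' molecule together with a ranking energy per conformer (force-field or
#' continuum-solvent energy, depending on pipeline stage). All conformers
#' share the same atoms in the same order.
#'
#' @param coords List of N x 3 numeric matrices (Angstrom), one per conformer.
#' @param energy Numeric vector of ranking energies, kcal/mol.
#' @param atoms Character vector of element symbols, length N.
#' @param ids Conformer labels; defaults to `conf_1 ... conf_n`.
#' @return An object of class `conformer_set`.
#' @export
conformer_set <- function(coords, energy, atoms, ids = NULL) {
  if (!is.list(coords) || length(coords) == 0L) {
    stop("`coords` must be a non-empty list of N x 3 matrices")
  }
  n_atoms <- nrow(coords[[1L]])
  if (n_atoms < 1L) stop("conformers need at least one atom")
  ok <- vapply(coords, function(m) {
    is.matrix(m) && is.numeric(m) && ncol(m) == 3L && nrow(m) == n_atoms &&
      all(is.finite(m))
  }, logical(1L))
  if (!all(ok)) stop("all conformers must be finite matrices with ", n_atoms, " x 3 entries")
  if (length(atoms) != n_atoms) stop("`atoms` must have one symbol per atom")
  if (length(energy) != length(coords) || any(!is.finite(energy))) {
    stop("`energy` must be finite, one value per conformer")
  }
  if (is.null(ids)) ids <- paste0("conf_", seq_along(coords))
  if (anyDuplicated(ids)) stop("duplicate conformer ids")
  structure(list(coords = coords, energy = as.numeric(energy),
                 atoms = as.character(atoms), ids = as.character(ids)),
            class = "conformer_set")
}

#' @export
length.conformer_set <- function(x) length(x$coords)

#' @export
`[.conformer_set` <- function(x, i) {
  conformer_set(x$coords[i], x$energy[i], x$atoms, x$ids[i])
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("conformer_set: %d conformer(s), %d atoms, energies [%.3f, %.3f] kcal/mol\n",
              length(x), length(x$atoms), min(x$energy), max(x$energy)))
  invisible(x)
}

#' Read a multi-structure XYZ file
#'
#' Standard XYZ blocks (atom count, comment line, one `element x y z` line per
#' atom). A `energy=<value>` token on the comment line is parsed as the
#' conformer's ranking energy; structures without one get energy 0 with a
#' warning.
#'
#' @param path Path to an XYZ file with one or more structures.
#' @return A [conformer_set()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop("empty XYZ file: ", path)
  coords <- list(); energy <- numeric(); atoms <- NULL; ids <- character()
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("invalid atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ block starting at line ", i)
    k <- k + 1L
    comment <- lines[i + 1L]
    em <- regmatches(comment, regexpr("energy=\\s*[-+0-9.eE]+", comment))
    if (length(em) == 1L) {
      energy[k] <- as.numeric(sub("energy=\\s*", "", em))
    } else {
      warning("no energy= token in comment of structure ", k, "; using 0")
      energy[k] <- 0
    }
    block <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    sym <- vapply(block, `[[`, character(1L), 1L)
    xyz <- t(vapply(block, function(f) as.numeric(f[2:4]), numeric(3L)))
    if (any(!is.finite(xyz))) stop("non-numeric coordinates in structure ", k)
    if (is.null(atoms)) atoms <- sym
    else if (!identical(atoms, sym)) stop("structure ", k, " has different atoms/order")
    coords[[k]] <- unname(xyz)
    ids[k] <- paste0("conf_", k)
    i <- i + 2L + n
  }
  conformer_set(coords, energy, atoms, ids)
}

#' Write a conformer set as a multi-structure XYZ file
#'
#' @param x A [conformer_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  stopifnot(inherits(x, "conformer_set"))
  con <- file(path, "w"); on.exit(close(con))
  n <- length(x$atoms)
  for (k in seq_along(x$coords)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("%s energy=%.12g", x$ids[k], x$energy[k]), con)
    m <- x$coords[[k]]
    writeLines(sprintf("%-3s %18.12f %18.12f %18.12f",
                       x$atoms, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Minimal RMSD between two conformers (Kabsch superposition)
#'
#' Root-mean-square deviation after optimal rigid-body superposition of `b`
#' onto `a` (centroid translation plus the rotation from the Kabsch SVD
#' algorithm, with the determinant sign corrected so no reflection is
#' allowed). Symmetric in its arguments. Atom-symmetry permutations are not
#' searched; atoms are matched by position in the input order.
#'
#' @param a,b N x 3 coordinate matrices with identical atom ordering.
#' @param atoms Optional element symbols, length N; needed only to exclude
#'   hydrogens.
#' @param include_hydrogens Keep hydrogen atoms in the superposition?
#'   Default `FALSE` (heavy atoms only) when `atoms` is supplied.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, atoms = NULL, include_hydrogens = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L) {
    stop("atom-count mismatch: conformers must share an N x 3 layout")
  }
  if (!is.null(atoms) && !include_hydrogens) {
    keep <- toupper(atoms) != "H"
    if (!any(keep)) stop("no heavy atoms left after excluding hydrogens")
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  }
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  s <- svd(crossprod(b, a))                      # 3 x 3 covariance
  sign3 <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, sign3)) %*% t(s$v)
  d <- a - b %*% rot
  sqrt(sum(d * d) / nrow(a))
}

#' RMSD between two members of a conformer set
#'
#' Convenience wrapper around [kabsch_rmsd()] using the set's element labels.
#'
#' @param x A [conformer_set()].
#' @param i,j Conformer indices or ids.
#' @param include_hydrogens Keep hydrogens? Default `FALSE`.
#' @return RMSD in Angstrom.
#' @export
conformer_rmsd <- function(x, i, j, include_hydrogens = FALSE) {
  stopifnot(inherits(x, "conformer_set"))
  if (is.character(i)) i <- match(i, x$ids)
  if (is.character(j)) j <- match(j, x$ids)
  kabsch_rmsd(x$coords[[i]], x$coords[[j]], atoms = x$atoms,
              include_hydrogens = include_hydrogens)
}

#' Discard high-energy conformers
#'
#' Retains conformers whose ranking energy lies strictly less than `window`
#' above the minimum; conformers at least `window` kcal/mol above the minimum
#' are discarded. The minimum-energy conformer is always retained.
#'
#' @param confs A [conformer_set()].
#' @param window Energy window, kcal/mol (default 5).
#' @return The retained subset, with the discarded ids in attribute
#'   `"discarded"`.
#' @export
energy_window_filter <- function(confs, window = 5.0) {
  stopifnot(inherits(confs, "conformer_set"))
  if (length(confs) == 0L) stop("empty conformer set")
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  keep <- confs$energy - min(confs$energy) < window
  out <- confs[keep]
  attr(out, "discarded") <- confs$ids[!keep]
  out
}

#' Greedy energy-ordered RMSD clustering
#'
#' Conformers are processed in ascending energy order (stable in input order
#' on ties). The minimum-energy conformer seeds the first cluster; each
#' subsequent conformer joins the first existing cluster whose representative
#' lies within `rmsd_cut`, and seeds a new cluster only if it is at least
#' `rmsd_cut` away from every representative. Representatives are therefore
#' the lowest-energy member of each cluster and pairwise >= `rmsd_cut` apart.
#'
#' @param confs A [conformer_set()], typically after
#'   [energy_window_filter()].
#' @param rmsd_cut Clustering radius, Angstrom (default 0.5).
#' @param include_hydrogens Use hydrogens in the RMSD? Default `FALSE`.
#' @return An object of class `cluster_result`: list with `representatives`
#'   (a `conformer_set`), `assignments` (integer cluster index named by
#'   conformer id, in input order), and `discarded` (ids removed upstream,
#'   empty here; populated by [reduce_conformers()]).
#' @export
greedy_rmsd_cluster <- function(confs, rmsd_cut = 0.5, include_hydrogens = FALSE) {
  stopifnot(inherits(confs, "conformer_set"))
  if (length(confs) == 0L) stop("empty conformer set")
  if (!is.finite(rmsd_cut) || rmsd_cut <= 0) stop("rmsd_cut must be positive")
  ord <- order(confs$energy)                     # stable: ties keep input order
  rep_idx <- integer(0)
  assign_ord <- integer(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    hit <- 0L
    for (r in seq_along(rep_idx)) {
      d <- kabsch_rmsd(confs$coords[[rep_idx[r]]], confs$coords[[i]],
                       atoms = confs$atoms, include_hydrogens = include_hydrogens)
      if (d < rmsd_cut) { hit <- r; break }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      hit <- length(rep_idx)
    }
    assign_ord[i] <- hit
  }
  assignments <- assign_ord
  names(assignments) <- confs$ids
  structure(list(representatives = confs[rep_idx],
                 assignments = assignments,
                 discarded = character(0)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s) over %d conformer(s), %d discarded upstream\n",
              length(x$representatives), length(x$assignments), length(x$discarded)))
  invisible(x)
}

#' Lowest-energy conformer selection
#'
#' Returns the `min(k, n)` conformers of lowest ranking energy, sorted
#' ascending, ties broken by input order. With `k = 1` this reduces to
#' picking the single globally optimal conformer.
#'
#' @param confs A [conformer_set()].
#' @param k Maximum number of conformers to keep (default 5).
#' @return A [conformer_set()] of at most `k` conformers.
#' @export
select_lowest <- function(confs, k = 5L) {
  stopifnot(inherits(confs, "conformer_set"))
  if (!is.finite(k) || k < 1) stop("k must be at least 1")
  ord <- order(confs$energy)
  confs[ord[seq_len(min(length(confs), as.integer(k)))]]
}

#' Full conformer-reduction pipeline
#'
#' Energy-window filtering, greedy RMSD clustering of the survivors, and
#' selection of the `k` lowest-energy cluster representatives — the protocol
#' used to shrink a raw conformer sample down to the states that enter the
#' partition function.
#'
#' @inheritParams greedy_rmsd_cluster
#' @param window Energy window, kcal/mol (default 5).
#' @param k Maximum number of representatives to keep (default 5).
#' @return A `cluster_result` whose `representatives` are the selected
#'   conformers and whose `discarded` field lists ids removed by the energy
#'   window.
#' @export
reduce_conformers <- function(confs, window = 5.0, rmsd_cut = 0.5, k = 5L,
                              include_hydrogens = FALSE) {
  kept <- energy_window_filter(confs, window)
  cl <- greedy_rmsd_cluster(kept, rmsd_cut, include_hydrogens)
  cl$discarded <- attr(kept, "discarded")
  cl$representatives <- select_lowest(cl$representatives, k)
  cl
}

#' Export a clustering result as a table
#'
#' @param x A `cluster_result`.
#' @return Data frame with columns `conformer_id`, `cluster`,
#'   `representative` and `discarded`.
#' @export
cluster_table <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  ids <- c(names(x$assignments), x$discarded)
  data.frame(
    conformer_id = ids,
    cluster = c(unname(x$assignments), rep(NA_integer_, length(x$discarded))),
    representative = ids %in% x$representatives$ids,
    discarded = ids %in% x$discarded,
    stringsAsFactors = FALSE
  )
}
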