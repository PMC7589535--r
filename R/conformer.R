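#' Conformer and ensemble containers
#'
#' A conformer stores the atom records of a single structural model; an
#' ensemble is an ordered collection of conformers sharing one topology for
#' the C-alpha selection.  Conformers hold an atom table (one row per atom)
#' with 1-based residue numbering as in the source file.  Heteroatom records
#' are retained but excluded from the C-alpha selection.
#'
#' @param atoms A data frame with columns `chain`, `resid`, `insert`,
#'   `resname`, `elety` (atom name), `x`, `y`, `z` and logical `het`.
#' @param label Character label identifying the conformer (e.g. source file
#'   and model number).
#' @return `conformer()` returns a `conformer` object; `ensemble()` returns an
#'   `ensemble` (list of conformers with a validated shared topology).
#' @export
conformer <- function(atoms, label = "conformer") {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("chain", "resid", "resname", "elety", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("conformer atom table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  atoms$insert[is.na(atoms$insert)] <- ""
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) {
    abort(paste0("conformer '", label, "' contains non-finite coordinates"))
  }
  x <- list(atoms = atoms, label = label)
  class(x) <- "conformer"
  x
}

#' @export
print.conformer <- function(x, ...) {
  n_ca <- length(ca_indices(x))
  cat("<conformer> ", x$label, ": ", nrow(x$atoms), " atoms, ",
      n_ca, " C-alpha\n", sep = "")
  invisible(x)
}

topology_key <- function(atoms) {
  paste(atoms$chain, atoms$resid, atoms$insert, atoms$elety, sep = "|")
}

#' Indices of the C-alpha selection of a conformer
#'
#' @param conf A [conformer()].
#' @return Integer row indices into the atom table.
#' @export
ca_indices <- function(conf) {
  which(conf$atoms$elety == "CA" & !conf$atoms$het)
}

#' C-alpha coordinate matrix of a conformer
#'
#' @param conf A [conformer()].
#' @return Numeric matrix (n_residues x 3) with topology keys as row names.
#' @export
ca_coords <- function(conf) {
  idx <- ca_indices(conf)
  m <- as.matrix(conf$atoms[idx, c("x", "y", "z")])
  rownames(m) <- topology_key(conf$atoms[idx, ])
  m
}

atom_coord <- function(conf, chain, resid, elety) {
  a <- conf$atoms
  i <- which(a$chain == chain & a$resid == resid & a$elety == elety & !a$het)
  if (length(i) == 0) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' @rdname conformer
#' @param conformers List of [conformer()] objects (at least one).
#' @export
ensemble <- function(conformers) {
  if (length(conformers) < 1) abort("an ensemble needs at least one conformer")
  if (!all(vapply(conformers, inherits, logical(1), "conformer"))) {
    abort("all elements must be conformer objects")
  }
  ref_key <- rownames(ca_coords(conformers[[1]]))
  for (k in seq_along(conformers)) {
    key <- rownames(ca_coords(conformers[[k]]))
    if (!identical(key, ref_key)) {
      abort(paste0("topology mismatch: conformer '", conformers[[k]]$label,
                   "' does not share the C-alpha topology of '",
                   conformers[[1]]$label, "'"))
    }
  }
  x <- structure(conformers, class = "ensemble")
  x
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", length(x), " conformer(s), ",
      length(ca_indices(x[[1]])), " C-alpha each\n", sep = "")
  invisible(x)
}

#' @export
`[.ensemble` <- function(x, i) {
  ensemble(unclass(x)[i])
}

#' Labels of the conformers in an ensemble
#' @param ens An [ensemble()].
#' @return Character vector of conformer labels.
#' @export
conformer_labels <- function(ens) {
  vapply(ens, function(cf) cf$label, character(1))
}

#' Replace the coordinates of a conformer
#'
#' Utility for proposal engines: returns a copy of `conf` with new positions
#' for the given atom rows (topology unchanged).
#'
#' @param conf A [conformer()].
#' @param rows Integer row indices into the atom table.
#' @param xyz Numeric matrix `length(rows)` x 3 of new positions.
#' @return A [conformer()].
#' @export
set_coords <- function(conf, rows, xyz) {
  stopifnot(length(rows) == nrow(xyz))
  conf$atoms$x[rows] <- xyz[, 1]
  conf$atoms$y[rows] <- xyz[, 2]
  conf$atoms$z[rows] <- xyz[, 3]
  conf
}
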