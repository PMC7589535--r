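#' Least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the RMSD between
#' two paired coordinate sets, with a determinant guard against reflections.
#'
#' @param mobile,target Numeric n x 3 matrices of paired coordinates (n >= 3).
#' @return A list with `rotation` (3 x 3), `translation` (length 3) and
#'   `transformed` (`mobile` after superposition onto `target`).
#' @export
kabsch <- function(mobile, target) {
  if (nrow(mobile) != nrow(target)) abort("coordinate sets differ in size")
  if (nrow(mobile) < 3) abort("superposition needs at least 3 atoms")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  p <- sweep(mobile, 2, cm)
  q <- sweep(target, 2, ct)
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- sweep(p %*% t(rot), 2, ct, `+`)
  list(rotation = rot, translation = as.numeric(ct - rot %*% cm),
       transformed = transformed)
}

rmsd_xyz <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' C-alpha RMSD between two conformers
#'
#' Root-mean-square deviation over the shared C-alpha selection.  By default
#' an optimal rigid-body superposition (rotation + translation minimising the
#' RMSD) is applied first, so the value reflects internal structural
#' difference rather than pose.
#'
#' @param conf,ref [conformer()] objects sharing the C-alpha topology.
#' @param superpose Apply least-squares superposition first (default `TRUE`).
#' @return RMSD in Angstrom (non-negative, symmetric in its arguments).
#' @export
rmsd_ca <- function(conf, ref, superpose = TRUE) {
  a <- ca_coords(conf)
  b <- ca_coords(ref)
  if (!identical(rownames(a), rownames(b))) {
    abort(paste0("topology mismatch between '", conf$label, "' and '",
                 ref$label, "'"))
  }
  if (superpose) {
    a <- kabsch(a, b)$transformed
  }
  rmsd_xyz(a, b)
}

#' Pairwise C-alpha RMSD matrix of an ensemble
#'
#' @param ens An [ensemble()].
#' @param superpose Passed to [rmsd_ca()].
#' @return Symmetric `N x N` matrix (Angstrom) with zero diagonal and
#'   conformer labels as dimnames.
#' @export
rmsd_matrix <- function(ens, superpose = TRUE) {
  n <- length(ens)
  labels <- conformer_labels(ens)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n == 1) return(m)
  coords <- lapply(ens, ca_coords)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- coords[[i]]
      b <- coords[[j]]
      if (superpose) a <- kabsch(a, b)$transformed
      m[i, j] <- m[j, i] <- rmsd_xyz(a, b)
    }
  }
  m
}
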