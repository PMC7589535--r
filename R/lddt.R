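#' Local distance difference test (lDDT) over C-alpha atoms
#'
#' Superposition-free model similarity: the fraction of C-alpha pair
#' distances, taken among pairs closer than the inclusion radius in the
#' reference, that are conserved in the model within each tolerance
#' threshold, averaged over the thresholds.  The inclusion set is determined
#' by the reference structure only; a pair contributes to the per-residue
#' score of both of its residues.
#'
#' @param conf,ref [conformer()] objects sharing the C-alpha topology.
#' @param inclusion_radius Pairs with reference distance below this radius
#'   (Angstrom) are scored. Default 15.
#' @param thresholds Tolerance thresholds in Angstrom. Default
#'   `c(0.5, 1, 2, 4)`.
#' @return A list with `global` (score in `[0, 1]`) and `per_residue`
#'   (tibble: `chain`, `resid`, `lddt`; `NA` for residues without included
#'   pairs).
#' @export
lddt_ca <- function(conf, ref, inclusion_radius = 15,
                    thresholds = c(0.5, 1, 2, 4)) {
  a <- ca_coords(conf)
  b <- ca_coords(ref)
  if (!identical(rownames(a), rownames(b))) {
    abort(paste0("topology mismatch between '", conf$label, "' and '",
                 ref$label, "'"))
  }
  n <- nrow(b)
  d_ref <- as.matrix(stats::dist(b))
  d_conf <- as.matrix(stats::dist(a))
  inc <- upper.tri(d_ref) & d_ref < inclusion_radius
  if (!any(inc)) {
    abort("no C-alpha pairs within the inclusion radius; lDDT is undefined")
  }
  dev <- abs(d_conf - d_ref)

  # conserved-fraction per threshold, mean over thresholds
  conserved <- vapply(thresholds, function(t) mean(dev[inc] < t), numeric(1))
  global <- mean(conserved)

  pair_idx <- which(inc, arr.ind = TRUE)
  per_res <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    touch <- pair_idx[, 1] == r | pair_idx[, 2] == r
    if (!any(touch)) next
    devs <- dev[pair_idx[touch, , drop = FALSE]]
    per_res[r] <- mean(vapply(thresholds, function(t) mean(devs < t),
                              numeric(1)))
  }
  ca <- conf$atoms[ca_indices(conf), ]
  list(
    global = global,
    per_residue = tibble::tibble(chain = ca$chain, resid = ca$resid,
                                 lddt = per_res)
  )
}

#' Granularity of a FRET network
#'
#' Residues per informative FRET pair: how many amino acids each measured
#' pair has to "cover" to reach a given model uncertainty.
#'
#' @param n_residues Number of amino acids in the protein.
#' @param n_pairs Number of FRET pairs (must be >= 1).
#' @return The ratio `n_residues / n_pairs`.
#' @export
granularity <- function(n_residues, n_pairs) {
  if (n_pairs < 1) abort("granularity needs at least one FRET pair")
  n_residues / n_pairs
}

#' @rdname granularity
#' @return `format_granularity()` returns the conventional "1:x" string with
#'   one decimal, e.g. `"1:11.1"`.
#' @export
format_granularity <- function(n_residues, n_pairs) {
  sprintf("1:%.1f", round(granularity(n_residues, n_pairs), 1))
}
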