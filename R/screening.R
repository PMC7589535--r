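#' Chi-squared agreement statistics for FRET screening
#'
#' `chi2()` is the weighted sum of squared deviations between model and
#' reference distances.  `n_dof()` is the number of degrees of freedom,
#' measurements minus fitted parameters.  `p_value()` is the upper-tail
#' probability that a chi-squared sample exceeds the observed value.
#' `chi2_reduced()` is chi-squared per degree of freedom.
#' `chi2_threshold()` is the chi-squared value sitting at a given confidence
#' level (upper-tail quantile), and `chi2_n()` normalises chi-squared by that
#' bound so that the value 1 marks the 68% confidence level for any number
#' of degrees of freedom.
#'
#' @param model_distances Named numeric vector of model distances (Angstrom),
#'   names are pair ids covering every measurement.
#' @param meas Measurement tibble with `pair_id`, `r_ref`, `dr_ref`.
#' @return `chi2()`: non-negative scalar.
#' @export
chi2 <- function(model_distances, meas) {
  check_measurements(meas)
  missing <- setdiff(meas$pair_id, names(model_distances))
  if (length(missing) > 0) {
    abort(paste0("model distances missing for pair id(s): ",
                 paste(missing, collapse = ", ")))
  }
  r_model <- model_distances[meas$pair_id]
  sum(((r_model - meas$r_ref) / meas$dr_ref)^2)
}

#' @rdname chi2
#' @param n_meas Number of measurements.
#' @param n_fit_param Number of fitted model parameters.
#' @return `n_dof()`: integer (possibly non-positive; statistics requiring
#'   positive degrees of freedom refuse such values).
#' @export
n_dof <- function(n_meas, n_fit_param) {
  if (n_meas < 0 || n_fit_param < 0) abort("counts must be non-negative")
  as.integer(n_meas) - as.integer(n_fit_param)
}

#' @rdname chi2
#' @param x Observed chi-squared value.
#' @param dof Degrees of freedom (>= 1).
#' @return `p_value()`: probability in `[0, 1]`.
#' @export
p_value <- function(x, dof) {
  check_dof(dof)
  pchisq(x, df = dof, lower.tail = FALSE)
}

#' @rdname chi2
#' @return `chi2_reduced()`: chi-squared divided by the degrees of freedom.
#' @export
chi2_reduced <- function(x, dof) {
  check_dof(dof)
  x / dof
}

#' @rdname chi2
#' @param confidence Confidence level in (0, 1). Default 0.68.
#' @return `chi2_threshold()`: the value `c` with
#'   `p_value(c, dof) == 1 - confidence`.
#' @export
chi2_threshold <- function(confidence = 0.68, dof) {
  check_dof(dof)
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must lie strictly between 0 and 1")
  }
  qchisq(confidence, df = dof)
}

#' @rdname chi2
#' @return `chi2_n()`: chi-squared divided by its confidence bound; equals 1
#'   exactly at the bound, for any degrees of freedom.
#' @export
chi2_n <- function(x, dof, confidence = 0.68) {
  x / chi2_threshold(confidence, dof)
}

check_dof <- function(dof) {
  if (any(dof < 1)) {
    abort(paste0(
      "undefined statistic: N_dof <= 0 (overfitted model). ",
      "Add cross-validation FRET pairs not used during fitting so that ",
      "N_measurements exceeds N_fit.param."))
  }
  invisible(dof)
}

#' Screen an ensemble against a FRET measurement set
#'
#' Computes model distances for every conformer (AV simulation), the
#' chi-squared statistics and the FRET-selected sub-ensemble (conformers
#' with normalized chi-squared below `threshold`).  The run is refused when
#' the degrees of freedom are non-positive.  The selection's maximum pairwise
#' C-alpha RMSD decides convergence (`< convergence_rmsd` for all pairs).
#'
#' @param ens An [ensemble()].
#' @param pairs List of [fret_pair()] objects covering the measurement ids.
#' @param meas Measurement tibble (`pair_id`, `r_ref`, `dr_ref`).
#' @param n_fit_param Number of fitted parameters of the structural model.
#' @param grid_spacing,contact,n_samples,seed AV / observable parameters,
#'   see [compute_av()] and [model_distance()].
#' @param confidence Confidence level defining the chi2_n bound. Default 0.68.
#' @param threshold chi2_n selection threshold. Default 1.0.
#' @param convergence_rmsd Convergence criterion on the selection's pairwise
#'   RMSD in Angstrom. Default 3.
#' @param distances Optional precomputed conformer x pair distance matrix
#'   (rows in ensemble order, columns named by pair id); skips the AV step.
#' @return A `fret_screen` object; `tidy()` gives the per-conformer table,
#'   `glance()` the run summary.
#' @export
screen_ensemble <- function(ens, pairs, meas, n_fit_param = 0,
                            grid_spacing = 0.9, contact = NULL,
                            n_samples = 1e5, seed = 1, confidence = 0.68,
                            threshold = 1.0, convergence_rmsd = 3,
                            distances = NULL) {
  check_measurements(meas)
  dof <- n_dof(nrow(meas), n_fit_param)
  check_dof(dof)
  if (is.null(distances)) {
    distances <- model_distance_matrix(ens, pairs, grid_spacing = grid_spacing,
                                       contact = contact,
                                       n_samples = n_samples, seed = seed)
  }
  stats <- purrr::map_dfr(seq_along(ens), function(k) {
    x2 <- chi2(setNames(distances[k, ], colnames(distances)), meas)
    tibble::tibble(
      conformer = ens[[k]]$label,
      chi2 = x2,
      p = p_value(x2, dof),
      chi2_r = chi2_reduced(x2, dof),
      chi2_n = chi2_n(x2, dof, confidence)
    )
  })
  stats$selected <- stats$chi2_n < threshold
  sel_idx <- which(stats$selected)
  if (length(sel_idx) > 0) {
    sel <- ens[sel_idx]
    max_rmsd <- if (length(sel_idx) > 1) max(rmsd_matrix(sel)) else 0
    converged <- max_rmsd < convergence_rmsd
  } else {
    sel <- NULL
    max_rmsd <- NA_real_
    converged <- FALSE
  }
  out <- list(stats = stats, selected_ensemble = sel,
              max_rmsd_selected = max_rmsd, converged = converged,
              n_dof = dof, n_fit_param = n_fit_param,
              threshold = threshold, confidence = confidence,
              convergence_rmsd = convergence_rmsd, distances = distances)
  class(out) <- "fret_screen"
  out
}

#' Model-distance matrix of an ensemble
#'
#' AV-averaged inter-dye distances for every conformer and pair.  Pairs with
#' a buried site on any conformer are dropped for all conformers (reported in
#' the `dropped` attribute).
#'
#' @inheritParams screen_ensemble
#' @return Numeric matrix, conformers x pairs, columns named by pair id.
#' @export
model_distance_matrix <- function(ens, pairs, grid_spacing = 0.9,
                                  contact = NULL, n_samples = 1e5, seed = 1) {
  ids <- pair_ids(pairs)
  sites <- unique_sites(pairs)
  m <- matrix(NA_real_, nrow = length(ens), ncol = length(pairs),
              dimnames = list(conformer_labels(ens), ids))
  for (k in seq_along(ens)) {
    avs <- lapply(sites, function(s) compute_av(ens[[k]], s, grid_spacing,
                                                contact))
    for (j in seq_along(pairs)) {
      d <- avs[[site_id(pairs[[j]]$donor)]]
      a <- avs[[site_id(pairs[[j]]$acceptor)]]
      if (d$empty || a$empty) next
      m[k, j] <- model_distance(d, a, kind = "mean_RDA",
                                n_samples = n_samples, seed = seed)
    }
  }
  dropped <- ids[apply(m, 2, anyNA)]
  if (length(dropped) > 0) {
    inform(paste0("pair(s) dropped for all conformers (buried site on some ",
                  "conformer): ", paste(dropped, collapse = ", ")))
    m <- m[, !ids %in% dropped, drop = FALSE]
  }
  attr(m, "dropped") <- dropped
  m
}

#' @export
print.fret_screen <- function(x, ...) {
  n_sel <- sum(x$stats$selected)
  cat("<fret_screen> ", nrow(x$stats), " conformer(s), N_dof = ", x$n_dof,
      "\n  selected (chi2_n < ", x$threshold, "): ", n_sel, sep = "")
  if (n_sel > 1) {
    cat(sprintf("; max pairwise RMSD %.2f A (%s)", x$max_rmsd_selected,
                if (x$converged) "converged" else "not converged"))
  }
  cat("\n")
  invisible(x)
}

#' Write a screening report as CSV
#'
#' @param x A `fret_screen` object.
#' @param path CSV output path.
#' @export
write_screen_csv <- function(x, path) {
  write.csv(as.data.frame(x$stats), path, row.names = FALSE)
  invisible(path)
}
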