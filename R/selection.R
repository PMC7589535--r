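#' Build a candidate FRET-pair pool over an ensemble
#'
#' Precomputes everything the pair-selection algorithms need: the per
#' conformer / per pair model-distance matrix (AV simulation), the
#' reference-evaluated distance-error model (efficiency-error propagation at
#' each conformer's own model distance, which automatically favours pairs
#' close to the Foerster radius where the measurement is most sensitive) and
#' the pairwise C-alpha RMSD matrix.  Pairs with a buried site on any
#' conformer are dropped for all conformers and reported.
#'
#' @param ens An [ensemble()] with at least two conformers.
#' @param pairs List of candidate [fret_pair()] objects.
#' @param grid_spacing,contact,n_samples,seed See [compute_av()] and
#'   [model_distance()].
#' @param dE,clamp Error model, see [distance_error_from_efficiency()].
#' @return A `pair_pool` object.
#' @export
build_pair_pool <- function(ens, pairs, grid_spacing = 0.9, contact = NULL,
                            n_samples = 1e5, seed = 1, dE = 0.06,
                            clamp = c(0.5, 30)) {
  if (length(ens) < 2) abort("pair selection needs at least two conformers")
  dist <- model_distance_matrix(ens, pairs, grid_spacing = grid_spacing,
                                contact = contact, n_samples = n_samples,
                                seed = seed)
  kept <- colnames(dist)
  pairs <- pairs[pair_ids(pairs) %in% kept]
  r0 <- vapply(pairs, function(p) p$r0, numeric(1))
  dr <- dist
  for (j in seq_along(kept)) {
    dr[, j] <- distance_error_from_efficiency(dist[, j], r0[j], dE, clamp)
  }
  pool <- list(pairs = pairs, ids = kept, dist = dist, dr = dr,
               rmsd = rmsd_matrix(ens), labels = conformer_labels(ens),
               dropped = attr(dist, "dropped"))
  class(pool) <- "pair_pool"
  pool
}

#' @export
print.pair_pool <- function(x, ...) {
  cat("<pair_pool> ", length(x$ids), " candidate pair(s) x ",
      nrow(x$dist), " conformer(s)\n", sep = "")
  invisible(x)
}

# squared residual array A[conf, ref, pair] with the reference's error model
pool_res2 <- function(pool, cols) {
  n <- nrow(pool$dist)
  a <- array(0, dim = c(n, n, length(cols)))
  for (k in seq_along(cols)) {
    j <- cols[k]
    d <- pool$dist[, j]
    e <- pool$dr[, j]
    a[, , k] <- (outer(d, d, `-`) / rep(e, each = n))^2
  }
  a
}

rmsd_from_chi2 <- function(chi2_mat, rmsd_mat, dof) {
  p <- pchisq(chi2_mat, df = dof, lower.tail = FALSE)
  inner <- colSums(p * rmsd_mat) / colSums(p)
  mean(inner)
}

#' Expected model uncertainty of a FRET-pair set
#'
#' The expected uncertainty `<<RMSD>>` of the structural model that a given
#' set of FRET pairs would support, for a candidate ensemble: every
#' conformer in turn plays the "true" reference whose simulated distances
#' (and error model) score all conformers by chi-squared; the upper-tail
#' p-values weight the pairwise RMSDs (the reference's self term enters with
#' p = 1 and RMSD = 0); the per-reference weighted averages are then averaged
#' over all references.
#'
#' @param pool A [build_pair_pool()] result.
#' @param ids Pair ids to evaluate (default: all pairs in the pool).
#' @param n_fit_param Fitted-parameter count of the structural model;
#'   degrees of freedom are `length(ids) - n_fit_param` and must be >= 1.
#' @return Expected uncertainty in Angstrom.
#' @export
expected_rmsd <- function(pool, ids = pool$ids, n_fit_param = 0) {
  cols <- match(ids, pool$ids)
  if (anyNA(cols)) abort("unknown pair id(s) in `ids`")
  dof <- n_dof(length(cols), n_fit_param)
  check_dof(dof)
  n <- nrow(pool$dist)
  chi2_mat <- matrix(0, n, n)
  for (j in cols) {
    d <- pool$dist[, j]
    e <- pool$dr[, j]
    chi2_mat <- chi2_mat + (outer(d, d, `-`) / rep(e, each = n))^2
  }
  rmsd_from_chi2(chi2_mat, pool$rmsd, dof)
}

#' Baseline model uncertainty without measurements
#'
#' `<<RMSD>>` with all p-values equal to 1 (no information): the mean over
#' references of the mean pairwise RMSD (self term included).
#'
#' @param pool A [build_pair_pool()] result.
#' @return Baseline uncertainty in Angstrom.
#' @export
baseline_rmsd <- function(pool) {
  mean(colMeans(pool$rmsd))
}

new_selection <- function(trace, selected, algorithm, stop_reason) {
  x <- list(trace = trace, selected = selected, algorithm = algorithm,
            stop = stop_reason)
  class(x) <- "fret_selection"
  x
}

#' @export
print.fret_selection <- function(x, ...) {
  cat("<fret_selection> ", x$algorithm, ": ", length(x$selected),
      " pair(s) [", paste(x$selected, collapse = ", "), "]; stop: ",
      x$stop, "\n", sep = "")
  invisible(x)
}

#' Greedy forward FRET-pair selection
#'
#' Iteratively adds the candidate pair whose addition yields the minimal
#' expected model uncertainty `<<RMSD>>`, until the target uncertainty is
#' reached, `max_pairs` are chosen or the pool is exhausted.  Ties break
#' toward the lowest pair id.  Deterministic.
#'
#' @inheritParams expected_rmsd
#' @param target_rmsd Desired `<<RMSD>>` in Angstrom. Default 3.
#' @param max_pairs Maximum number of pairs to select.
#' @param initial Pair ids fixed into the set before selection starts (used
#'   by the complexity heuristic).
#' @return A `fret_selection` with the ordered trace of additions and the
#'   `<<RMSD>>` after each.
#' @export
select_greedy_forward <- function(pool, target_rmsd = 3, max_pairs = Inf,
                                  n_fit_param = 0, initial = character(0)) {
  if (length(pool$ids) == 0) abort("empty candidate pool")
  n <- nrow(pool$dist)
  res2 <- pool_res2(pool, seq_along(pool$ids))
  chosen <- match(initial, pool$ids)
  if (anyNA(chosen)) abort("unknown pair id(s) in `initial`")
  chi2_acc <- matrix(0, n, n)
  for (j in chosen) chi2_acc <- chi2_acc + res2[, , j]
  remaining <- setdiff(seq_along(pool$ids), chosen)
  trace <- list()
  stop_reason <- "pool exhausted"
  while (length(remaining) > 0) {
    if (length(chosen) - length(initial) >= max_pairs) {
      stop_reason <- "max_pairs reached"
      break
    }
    dof <- length(chosen) + 1 - n_fit_param
    if (dof < 1) {
      # cannot score yet; defer to informativeness-free order (lowest id)
      abort("n_fit_param too large: cannot score any candidate set")
    }
    vals <- vapply(remaining, function(j) {
      rmsd_from_chi2(chi2_acc + res2[, , j], pool$rmsd, dof)
    }, numeric(1))
    best <- remaining[order(vals, pool$ids[remaining])][1]
    chosen <- c(chosen, best)
    chi2_acc <- chi2_acc + res2[, , best]
    remaining <- setdiff(remaining, best)
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(trace) + 1, action = "add", pair_id = pool$ids[best],
      expected_rmsd = min(vals), n_pairs = length(chosen))
    if (min(vals) <= target_rmsd) {
      stop_reason <- "target reached"
      break
    }
  }
  new_selection(dplyr::bind_rows(trace), pool$ids[chosen],
                "greedy_forward", stop_reason)
}

#' Greedy backward FRET-pair elimination
#'
#' Starts from the full pool and iteratively removes the pair whose removal
#' least degrades (keeps smallest) the expected uncertainty `<<RMSD>>`,
#' recording the elimination order, until `min_pairs` remain, the degrees of
#' freedom would vanish, or a removal would push `<<RMSD>>` above
#' `target_rmsd`.
#'
#' @inheritParams select_greedy_forward
#' @param min_pairs Minimum number of pairs to keep. Default 1.
#' @return A `fret_selection`; the trace starts with the full-pool value
#'   (step 0) and the `selected` field holds the surviving set.
#' @export
select_greedy_backward <- function(pool, target_rmsd = Inf, min_pairs = 1,
                                   n_fit_param = 0) {
  if (length(pool$ids) < 2) abort("backward elimination needs >= 2 pairs")
  n <- nrow(pool$dist)
  res2 <- pool_res2(pool, seq_along(pool$ids))
  kept <- seq_along(pool$ids)
  chi2_acc <- matrix(0, n, n)
  for (j in kept) chi2_acc <- chi2_acc + res2[, , j]
  full_val <- rmsd_from_chi2(chi2_acc, pool$rmsd,
                             n_dof_checked(length(kept), n_fit_param))
  trace <- list(tibble::tibble(step = 0, action = "start",
                               pair_id = NA_character_,
                               expected_rmsd = full_val,
                               n_pairs = length(kept)))
  stop_reason <- "min_pairs reached"
  while (length(kept) > max(min_pairs, n_fit_param + 1)) {
    dof <- length(kept) - 1 - n_fit_param
    vals <- vapply(kept, function(j) {
      rmsd_from_chi2(chi2_acc - res2[, , j], pool$rmsd, dof)
    }, numeric(1))
    best <- kept[order(vals, pool$ids[kept])][1]
    best_val <- min(vals)
    if (best_val > target_rmsd) {
      stop_reason <- "removal would exceed target"
      break
    }
    chi2_acc <- chi2_acc - res2[, , best]
    kept <- setdiff(kept, best)
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(trace) - 1 + 1, action = "remove",
      pair_id = pool$ids[best], expected_rmsd = best_val,
      n_pairs = length(kept))
  }
  if (length(kept) <= max(min_pairs, n_fit_param + 1) &&
      stop_reason == "min_pairs reached" &&
      length(kept) == n_fit_param + 1 && n_fit_param + 1 > min_pairs) {
    stop_reason <- "degrees of freedom floor"
  }
  new_selection(dplyr::bind_rows(trace), pool$ids[sort(kept)],
                "greedy_backward", stop_reason)
}

n_dof_checked <- function(n_meas, n_fit_param) {
  dof <- n_dof(n_meas, n_fit_param)
  check_dof(dof)
  dof
}

#' Mutual-information (conditional-entropy) FRET-pair selection
#'
#' Model distances of each candidate pair are discretised over the ensemble
#' into fixed-width bins spanning the pooled distance range.  The first pick
#' maximises the marginal Shannon entropy; each further pick maximises the
#' minimum conditional entropy with respect to the already-chosen pairs
#' (maximum new information, minimum redundancy).  Entropies are plug-in
#' (maximum-likelihood) estimates in bits.  Constant-distance candidates
#' carry zero entropy and are never picked before informative ones.  Ties
#' break toward the lowest pair id.
#'
#' @inheritParams select_greedy_forward
#' @param n_pairs Number of pairs to select.
#' @param bin_width Discretisation bin width in Angstrom (about a typical
#'   distance uncertainty). Default 3.
#' @return A `fret_selection`; the trace also reports `<<RMSD>>` after each
#'   addition (with `n_fit_param` as given) where defined.
#' @export
select_mutual_information <- function(pool, n_pairs, bin_width = 3,
                                      n_fit_param = 0) {
  if (length(pool$ids) == 0) abort("empty candidate pool")
  n_pairs <- min(n_pairs, length(pool$ids))
  rng <- range(pool$dist)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width, rng[2] + bin_width,
                by = bin_width)
  bins <- matrix(findInterval(pool$dist, breaks), nrow = nrow(pool$dist))

  entropy <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  h_marg <- vapply(seq_along(pool$ids),
                   function(j) entropy(table(bins[, j])), numeric(1))
  h_cond <- function(cand, given) {
    # H(cand | given) = H(cand, given) - H(given)
    entropy(table(bins[, cand], bins[, given])) - entropy(table(bins[, given]))
  }

  chosen <- integer(0)
  trace <- list()
  remaining <- seq_along(pool$ids)
  while (length(chosen) < n_pairs && length(remaining) > 0) {
    if (length(chosen) == 0) {
      score <- h_marg[remaining]
    } else {
      score <- vapply(remaining, function(c) {
        min(vapply(chosen, function(s) h_cond(c, s), numeric(1)))
      }, numeric(1))
    }
    best <- remaining[order(-score, pool$ids[remaining])][1]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
    dof <- length(chosen) - n_fit_param
    val <- if (dof >= 1) {
      expected_rmsd(pool, pool$ids[chosen], n_fit_param)
    } else {
      NA_real_
    }
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(trace) + 1, action = "add", pair_id = pool$ids[best],
      expected_rmsd = val, n_pairs = length(chosen))
  }
  new_selection(dplyr::bind_rows(trace), pool$ids[chosen],
                "mutual_information", "n_pairs reached")
}

#' Choose the default selection algorithm
#'
#' Greedy forward selection for small requests (fewer than six pairs),
#' mutual-information selection otherwise; backward elimination only on
#' explicit request, with a warning for ensembles of 10,000 conformers or
#' more where it becomes impractical.
#'
#' @param n_requested Number of pairs the user asks for.
#' @param n_conf Number of conformers in the ensemble.
#' @param backward Explicitly request backward elimination? Default `FALSE`.
#' @return `"greedy_forward"`, `"mutual_information"` or `"greedy_backward"`.
#' @export
choose_algorithm <- function(n_requested, n_conf, backward = FALSE) {
  if (backward) {
    if (n_conf >= 10000) {
      warn(paste0("backward elimination with ", n_conf, " conformers is ",
                  "computationally demanding; advisable only below 10,000"))
    }
    return("greedy_backward")
  }
  if (n_requested < 6) "greedy_forward" else "mutual_information"
}

#' Estimate the complexity of a structure model
#'
#' Two-stage heuristic.  Stage 1 assumes zero fitted parameters and runs the
#' pair selection until the target uncertainty is reached; the number of
#' chosen pairs is the estimate of the model's fitted-parameter count (each
#' informative pair resolves one effective coordinate).  Stage 2 fixes that
#' count and re-runs the selection; the new total is the recommended number
#' of measurements, including the cross-validation pairs that make the
#' degrees of freedom positive.  For a rigid-body model the analytic count
#' `(N_bodies - 1) * 6 - N_bonds` serves as a sanity cross-check.
#'
#' @inheritParams select_greedy_forward
#' @param target_rmsd Target model uncertainty in Angstrom.
#' @return A list with `n_fit_param` (stage-1 estimate), `n_recommended`
#'   (stage-2 count, always larger), the two selection traces and
#'   `reached` flags.
#' @export
estimate_complexity <- function(pool, target_rmsd, max_pairs = Inf) {
  if (baseline_rmsd(pool) <= target_rmsd) {
    stage1 <- NULL
    k <- 0L
  } else {
    stage1 <- select_greedy_forward(pool, target_rmsd = target_rmsd,
                                    max_pairs = max_pairs, n_fit_param = 0)
    k <- length(stage1$selected)
    if (stage1$stop != "target reached") {
      warn(paste0("stage 1: target <<RMSD>> ", target_rmsd,
                  " A not reachable with this pool (best ",
                  sprintf("%.2f", min(stage1$trace$expected_rmsd)),
                  " A); complexity estimate is a lower bound"))
    }
  }
  initial <- if (k > 0) stage1$selected else character(0)
  stage2 <- select_greedy_forward(pool, target_rmsd = target_rmsd,
                                  max_pairs = max_pairs, n_fit_param = k,
                                  initial = initial)
  list(
    n_fit_param = k,
    n_recommended = length(stage2$selected),
    stage1 = stage1,
    stage2 = stage2,
    reached = list(
      stage1 = is.null(stage1) || stage1$stop == "target reached",
      stage2 = stage2$stop == "target reached"
    )
  )
}

#' Rigid-body fitted-parameter count
#'
#' Analytic complexity of a rigid-body model: each body beyond the first
#' contributes six rigid-body coordinates, minus one per hard inter-body
#' bond.
#'
#' @param n_bodies Number of rigid bodies.
#' @param n_bonds Number of hard bonds between the bodies.
#' @return Integer parameter count.
#' @export
rigid_body_parameters <- function(n_bodies, n_bonds = 0) {
  (n_bodies - 1) * 6 - n_bonds
}

#' Write a selection trace as CSV
#'
#' @param x A `fret_selection`.
#' @param path CSV output path.
#' @export
write_selection_csv <- function(x, path) {
  write.csv(as.data.frame(x$trace), path, row.names = FALSE)
  invisible(path)
}
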