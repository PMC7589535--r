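#' Metropolis acceptance for chi2_n-guided sampling
#'
#' Acceptance weight `exp((chi2n_prev - chi2n_curr) / kT)`, capped at 1 for
#' reporting; a move is accepted when the weight exceeds a uniform random
#' number.  At `kT = 0` the rule degenerates to greedy descent (accept iff
#' not worse).
#'
#' @param chi2n_prev,chi2n_curr Normalized chi-squared of the previous and
#'   proposed state.
#' @param kT Sampling temperature in units of chi2_n.
#' @return Acceptance probability in `[0, 1]`.
#' @export
accept_probability <- function(chi2n_prev, chi2n_curr, kT) {
  if (kT <= 0) {
    return(as.numeric(chi2n_curr <= chi2n_prev))
  }
  min(1, exp((chi2n_prev - chi2n_curr) / kT))
}

#' Triangular annealing schedule
#'
#' Piecewise-linear annealing: each cycle ramps `kT` from `floor` up to
#' `peak_kT` and back down, in units of chi2_n; cycles are concatenated.
#' Two cycles with a peak of one chi2_n unit are the default.
#'
#' @param n_iterations Total iterations (>= `2 * n_cycles`).
#' @param peak_kT Peak temperature. Default 1.0.
#' @param n_cycles Number of annealing cycles. Default 2.
#' @param floor Minimal temperature (> 0 keeps the greedy limit well
#'   defined). Default 1e-3.
#' @return An `annealing_schedule` with the per-iteration `kT` vector.
#' @export
make_schedule <- function(n_iterations, peak_kT = 1.0, n_cycles = 2,
                          floor = 1e-3) {
  if (n_iterations < 2 * n_cycles) {
    abort("need at least two iterations per annealing cycle")
  }
  len <- diff(round(seq(0, n_iterations, length.out = n_cycles + 1)))
  kT <- unlist(lapply(len, function(L) {
    half1 <- ceiling(L / 2)
    half2 <- L - half1
    up <- seq(floor, peak_kT, length.out = half1)
    down <- if (half2 > 0) seq(peak_kT, floor, length.out = half2 + 1)[-1]
    c(up, down)
  }))
  x <- list(kT = kT, n_cycles = n_cycles, peak_kT = peak_kT, floor = floor)
  class(x) <- "annealing_schedule"
  x
}

#' @export
print.annealing_schedule <- function(x, ...) {
  cat("<annealing_schedule> ", length(x$kT), " iterations, ", x$n_cycles,
      " cycle(s), kT in [", x$floor, ", ", x$peak_kT, "]\n", sep = "")
  invisible(x)
}

#' Proposal engines for guided sampling
#'
#' A proposal engine maps the current conformer to a candidate with
#' identical topology, drawing randomness from the ambient (seeded) RNG
#' stream of the guided run.  `identity_engine()` proposes the unchanged
#' conformer (useful for testing).  `toy_hinge_engine()` rigidly rotates the
#' second of two rigid segments about a random axis through the hinge
#' C-alpha by an angle uniform in `(-max_angle_step, +max_angle_step)`
#' degrees, re-proposing on inter-segment C-alpha clashes (< 3 Angstrom) up
#' to `max_retries` times; on retry exhaustion the current conformer is
#' returned with a stall flag.
#'
#' @param segments List with integer residue vectors `seg1` and `seg2`
#'   partitioning the chain and `hinge`, the hinge residue (last residue of
#'   the fixed segment).
#' @param max_angle_step Maximal rotation step in degrees.
#' @param max_retries Clash re-proposal budget. Default 20.
#' @return A `proposal_engine`; calling `propose(engine, conf)` returns the
#'   candidate conformer (attribute `stalled` flags retry exhaustion).
#' @export
toy_hinge_engine <- function(segments, max_angle_step, max_retries = 20) {
  stopifnot(all(c("seg1", "seg2", "hinge") %in% names(segments)))
  propose <- function(conf) {
    rows2 <- which(conf$atoms$resid %in% segments$seg2)
    ca1 <- which(conf$atoms$resid %in% segments$seg1 &
                   conf$atoms$elety == "CA")
    ca2 <- which(conf$atoms$resid %in% segments$seg2 &
                   conf$atoms$elety == "CA")
    pivot <- atom_coord(conf, conf$atoms$chain[1], segments$hinge, "CA")
    xyz2 <- as.matrix(conf$atoms[rows2, c("x", "y", "z")])
    seg_sep <- function(cf) {
      a <- as.matrix(cf$atoms[ca1, c("x", "y", "z")])
      b <- as.matrix(cf$atoms[ca2, c("x", "y", "z")])
      sqrt(min(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)))
    }
    start_sep <- seg_sep(conf)
    for (try in seq_len(max_retries)) {
      axis <- rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      theta <- runif(1, -max_angle_step, max_angle_step) * pi / 180
      rot <- rotation_about_axis(axis, theta)
      moved <- sweep(sweep(xyz2, 2, pivot) %*% t(rot), 2, pivot, `+`)
      cand <- set_coords(conf, rows2, moved)
      min_sep <- seg_sep(cand)
      # clash-free proposals are accepted; from an already-clashed state any
      # move that relieves the clash is allowed, so the chain cannot deadlock
      if (max_angle_step == 0 || min_sep >= 3.0 ||
          (start_sep < 3.0 && min_sep > start_sep)) {
        return(cand)
      }
    }
    attr(conf, "stalled") <- TRUE
    conf
  }
  structure(list(propose = propose, name = "toy_hinge"),
            class = "proposal_engine")
}

#' @rdname toy_hinge_engine
#' @export
identity_engine <- function() {
  structure(list(propose = function(conf) conf, name = "identity"),
            class = "proposal_engine")
}

#' @rdname toy_hinge_engine
#' @param engine A `proposal_engine`.
#' @param conf Current [conformer()].
#' @export
propose <- function(engine, conf) {
  engine$propose(conf)
}

rotation_about_axis <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

#' FRET-guided Metropolis sampling with annealing
#'
#' Iterates propose / re-simulate dyes / score / Metropolis-accept over an
#' annealing schedule: each candidate conformer gets fresh accessible
#' volumes (cached per labeling site and recomputed only when the site's
#' local backbone, the attachment residue plus two on either side, moved by
#' more than 0.1 Angstrom), model distances, and a normalized chi-squared
#' against the guiding measurements.  During guidance all guiding pairs are
#' effectively fitted, so the internal score uses `n_fit_param` (default 0)
#' for relative ranking only; absolute quality must come from the held-out
#' `validation` set, scored with the number of guiding restraints as the
#' fitted-parameter count.
#'
#' @param seed_conf Starting [conformer()].
#' @param engine A `proposal_engine`.
#' @param pairs Guiding [fret_pair()] list.
#' @param meas Guiding measurement tibble.
#' @param schedule An [make_schedule()] annealing schedule.
#' @param n_fit_param Guidance-time fitted-parameter count. Default 0.
#' @param seed Integer seed; the whole run (proposals, observable sampling,
#'   acceptance draws) is reproducible from it.
#' @param grid_spacing,contact,n_samples AV / observable parameters.
#' @param validation Optional held-out measurement tibble for
#'   cross-validated quality of the best conformer.
#' @param validation_pairs Pair definitions covering the validation
#'   measurements (defaults to the guiding pairs).
#' @return A `guided_run` with the acceptance log (`iteration`, `kT`,
#'   `chi2n`, `accepted`), the trajectory of accepted conformers, the best
#'   conformer with its guidance chi2_n, and, when `validation` is given,
#'   the cross-validated chi2_n.
#' @export
run_guided <- function(seed_conf, engine, pairs, meas, schedule,
                       n_fit_param = 0, seed = 1, grid_spacing = 0.9,
                       contact = NULL, n_samples = 2e4, validation = NULL,
                       validation_pairs = pairs) {
  check_measurements(meas)
  dof <- n_dof(nrow(meas), n_fit_param)
  check_dof(dof)
  sites <- unique_sites(pairs)
  ref_key <- rownames(ca_coords(seed_conf))
  cache <- new.env(parent = emptyenv())

  local_rows <- function(conf, site) {
    which(conf$atoms$chain == site$chain &
            abs(conf$atoms$resid - site$resid) <= 2 & !conf$atoms$het)
  }
  site_avs <- function(conf) {
    lapply(sites, function(s) {
      id <- site_id(s)
      rows <- local_rows(conf, s)
      snap <- as.matrix(conf$atoms[rows, c("x", "y", "z")])
      hit <- cache[[id]]
      if (!is.null(hit) && nrow(hit$snap) == nrow(snap) &&
          max(abs(hit$snap - snap)) <= 0.1) {
        return(hit$av)
      }
      av <- compute_av(conf, s, grid_spacing, contact)
      if (av$empty) {
        abort(paste0("site ", id, " became buried during guided sampling"))
      }
      assign(id, list(snap = snap, av = av), envir = cache)
      av
    })
  }
  score <- function(conf) {
    avs <- site_avs(conf)
    d <- vapply(pairs, function(p) {
      # common random numbers: one fixed sampling seed per run makes the
      # Monte-Carlo error a smooth offset instead of state-to-state jitter,
      # so nearby conformers rank reliably
      model_distance(avs[[site_id(p$donor)]], avs[[site_id(p$acceptor)]],
                     kind = "mean_RDA", n_samples = n_samples, seed = seed)
    }, numeric(1))
    names(d) <- pair_ids(pairs)
    chi2_n(chi2(d, meas), dof)
  }

  run <- withr::with_seed(seed, {
    current <- seed_conf
    curr_score <- score(current)
    best <- current
    best_score <- curr_score
    trajectory <- list(current)
    log <- vector("list", length(schedule$kT))
    for (it in seq_along(schedule$kT)) {
      cand <- propose(engine, current)
      if (!identical(rownames(ca_coords(cand)), ref_key)) {
        abort(paste0("proposal engine '", engine$name,
                     "' violated the topology at iteration ", it))
      }
      cand_score <- score(cand)
      if (cand_score < best_score) {
        best <- cand
        best_score <- cand_score
      }
      p_acc <- accept_probability(curr_score, cand_score, schedule$kT[it])
      accepted <- p_acc > runif(1)
      if (accepted) {
        current <- cand
        curr_score <- cand_score
        trajectory[[length(trajectory) + 1]] <- current
      }
      log[[it]] <- tibble::tibble(
        iteration = it, kT = schedule$kT[it], chi2n = cand_score,
        accepted = accepted,
        stalled = isTRUE(attr(cand, "stalled")))
    }
    list(current = current, best = best, best_score = best_score,
         trajectory = trajectory, log = dplyr::bind_rows(log))
  })

  out <- list(
    log = run$log, trajectory = run$trajectory,
    best_conformer = run$best, best_chi2n = run$best_score,
    final_conformer = run$current, reached_target = run$best_score < 1,
    n_dof = dof, seed = seed, engine = engine$name
  )
  if (!is.null(validation)) {
    check_measurements(validation)
    v_dof <- n_dof(nrow(validation), nrow(meas))
    check_dof(v_dof)
    v_pairs <- validation_pairs[pair_ids(validation_pairs) %in%
                                  validation$pair_id]
    v_sites <- unique_sites(v_pairs)
    avs <- lapply(v_sites, function(s) compute_av(run$best, s, grid_spacing,
                                                  contact))
    d <- vapply(v_pairs, function(p) {
      model_distance(avs[[site_id(p$donor)]], avs[[site_id(p$acceptor)]],
                     kind = "mean_RDA", n_samples = n_samples, seed = seed)
    }, numeric(1))
    names(d) <- pair_ids(v_pairs)
    out$validation_chi2n <- chi2_n(chi2(d, validation), v_dof)
    out$validation_n_dof <- v_dof
  }
  class(out) <- "guided_run"
  out
}

#' @export
print.guided_run <- function(x, ...) {
  cat("<guided_run> ", nrow(x$log), " iterations (", x$engine, "), ",
      sum(x$log$accepted), " accepted\n", sep = "")
  cat(sprintf("  best chi2_n = %.3f (%s)\n", x$best_chi2n,
              if (x$reached_target) "chi2_n < 1 reached"
              else "chi2_n < 1 not reached; consider alternative seeds"))
  if (!is.null(x$validation_chi2n)) {
    cat(sprintf("  cross-validated chi2_n = %.3f (N_dof = %d)\n",
                x$validation_chi2n, x$validation_n_dof))
  }
  invisible(x)
}

#' Write a guided-run log as CSV
#'
#' @param x A `guided_run`.
#' @param path CSV output path.
#' @export
write_guided_csv <- function(x, path) {
  write.csv(as.data.frame(x$log), path, row.names = FALSE)
  invisible(path)
}
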