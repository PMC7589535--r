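#' Synthetic two-domain hinge-protein generator
#'
#' A deterministic toy protein for end-to-end testing and benchmarking: an
#' ideal C-alpha helix (3.8 Angstrom virtual bonds) split into two
#' internally rigid segments joined at a hinge residue; the second segment
#' is bent about an axis through the hinge C-alpha by the hinge angle theta.
#' A pseudo-C-beta stub (1.5 Angstrom, radially outward) on every residue
#' provides dye attachment points.  This emulates the hinge-bending class of
#' interdomain motions; it has no realistic side chains or secondary
#' structure beyond the helical trace.
#'
#' @param n_res Residues per segment, length-2 integer vector.
#'   Default `c(14, 14)` (a hinge range free of inter-segment clashes).
#' @return A `hinge_spec` (segment definitions and geometry constants).
#' @export
hinge_spec <- function(n_res = c(14, 14)) {
  stopifnot(length(n_res) == 2, all(n_res >= 3))
  n1 <- as.integer(n_res[1])
  n2 <- as.integer(n_res[2])
  x <- list(n_res = c(n1, n2), n_total = n1 + n2,
            seg1 = seq_len(n1), seg2 = n1 + seq_len(n2), hinge = n1,
            # helix giving exact 3.8 A virtual C-alpha bonds
            helix_radius = sqrt((3.8^2 - 1.5^2) / (2 * (1 - cos(100 * pi / 180)))),
            rise = 1.5, turn_deg = 100, cb_length = 1.5)
  class(x) <- "hinge_spec"
  x
}

#' @export
print.hinge_spec <- function(x, ...) {
  cat("<hinge_spec> segments of ", x$n_res[1], " + ", x$n_res[2],
      " residues, hinge at residue ", x$hinge, "\n", sep = "")
  invisible(x)
}

#' @rdname hinge_spec
#' @param spec A `hinge_spec`.
#' @param theta Hinge angle in degrees (0 = straight helix).
#' @param label Conformer label; defaults to `theta_<angle>`.
#' @return `make_hinge_conformer()` returns a [conformer()]; reconstruction
#'   from `(spec, theta)` is exact and deterministic, and the segments are
#'   internally rigid across theta.
#' @export
make_hinge_conformer <- function(spec, theta, label = NULL) {
  n <- spec$n_total
  i <- seq_len(n) - 1
  phi <- i * spec$turn_deg * pi / 180
  ca <- cbind(spec$helix_radius * cos(phi), spec$helix_radius * sin(phi),
              i * spec$rise)
  radial <- cbind(cos(phi), sin(phi), 0)
  cb <- ca + spec$cb_length * radial

  # bend segment 2 about the x axis through the hinge C-alpha
  pivot <- ca[spec$hinge, ]
  rot <- rotation_about_axis(c(1, 0, 0), theta * pi / 180)
  bend <- function(m, rows) {
    m[rows, ] <- sweep(sweep(m[rows, , drop = FALSE], 2, pivot) %*% t(rot),
                       2, pivot, `+`)
    m
  }
  ca <- bend(ca, spec$seg2)
  cb <- bend(cb, spec$seg2)

  ord <- rep(seq_len(n), each = 2)
  ety <- rep(c("CA", "CB"), n)
  xyz <- matrix(NA_real_, 2 * n, 3)
  xyz[ety == "CA", ] <- ca
  xyz[ety == "CB", ] <- cb
  atoms <- tibble::tibble(
    chain = "A", resid = ord, insert = "", resname = "ALA", elety = ety,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE)
  conformer(atoms, label = label %||% paste0("theta_", theta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a hinge-protein ensemble
#'
#' One conformer per hinge angle.  Angles whose two segments clash
#' (inter-segment C-alpha contact below 3 Angstrom) are flagged with a
#' warning but kept, mirroring how unphysical conformers can enter real
#' candidate ensembles.
#'
#' @inheritParams make_hinge_conformer
#' @param thetas Numeric vector of hinge angles in degrees.
#' @return An [ensemble()].
#' @export
make_hinge_ensemble <- function(spec, thetas) {
  confs <- lapply(thetas, function(t) make_hinge_conformer(spec, t))
  for (k in seq_along(confs)) {
    a <- ca_coords(confs[[k]])[spec$seg1, , drop = FALSE]
    b <- ca_coords(confs[[k]])[spec$seg2, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    # ignore the bonded hinge contact
    d2[nrow(a), 1] <- Inf
    if (min(d2) < 9) {
      warn(paste0("hinge angle ", thetas[k],
                  " deg produces an inter-segment clash"))
    }
  }
  ensemble(confs)
}

#' Recover the hinge-bend angle of a conformer
#'
#' Superposes the first segment onto the straight (`theta = 0`) reference
#' and measures the angle between the second segment's inertial axis and
#' its reference direction.  This is the inter-domain bend angle: for
#' conformers generated by [make_hinge_conformer()] it recovers `|theta|`;
#' torsional rotation of the second segment about its own axis (a mode that
#' leaves inter-dye distances nearly unchanged and is therefore invisible
#' to FRET) does not contribute.
#'
#' @inheritParams make_hinge_conformer
#' @param conf A [conformer()] with the spec's topology.
#' @return Unsigned hinge-bend angle in degrees.
#' @export
hinge_angle <- function(conf, spec) {
  ref <- make_hinge_conformer(spec, 0)
  a <- ca_coords(conf)
  b <- ca_coords(ref)
  fit <- kabsch(a[spec$seg1, ], b[spec$seg1, ])
  a_all <- sweep(a %*% t(fit$rotation), 2, fit$translation, `+`)
  seg_axis <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    v <- svd(m)$v[, 1]
    # orient from hinge toward the far end
    if (sum(v * (m[nrow(m), ] - m[1, ])) < 0) v <- -v
    v
  }
  va <- seg_axis(a_all[spec$seg2, ])
  vb <- seg_axis(b[spec$seg2, ])
  acos(pmin(1, pmax(-1, sum(va * vb)))) * 180 / pi
}

#' Default FRET-pair candidates on the hinge toy
#'
#' Donor sites spread over segment 1 and acceptor sites over segment 2
#' (pseudo-C-beta attachment), crossed into candidate pairs ordered by id.
#' The dye linker defaults (10 Angstrom length, 3 Angstrom width, single
#' 3.5 Angstrom radius) are scaled to the toy: a full-length maleimide
#' linker on a two-segment miniature would smear the positional cloud over
#' the whole molecule and wash out the distance signal.
#'
#' @inheritParams make_hinge_conformer
#' @param n_sites_per_segment Number of labeling sites per segment.
#'   Default 3.
#' @param r0 Foerster radius in Angstrom. Default 30, matching the toy's
#'   inter-site distance range (sensitivity is best near the Foerster
#'   radius).
#' @param linker_length,linker_width,dye_radii Toy-scaled dye geometry,
#'   forwarded to [labeling_site()].
#' @param ... Further site parameters forwarded to [labeling_site()].
#' @return List of [fret_pair()] objects.
#' @export
hinge_candidate_pairs <- function(spec, n_sites_per_segment = 3, r0 = 30,
                                  linker_length = 10, linker_width = 3,
                                  dye_radii = 3.5, ...) {
  pick <- function(seg) {
    seg[unique(round(seq(2, length(seg) - 1,
                         length.out = n_sites_per_segment)))]
  }
  d_res <- pick(spec$seg1)
  a_res <- pick(spec$seg2)
  pairs <- list()
  for (d in d_res) {
    for (a in a_res) {
      id <- sprintf("p%02d_%02d", d, a)
      pairs[[length(pairs) + 1]] <- fret_pair(
        id,
        donor = labeling_site("A", d, "CB", role = "donor",
                              linker_length = linker_length,
                              linker_width = linker_width,
                              dye_radii = dye_radii, ...),
        acceptor = labeling_site("A", a, "CB", role = "acceptor",
                                 linker_length = linker_length,
                                 linker_width = linker_width,
                                 dye_radii = dye_radii, ...),
        r0 = r0)
    }
  }
  pairs
}

#' Generate a complete synthetic benchmark case
#'
#' The study design in miniature: a candidate ensemble of seed
#' conformations (hinge angles excluding the target), a candidate FRET-pair
#' pool, and reference measurements simulated on the target conformer with
#' efficiency-error-propagated uncertainties -- everything needed to
#' exercise pair selection, screening and guided sampling without external
#' data.
#'
#' @inheritParams make_hinge_conformer
#' @param target_theta Hinge angle of the "true" target state (degrees).
#' @param seed_thetas Hinge angles of the candidate ensemble (must not
#'   contain `target_theta`).
#' @param pair_pool_size Number of candidate pairs to keep.
#' @param dE Absolute FRET-efficiency error. Default 0.06.
#' @param noise Add Gaussian noise of scale `dR_ref`? Default `FALSE`.
#' @param seed Integer seed.
#' @param grid_spacing AV grid spacing. Default 0.9.
#' @param n_samples Monte-Carlo pairs for distance averaging.
#' @return A list: `ensemble`, `target` (conformer), `pairs`,
#'   `measurements`, `truth` (target angle and seed).
#' @export
make_benchmark_case <- function(spec = hinge_spec(), target_theta = 30,
                                seed_thetas = c(-20, -10, 0, 10, 20, 40, 50,
                                                60),
                                pair_pool_size = 9, dE = 0.06, noise = FALSE,
                                seed = 1, grid_spacing = 0.9,
                                n_samples = 1e5) {
  if (target_theta %in% seed_thetas) {
    abort("the target angle must not be part of the seed ensemble")
  }
  ens <- make_hinge_ensemble(spec, seed_thetas)
  target <- make_hinge_conformer(spec, target_theta, label = "target")
  pairs <- hinge_candidate_pairs(spec)
  pairs <- pairs[seq_len(min(pair_pool_size, length(pairs)))]
  meas <- simulate_measurements(target, pairs, grid_spacing = grid_spacing,
                                dE = dE, noise = noise, seed = seed,
                                n_samples = n_samples)
  list(ensemble = ens, target = target, pairs = pairs, measurements = meas,
       truth = list(target_theta = target_theta, seed = seed, noise = noise))
}
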