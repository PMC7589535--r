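#' Simulate the accessible volume (AV) of a tethered dye
#'
#' Coarse-grained dye model: the dye is a sphere on a flexible linker
#' attached at one atom.  All positions are enumerated on a cubic grid
#' covering a sphere of radius `linker_length + max(dye_radii)` around the
#' attachment atom.  A grid point is an allowed dye position if (a) a sphere
#' of the dye radius centred there does not overlap any protein heavy atom's
#' van-der-Waals sphere and (b) its shortest obstacle-avoiding path from the
#' attachment point, computed by Dijkstra flood-fill over the 26-connected
#' grid graph (the linker, of half-width `linker_width / 2`, must fit along
#' the path), is no longer than the linker.  With three dye radii the AV is
#' the union of the three single-radius AVs, each carrying total weight 1/3.
#'
#' With `contact` parameters (accessible contact volume, ACV), points whose
#' dye sphere lies within `thickness` Angstrom of the protein surface are
#' re-weighted so that their total weight equals `fraction`, emulating dyes
#' that stick to the surface (fraction calibrated from residual anisotropy).
#'
#' @param conf A [conformer()].
#' @param site A [labeling_site()]; the attachment atom must exist in `conf`.
#' @param grid_spacing Grid spacing in Angstrom. Default 0.9.
#' @param contact Optional list `list(thickness = 3, fraction = ...)` for the
#'   ACV contact layer.
#' @return An `accessible_volume` object: grid points with weights (summing
#'   to 1 when non-empty), the weighted mean dye position, the attachment
#'   position and an `empty` flag for fully buried sites.
#' @export
compute_av <- function(conf, site, grid_spacing = 0.9, contact = NULL) {
  attach <- atom_coord(conf, site$chain, site$resid, site$atom)
  if (is.null(attach)) {
    abort(paste0("attachment atom ", site_id(site), " not found in conformer '",
                 conf$label, "'"))
  }
  a <- conf$atoms
  heavy <- !grepl("^[0-9]*H", a$elety)
  # the linker emerges from the attachment atom; it is not an obstacle
  is_attach <- a$chain == site$chain & a$resid == site$resid &
    a$elety == site$atom & !a$het
  obst <- a[heavy & !is_attach, , drop = FALSE]
  xyz <- as.matrix(obst[, c("x", "y", "z")])
  vdw <- vdw_radius(obst$elety)

  res <- av_grid_cpp(xyz, vdw, attach,
                     linker_length = site$linker_length,
                     linker_width = site$linker_width,
                     max_dye_radius = max(site$dye_radii),
                     spacing = grid_spacing)
  pts <- res$points
  clearance <- res$clearance

  k <- length(site$dye_radii)
  w_free <- rep(0, nrow(pts))
  w_contact <- rep(0, nrow(pts))
  for (r in site$dye_radii) {
    ok <- clearance >= r
    if (!any(ok)) next
    share <- (1 / k) / sum(ok)
    if (is.null(contact)) {
      w_free[ok] <- w_free[ok] + share
    } else {
      in_layer <- ok & (clearance - r) <= contact$thickness
      w_contact[in_layer] <- w_contact[in_layer] + share
      w_free[ok & !in_layer] <- w_free[ok & !in_layer] + share
    }
  }
  total <- sum(w_free) + sum(w_contact)
  if (total <= 0) {
    av <- list(points = matrix(numeric(0), 0, 3), weights = numeric(0),
               mean_position = rep(NA_real_, 3), attachment = attach,
               spacing = grid_spacing, empty = TRUE, site_id = site_id(site))
    class(av) <- "accessible_volume"
    return(av)
  }
  if (is.null(contact)) {
    w <- w_free / total
  } else {
    cw <- sum(w_contact)
    fw <- sum(w_free)
    f <- contact$fraction
    w <- numeric(nrow(pts))
    if (cw > 0 && fw > 0) {
      w <- w_contact * (f / cw) + w_free * ((1 - f) / fw)
    } else if (cw > 0) {
      w <- w_contact / cw
    } else {
      w <- w_free / fw
    }
  }
  keep <- w > 0
  pts <- pts[keep, , drop = FALSE]
  w <- w[keep]
  w <- w / sum(w)
  av <- list(points = pts, weights = w,
             mean_position = as.numeric(colSums(pts * w)),
             attachment = attach, spacing = grid_spacing, empty = FALSE,
             site_id = site_id(site))
  class(av) <- "accessible_volume"
  av
}

#' @export
print.accessible_volume <- function(x, ...) {
  if (x$empty) {
    cat("<accessible_volume> ", x$site_id, ": EMPTY (buried site)\n", sep = "")
  } else {
    cat("<accessible_volume> ", x$site_id, ": ", nrow(x$points),
        " grid points, mean position (",
        paste(sprintf("%.1f", x$mean_position), collapse = ", "), ") A\n",
        sep = "")
  }
  invisible(x)
}

# Standard van-der-Waals radii keyed on the leading element letter of the
# atom name; the default carbon radius covers coarse-grained pseudoatoms.
vdw_radius <- function(elety) {
  first <- substr(gsub("^[0-9]+", "", elety), 1, 1)
  r <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)[first]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Inter-dye distance observables from two accessible volumes
#'
#' `"Rmp"` is the distance between the two mean dye positions.
#' `"mean_RDA"` is the AV-weighted average over all point-pair distances --
#' the distance-like observable an intensity-based FRET measurement reports.
#' It is evaluated exhaustively when the point-count product is at most
#' `exhaustive_limit`, otherwise by `n_samples` weighted random pairs
#' (deterministic for a fixed `seed`).
#'
#' @param av_d,av_a Non-empty `accessible_volume` objects.
#' @param kind `"mean_RDA"` (default) or `"Rmp"`.
#' @param n_samples Number of Monte-Carlo point pairs. Default 100000.
#' @param seed Integer seed for the Monte-Carlo estimate; required when
#'   sampling is used and `NULL` would make the result irreproducible.
#' @param exhaustive_limit Point-count product below which all pairs are
#'   enumerated. Default 1e6.
#' @return Distance in Angstrom.
#' @export
model_distance <- function(av_d, av_a, kind = c("mean_RDA", "Rmp"),
                           n_samples = 1e5, seed = NULL,
                           exhaustive_limit = 1e6) {
  kind <- match.arg(kind)
  if (av_d$empty || av_a$empty) {
    abort("cannot compute a distance involving an empty accessible volume")
  }
  if (kind == "Rmp") {
    return(sqrt(sum((av_d$mean_position - av_a$mean_position)^2)))
  }
  nd <- nrow(av_d$points)
  na <- nrow(av_a$points)
  if (as.double(nd) * as.double(na) <= exhaustive_limit) {
    return(pair_mean_distance_cpp(av_d$points, av_d$weights,
                                  av_a$points, av_a$weights))
  }
  draw <- function() {
    i <- sample.int(nd, n_samples, replace = TRUE, prob = av_d$weights)
    j <- sample.int(na, n_samples, replace = TRUE, prob = av_a$weights)
    mean(sqrt(rowSums((av_d$points[i, , drop = FALSE] -
                         av_a$points[j, , drop = FALSE])^2)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Propagate a FRET-efficiency error to a distance error
#'
#' The transfer efficiency is `E(R) = 1 / (1 + (R / R0)^6)`.  A (typical)
#' absolute efficiency error `dE` maps onto the distance error
#' `dR = dE * |dR/dE| = dE * (1 + (R/R0)^6)^2 * R0^6 / (6 R^5)`, which blows
#' up away from the Foerster radius where the measurement loses sensitivity;
#' the result is therefore clamped.
#'
#' @param R Inter-dye distance(s) in Angstrom (> 0).
#' @param R0 Foerster radius in Angstrom (> 0).
#' @param dE Absolute FRET-efficiency error. Default 0.06.
#' @param clamp Two-element `c(min, max)` clamp in Angstrom.
#'   Default `c(0.5, 30)`.
#' @return Distance uncertainty in Angstrom (vectorised over `R`).
#' @export
distance_error_from_efficiency <- function(R, R0, dE = 0.06,
                                           clamp = c(0.5, 30)) {
  if (any(R <= 0) || R0 <= 0) abort("distances and R0 must be positive")
  u <- (R / R0)^6
  dr <- dE * (1 + u)^2 * R0^6 / (6 * R^5)
  pmin(pmax(dr, clamp[1]), clamp[2])
}

#' Simulate a FRET measurement set on a target conformer
#'
#' Generates reference distances by AV simulation on the target structure:
#' `R_ref` is the AV-averaged inter-dye distance, `dR_ref` comes from
#' propagating the FRET-efficiency error `dE`.  With `noise = TRUE`,
#' Gaussian noise of scale `dR_ref` is added to each distance (seeded).
#' Pairs with a buried (empty-AV) site are skipped and reported in the
#' `skipped` attribute.
#'
#' @param target A [conformer()] (the "true" structure).
#' @param pairs List of [fret_pair()] objects.
#' @param grid_spacing,contact AV parameters, see [compute_av()].
#' @param dE,clamp Error-propagation parameters, see
#'   [distance_error_from_efficiency()].
#' @param noise Add Gaussian measurement noise? Default `FALSE`.
#' @param seed Integer seed (used for distance sampling and noise).
#' @param n_samples Monte-Carlo pairs for [model_distance()].
#' @return A measurement tibble with columns `pair_id`, `donor_site`,
#'   `acceptor_site`, `r0`, `r_ref`, `dr_ref`, `provenance`, carrying a
#'   `skipped` attribute listing unlabelable sites.
#' @export
simulate_measurements <- function(target, pairs, grid_spacing = 0.9,
                                  contact = NULL, dE = 0.06,
                                  clamp = c(0.5, 30), noise = FALSE,
                                  seed = 1, n_samples = 1e5) {
  sites <- unique_sites(pairs)
  avs <- lapply(sites, function(s) compute_av(target, s, grid_spacing,
                                              contact))
  skipped <- names(avs)[vapply(avs, function(v) v$empty, logical(1))]

  rows <- list()
  for (p in pairs) {
    d_id <- site_id(p$donor)
    a_id <- site_id(p$acceptor)
    if (d_id %in% skipped || a_id %in% skipped) next
    r <- model_distance(avs[[d_id]], avs[[a_id]], kind = "mean_RDA",
                        n_samples = n_samples, seed = seed)
    rows[[length(rows) + 1]] <- tibble::tibble(
      pair_id = p$pair_id, donor_site = d_id, acceptor_site = a_id,
      r0 = p$r0, r_ref = r,
      dr_ref = distance_error_from_efficiency(r, p$r0, dE, clamp),
      provenance = "simulated"
    )
  }
  if (length(rows) == 0) abort("all pairs were skipped (buried sites)")
  meas <- dplyr::bind_rows(rows)
  if (noise) meas <- add_measurement_noise(meas, seed = seed)
  attr(meas, "skipped") <- skipped
  meas
}

#' Add Gaussian noise to a measurement set
#'
#' Draws each noisy distance from `N(r_ref, dr_ref^2)`; useful for replicate
#' simulations of the same AV-derived reference set.
#'
#' @param meas Measurement tibble (see [simulate_measurements()]).
#' @param seed Integer seed.
#' @return The measurement tibble with perturbed `r_ref`.
#' @export
add_measurement_noise <- function(meas, seed) {
  withr::with_seed(seed, {
    meas$r_ref <- meas$r_ref + rnorm(nrow(meas), 0, meas$dr_ref)
  })
  meas$provenance <- paste0(meas$provenance, "+noise")
  meas
}

#' Read and write measurement sets as CSV
#'
#' Columns: `pair_id`, `donor_site`, `acceptor_site`, `r0`, `r_ref`,
#' `dr_ref`, `provenance`.
#'
#' @param meas Measurement tibble.
#' @param path CSV file path.
#' @export
write_measurements <- function(meas, path) {
  write.csv(as.data.frame(meas), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  meas <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  check_measurements(meas)
  meas
}

check_measurements <- function(meas) {
  if (nrow(meas) < 1) abort("measurement set is empty")
  if (anyDuplicated(meas$pair_id)) abort("measurement pair ids must be unique")
  if (any(meas$r_ref <= 0) || any(meas$dr_ref <= 0)) {
    abort("measured distances and uncertainties must be positive")
  }
  invisible(meas)
}

#' Export an accessible volume for visual inspection
#'
#' `write_av_xyz()` writes the weighted point cloud in XYZ format (element
#' `D`); `write_av_dx()` writes the weights on the full cubic grid as an
#' OpenDX scalar field.
#'
#' @param av A non-empty `accessible_volume`.
#' @param path Output file path.
#' @export
write_av_xyz <- function(av, path) {
  if (av$empty) abort("cannot export an empty accessible volume")
  n <- nrow(av$points)
  lines <- c(as.character(n), paste0("accessible volume ", av$site_id),
             sprintf("D %.3f %.3f %.3f", av$points[, 1], av$points[, 2],
                     av$points[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_av_xyz
#' @export
write_av_dx <- function(av, path) {
  if (av$empty) abort("cannot export an empty accessible volume")
  sp <- av$spacing
  lo <- apply(av$points, 2, min)
  hi <- apply(av$points, 2, max)
  dims <- round((hi - lo) / sp) + 1
  grid <- array(0, dim = dims)
  idx <- round(sweep(av$points, 2, lo) / sp) + 1
  grid[cbind(idx[, 1], idx[, 2], idx[, 3])] <- av$weights
  # OpenDX stores with z fastest
  values <- as.numeric(aperm(grid, c(3, 2, 1)))
  pad <- c(values, rep(0, (3 - length(values) %% 3) %% 3))
  triples <- matrix(pad, ncol = 3, byrow = TRUE)
  lines <- c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("origin %.4f %.4f %.4f", lo[1], lo[2], lo[3]),
    sprintf("delta %.4f 0 0", sp),
    sprintf("delta 0 %.4f 0", sp),
    sprintf("delta 0 0 %.4f", sp),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(values)),
    sprintf("%.6g %.6g %.6g", triples[, 1], triples[, 2], triples[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
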