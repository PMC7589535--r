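# Restrained-mean-position (RMP) restraint generation for FRET-guided MD.
# Forces are applied between pseudoatoms at the mean dye positions, which are
# anchored to the local backbone so strain propagates to the protein instead
# of being absorbed by the soft dye linker.

KCAL_PER_MOL_A2_IN_PN_PER_A <- 69.48  # 1 kcal/mol/A^2 gradient = 69.48 pN/A

#' Build mean-position pseudoatoms with backbone anchors
#'
#' One pseudoatom per labeling site, placed at the mean position of the
#' site's accessible volume and anchored by pseudobonds to the C-alpha and
#' C-beta atoms of the attachment residue and of residues up to two
#' positions toward either terminus -- ten anchors for a mid-chain site,
#' fewer at chain ends (warned) or where a residue lacks a C-beta (logged).
#' Anchor equilibrium distances come from the current geometry; anchor force
#' constants are set to ten times the site's FRET-restraint constants once
#' those are tuned.
#'
#' @param conf The [conformer()] to generate restraints for.
#' @param sites List of [labeling_site()] objects.
#' @param grid_spacing,contact AV parameters, see [compute_av()].
#' @return A list with `pseudoatoms` (tibble: `site_id`, `chain`, `resid`,
#'   `x`, `y`, `z`) and `anchors` (tibble: `site_id`, `resid`, `elety`,
#'   `eq_distance`, `k`).
#' @export
build_pseudoatoms <- function(conf, sites, grid_spacing = 0.9,
                              contact = NULL) {
  ps <- list()
  an <- list()
  for (s in sites) {
    av <- compute_av(conf, s, grid_spacing, contact)
    if (av$empty) {
      abort(paste0("site ", site_id(s), " is buried (empty accessible ",
                   "volume); it cannot carry a pseudoatom"))
    }
    ps[[length(ps) + 1]] <- tibble::tibble(
      site_id = site_id(s), chain = s$chain, resid = s$resid,
      x = av$mean_position[1], y = av$mean_position[2],
      z = av$mean_position[3])
    window <- (s$resid - 2):(s$resid + 2)
    n_found <- 0
    for (r in window) {
      for (ety in c("CA", "CB")) {
        pos <- atom_coord(conf, s$chain, r, ety)
        if (is.null(pos)) {
          if (ety == "CB" && !is.null(atom_coord(conf, s$chain, r, "CA"))) {
            inform(paste0("anchor C-beta skipped for residue ", r,
                          " (site ", site_id(s), "): no C-beta atom"))
          }
          next
        }
        n_found <- n_found + 1
        an[[length(an) + 1]] <- tibble::tibble(
          site_id = site_id(s), chain = s$chain, resid = r, elety = ety,
          eq_distance = sqrt(sum((pos - av$mean_position)^2)),
          k = NA_real_)
      }
    }
    if (n_found < 10) {
      warn(paste0("site ", site_id(s), ": only ", n_found,
                  " anchor atoms available (chain end or missing atoms)"))
    }
  }
  list(pseudoatoms = dplyr::bind_rows(ps), anchors = dplyr::bind_rows(an))
}

#' Harmonic-linear restraint force
#'
#' Zero force at the target distance, harmonic restoring force within one
#' standard error of it, constant (capped) force beyond -- continuous at the
#' crossover.  With the untuned constant `k = f_max / dr` the plateau force
#' is exactly `f_max`.
#'
#' @param R Current pseudoatom-pseudoatom distance(s) in Angstrom.
#' @param r_exp Target distance in Angstrom.
#' @param dr Standard error of the measured distance in Angstrom.
#' @param k Force constant in pN/Angstrom.
#' @return Signed force in pN (positive pushes R up toward `r_exp`);
#'   magnitude never exceeds `k * dr`.
#' @export
restraint_force <- function(R, r_exp, dr, k) {
  dev <- R - r_exp
  ifelse(abs(dev) <= dr, -k * dev, -sign(dev) * k * dr)
}

#' Correct an averaged distance observable to a mean-position target
#'
#' Measurements report distribution-averaged inter-dye distances, but RMP
#' restraints act between mean dye positions; the model-computed offset
#' `mean_RDA - Rmp`, evaluated on the restraint-generation conformer,
#' bridges the two: `R_exp = R_ref - (mean_RDA - Rmp)`.
#'
#' @param r_ref Measured (averaged) distance in Angstrom.
#' @param av_d,av_a Non-empty accessible volumes of the pair on the
#'   restraint-generation conformer.
#' @param n_samples,seed Passed to [model_distance()].
#' @return Mean-position target distance `R_exp` in Angstrom.
#' @export
measurement_to_target <- function(r_ref, av_d, av_a, n_samples = 1e5,
                                  seed = 1) {
  mean_rda <- model_distance(av_d, av_a, kind = "mean_RDA",
                             n_samples = n_samples, seed = seed)
  rmp <- model_distance(av_d, av_a, kind = "Rmp")
  r_ref - (mean_rda - rmp)
}

#' Generate a FRET restraint set for a conformer snapshot
#'
#' Builds pseudoatoms, converts each measured distance to a mean-position
#' target, initialises every force constant at `f_max / dr` and tunes the
#' constants for collinearity (see [tune_force_constants()]).  Intended to
#' be re-run on simulation snapshots at the user's refresh cadence
#' (recalculating pseudoatom positions, anchors and restraints as the local
#' structure changes, e.g. every 2 ns of MD).
#'
#' @param conf The [conformer()] snapshot.
#' @param pairs List of [fret_pair()] objects covering the measurements.
#' @param meas Measurement tibble (`pair_id`, `r_ref`, `dr_ref`).
#' @param f_max Force cap in pN. Default 50.
#' @param grid_spacing,contact AV parameters.
#' @param n_samples,seed Observable parameters, see [model_distance()].
#' @return A `restraint_set`: pseudoatoms, anchors (with force constants ten
#'   times the site's largest tuned restraint constant) and the tuned
#'   harmonic-linear restraints.
#' @export
make_restraints <- function(conf, pairs, meas, f_max = 50, grid_spacing = 0.9,
                            contact = NULL, n_samples = 1e5, seed = 1) {
  check_measurements(meas)
  pairs <- pairs[pair_ids(pairs) %in% meas$pair_id]
  if (length(pairs) == 0) abort("no pair definitions match the measurements")
  sites <- unique_sites(pairs)
  pa <- build_pseudoatoms(conf, sites, grid_spacing, contact)
  avs <- lapply(sites, function(s) compute_av(conf, s, grid_spacing, contact))

  rows <- list()
  for (p in pairs) {
    m <- meas[meas$pair_id == p$pair_id, ]
    r_exp <- measurement_to_target(m$r_ref, avs[[site_id(p$donor)]],
                                   avs[[site_id(p$acceptor)]],
                                   n_samples = n_samples, seed = seed)
    rows[[length(rows) + 1]] <- tibble::tibble(
      pair_id = p$pair_id, donor_site = site_id(p$donor),
      acceptor_site = site_id(p$acceptor), r_exp = r_exp,
      dr = m$dr_ref, k = f_max / m$dr_ref, f_max = f_max)
  }
  rests <- dplyr::bind_rows(rows)
  rests <- tune_force_constants(rests, pa$pseudoatoms, f_max = f_max)

  # anchor constants: ten times the site's strongest tuned FRET constant
  k_by_site <- c(
    tapply(rests$k, rests$donor_site, max),
    tapply(rests$k, rests$acceptor_site, max))
  k_by_site <- tapply(k_by_site, names(k_by_site), max)
  pa$anchors$k <- 10 * as.numeric(k_by_site[pa$anchors$site_id])

  out <- list(pseudoatoms = pa$pseudoatoms, anchors = pa$anchors,
              restraints = rests,
              metadata = list(conformer = conf$label, f_max = f_max,
                              refresh_note = paste0(
                                "regenerate from a fresh snapshot at the MD ",
                                "wrapper's cadence (e.g. every 2 ns); ",
                                "pseudoatoms must be massless-excluded from ",
                                "protein/solvent nonbonded interactions")))
  class(out) <- "restraint_set"
  out
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("<restraint_set> ", nrow(x$pseudoatoms), " pseudoatom(s), ",
      nrow(x$anchors), " anchor(s), ", nrow(x$restraints),
      " FRET restraint(s), F_max = ", x$metadata$f_max, " pN\n", sep = "")
  invisible(x)
}

#' Tune restraint force constants for collinearity
#'
#' Scales force constants down so that, with every restraint simultaneously
#' at its cap force and directions taken from the current pseudoatom
#' geometry, the vector sum of restraint forces at each pseudoatom never
#' exceeds `f_max`.  Each restraint is scaled by the smaller of its two
#' endpoint factors; the reduction is iterated to a fixed point.  A lone
#' restraint keeps `k = f_max / dr`; collinear restraint sets are reduced
#' the most.
#'
#' @param rests Restraint tibble (`donor_site`, `acceptor_site`, `dr`, `k`).
#' @param pseudoatoms Pseudoatom tibble with positions (`site_id`, `x`,
#'   `y`, `z`).
#' @param f_max Force cap in pN. Default 50.
#' @return The restraint tibble with tuned `k`.
#' @export
tune_force_constants <- function(rests, pseudoatoms, f_max = 50) {
  pos <- as.matrix(pseudoatoms[, c("x", "y", "z")])
  rownames(pos) <- pseudoatoms$site_id
  site_ids <- pseudoatoms$site_id
  for (iter in seq_len(100)) {
    factors <- setNames(rep(1, length(site_ids)), site_ids)
    for (sid in site_ids) {
      touching <- which(rests$donor_site == sid | rests$acceptor_site == sid)
      if (length(touching) == 0) next
      vec <- c(0, 0, 0)
      for (i in touching) {
        other <- if (rests$donor_site[i] == sid) {
          rests$acceptor_site[i]
        } else {
          rests$donor_site[i]
        }
        u <- pos[other, ] - pos[sid, ]
        u <- u / sqrt(sum(u^2))
        vec <- vec + rests$k[i] * rests$dr[i] * u
      }
      mag <- sqrt(sum(vec^2))
      if (mag > f_max) factors[sid] <- f_max / mag
    }
    if (all(factors > 1 - 1e-12)) break
    scale <- pmin(factors[rests$donor_site], factors[rests$acceptor_site])
    rests$k <- rests$k * as.numeric(scale)
  }
  rests
}

#' Net cap-force magnitudes per pseudoatom
#'
#' Diagnostic for [tune_force_constants()]: the magnitude of the vector sum
#' of cap forces at each pseudoatom with directions from the current
#' geometry.
#'
#' @inheritParams tune_force_constants
#' @return Named numeric vector (pN) keyed by site id.
#' @export
net_cap_forces <- function(rests, pseudoatoms) {
  pos <- as.matrix(pseudoatoms[, c("x", "y", "z")])
  rownames(pos) <- pseudoatoms$site_id
  out <- setNames(numeric(nrow(pseudoatoms)), pseudoatoms$site_id)
  for (sid in pseudoatoms$site_id) {
    touching <- which(rests$donor_site == sid | rests$acceptor_site == sid)
    vec <- c(0, 0, 0)
    for (i in touching) {
      other <- if (rests$donor_site[i] == sid) rests$acceptor_site[i]
               else rests$donor_site[i]
      u <- pos[other, ] - pos[sid, ]
      u <- u / sqrt(sum(u^2))
      vec <- vec + rests$k[i] * rests$dr[i] * u
    }
    out[sid] <- sqrt(sum(vec^2))
  }
  out
}

#' Write and read an AMBER-dialect NMR restraint (DISANG) file
#'
#' Serialises a restraint set as `&rst` namelist blocks.  Atom serials
#' follow the conformer's atom order (1-based), with pseudoatoms appended
#' after the protein atoms in pseudoatom-table order.  Anchor pseudobonds
#' are plain harmonic wells (`r2 = r3 =` equilibrium distance, parabola out
#' to `r1 = max(0, eq - 5)` and `r4 = eq + 5`).  FRET restraints use
#' `r2 = R_exp - dR`, `r3 = R_exp + dR`, `r1 = max(0, r2 - 2 dR)`,
#' `r4 = r3 + 2 dR`, with `rk2 = rk3` chosen so the linear tail's force
#' matches the harmonic-linear cap `k * dR`.  Force constants are written in
#' kcal/mol/A^2 under AMBER's `E = rk (r - r0)^2` convention (gradient
#' `2 rk (r - r0)`; 1 kcal/mol/A^2 of gradient slope = 69.48 pN/A), so
#' `rk_anchor = k / (2 * 69.48)` and `rk_fret = k / (4 * 69.48)`.
#'
#' @param set A `restraint_set`.
#' @param conf The [conformer()] the serial numbering refers to.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_restraint_file <- function(set, conf, path) {
  a <- conf$atoms
  serial_of <- function(chain, resid, elety) {
    i <- which(a$chain == chain & a$resid == resid & a$elety == elety & !a$het)
    if (length(i) == 0) {
      abort(paste0("no atom serial for ", chain, ":", resid, ":", elety))
    }
    i[1]
  }
  pseudo_serial <- setNames(nrow(a) + seq_len(nrow(set$pseudoatoms)),
                            set$pseudoatoms$site_id)
  lines <- c(
    "# restrained-mean-position FRET restraints (AMBER DISANG dialect)",
    paste0("# conformer: ", set$metadata$conformer),
    paste0("# pseudoatom serials start at ", nrow(a) + 1,
           " in pseudoatom-table order"),
    paste0("# ", set$metadata$refresh_note))
  fmt <- function(iat1, iat2, r1, r2, r3, r4, rk) {
    sprintf(paste0(" &rst iat=%d,%d, r1=%.4f, r2=%.4f, r3=%.4f, r4=%.4f,",
                   " rk2=%.6f, rk3=%.6f, /"),
            iat1, iat2, r1, r2, r3, r4, rk, rk)
  }
  for (i in seq_len(nrow(set$anchors))) {
    an <- set$anchors[i, ]
    rk <- an$k / (2 * KCAL_PER_MOL_A2_IN_PN_PER_A)
    lines <- c(lines, fmt(pseudo_serial[an$site_id],
                          serial_of(an$chain, an$resid, an$elety),
                          max(0, an$eq_distance - 5), an$eq_distance,
                          an$eq_distance, an$eq_distance + 5, rk))
  }
  for (i in seq_len(nrow(set$restraints))) {
    r <- set$restraints[i, ]
    r2 <- r$r_exp - r$dr
    r3 <- r$r_exp + r$dr
    rk <- r$k / (4 * KCAL_PER_MOL_A2_IN_PN_PER_A)
    lines <- c(lines, fmt(pseudo_serial[r$donor_site],
                          pseudo_serial[r$acceptor_site],
                          max(0, r2 - 2 * r$dr), r2, r3, r3 + 2 * r$dr, rk))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_restraint_file
#' @return `read_restraint_file()` returns a tibble of the parsed `&rst`
#'   blocks (`iat1`, `iat2`, `r1`..`r4`, `rk2`, `rk3`).
#' @export
read_restraint_file <- function(path) {
  lines <- grep("^\\s*&rst", readLines(path), value = TRUE)
  get <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([-0-9.,eE+]+)"), line))[[1]]
    if (length(m) < 2) abort(paste0("malformed &rst line: ", line))
    as.numeric(strsplit(m[2], ",")[[1]])
  }
  purrr::map_dfr(lines, function(l) {
    iat <- get(l, "iat")
    tibble::tibble(iat1 = iat[1], iat2 = iat[2],
                   r1 = get(l, "r1")[1], r2 = get(l, "r2")[1],
                   r3 = get(l, "r3")[1], r4 = get(l, "r4")[1],
                   rk2 = get(l, "rk2")[1], rk3 = get(l, "rk3")[1])
  })
}

#' Write the pseudoatom sidecar as JSON
#'
#' Topology-patching metadata for the user's MD setup: pseudoatom positions,
#' anchors with equilibrium distances and tuned constants, and the
#' requirements checklist (massive enough to integrate, excluded from
#' nonbonded interactions with protein and solvent).
#'
#' @param set A `restraint_set`.
#' @param path Output `.json` path.
#' @export
write_restraint_json <- function(set, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("the jsonlite package is required for JSON sidecar output")
  }
  jsonlite::write_json(
    list(pseudoatoms = set$pseudoatoms, anchors = set$anchors,
         restraints = set$restraints, metadata = set$metadata),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
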