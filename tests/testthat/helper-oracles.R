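# Independent oracle implementations and tiny fixtures shared across tests.
# The oracles are deliberately naive (brute-force loops, generic graph
# algorithms) and never call the package code paths they check.

toy_conformer <- function(xyz, label = "toy", elety = NULL, resname = "ALA") {
  n <- nrow(xyz)
  if (is.null(elety)) elety <- rep("CA", n)
  conformer(tibble::tibble(
    chain = "A", resid = seq_len(n), insert = "", resname = resname,
    elety = elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE),
    label = label)
}

random_ca_conformer <- function(n, label, sd = 3) {
  toy_conformer(matrix(rnorm(3 * n, sd = sd), ncol = 3), label = label)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

rigid_motion <- function(conf) {
  r <- random_rotation()
  if (det(r) < 0) r[, 1] <- -r[, 1]
  shift <- rnorm(3, sd = 10)
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% t(r)
  xyz <- sweep(xyz, 2, shift, `+`)
  set_coords(conf, seq_len(nrow(xyz)), xyz)
}

# brute-force lDDT: plain double loop over residue pairs and thresholds
oracle_lddt <- function(conf, ref, radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  a <- ca_coords(conf)
  b <- ca_coords(ref)
  n <- nrow(b)
  hits <- total <- 0
  for (t in thresholds) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dr <- sqrt(sum((b[i, ] - b[j, ])^2))
        if (dr >= radius) next
        dc <- sqrt(sum((a[i, ] - a[j, ])^2))
        total <- total + 1
        if (abs(dc - dr) < t) hits <- hits + 1
      }
    }
  }
  hits / total
}

# direct evaluation of the root-mean-square deviation without superposition
oracle_rmsd_raw <- function(a, b) {
  sqrt(sum((a - b)^2) / nrow(a))
}

# triple-loop expected-uncertainty oracle: references x conformers x pairs
oracle_expected_rmsd <- function(dist, dr, rmsd, cols, n_fit_param = 0) {
  n <- nrow(dist)
  dof <- length(cols) - n_fit_param
  refs <- numeric(n)
  for (ref in seq_len(n)) {
    num <- den <- 0
    for (conf in seq_len(n)) {
      x2 <- 0
      for (j in cols) {
        x2 <- x2 + ((dist[conf, j] - dist[ref, j]) / dr[ref, j])^2
      }
      p <- pchisq(x2, df = dof, lower.tail = FALSE)
      num <- num + p * rmsd[conf, ref]
      den <- den + p
    }
    refs[ref] <- num / den
  }
  mean(refs)
}

# accessible-volume oracle on a coarse grid: explicit condition checks with
# igraph shortest paths standing in for the flood fill
oracle_av_points <- function(atoms_xyz, vdw, attach, linker_length,
                             linker_width, dye_radius, spacing) {
  L <- linker_length + dye_radius
  half <- ceiling(L / spacing)
  ax <- seq(-half, half) * spacing
  grid <- as.matrix(expand.grid(x = ax + attach[1], y = ax + attach[2],
                                z = ax + attach[3]))
  clear <- apply(grid, 1, function(p) {
    if (nrow(atoms_xyz) == 0) return(Inf)
    min(sqrt(colSums((t(atoms_xyz) - p)^2)) - vdw)
  })
  pass <- clear >= linker_width / 2 |
    sqrt(rowSums(sweep(grid, 2, attach)^2)) <= linker_width
  idx <- which(pass)
  sub <- grid[idx, , drop = FALSE]
  edges <- NULL
  wts <- NULL
  nn <- length(idx)
  for (i in seq_len(nn)) {
    d <- sqrt(rowSums(sweep(sub, 2, sub[i, ])^2))
    nb <- which(d > 0 & d <= spacing * sqrt(3) + 1e-9 & seq_len(nn) > i)
    if (length(nb) > 0) {
      edges <- rbind(edges, cbind(i, nb))
      wts <- c(wts, d[nb])
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nn - igraph::vcount(g)))
  start <- which.min(rowSums(sweep(sub, 2, attach)^2))
  pl <- as.numeric(igraph::distances(g, v = start, weights = wts))
  ok <- pl <= linker_length + 1e-9 & clear[idx] >= dye_radius
  sub[ok, , drop = FALSE]
}

# deterministic mini-case cache (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_benchmark <- function() {
  cached("small_benchmark", {
    spec <- hinge_spec(c(12, 12))
    suppressWarnings(suppressMessages(make_benchmark_case(
      spec, target_theta = 30, seed_thetas = c(-20, 0, 10, 20, 40, 50),
      pair_pool_size = 6, seed = 42, grid_spacing = 1.5, n_samples = 2e4)))
  })
}

small_pool <- function() {
  cached("small_pool", {
    case <- small_benchmark()
    suppressMessages(build_pair_pool(case$ensemble, case$pairs,
                                     grid_spacing = 1.5, n_samples = 2e4,
                                     seed = 42))
  })
}

identical_pool <- function(n_conf = 4) {
  # all conformers identical: zero RMSD everywhere
  dist <- matrix(40, n_conf, 3, dimnames = list(NULL, c("a", "b", "c")))
  structure(list(pairs = list(), ids = c("a", "b", "c"), dist = dist,
                 dr = matrix(2, n_conf, 3), rmsd = matrix(0, n_conf, n_conf),
                 labels = paste0("c", 1:n_conf), dropped = character(0)),
            class = "pair_pool")
}

synthetic_pool <- function(n_conf, ids, seed = 1, rmsd_scale = 5) {
  withr::with_seed(seed, {
    dist <- matrix(runif(n_conf * length(ids), 30, 70), n_conf,
                   dimnames = list(NULL, ids))
    dr <- matrix(runif(n_conf * length(ids), 1, 4), n_conf)
    pts <- matrix(rnorm(3 * n_conf, sd = rmsd_scale), n_conf)
    rmsd <- as.matrix(stats::dist(pts))
  })
  structure(list(pairs = list(), ids = ids, dist = dist, dr = dr,
                 rmsd = rmsd, labels = paste0("c", seq_len(n_conf)),
                 dropped = character(0)), class = "pair_pool")
}


three_restraint_toy <- function(angles_deg, dr = 2, f_max = 50) {
  # one central pseudoatom with partners on given bearings
  pos <- rbind(c(0, 0, 0),
               t(vapply(angles_deg, function(a) {
                 30 * c(cos(a * pi / 180), sin(a * pi / 180), 0)
               }, numeric(3))))
  ps <- tibble::tibble(site_id = c("hub", paste0("s", seq_along(angles_deg))),
                       chain = "A", resid = seq_len(nrow(pos)),
                       x = pos[, 1], y = pos[, 2], z = pos[, 3])
  rests <- tibble::tibble(
    pair_id = paste0("r", seq_along(angles_deg)),
    donor_site = "hub", acceptor_site = paste0("s", seq_along(angles_deg)),
    r_exp = 30, dr = dr, k = f_max / dr, f_max = f_max)
  list(ps = ps, rests = rests)
}

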