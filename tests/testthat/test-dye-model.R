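test_that("an unobstructed AV is a ball centred on the attachment point", {
  lone <- toy_conformer(matrix(c(0, 0, 0), 1, 3), elety = "CB")
  site <- labeling_site("A", 1, "CB", linker_length = 10, linker_width = 2,
                        dye_radii = 3.5)
  av <- compute_av(lone, site, grid_spacing = 1)
  expect_false(av$empty)
  expect_equal(sum(av$weights), 1, tolerance = 1e-9)
  # mean position at the attachment (symmetry), within a grid spacing
  expect_lt(sqrt(sum((av$mean_position - c(0, 0, 0))^2)), 1)
  # every point inside the linker reach
  expect_true(all(sqrt(rowSums(av$points^2)) <= 10 + 1e-9))
})

test_that("a wall of obstacles pushes the AV into the free half-space", {
  wall <- as.matrix(expand.grid(x = 3, y = seq(-30, 30, 1.5),
                                z = seq(-30, 30, 1.5)))
  atoms <- rbind(c(0, 0, 0), wall)
  conf <- toy_conformer(atoms, elety = c("CB", rep("CA", nrow(wall))))
  site <- labeling_site("A", 1, "CB", linker_length = 10, linker_width = 2,
                        dye_radii = 3.5)
  av <- compute_av(conf, site, grid_spacing = 1)
  expect_false(av$empty)
  expect_lt(av$mean_position[1], -1)        # displaced away from the wall
  expect_true(all(av$points[, 1] < 3))      # nothing beyond the wall
})

test_that("the grid flood fill agrees with an independent Dijkstra oracle", {
  # two-obstacle configuration on a coarse 1 A grid
  obstacles <- matrix(c(3, 0, 0, 0, 3.5, 1), ncol = 3, byrow = TRUE)
  conf <- toy_conformer(rbind(c(0, 0, 0), obstacles),
                        elety = c("CB", "CA", "CA"))
  site <- labeling_site("A", 1, "CB", linker_length = 6, linker_width = 2,
                        dye_radii = 2.5)
  av <- compute_av(conf, site, grid_spacing = 1)
  got <- av$points[order(av$points[, 1], av$points[, 2], av$points[, 3]), ]
  want <- oracle_av_points(obstacles, vdw_radius(c("CA", "CA")), c(0, 0, 0),
                           linker_length = 6, linker_width = 2,
                           dye_radius = 2.5, spacing = 1)
  want <- want[order(want[, 1], want[, 2], want[, 3]), ]
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
})

test_that("AV invariants hold on a protein-like system", {
  conf <- make_hinge_conformer(hinge_spec(c(10, 10)), 20)
  site <- labeling_site("A", 8, "CB", linker_length = 12)
  av <- compute_av(conf, site, grid_spacing = 1.2)
  expect_equal(sum(av$weights), 1, tolerance = 1e-9)
  # no accessible point beyond the linker's path reach
  expect_true(all(sqrt(rowSums(sweep(av$points, 2, av$attachment)^2))
                  <= site$linker_length + 1e-9))
  # refinement stability: halving the spacing moves the mean by less than
  # the coarse spacing
  av_fine <- compute_av(conf, site, grid_spacing = 0.6)
  expect_lt(sqrt(sum((av$mean_position - av_fine$mean_position)^2)), 1.2)
})

test_that("a fully buried site yields an empty AV flagged as unlabelable", {
  cage <- as.matrix(expand.grid(x = c(-2, 2), y = c(-2, 2), z = c(-2, 2)))
  shell <- cage[rep(1:8, 27), ] +
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[rep(1:27, each = 8), ] * 2
  conf <- toy_conformer(rbind(c(0, 0, 0), shell),
                        elety = c("CB", rep("CA", nrow(shell))))
  site <- labeling_site("A", 1, "CB", linker_length = 4, linker_width = 2,
                        dye_radii = 3.5)
  av <- compute_av(conf, site, grid_spacing = 1)
  expect_true(av$empty)
  expect_true(all(is.na(av$mean_position)))
  expect_error(model_distance(av, av), "empty")
})

point_cloud_av <- function(points, weights = NULL) {
  n <- nrow(points)
  w <- if (is.null(weights)) rep(1 / n, n) else weights
  structure(list(points = points, weights = w / sum(w),
                 mean_position = as.numeric(colSums(points * w / sum(w))),
                 attachment = points[1, ], spacing = 1, empty = FALSE,
                 site_id = "cloud"), class = "accessible_volume")
}

test_that("distance observables: point AVs, Jensen inequality, exhaustive oracle", {
  a <- point_cloud_av(matrix(c(0, 0, 0), 1, 3))
  b <- point_cloud_av(matrix(c(20, 0, 0), 1, 3))
  expect_equal(model_distance(a, b, "mean_RDA"), 20)
  expect_equal(model_distance(a, b, "Rmp"), 20)

  withr::local_seed(5)
  ca <- point_cloud_av(matrix(rnorm(30, sd = 4), ncol = 3),
                       weights = runif(10))
  cb <- point_cloud_av(sweep(matrix(rnorm(30, sd = 4), ncol = 3), 2,
                             c(25, 0, 0), `+`), weights = runif(10))
  # averaged distance dominates the distance of the averages
  expect_gte(model_distance(ca, cb, "mean_RDA"),
             model_distance(ca, cb, "Rmp"))
  # 10 x 10 clouds: exhaustive weighted double sum as oracle
  manual <- 0
  for (i in 1:10) for (j in 1:10) {
    manual <- manual + ca$weights[i] * cb$weights[j] *
      sqrt(sum((ca$points[i, ] - cb$points[j, ])^2))
  }
  expect_equal(model_distance(ca, cb, "mean_RDA"), manual, tolerance = 1e-12)
})

test_that("Monte-Carlo distance averaging is seeded and converges as 1/sqrt(n)", {
  withr::local_seed(9)
  big_a <- point_cloud_av(matrix(rnorm(6000, sd = 6), ncol = 3))
  big_b <- point_cloud_av(sweep(matrix(rnorm(6000, sd = 6), ncol = 3), 2,
                                c(40, 0, 0), `+`))
  d1 <- model_distance(big_a, big_b, "mean_RDA", n_samples = 500, seed = 3,
                       exhaustive_limit = 1)
  d2 <- model_distance(big_a, big_b, "mean_RDA", n_samples = 500, seed = 3,
                       exhaustive_limit = 1)
  expect_identical(d1, d2)

  truth <- model_distance(big_a, big_b, "mean_RDA")  # exhaustive
  err_at <- function(n) {
    est <- vapply(1:40, function(s) {
      model_distance(big_a, big_b, "mean_RDA", n_samples = n, seed = s,
                     exhaustive_limit = 1)
    }, numeric(1))
    sqrt(mean((est - truth)^2))
  }
  ratio <- err_at(100) / err_at(1600)
  expect_gt(ratio, 2)   # ideal factor 4 for 16x the samples
  expect_lt(ratio, 8)
})

test_that("efficiency-error propagation matches algebra and a finite-difference oracle", {
  # at R = R0: dR = dE * 4 R0 / 6
  expect_equal(distance_error_from_efficiency(52, 52, dE = 0.06),
               0.06 * 4 * 52 / 6)
  # sensitivity is lost both far above and far below R0: the upper clamp
  # takes over at either extreme
  expect_equal(distance_error_from_efficiency(300, 52), 30)
  expect_equal(distance_error_from_efficiency(5, 52), 30)
  # the lower clamp engages when the raw error falls below it
  expect_equal(distance_error_from_efficiency(52, 52, dE = 0.001), 0.5)

  # finite-difference oracle at R = 40, R0 = 52
  eff <- function(R) 1 / (1 + (R / 52)^6)
  h <- 1e-5
  slope <- (eff(40 + h) - eff(40 - h)) / (2 * h)
  expect_equal(distance_error_from_efficiency(40, 52, dE = 0.06),
               0.06 / abs(slope), tolerance = 1e-6)
})

test_that("simulated measurements are deterministic and self-consistent", {
  case <- small_benchmark()
  meas2 <- suppressMessages(simulate_measurements(
    case$target, case$pairs, grid_spacing = 1.5, noise = TRUE, seed = 42,
    n_samples = 2e4))
  meas3 <- suppressMessages(simulate_measurements(
    case$target, case$pairs, grid_spacing = 1.5, noise = TRUE, seed = 42,
    n_samples = 2e4))
  expect_identical(meas2$r_ref, meas3$r_ref)

  # noise-free screening of the target against its own set gives chi2 = 0
  d <- model_distance_matrix(ensemble(list(case$target)), case$pairs,
                             grid_spacing = 1.5, n_samples = 2e4, seed = 42)
  expect_equal(chi2(d[1, ], case$measurements), 0, tolerance = 1e-9)
})

test_that("replicate noise has the promised scale", {
  case <- small_benchmark()
  base <- case$measurements
  reps <- vapply(1:1000, function(s) add_measurement_noise(base, s)$r_ref[1],
                 numeric(1))
  expect_equal(sd(reps), base$dr_ref[1], tolerance = 0.05 * base$dr_ref[1])
})

test_that("ACV contact layering re-weights the surface shell to the requested fraction", {
  conf <- make_hinge_conformer(hinge_spec(c(10, 10)), 0)
  site <- labeling_site("A", 8, "CB", linker_length = 12, dye_radii = 3.5)
  acv <- compute_av(conf, site, grid_spacing = 1.2,
                    contact = list(thickness = 3, fraction = 0.9))
  av <- compute_av(conf, site, grid_spacing = 1.2)
  expect_equal(sum(acv$weights), 1, tolerance = 1e-9)
  # the contact layer (dye surface within 3 A of a vdW surface) carries
  # exactly the requested total weight; recompute membership independently
  heavy <- conf$atoms[!(conf$atoms$chain == site$chain &
                          conf$atoms$resid == site$resid &
                          conf$atoms$elety == site$atom), ]
  axyz <- as.matrix(heavy[, c("x", "y", "z")])
  clearance <- apply(acv$points, 1, function(p) {
    min(sqrt(colSums((t(axyz) - p)^2)) - 1.7)
  })
  in_layer <- clearance - site$dye_radii[1] <= 3
  expect_equal(sum(acv$weights[in_layer]), 0.9, tolerance = 1e-9)
  # relative to the plain AV, weight moves into the layer
  clearance_av <- apply(av$points, 1, function(p) {
    min(sqrt(colSums((t(axyz) - p)^2)) - 1.7)
  })
  in_layer_av <- clearance_av - site$dye_radii[1] <= 3
  expect_gt(sum(acv$weights[in_layer]), sum(av$weights[in_layer_av]))
})

test_that("AV exports produce well-formed files", {
  conf <- make_hinge_conformer(hinge_spec(c(6, 6)), 0)
  av <- compute_av(conf, labeling_site("A", 4, "CB", linker_length = 8),
                   grid_spacing = 1.5)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_av_xyz(av, xyz)
  lines <- readLines(xyz)
  expect_equal(as.integer(lines[1]), nrow(av$points))
  dx <- withr::local_tempfile(fileext = ".dx")
  write_av_dx(av, dx)
  expect_match(readLines(dx, n = 1), "gridpositions")
})
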