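test_that("convex hull volumes of canonical solids are exact", {
  cube <- as.matrix(expand.grid(c(0, 1000), c(0, 1000), c(0, 1000)))
  expect_equal(region_volume(build_region(cube)), 1, tolerance = 1e-4)
  tet <- rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0), c(0, 0, 1000))
  expect_equal(region_volume(build_region(tet)), 1 / 6, tolerance = 1e-4)
  # interior points must not change the hull volume
  set.seed(3)
  inner <- matrix(runif(60, 100, 900), ncol = 3)
  expect_equal(region_volume(build_region(rbind(cube, inner))), 1,
               tolerance = 1e-4)
})

test_that("hull volume of a random cloud agrees with an independent hull routine", {
  set.seed(1)
  pts <- matrix(runif(150 * 3, 0, 1000), ncol = 3)
  v_pkg <- region_volume(build_region(pts))
  csv <- tempfile(fileext = ".csv")
  write.csv(pts, csv, row.names = FALSE)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import numpy, scipy.spatial, csv;",
    "rows=list(csv.reader(open('", csv, "')));",
    "p=numpy.array(rows[1:],dtype=float);",
    "print(scipy.spatial.ConvexHull(p).volume/1e9)"
  ))), stdout = TRUE, stderr = TRUE))
  v_ref <- suppressWarnings(as.numeric(out[length(out)]))
  expect_false(is.na(v_ref))
  expect_equal(v_pkg, v_ref, tolerance = 1e-4)
})

test_that("alpha-complex volume is monotone in alpha and below the hull", {
  set.seed(7)
  blob1 <- matrix(rnorm(60, 0, 250), ncol = 3)
  blob2 <- sweep(matrix(rnorm(60, 0, 250), ncol = 3), 2, c(5000, 0, 0), "+")
  pts <- rbind(blob1, blob2)
  hull <- region_volume(build_region(pts, alpha_um = Inf))
  alpha <- region_volume(build_region(pts, alpha_um = 1000))
  expect_lt(alpha, hull)
  for (a in c(600, 1200)) {
    expect_lte(region_volume(build_region(pts, alpha_um = a)), hull + 1e-12)
  }
  expect_error(build_region(pts, alpha_um = 1e-3),
               class = "somaspat_empty_region_error")
})

test_that("degenerate point sets raise geometry errors", {
  flat <- cbind(matrix(runif(40, 0, 1000), ncol = 2), 0)
  expect_error(build_region(flat), class = "somaspat_geometry_error")
  line <- cbind(seq(0, 1000, length.out = 10), 0, 0)
  expect_error(build_region(line), class = "somaspat_geometry_error")
  expect_error(build_region(matrix(0, 3, 3)), class = "somaspat_geometry_error")
})

test_that("membership honours boundaries, exclusions and rejects non-finite input", {
  cube <- region_box(c(0, 0, 0), c(1000, 1000, 1000))
  expect_true(contains(cube, c(500, 500, 500)))
  expect_false(contains(cube, c(2000, 0, 0)))
  expect_true(contains(cube, c(0, 0, 0)))       # boundary counts as inside
  expect_true(contains(cube, c(1000, 500, 0)))
  tube <- tube_exclusions(500, 500, 150)
  cubex <- set_exclusions(cube, tube)
  expect_false(contains(cubex, c(500, 200, 500), honor_exclusions = TRUE))
  expect_true(contains(cubex, c(500, 200, 500), honor_exclusions = FALSE))
  expect_true(contains(cubex, c(100, 500, 100), honor_exclusions = TRUE))
  expect_error(contains(cube, c(NA, 0, 0)), class = "somaspat_coord_error")
})

test_that("uniform sampling has uniform moments and respects exclusions", {
  cube <- region_box(c(0, 0, 0), c(1000, 1000, 1000))
  p <- sample_uniform(cube, 1e4, seed = 11)
  se <- 1000 / sqrt(12) / sqrt(1e4)
  for (j in 1:3) expect_lt(abs(mean(p$coords[, j]) - 500), 5 * se)

  # central tube excluding ~25% of the cube
  r25 <- sqrt(0.25e6 / pi)
  tube <- tube_exclusions(500, 500, r25)
  cubex <- set_exclusions(cube, tube)
  px <- sample_uniform(cubex, 1e4, honor_exclusions = TRUE, seed = 12)
  expect_equal(sum(in_exclusion(tube, px$coords)), 0)
  # symmetric octants of the admissible volume stay uniform
  oct <- 1 + (px$coords[, 1] > 500) + 2 * (px$coords[, 2] > 500) +
    4 * (px$coords[, 3] > 500)
  expect_gt(chisq.test(tabulate(oct, 8))$p.value, 0.01)

  expect_equal(npoints(sample_uniform(cube, 0, seed = 1)), 0)
  # near-empty admissible volume errors instead of looping forever
  tiny <- set_exclusions(cube, tube_exclusions(500, 500, 1e6))
  expect_error(sample_uniform(tiny, 10, honor_exclusions = TRUE, seed = 1),
               class = "somaspat_sampling_error")
})

test_that("sampled patterns always pass their own membership test", {
  regions <- list(region_box(c(0, 0, 0), c(2000, 1000, 500)),
                  region_ellipsoid(c(0, 0, 0), c(800, 1600, 800)),
                  make_region_fixture("GP", "R"))
  for (reg in regions) {
    p <- sample_uniform(reg, 500, seed = 5)
    expect_true(all(contains(reg, p$coords, honor_exclusions = TRUE)))
  }
})

test_that("ball sub-region extraction matches analytic volumes and placements", {
  cube <- region_box(c(0, 0, 0), c(4000, 4000, 4000))
  p <- sample_uniform(cube, 400, seed = 21)
  ext <- extract_ball_subregion(p, cube, radius_um = 1000,
                                center = c(2000, 2000, 2000))
  expect_equal(region_volume(ext$region), 4 / 3 * pi, tolerance = 1e-12)
  d2 <- rowSums(sweep(ext$pattern$coords, 2, c(2000, 2000, 2000))^2)
  expect_true(all(d2 <= 1000^2))
  expect_equal(npoints(ext$pattern), sum(rowSums(
    sweep(p$coords, 2, c(2000, 2000, 2000))^2) <= 1000^2))

  # count fraction tracks volume fraction for CSR input
  frac <- npoints(ext$pattern) / npoints(p)
  vfrac <- region_volume(ext$region) / region_volume(cube)
  expect_lt(abs(frac - vfrac), 5 * sqrt(vfrac * (1 - vfrac) / npoints(p)))

  # auto placement of an ellipsoid ball lands near the centre
  ell <- region_ellipsoid(c(0, 0, 0), c(1500, 3000, 1500))
  ext2 <- extract_ball_subregion(p[0], ell, radius_um = 1000, center = "auto")
  expect_lt(sqrt(sum(ext2$center^2)), 400)
  expect_equal(npoints(ext2$pattern), 0)  # empty sub-pattern is valid

  expect_error(extract_ball_subregion(p, cube, radius_um = 10000),
               class = "somaspat_geometry_error")
})

test_that("voxel, mesh and analytic representations of a ball agree on volume", {
  ball <- region_sphere(c(0, 0, 0), 1000)
  v_true <- region_volume(ball)
  expect_equal(v_true, 4 / 3 * pi, tolerance = 1e-12)
  vox <- voxelize(ball, 50)
  expect_equal(region_volume(vox), v_true, tolerance = 0.02)
  mesh <- sphere_mesh(c(0, 0, 0), 1000)
  expect_equal(region_volume(mesh), v_true, tolerance = 0.02)
  # mesh membership agrees with the analytic ball away from the surface
  set.seed(2)
  probes <- matrix(runif(300, -1200, 1200), ncol = 3)
  rad <- sqrt(rowSums(probes^2))
  clear <- abs(rad - 1000) > 30
  expect_equal(contains(mesh, probes[clear, ]),
               (rad < 1000)[clear])
})

test_that("open meshes are rejected for volume computations", {
  mesh <- sphere_mesh(c(0, 0, 0), 500, n_lat = 8, n_lon = 12)
  open <- region_mesh(mesh$vertices, mesh$faces[-1, ])
  expect_error(region_volume(open), class = "somaspat_geometry_error")
})

test_that("voxel regions compute volume by voxel counting", {
  mask <- array(FALSE, c(10, 10, 10))
  mask[1:10, 1:10, 1:10] <- TRUE
  reg <- region_voxel(mask, 100)  # 1000 voxels of (0.1 mm)^3
  expect_equal(region_volume(reg), 1)
  expect_true(contains(reg, c(50, 50, 50)))
  expect_false(contains(reg, c(1500, 50, 50)))
})

test_that("region volume can exclude bundle zones on request", {
  cube <- region_box(c(0, 0, 0), c(1000, 1000, 1000))
  tube <- tube_exclusions(500, 500, sqrt(0.25e6 / pi))
  cubex <- set_exclusions(cube, tube)
  expect_equal(region_volume(cubex), 1)  # default includes the bundles
  expect_equal(region_volume(cubex, exclude_zones = TRUE), 0.75,
               tolerance = 0.01)
})
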