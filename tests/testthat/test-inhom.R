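test_that("kernel intensity is consistent for CSR and integrates to n", {
  box <- unit_box()
  p <- sample_uniform(box, 5000, seed = 2)
  f <- kernel_intensity(p, box)
  lam_c <- predict(f, matrix(c(500, 500, 500), 1))
  expect_lt(abs(lam_c / 5000 - 1), 0.1)
  # Monte Carlo integral over the region within 5% of n
  q <- sample_uniform(box, 2e4, seed = 9)$coords
  expect_lt(abs(mean(predict(f, q)) * region_volume(box) / 5000 - 1), 0.05)
})

test_that("kernel intensity obeys the KDE scaling identity", {
  box <- unit_box()
  p <- sample_uniform(box, 400, seed = 3)
  f1 <- kernel_intensity(p, box, bandwidth = 120)
  box2 <- region_box(c(0, 0, 0), c(2000, 2000, 2000))
  f2 <- kernel_intensity(soma_pattern(2 * p$coords), box2, bandwidth = 240)
  q <- sample_uniform(box, 200, seed = 4)$coords
  expect_equal(predict(f2, 2 * q), predict(f1, q) / 8, tolerance = 0.03)
})

test_that("kernel intensity is larger at blob centres than between them", {
  set.seed(5)
  blob1 <- matrix(rnorm(300, 300, 60), ncol = 3)
  blob2 <- matrix(rnorm(300, 700, 60), ncol = 3)
  box <- unit_box()
  p <- soma_pattern(rbind(blob1, blob2))
  f <- kernel_intensity(p, box, bandwidth = 80)
  lam <- predict(f, rbind(c(300, 300, 300), c(500, 500, 500),
                          c(700, 700, 700)))
  expect_gt(lam[1], lam[2])
  expect_gt(lam[3], lam[2])
  same <- soma_pattern(matrix(rep(c(1, 2, 3), each = 5), ncol = 3))
  expect_error(kernel_intensity(same, box), class = "somaspat_input_error")
})

test_that("K_inhom pair arithmetic and the constant-intensity identity", {
  # one pair at distance d with lambda = 2 mm^-3 at both points:
  # two ordered pairs x 1/4
  box <- unit_box()
  p2 <- soma_pattern(rbind(c(100, 0, 0), c(400, 0, 0)))
  f2 <- uniform_intensity(box, 2)   # lambda = 2 mm^-3
  ki <- k_inhom(p2, f2, radii_um = c(100, 300, 600))
  expect_equal(ki$k_inhom, c(0, 0.5, 0.5))

  # constant lambda = n/|V|: K_inhom == |V| K exactly, on every grid point
  for (r in 1:5) {
    n <- sample(10:120, 1)
    p <- sample_uniform(box, n, seed = 500 + r)
    radii <- seq(10, 1500, length.out = 60)
    k <- k_function(p, region_volume_mm3 = 1, radii_um = radii)$k_obs
    ki <- k_inhom(p, uniform_intensity(box, n), radii)$k_inhom
    expect_equal(ki, 1 * k, tolerance = 1e-9)
  }
})

test_that("K_inhom matches the brute-force loop with the same intensities", {
  box <- unit_box()
  radii <- seq(30, 1200, length.out = 25)
  for (r in 1:20) {
    n <- sample(10:200, 1)
    p <- generate_gradient(box, n, ratio = 2, seed = 700 + r)
    f <- kernel_intensity(p, box)
    ki <- k_inhom(p, f, radii)
    ref <- brute_kinhom(p$coords, attr(ki, "lambda"), radii)
    expect_equal(ki$k_inhom, ref, tolerance = 1e-9)
  }
})

test_that("zero intensity at a data point is reported with its index", {
  box <- unit_box()
  p <- sample_uniform(box, 10, seed = 6)
  f <- uniform_intensity(box, 10)
  f$lambda <- 0
  expect_error(k_inhom(p, f, c(100)), class = "somaspat_input_error")
})

test_that("fixed-count inhomogeneous Poisson simulation follows the field", {
  box <- unit_box()
  f <- uniform_intensity(box, 200)
  s1 <- simulate_inhom_poisson(f, box, 200, seed = 11)
  s2 <- simulate_inhom_poisson(f, box, 200, seed = 11)
  expect_identical(s1$coords, s2$coords)
  expect_equal(npoints(s1), 200)
  # constant field: octant occupancies uniform
  oct <- 1 + (s1$coords[, 1] > 500) + 2 * (s1$coords[, 2] > 500) +
    4 * (s1$coords[, 3] > 500)
  expect_gt(chisq.test(tabulate(oct, 8))$p.value, 0.01)
  # linear gradient with ratio 2: halves split 2:1 in expectation
  g <- generate_gradient(box, 600, ratio = 2, seed = 12)
  fg <- kernel_intensity(g, box)
  sg <- simulate_inhom_poisson(fg, box, 900, seed = 13)
  ant <- sum(sg$coords[, 2] <= 500)
  expect_lt(abs(ant / 900 - 2 / 3), 0.08)
})

test_that("rank test arithmetic and failure modes", {
  set.seed(21)
  nulls <- matrix(rnorm(99 * 10), 99, 10)
  # observed more extreme than every null
  obs <- colMeans(nulls) + 100
  rt <- monte_carlo_rank_test(obs, nulls)
  expect_equal(rt$p, 0.01)
  expect_equal(rt$rank, 1)
  # observed equal to one of the nulls ranks at least second
  rt2 <- monte_carlo_rank_test(nulls[5, ], nulls)
  expect_gte(rt2$rank, 2)
  expect_error(monte_carlo_rank_test(obs[1:5], nulls),
               class = "somaspat_input_error")
  expect_error(monte_carlo_rank_test(obs, nulls[1, , drop = FALSE]),
               class = "somaspat_input_error")
  # max-deviation criterion is accepted
  expect_lte(monte_carlo_rank_test(obs, nulls, summary = "max")$p, 0.01)
})

test_that("inhom analysis detects clustering superimposed on a gradient", {
  box <- region_box(c(0, 0, 0), c(1500, 3000, 1500))
  hits <- vapply(1:8, function(r) {
    g <- generate_gradient(box, 120, ratio = 2, seed = 800 + r)
    th <- generate_thomas(box, 20, 8, 30, seed = 900 + r)
    p <- bind_patterns(g, th)
    inhom_analysis(p, box, n_null = 99, seed = 8000 + r)$p <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 6)
})
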