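test_that("K formula arithmetic on minimal configurations", {
  # single point: the j != i sum is empty
  p1 <- soma_pattern(matrix(c(10, 10, 10), 1))
  k1 <- k_function(p1, region_volume_mm3 = 1, radii_um = c(10, 100, 500))
  expect_equal(k1$k_obs, c(0, 0, 0))
  # two points 100 um apart in 1 mm^3: one ordered pair each way
  p2 <- soma_pattern(rbind(c(0, 0, 0), c(100, 0, 0)))
  k2 <- k_function(p2, region_volume_mm3 = 1, radii_um = c(50, 99.999, 100, 200))
  expect_equal(k2$k_obs, c(0, 0, 0.5, 0.5))  # tie D = r counts as <= r
  expect_error(k_function(p1[0], region_volume_mm3 = 1, radii_um = 1),
               class = "somaspat_input_error")
  expect_error(k_function(p2, region_volume_mm3 = 0, radii_um = 1),
               class = "somaspat_input_error")
})

test_that("K matches the brute-force double loop on random instances", {
  box <- unit_box()
  radii <- seq(20, 1400, length.out = 37)
  for (r in 1:20) {
    n <- sample(2:200, 1)
    p <- sample_uniform(box, n, seed = 300 + r)
    k <- k_function(p, region_volume_mm3 = 1, radii_um = radii)$k_obs
    ref <- brute_k(p$coords, 1, radii)
    expect_equal(k, ref, tolerance = 1e-9)
  }
})

test_that("K is non-decreasing and saturates at |V|(n-1)/n", {
  box <- unit_box()
  p <- sample_uniform(box, 80, seed = 31)
  radii <- seq(0, 2000, length.out = 100)  # beyond the box diameter
  k <- k_function(p, region_volume_mm3 = 1, radii_um = radii)$k_obs
  expect_true(all(diff(k) >= 0))
  expect_equal(k[1], 0)
  expect_equal(k[100], 1 * 79 / 80, tolerance = 1e-12)
})

test_that("CSR simulation mean tracks (4/3) pi r^3 at small r and is biased low at large r", {
  box <- region_box(c(0, 0, 0), c(2000, 2000, 2000))
  p <- sample_uniform(box, 500, seed = 41)
  radii <- c(40, 60, 80, 100, 300, 500)
  env <- csr_envelope(p, box, n_sims = 199, radii_um = radii, seed = 42)
  theo <- k_csr_theoretical(radii)
  # interior-dominated regime: r at most 5% of the box side
  small <- radii <= 100
  expect_lt(max(abs(env$k_sim_mean[small] / theo[small] - 1)), 0.05)
  # uncorrected estimator loses pairs across the boundary as r grows
  expect_true(all(env$k_sim_mean <= theo * 1.01))
  expect_lt(env$k_sim_mean[length(radii)] / theo[length(radii)], 0.9)
})

test_that("envelope bookkeeping and determinism", {
  box <- unit_box()
  p <- sample_uniform(box, 40, seed = 51)
  e2 <- csr_envelope(p, box, n_sims = 2, radii_um = c(100, 300), seed = 52)
  expect_equal(dim(attr(e2, "sims")), c(2, 2))
  e2b <- csr_envelope(p, box, n_sims = 2, radii_um = c(100, 300), seed = 52)
  expect_identical(as.data.frame(e2), as.data.frame(e2b))
})

test_that("paired t comparison reproduces textbook arithmetic", {
  expect_equal(paired_t_compare(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2, p = 1, degenerate = FALSE))
  res <- paired_t_compare(c(2, 4, 6, 8), c(1, 2, 3, 4))  # diffs 1,2,3,4
  expect_equal(res$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_equal(res$df, 3)
  # constant nonzero difference is degenerate
  resd <- paired_t_compare(c(2, 3, 4), c(1, 2, 3))
  expect_true(resd$degenerate)
  expect_equal(resd$p, 0)
  expect_equal(resd$t, Inf)
  # the default radii grid has 100 points, hence df = 99
  box <- unit_box()
  p <- sample_uniform(box, 30, seed = 61)
  env <- csr_envelope(p, box, n_sims = 5, seed = 62)
  expect_equal(length(env$r_um), 100)
  expect_equal(paired_t_compare(env)$df, 99)
})
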