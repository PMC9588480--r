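test_that("region fixtures reproduce the reference structure volumes", {
  t1 <- table1_data()
  for (i in seq_len(nrow(t1))) {
    reg <- make_region_fixture(t1$region[i], t1$hemisphere[i])
    expect_equal(region_volume(reg), t1$volume_mm3[i],
                 tolerance = 0.005)
    # elongated 1:2:1 along the anterior-posterior axis
    expect_equal(reg$semiaxes[2] / reg$semiaxes[1], 2)
  }
  expect_equal(region_volume(make_region_fixture("GP", "L")), 2.74,
               tolerance = 1e-9)
  expect_equal(region_volume(make_region_fixture("CPu", "R")), 15.95,
               tolerance = 1e-9)
  expect_error(make_region_fixture("XX", "L"),
               class = "somaspat_fixture_error")
})

test_that("CSR generation is seed-deterministic and density-consistent", {
  gp <- make_region_fixture("GP", "L")
  a <- generate_csr(gp, 300, seed = 5)
  b <- generate_csr(gp, 300, seed = 5)
  c2 <- generate_csr(gp, 300, seed = 6)
  expect_identical(a$coords, b$coords)
  expect_false(identical(a$coords, c2$coords))
  expect_equal(npoints(generate_csr(gp, 0, seed = 1)), 0)
  # bilateral GP density is plain count/volume arithmetic
  expect_equal(density_mm3(508, 2.74 + 2.07), 105.6, tolerance = 0.001)
})

test_that("gradient patterns hit the requested anterior:posterior ratio", {
  cpu <- make_region_fixture("CPu", "L")
  g <- generate_gradient(cpu, 1652, ratio = 2.1, seed = 9)
  expect_true(all(contains(cpu, g$coords)))
  mid <- cpu$center[2]
  ant <- sum(g$coords[, 2] <= mid)
  p_target <- 2.1 / 3.1
  expect_lt(abs(ant / 1652 - p_target),
            5 * sqrt(p_target * (1 - p_target) / 1652) + 0.01)
  # anterior (low Y) is the dense side
  expect_gt(ant, 1652 - ant)
})

test_that("a ratio-1 gradient is indistinguishable from CSR", {
  box <- region_box(c(0, 0, 0), c(1000, 2000, 1000))
  n_rep <- 50
  pvals <- vapply(seq_len(n_rep), function(r) {
    g <- generate_gradient(box, 150, ratio = 1, seed = 100 + r)
    u <- generate_csr(box, 150, seed = 600 + r)
    t.test(knn_distances(g, 1)$dist[, 1],
           knn_distances(u, 1)$dist[, 1])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("Thomas process limits and moments behave as a cluster process", {
  cpu <- make_region_fixture("CPu", "L")
  # sd -> 0: children coincide with their parents (at most one distinct
  # location per parent; siblings at zero distance)
  th0 <- generate_thomas(cpu, 20, 5, sd_um = 0, seed = 3)
  expect_lte(nrow(unique(th0$coords)), 20)
  expect_equal(median(knn_distances(th0, 1)$dist[, 1]), 0)
  # expected count = parents x mean offspring (within sampling noise and
  # the small boundary clipping loss)
  counts <- vapply(1:10, function(r)
    npoints(generate_thomas(cpu, 50, 10, 50, seed = 40 + r)), numeric(1))
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500 / 10) + 0.1 * 500)
  expect_true(all(contains(cpu, generate_thomas(cpu, 30, 8, 100,
                                                seed = 4)$coords)))
})

test_that("Thomas clustering drives observed K above the CSR envelope", {
  cpu <- make_region_fixture("CPu", "L")
  radii <- seq(0, 600, length.out = 31)
  above <- vapply(1:8, function(r) {
    th <- generate_thomas(cpu, 50, 10, 50, seed = 70 + r)
    env <- csr_envelope(th, cpu, n_sims = 99, radii_um = radii,
                        seed = 700 + r)
    i200 <- which.min(abs(radii - 200))
    env$k_obs[i200] > env$k_hi[i200]
  }, logical(1))
  expect_gte(mean(above), 7 / 8)
})

test_that("bundle generation reaches the target excluded fraction", {
  cpu <- make_region_fixture("CPu", "R")
  b0 <- generate_bundles(cpu, 0, seed = 1)
  expect_equal(attr(b0, "measured_fraction"), 0)
  b <- generate_bundles(cpu, 0.268, seed = 5)
  got <- attr(b, "measured_fraction")
  expect_lt(abs(got - 0.268), 0.01)
  expect_equal(got, excluded_fraction(set_exclusions(cpu, b)))
  p <- sample_uniform(set_exclusions(cpu, b), 400, honor_exclusions = TRUE,
                      seed = 6)
  expect_equal(sum(in_exclusion(b, p$coords)), 0)
})

test_that("the bilateral dataset reproduces the reference census", {
  bil <- generate_bilateral_dataset(seed = 17)
  expect_equal(npoints(bil), 13989)
  tab <- table(bil$region_label, bil$hemisphere)
  t1 <- table1_data()
  for (i in seq_len(nrow(t1)))
    expect_equal(unname(tab[t1$region[i], t1$hemisphere[i]]), t1$count[i])
  expect_equal(abs(diff(colSums(tab))), 557, ignore_attr = TRUE)
  expect_false(any(is.na(bil$region_label)))
  expect_false(any(is.na(bil$hemisphere)))
  expect_true(all(bil$diameter_um >= 15))
  # byte-identical regeneration under the same seed
  bil2 <- generate_bilateral_dataset(seed = 17)
  expect_identical(bil$coords, bil2$coords)
  expect_false(identical(generate_bilateral_dataset(seed = 18)$coords,
                         bil$coords))
})
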