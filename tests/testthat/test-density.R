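test_that("density is the exact quotient and reproduces every printed value", {
  expect_equal(round(density_mm3(308, 2.74), 2), 112.41)
  expect_equal(round(density_mm3(7273, 23.94), 2), 303.80)
  expect_equal(density_mm3(0, 5), 0)
  expect_error(density_mm3(10, 0), class = "somaspat_input_error")
  t1 <- table1_data()
  printed <- c(112.41, 299.53, 716.85, 335.31, 265.74,
               96.62, 347.75, 706.84, 365.42, 285.20)
  expect_equal(round(density_mm3(t1$count, t1$volume_mm3), 2), printed)
})

test_that("hemispheric summary conserves counts and reports both orientations", {
  s <- hemispheric_summary()
  expect_equal(s$grand_total, 13989)
  expect_equal(s$count_difference, 557, ignore_attr = TRUE)
  expect_equal(round(s$count_difference_pct, 2), 3.98, ignore_attr = TRUE)
  expect_equal(sum(s$proportions$proportion), 1)
  expect_equal(sum(s$totals$count), s$grand_total)
  # per-hemisphere totals are the column sums of the per-structure table
  t1 <- table1_data()
  expect_setequal(s$totals$count, tapply(t1$count, t1$hemisphere, sum))
  # the denser hemisphere is the one with more cells in less volume
  denser <- s$totals[s$totals$hemisphere == s$denser_hemisphere, ]
  other <- s$totals[s$totals$hemisphere != s$denser_hemisphere, ]
  expect_gt(denser$count, other$count)
  expect_lt(denser$volume_mm3, other$volume_mm3)
  # equal hemispheres: zero differences
  eq <- t1
  eq$count <- rep(t1$count[1:5], 2)
  eq$volume_mm3 <- rep(t1$volume_mm3[1:5], 2)
  s0 <- hemispheric_summary(eq)
  expect_equal(s0$count_difference, 0, ignore_attr = TRUE)
  expect_equal(s0$density_difference_mm3, 0, ignore_attr = TRUE)
  # missing cells are reported
  expect_error(hemispheric_summary(t1[-1, ]), class = "somaspat_input_error")
})

test_that("homogeneity F statistic follows the published convention", {
  eq <- homogeneity_f_test(50, 2, 50, 2)
  expect_equal(eq$F, 1)
  gp <- homogeneity_f_test(51, 1, 43, 1)
  expect_equal(gp$F, 103 / 87)
  expect_equal(round(gp$F, 2), 1.18)
  expect_equal(gp$df, c(103, 87))
  expect_equal(gp$F_alt, 87 / 103)
  expect_equal(gp$df_alt, c(87, 103))
  expect_equal(round(gp$p, 2), 0.21, tolerance = 0.01)
  # exact reciprocal duality under window swap
  a <- homogeneity_f_test(37, 1.3, 61, 0.8)
  b <- homogeneity_f_test(61, 0.8, 37, 1.3)
  expect_equal(a$F * b$F, 1)
  # volume imbalance compensates count imbalance
  expect_equal(homogeneity_f_test(51, 103, 43, 87)$F, 1)
})

test_that("F-test type-I error is near nominal for equal-intensity windows", {
  set.seed(77)
  rej <- mean(replicate(1000, {
    homogeneity_f_test(rpois(1, 60), 1, rpois(1, 60), 1)$p <= 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("anterior/posterior splits bisect symmetric regions and feed the F-test", {
  cpu <- make_region_fixture("CPu", "L")
  p <- generate_csr(cpu, 400, seed = 31)
  sp <- split_anterior_posterior(p, cpu)
  expect_equal(sp$anterior$volume_mm3, sp$posterior$volume_mm3,
               tolerance = 0.01)
  expect_equal(sp$anterior$n + sp$posterior$n, 400)
  expect_equal(sp$plane_y_um, cpu$center[2])
  # CSR: non-significant in most replicates
  ps <- vapply(1:40, function(r) {
    split_anterior_posterior(generate_csr(cpu, 300, seed = 100 + r),
                             cpu)$f_test$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
  # ratio-2.1 gradient at the published CPu scale: strongly significant
  hits <- vapply(1:20, function(r) {
    g <- generate_gradient(cpu, 1652, ratio = 2.1, seed = 200 + r)
    split_anterior_posterior(g, cpu)$f_test$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(split_anterior_posterior(p, cpu, plane = 1e9),
               class = "somaspat_input_error")
})
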