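test_that("k-NN distances on forced configurations", {
  p2 <- soma_pattern(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(knn_distances(p2, 1)$dist[, 1], c(100, 100))
  grid <- as.matrix(expand.grid((0:2) * 50, (0:2) * 50, (0:2) * 50))
  kg <- knn_distances(soma_pattern(grid), 1)
  expect_equal(kg$dist[, 1], rep(50, 27))
  expect_error(knn_distances(p2, 5), class = "somaspat_input_error")
})

test_that("k-NN distances and NN-graph components match brute force", {
  box <- unit_box()
  for (r in 1:20) {
    n <- sample(12:200, 1)
    p <- sample_uniform(box, n, seed = 900 + r)
    k <- min(10, n - 1)
    expect_equal(knn_distances(p, k)$dist, brute_knn(p$coords, k),
                 ignore_attr = TRUE)
    g <- nn_graph(p)
    ref <- brute_nn_components(p$coords)
    expect_equal(g$nn, ref$nn)
    expect_equal(partition_signature(g$membership),
                 partition_signature(ref$membership))
    # invariants: minimum cluster size 2, sizes sum to n, 1-NN consistency
    expect_gte(min(g$sizes), 2)
    expect_equal(sum(g$sizes), n)
    expect_equal(g$nn_dist_um, knn_distances(p, 1)$dist[, 1])
  }
})

test_that("NN-graph structure on forced configurations", {
  # collinear points at 0, 1, 3 mm: one chain of size 3
  line <- soma_pattern(cbind(c(0, 1000, 3000), 0, 0))
  g <- nn_graph(line)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$sizes, 3)
  # two far-separated pairs: histogram {2: 2}
  pairs <- soma_pattern(rbind(c(0, 0, 0), c(10, 0, 0),
                              c(5000, 0, 0), c(5010, 0, 0)))
  g2 <- nn_graph(pairs)
  expect_equal(sort(g2$sizes), c(2, 2))
  expect_equal(unname(g2$histogram["2"]), 2L)
  # exact ties resolve to the lowest index
  sq <- soma_pattern(rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0),
                           c(100, 100, 0), c(50, 50, 2000)))
  expect_equal(nn_graph(sq)$nn[1], 2)
})

test_that("CSR cluster-size frequencies typically decrease from size 2", {
  box <- unit_box()
  # non-increasing over the well-populated head of the histogram (the sparse
  # tail fluctuates by single clusters)
  decreasing <- vapply(1:10, function(r) {
    h <- as.vector(nn_graph(sample_uniform(box, 500, seed = 40 + r))$histogram)
    all(diff(h[1:min(3, length(h))]) <= 0)
  }, logical(1))
  expect_gte(mean(decreasing), 0.7)
})

test_that("interior mean 1-NN distance matches the Poisson closed form", {
  box <- unit_box()
  n <- 3000
  p <- sample_uniform(box, n, seed = 11)
  d <- knn_distances(p, 1)$dist[, 1]
  margin <- 2 * mean(d)
  interior <- apply(p$coords > margin & p$coords < 1000 - margin, 1, all)
  theo <- gamma(4 / 3) * (4 * pi * (n / 1e9) / 3)^(-1 / 3)
  expect_lt(abs(mean(d[interior]) / theo - 1), 0.05)
})

test_that("mean k-NN envelopes separate clustered, random and regular patterns", {
  box <- unit_box()
  # regular lattice: 1-NN above the CSR band
  grid <- as.matrix(expand.grid((0:4) * 200 + 100, (0:4) * 200 + 100,
                                (0:4) * 200 + 100))
  env_g <- nn_compare_to_csr(soma_pattern(grid), box, n_sims = 199, k = 3,
                             seed = 51)
  expect_gt(env_g$obs_mean_um[1], env_g$hi_um[1])
  # Thomas clusters: 1-NN below the band
  th <- generate_thomas(box, 15, 9, 40, seed = 52)
  env_t <- nn_compare_to_csr(th, box, n_sims = 199, k = 3, seed = 53)
  expect_lt(env_t$obs_mean_um[1], env_t$lo_um[1])
  # CSR: inside the band for most of the 10 neighbour orders
  inside <- vapply(1:10, function(r) {
    p <- sample_uniform(box, 150, seed = 60 + r)
    e <- nn_compare_to_csr(p, box, n_sims = 99, k = 10, seed = 600 + r)
    mean(e$obs_mean_um >= e$lo_um & e$obs_mean_um <= e$hi_um)
  }, numeric(1))
  expect_gte(mean(inside), 0.85)
})

test_that("cluster-size histograms are robust to small coordinate noise", {
  box <- unit_box()
  p <- sample_uniform(box, 400, seed = 71)  # mean NN spacing ~80 um
  expect_equal(max(noise_robustness(p, 0, n_reps = 3, seed = 1)), 0)
  tv <- noise_robustness(p, 1, n_reps = 10, seed = 2)
  expect_lt(max(tv), 0.05)
})

test_that("large noise washes a clustered histogram out to the CSR shape", {
  box <- unit_box()
  th <- generate_thomas(box, 12, 15, 3, seed = 81)
  n <- npoints(th)
  tv_vs_csr <- function(pat) mean(vapply(1:5, function(r)
    histogram_tv(nn_graph(pat)$histogram,
                 nn_graph(sample_uniform(box, n, seed = 820 + r))$histogram),
    numeric(1)))
  # sampling spread of the CSR histogram itself
  baseline <- vapply(1:8, function(r)
    tv_vs_csr(sample_uniform(box, n, seed = 900 + r)), numeric(1))
  set.seed(83)
  noisy <- soma_pattern(th$coords + matrix(rnorm(3 * n, 0, 400), ncol = 3),
                        check = FALSE)
  # after noise much larger than the cluster scale, the histogram sits
  # inside the CSR sampling spread
  expect_lt(tv_vs_csr(noisy), max(baseline) + 0.05)
})
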