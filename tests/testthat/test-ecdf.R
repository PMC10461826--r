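test_that("marginal ecdf matches the counting definition, including ties", {
  expect_equal(marginal_ecdf(c(0.1, 0.5, 0.9)), c(1, 2, 3) / 3)
  expect_equal(marginal_ecdf(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  set.seed(101)
  for (k in 1:200) {
    n <- sample(1:60, 1)
    x <- random_tied_vector(n, n_distinct = sample(c(NA, 3, 10), 1))
    expect_equal(marginal_ecdf(x), oracle_marginal_ecdf(x))
  }
})

test_that("marginal ecdf rejects non-finite input, naming the index", {
  expect_error(marginal_ecdf(c(0.1, NA, 0.3)), "index 2",
               class = "gpstest_input_error")
  expect_error(marginal_ecdf(numeric(0)), class = "gpstest_input_error")
})

test_that("naive bivariate ecdf handles the elementary configurations", {
  expect_equal(bivariate_ecdf(c(0.1, 0.2), c(0.1, 0.2), "naive"),
               c(1 / 2, 1))
  expect_equal(bivariate_ecdf(c(0.1, 0.2), c(0.2, 0.1), "naive"),
               c(1 / 2, 1 / 2))
  # every point dominates itself
  set.seed(7)
  u <- runif(40); v <- runif(40)
  expect_true(all(bivariate_ecdf(u, v, "naive") >= 1 / 40))
  # constant vectors: every pair dominates every pair
  expect_equal(bivariate_ecdf(rep(0.3, 8), rep(0.3, 8), "tree"), rep(1, 8))
  # singleton
  expect_equal(bivariate_ecdf(0.5, 0.5, "dac"), 1)
  expect_error(bivariate_ecdf(c(0.1, 0.2), 0.1, "naive"),
               "equal length")
})

test_that("tree and divide-and-conquer backends equal the naive oracle exactly", {
  set.seed(202)
  for (k in 1:300) {
    n <- sample(5:300, 1)
    tie_u <- sample(c(NA, 3, 7, 25), 1)
    tie_v <- sample(c(NA, 3, 7, 25), 1)
    u <- if (is.na(tie_u)) runif(n) else random_tied_vector(n, tie_u)
    v <- if (is.na(tie_v)) runif(n) else random_tied_vector(n, tie_v)
    cn <- gpstest:::.joint_count_cpp(u, v, "naive")
    expect_identical(gpstest:::.joint_count_cpp(u, v, "tree"), cn)
    expect_identical(gpstest:::.joint_count_cpp(u, v, "dac"), cn)
  }
  # tie-heavy: only 3 distinct values at n = 100
  u <- random_tied_vector(100, 3)
  v <- random_tied_vector(100, 3)
  cn <- gpstest:::.joint_count_cpp(u, v, "naive")
  expect_identical(gpstest:::.joint_count_cpp(u, v, "tree"), cn)
  expect_identical(gpstest:::.joint_count_cpp(u, v, "dac"), cn)
})

test_that("reordering the input permutes the output identically", {
  set.seed(303)
  u <- random_tied_vector(80, 10)
  v <- random_tied_vector(80, 10)
  base <- bivariate_ecdf(u, v, "tree")
  perm <- sample(80)
  expect_equal(bivariate_ecdf(u[perm], v[perm], "tree"), base[perm])
  expect_equal(bivariate_ecdf(rev(u), rev(v), "dac"), rev(base))
})

test_that("ecdf profiles respect the Frechet bounds and the 1/n lattice", {
  set.seed(404)
  for (k in 1:20) {
    n <- sample(5:200, 1)
    pair <- gps_pair(random_tied_vector(n, sample(c(NA, 5), 1)),
                     runif(n))
    prof <- ecdf_profile(pair, backend = sample(c("tree", "dac", "naive"), 1))
    expect_true(all(prof$F_uv <= pmin(prof$F_u, prof$F_v) + 1e-12))
    expect_true(all(prof$F_uv >= pmax(0, prof$F_u + prof$F_v - 1) - 1e-12))
    for (col in c("F_u", "F_v", "F_uv")) {
      counts <- round(prof[[col]] * n)
      expect_equal(prof[[col]] * n, counts)  # multiples of 1/n
      expect_true(all(counts >= 1 & counts <= n))
    }
  }
})
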