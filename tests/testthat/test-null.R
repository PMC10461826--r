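test_that("the permutation null is seed-deterministic", {
  pair <- simulate_independent_null(500, seed = 21)
  n1 <- suppressWarnings(permutation_null(pair, n_perm = 150, seed = 22))
  n2 <- suppressWarnings(permutation_null(pair, n_perm = 150, seed = 22))
  expect_identical(n1$d_values, n2$d_values)
  n3 <- suppressWarnings(permutation_null(pair, n_perm = 150, seed = 23))
  expect_false(identical(n1$d_values, n3$d_values))
  expect_true(all(n1$d_values >= 0 & is.finite(n1$d_values)))
})

test_that("permutation counts are guarded and low counts warn", {
  pair <- simulate_independent_null(200, seed = 24)
  expect_error(permutation_null(pair, n_perm = 50),
               class = "gpstest_input_error")
  expect_warning(permutation_null(pair, n_perm = 200, seed = 1),
                 "imprecise")
})

test_that("backends give the same null sample given the same seed", {
  pair <- simulate_independent_null(300, seed = 25)
  nt <- suppressWarnings(permutation_null(pair, 120, seed = 9, backend = "tree"))
  nd <- suppressWarnings(permutation_null(pair, 120, seed = 9, backend = "dac"))
  nn <- suppressWarnings(permutation_null(pair, 120, seed = 9, backend = "naive"))
  expect_equal(nt$d_values, nd$d_values)
  expect_equal(nt$d_values, nn$d_values)
})

test_that("fitted null parameters depend on the number of variants", {
  fits <- lapply(c(1000, 10000), function(n) {
    pair <- simulate_independent_null(n, seed = 26)
    fit_gev(permutation_null(pair, n_perm = 1000, seed = 27))
  })
  # no single reference null: location and scale must differ materially
  expect_gt(abs(fits[[1]]$estimate[["a"]] - fits[[2]]$estimate[["a"]]),
            5 * fits[[1]]$std_errors[["a"]])
})

test_that("the observed statistic sits in the body of its own null", {
  set.seed(28)
  inside <- 0L
  n_trials <- 40
  for (k in seq_len(n_trials)) {
    pair <- simulate_independent_null(1000, seed = 2800 + k)
    d_obs <- gps_statistic(pair)$D
    null <- suppressWarnings(permutation_null(pair, 200, seed = 5800 + k))
    q <- quantile(null$d_values, c(0.01, 0.99))
    inside <- inside + as.integer(d_obs >= q[1] && d_obs <= q[2])
  }
  expect_gte(inside, round(0.85 * n_trials))
})

test_that("the full GPS-GEV pipeline is reproducible and detects comonotone data", {
  pair <- simulate_independent_null(800, seed = 30)
  r1 <- suppressWarnings(gps_gev_test(pair, n_perm = 300, seed = 31))
  r2 <- suppressWarnings(gps_gev_test(pair, n_perm = 300, seed = 31))
  expect_equal(tidy(r1), tidy(r2))
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  expect_true(r1$p_value_exp >= 0 && r1$p_value_exp <= 1)

  u <- runif(10000)
  dep <- gps_pair(u, u^1.5)  # perfectly rank-dependent
  rd <- suppressWarnings(gps_gev_test(dep, n_perm = 300, seed = 32))
  expect_lt(rd$p_value, 0.001)
  expect_lt(rd$p_value_exp, 0.001)
})

test_that("report serialisation writes the single-row TSV contract", {
  pair <- simulate_independent_null(500, seed = 33)
  rep <- suppressWarnings(gps_gev_test(pair, n_perm = 200, seed = 34))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 1)
  expect_named(back, c("method", "statistic", "p_value", "n_variants",
                       "n_perm", "a", "b", "c", "flags"))
  expect_equal(back$statistic, rep$statistic)
  expect_equal(back$method, "gps-gev")
})

test_that("the method dispatcher covers all three tests", {
  pair <- simulate_independent_null(400, seed = 35)
  for (m in c("gps-gev", "gps-exp", "hoeffding")) {
    rep <- suppressWarnings(gps_test(pair, method = m, n_perm = 150, seed = 36))
    expect_equal(rep$method, m)
    expect_true(rep$p_value >= 0 && rep$p_value <= 1)
  }
  expect_equal(suppressWarnings(gps_test(pair, "gps-exp"))$n_perm, 0L)
})
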