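test_that("the GEV cdf honours its closed-form anchor points", {
  for (c in c(-0.3, 0, 0.2, 0.5)) {
    expect_equal(pgev(2, a = 2, b = 0.7, c = c), exp(-1))
  }
  # Gumbel median: x = a - b * log(log(2))
  expect_equal(pgev(1 - 0.5 * log(log(2)), a = 1, b = 0.5, c = 0), 0.5)
  # monotone non-decreasing on a grid, support endpoints respected
  x <- seq(-5, 10, length.out = 200)
  for (c in c(-0.4, 0, 0.3)) {
    p <- pgev(x, a = 1, b = 0.5, c = c)
    expect_true(all(diff(p) >= -1e-14))
    expect_true(all(p >= 0 & p <= 1))
  }
  # below the lower endpoint (c > 0) the cdf is 0; above the upper (c < 0) it is 1
  expect_equal(pgev(1 - 0.5 / 0.3 - 1, a = 1, b = 0.5, c = 0.3), 0)
  expect_equal(pgev(1 + 0.5 / 0.4 + 1, a = 1, b = 0.5, c = -0.4), 1)
})

test_that("quantile and cdf are inverse; random draws follow the cdf", {
  p <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  for (c in c(-0.2, 0, 0.4)) {
    expect_equal(pgev(qgev(p, 2, 0.5, c), 2, 0.5, c), p)
  }
  set.seed(11)
  x <- rgev(5000, a = 2, b = 0.5, c = 0.1)
  ks <- suppressWarnings(
    ks.test(x, function(q) pgev(q, 2, 0.5, 0.1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("maximum likelihood recovers known parameters within 3 SEs", {
  set.seed(12)
  x <- rgev(3000, a = 2, b = 0.5, c = 0.1)
  fit <- fit_gev(x)
  expect_true(fit$converged)
  truth <- c(a = 2, b = 0.5, c = 0.1)
  for (p in names(truth)) {
    expect_lt(abs(fit$estimate[[p]] - truth[[p]]), 3 * fit$std_errors[[p]])
  }
  # support constraint holds at the optimum
  e <- fit$estimate
  expect_true(all(1 + e[["c"]] * (x - e[["a"]]) / e[["b"]] > 0))
})

test_that("the Gumbel boundary is recovered with small fitted shape", {
  set.seed(13)
  x <- rgev(3000, a = 1, b = 0.4, c = 0)
  fit <- fit_gev(x)
  expect_lt(abs(fit$estimate[["c"]]), 0.1)
})

test_that("the optimum matches an independent optimiser on the same likelihood", {
  set.seed(14)
  x <- rgev(2000, a = 3, b = 0.8, c = 0.15)
  fit <- fit_gev(x)
  alt <- suppressWarnings(fitdistrplus::fitdist(
    x, "gev",
    start = list(a = median(x), b = stats::IQR(x) / 2, c = 0.01)))
  # our likelihood at our optimum is no worse than the reference optimiser's
  expect_gte(fit$loglik, alt$loglik - 1e-3)
  expect_equal(unname(fit$estimate), unname(alt$estimate), tolerance = 0.02)
})

test_that("fitting guards against unusable samples", {
  expect_error(fit_gev(rep(1, 200)), class = "gpstest_input_error")
  expect_error(fit_gev(rnorm(50)), class = "gpstest_input_error")
})

test_that("tidy and glance summarise a fit in broom style", {
  set.seed(15)
  fit <- fit_gev(rgev(500, 2, 0.5, 0.1))
  td <- tidy(fit)
  expect_equal(td$term, c("location", "scale", "shape"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 500)
  expect_true(gl$converged)
})

test_that("GEV and exponential p-values obey their closed forms", {
  set.seed(16)
  fit <- fit_gev(rgev(500, 2, 0.5, 0.1))
  a <- fit$estimate[["a"]]
  expect_equal(gps_gev_pvalue(a, fit)$p_value, 1 - exp(-1))
  # monotone non-increasing in D
  ds <- seq(0.1, 10, length.out = 50)
  ps <- vapply(ds, function(d) gps_gev_pvalue(d, fit)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-14))
  expect_equal(gps_exp_pvalue(1 / sqrt(log(2)))$p_value, 0.5)
  expect_equal(gps_exp_pvalue(1e8)$p_value, 0, tolerance = 1e-12)
  expect_equal(gps_exp_pvalue(0)$p_value, 1)
  expect_match(gps_exp_pvalue(0)$flags, "continuity")
})

test_that("a statistic beyond a negative-shape upper endpoint is flagged", {
  fit <- structure(list(estimate = c(a = 1, b = 0.5, c = -0.5)),
                   class = "gev_fit")
  out <- gps_gev_pvalue(5, fit)  # upper endpoint at 1 + 0.5/0.5 = 2
  expect_equal(out$p_value, 0)
  expect_match(out$flags, "support")
})
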