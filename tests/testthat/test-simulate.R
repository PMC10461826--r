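test_that("all generators are seed-deterministic and emit valid pairs", {
  gens <- list(
    function(s) simulate_independent_null(500, seed = s),
    function(s) simulate_overlap_mixture(
      sim_spec(n_snps = 500, pi1_a = 0.02, pi1_b = 0.02, zmean = 4,
               rho = 0.3, seed = s)),
    function(s) simulate_shared_effects(
      sim_spec(n_snps = 500, pi1_a = 0.02, pi1_b = 0.02, n_shared = 5,
               zmean = 4, seed = s)),
    function(s) simulate_ld_blocks(
      sim_spec(n_snps = 500, pi1_a = 0, pi1_b = 0, block_size = 10,
               block_r = 0.5, seed = s))
  )
  for (gen in gens) {
    p1 <- gen(61)
    p2 <- gen(61)
    p3 <- gen(62)
    expect_equal(p1$p_a, p2$p_a)
    expect_equal(p1$p_b, p2$p_b)
    expect_false(identical(p1$p_a, p3$p_a))
    expect_s3_class(validate_gps_pair(p1), "gps_pair")
    expect_true(all(p1$p_a > 0 & p1$p_a <= 1))
  }
})

test_that("null p-values are marginally uniform and traits independent", {
  ok_u <- 0L
  for (s in 1:100) {
    pair <- simulate_independent_null(500, seed = 6000 + s)
    ok_u <- ok_u + (suppressWarnings(ks.test(pair$p_a, "punif"))$p.value > 0.01)
  }
  expect_gte(ok_u, 95)
  pair <- simulate_independent_null(10000, seed = 63)
  expect_lt(abs(cor(pair$p_a, pair$p_b)), 3 / sqrt(10000))
})

test_that("the mixture generator degenerates to independence at pi1 = rho = 0", {
  spec <- sim_spec(n_snps = 5000, pi1_a = 0, pi1_b = 0, rho = 0, seed = 64)
  mix <- simulate_overlap_mixture(spec)
  ind <- simulate_independent_null(5000, seed = 65)
  expect_gt(suppressWarnings(ks.test(mix$p_a, ind$p_a))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(mix$p_b, ind$p_b))$p.value, 0.01)
})

test_that("associated SNPs reach genome-wide significance at the closed-form rate", {
  spec <- sim_spec(n_snps = 100000, pi1_a = 0.01, pi1_b = 0, zmean = 5.5,
                   zsd = 1, seed = 66)
  pair <- simulate_overlap_mixture(spec)
  md <- pair_metadata(pair)
  assoc <- md$assoc_a
  frac <- mean(pair$p_a[assoc] < 5e-8)
  zthr <- qnorm(1 - 2.5e-8)
  expected <- pnorm((5.5 - zthr) / sqrt(2)) + pnorm((-5.5 - zthr) / sqrt(2))
  se <- sqrt(expected * (1 - expected) / length(assoc))
  expect_lt(abs(frac - expected), 3 * se)
  # and the overall closed form agrees with simulation
  overall <- mean(pair$p_a < 5e-8)
  ef <- expected_gws_fraction(0.01, 5.5, 1)
  expect_lt(abs(overall - ef), 3 * sqrt(ef * (1 - ef) / 100000))
})

test_that("null-SNP Z-score correlation matches rho by construction", {
  spec <- sim_spec(n_snps = 20000, pi1_a = 0.01, pi1_b = 0.01, zmean = 4,
                   rho = 0.25, seed = 67)
  pair <- simulate_overlap_mixture(spec)
  md <- pair_metadata(pair)
  nulls <- setdiff(seq_len(20000), c(md$assoc_a, md$assoc_b))
  r <- cor(md$z_a[nulls], md$z_b[nulls])
  expect_lt(abs(r - 0.25), 3 / sqrt(length(nulls)))
})

test_that("shared effects reduce to the mixture when n_shared = 0", {
  s0 <- sim_spec(n_snps = 2000, pi1_a = 0.05, pi1_b = 0.05, n_shared = 0,
                 zmean = 4, seed = 68)
  expect_equal(simulate_shared_effects(s0)$p_a,
               simulate_overlap_mixture(s0)$p_a)
  shared <- simulate_shared_effects(
    sim_spec(n_snps = 2000, pi1_a = 0.05, pi1_b = 0.05, n_shared = 100,
             zmean = 6, seed = 69))
  md <- pair_metadata(shared)
  expect_length(md$shared, 100)
  # shared SNPs carry signal in both traits
  expect_lt(median(shared$p_a[md$shared]), 1e-4)
  expect_lt(median(shared$p_b[md$shared]), 1e-4)
})

test_that("block simulation reproduces within-block correlation", {
  spec <- sim_spec(n_snps = 20000, pi1_a = 0, pi1_b = 0, block_size = 10,
                   block_r = 0.6, seed = 70)
  pair <- simulate_ld_blocks(spec)
  z <- pair_metadata(pair)$z_a
  m <- matrix(z, nrow = 10)  # columns are blocks
  cm <- cor(t(m))  # correlation between within-block positions, across blocks
  within_mean <- mean(cm[upper.tri(cm)])
  expect_lt(abs(within_mean - 0.6), 0.05)
  # block_r = 0 degenerates to the unblocked generator
  s0 <- sim_spec(n_snps = 3000, pi1_a = 0, pi1_b = 0, block_size = 10,
                 block_r = 0, seed = 71)
  unb <- sim_spec(n_snps = 3000, pi1_a = 0, pi1_b = 0, seed = 71)
  expect_gt(suppressWarnings(
    ks.test(simulate_ld_blocks(s0)$p_a,
            simulate_overlap_mixture(unb)$p_a))$p.value, 0.01)
})

test_that("extreme signals are clamped away from p = 0 and recorded", {
  spec <- sim_spec(n_snps = 100, pi1_a = 0.5, pi1_b = 0, zmean = 60,
                   zsd = 0, seed = 72)
  pair <- simulate_overlap_mixture(spec)
  expect_true(all(pair$p_a > 0))
  expect_gt(pair_metadata(pair)$n_clamped, 0)
})

test_that("specification invariants are enforced", {
  expect_error(sim_spec(n_snps = 4), class = "gpstest_input_error")
  expect_error(sim_spec(rho = 1), class = "gpstest_input_error")
  expect_error(sim_spec(zsd = -1), class = "gpstest_input_error")
  expect_error(sim_spec(pi1_a = 0.7, pi1_b = 0.7),
               class = "gpstest_input_error")
  expect_error(sim_spec(pi1_a = 0.01, pi1_b = 0.01, n_shared = 500,
                        n_snps = 1000),
               class = "gpstest_input_error")
  expect_error(simulate_overlap_mixture(
    sim_spec(pi1_a = 0.01, pi1_b = 0.01, n_shared = 10, n_snps = 10000)),
    class = "gpstest_input_error")
  expect_error(simulate_ld_blocks(sim_spec()),
               class = "gpstest_input_error")
})

test_that("the expected significant fraction obeys its limits", {
  expect_equal(expected_gws_fraction(0, 5, 1), 5e-8)
  expect_equal(expected_gws_fraction(0.02, 1e4, 1),
               0.02 + 0.98 * 5e-8, tolerance = 1e-12)
  expect_gt(expected_gws_fraction(0.01, 6, 1),
            expected_gws_fraction(0.01, 4, 1))
})
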