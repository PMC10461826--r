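#' Specify a synthetic paired-GWAS scenario
#'
#' The synthetic generator emulates the statistical structure the tests are
#' sensitive to, without whole-genome LD simulation: per-SNP Z-scores are
#' drawn bivariate standard normal with between-study correlation `rho` at
#' null SNPs (the sample-overlap effect), a fraction `pi1` of SNPs per trait
#' receives a non-null Z-score addend drawn Normal(`zmean`, `zsd`),
#' `n_shared` SNPs are associated in both traits with the same sign-aligned
#' addend, and optional equicorrelated blocks (`block_size`, `block_r`)
#' emulate the residual dependence left by LD pruning at high r-squared.
#' P-values are two-sided: `p = 2 * pnorm(-|z|)` (the GPS tests are
#' agnostic to effect direction).
#'
#' @param n_snps Number of variants.
#' @param pi1_a,pi1_b Fractions of truly associated SNPs per trait.
#' @param n_shared SNPs associated in both traits; at most
#'   `min(round(pi1_a * n_snps), round(pi1_b * n_snps))`.
#' @param zmean,zsd Mean and sd of the non-null Z-score addend.
#' @param rho Null-SNP between-study correlation, in \[0, 1).
#' @param block_size,block_r Optional within-trait LD-block emulation:
#'   blocks of `block_size` SNPs with equicorrelation `block_r` in \[0, 1).
#' @param seed Integer seed; same seed, same pair.
#' @return A validated `sim_spec` list.
#' @export
sim_spec <- function(n_snps = 10000, pi1_a = 0.01, pi1_b = 0.01,
                     n_shared = 0, zmean = 4, zsd = 1, rho = 0,
                     block_size = NULL, block_r = 0, seed = NULL) {
  spec <- list(n_snps = as.integer(n_snps), pi1_a = pi1_a, pi1_b = pi1_b,
               n_shared = as.integer(n_shared), zmean = zmean, zsd = zsd,
               rho = rho, block_size = block_size, block_r = block_r,
               seed = seed)
  .validate_sim_spec(spec)
}

.validate_sim_spec <- function(spec) {
  with(spec, {
    if (n_snps < 5) abort("`n_snps` must be at least 5",
                          class = "gpstest_input_error")
    if (pi1_a < 0 || pi1_a > 1 || pi1_b < 0 || pi1_b > 1) {
      abort("`pi1_a` and `pi1_b` must lie in [0, 1]",
            class = "gpstest_input_error")
    }
    if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1)",
                                   class = "gpstest_input_error")
    if (zsd < 0) abort("`zsd` must be non-negative",
                       class = "gpstest_input_error")
    if (block_r < 0 || block_r >= 1) abort("`block_r` must lie in [0, 1)",
                                           class = "gpstest_input_error")
    if (!is.null(block_size) && block_size < 2) {
      abort("`block_size` must be at least 2", class = "gpstest_input_error")
    }
    n_a <- round(pi1_a * n_snps)
    n_b <- round(pi1_b * n_snps)
    if (n_shared > min(n_a, n_b)) {
      abort(sprintf(
        "`n_shared` (%d) exceeds the smaller associated set (%d)",
        n_shared, min(n_a, n_b)), class = "gpstest_input_error")
    }
    if (n_a + n_b - n_shared > n_snps) {
      abort("associated sets cannot be disjoint: pi1_a + pi1_b too large",
            class = "gpstest_input_error")
    }
  })
  structure(spec, class = "sim_spec")
}

# Base Z-scores: bivariate standard normal with cross-trait correlation rho;
# optionally equicorrelated within blocks of block_size per trait (block
# structure shared across traits only through rho).
.base_z <- function(n, rho, block_size = NULL, block_r = 0) {
  draw_bvn <- function(m) {
    za <- rnorm(m)
    zb <- rho * za + sqrt(1 - rho^2) * rnorm(m)
    list(a = za, b = zb)
  }
  if (is.null(block_size) || block_r == 0) {
    return(draw_bvn(n))
  }
  n_blocks <- ceiling(n / block_size)
  g <- draw_bvn(n_blocks)   # per-block shared factor, cross-trait corr rho
  e <- draw_bvn(n)          # per-SNP residual, cross-trait corr rho
  idx <- rep(seq_len(n_blocks), each = block_size)[seq_len(n)]
  list(a = sqrt(block_r) * g$a[idx] + sqrt(1 - block_r) * e$a,
       b = sqrt(block_r) * g$b[idx] + sqrt(1 - block_r) * e$b)
}

.z_to_p <- function(z) {
  p <- 2 * pnorm(-abs(z))
  n_clamped <- sum(p == 0)
  p[p == 0] <- .Machine$double.xmin
  list(p = p, n_clamped = n_clamped)
}

.simulate_core <- function(spec, generator) {
  spec <- .validate_sim_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_snps
  z <- .base_z(n, spec$rho, spec$block_size, spec$block_r)
  n_a <- round(spec$pi1_a * n)
  n_b <- round(spec$pi1_b * n)
  ns <- spec$n_shared
  assoc <- if (n_a + n_b - ns > 0) {
    sample.int(n, n_a + n_b - ns)
  } else integer(0)
  shared <- head(assoc, ns)
  priv_a <- assoc[seq_len(n_a - ns) + ns]
  priv_b <- assoc[seq_len(n_b - ns) + n_a]
  if (ns > 0) {
    w <- rnorm(ns, spec$zmean, spec$zsd)  # identical, sign-aligned addend
    z$a[shared] <- z$a[shared] + w
    z$b[shared] <- z$b[shared] + w
  }
  if (length(priv_a) > 0) {
    z$a[priv_a] <- z$a[priv_a] + rnorm(length(priv_a), spec$zmean, spec$zsd)
  }
  if (length(priv_b) > 0) {
    z$b[priv_b] <- z$b[priv_b] + rnorm(length(priv_b), spec$zmean, spec$zsd)
  }
  pa <- .z_to_p(z$a)
  pb <- .z_to_p(z$b)
  assoc_a <- sort(c(shared, priv_a))
  assoc_b <- sort(c(shared, priv_b))
  gps_pair(
    pa$p, pb$p,
    metadata = list(
      generator = generator, spec = unclass(spec),
      assoc_a = assoc_a, assoc_b = assoc_b, shared = sort(shared),
      z_a = z$a, z_b = z$b,  # diagnostic: the Z-scores behind the p-values
      n_clamped = pa$n_clamped + pb$n_clamped
    )
  )
}

#' Simulate a fully independent null pair
#'
#' Both p-value vectors i.i.d. Uniform(0, 1), independent across and within
#' traits: the exact null of bivariate independence.
#'
#' @param n_snps Number of variants (>= 5).
#' @param seed Integer seed.
#' @return A `gps_pair` with synthetic variant IDs.
#' @export
simulate_independent_null <- function(n_snps, seed = NULL) {
  if (n_snps < 5) abort("`n_snps` must be at least 5",
                        class = "gpstest_input_error")
  if (!is.null(seed)) set.seed(seed)
  gps_pair(runif(n_snps), runif(n_snps),
           metadata = list(generator = "independent_null",
                           spec = list(n_snps = n_snps, seed = seed)))
}

#' Simulate a null/non-null mixture with sample-overlap correlation
#'
#' Each trait holds a mixture of truly associated and non-associated SNPs,
#' but no associated SNP is shared: the GPS null of no shared signal, with
#' between-study correlation `rho` at every SNP emulating case/control
#' sample overlap. Used to study type-1-error inflation as a function of
#' `rho` and per-trait power.
#'
#' @param spec A [sim_spec()] with `n_shared = 0`.
#' @return A `gps_pair`; metadata records the associated index sets.
#' @export
simulate_overlap_mixture <- function(spec) {
  if (spec$n_shared != 0) {
    abort("`simulate_overlap_mixture()` requires n_shared = 0 (use `simulate_shared_effects()`)",
          class = "gpstest_input_error")
  }
  .simulate_core(spec, "overlap_mixture")
}

#' Simulate shared causal architecture
#'
#' As [simulate_overlap_mixture()], except `n_shared` SNPs are associated in
#' both traits and receive the same sign-aligned addend, inducing shared
#' signal; remaining associated SNPs are trait-private and disjoint.
#'
#' @param spec A [sim_spec()].
#' @return A `gps_pair`.
#' @export
simulate_shared_effects <- function(spec) {
  .simulate_core(spec, "shared_effects")
}

#' Simulate residual LD as equicorrelated blocks
#'
#' Within each block of `block_size` SNPs, base Z-scores are equicorrelated
#' with correlation `block_r` within each trait (the last block is
#' truncated if `n_snps` is not a multiple). This emulates the residual
#' dependence left by LD pruning at a high r-squared threshold, the regime
#' in which Hoeffding's test loses type-1-error control.
#'
#' @param spec A [sim_spec()] with `block_size` set.
#' @return A `gps_pair`.
#' @export
simulate_ld_blocks <- function(spec) {
  if (is.null(spec$block_size)) {
    abort("`simulate_ld_blocks()` requires `block_size`",
          class = "gpstest_input_error")
  }
  .simulate_core(spec, "ld_blocks")
}

#' Expected genome-wide-significant fraction under the mixture model
#'
#' Closed form for the fraction of SNPs expected to exceed a significance
#' threshold: an associated SNP has
#' \eqn{Z \sim N(zmean, \sqrt{1 + zsd^2})} (base standard normal plus the
#' addend), so
#' \deqn{\pi_1 P(|Z| > z_{thr}) + (1 - \pi_1)\, thr}
#' with \eqn{z_{thr} = \Phi^{-1}(1 - thr/2)}. Multiplying by `n_snps` gives
#' the expected count of genome-wide-significant SNPs, the quantity that
#' separates the low-power regime (overlap-induced type-1 inflation) from
#' the controlled regime.
#'
#' @param pi1 Fraction of associated SNPs.
#' @param zmean,zsd Addend mean and sd.
#' @param threshold Two-sided significance threshold (default 5e-8).
#' @return Expected fraction of SNPs exceeding the threshold.
#' @examples
#' expected_gws_fraction(0.01, zmean = 5, zsd = 1)
#' @export
expected_gws_fraction <- function(pi1, zmean, zsd, threshold = 5e-8) {
  stopifnot(pi1 >= 0, pi1 <= 1, zsd >= 0, threshold > 0, threshold < 1)
  zthr <- qnorm(1 - threshold / 2)
  s <- sqrt(1 + zsd^2)
  p_exceed <- pnorm((zmean - zthr) / s) + pnorm((-zmean - zthr) / s)
  pi1 * p_exceed + (1 - pi1) * threshold
}
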