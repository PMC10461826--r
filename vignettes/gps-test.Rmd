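---
title: "Testing for shared genetic architecture with the GPS test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for shared genetic architecture with the GPS test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpstest)
```

## The problem

Two genome-wide association studies (GWAS) of different traits each produce
a p-value per variant. If the traits share genetic architecture — some
causal variants influence both — then small p-values will coincide across
the two studies more often than chance predicts. Estimators of the genetic
correlation quantify such sharing but need thousands of cases to be usable;
for rare diseases they are hopelessly noisy. The GPS (genome-wide
pairwise-association signal sharing) test instead poses a nonparametric
question: are the two p-value vectors, viewed as paired samples over the
same LD-pruned SNP panel, bivariately independent? Rejection is evidence of
*some* sharing of genetic effects, without estimating an interpretable
effect-size parameter.

## The statistic

For p-value vectors $u, v$ over $n$ variants, with $F_U$, $F_V$ the
marginal empirical distribution functions and $F_{U,V}$ the bivariate one,

$$D = \sup_{(u,v)} \sqrt{\frac{n}{\ln n}}\;
\frac{\left|F_{U,V}(u,v) - F_U(u)\,F_V(v)\right|}
     {\sqrt{F_U(u) F_V(v) - F_U(u)^2 F_V(v)^2}}.$$

The weight in the denominator grows as $F_U F_V \to 0$ or $1$, so the
statistic is most sensitive to dependence in the tails — exactly where
coincident association signals live. $D$ depends on the data only through
ranks: it is invariant to strictly increasing transforms of either margin
and symmetric in its arguments, properties the test suite asserts.

Numerical choices we had to make because the definition leaves them open:

* **Evaluation set.** The supremum is evaluated at the $n$ observed pairs;
  the objective is piecewise constant between observed points, so nothing
  is lost.
* **Degenerate points.** Where $F_U F_V = 1$ (every point tied at the
  maximum of both margins at once) the ratio is $0/0$. Such points are
  excluded from the maximum and counted in `n_excluded`, rather than
  silently defined as zero, so the exclusion is visible to the user. If
  *all* points are degenerate — only possible when both vectors are
  constant — the statistic is undefined and a categorised error is raised.
* **Ties.** All three ecdfs use "count $\le$" (maximal rank). In the sweep
  algorithms, a group of points tied in $u$ is inserted into the structure
  before any member is queried, so that $u_j \le u_i$ holds for tied $j$.
  Arg-max ties resolve to the smallest index, for determinism.
* **Exact arithmetic.** Ecdf values are held as integer counts and divided
  by $n$ at the last moment; the three backends are compared on the integer
  counts, so "identical output" means exactly that.

## Bivariate ecdf backends

Computing $F_{U,V}$ at all observed points is the dominant cost. Three
interchangeable backends are provided, all returning identical counts:

* `naive` — two nested loops, $O(n^2)$; the ground-truth oracle.
* `tree` — sweep the points in $u$-order, maintaining a Fenwick
  (order-statistic) tree over $v$-ranks; $O(n \log n)$, the default.
* `dac` — divide-and-conquer dominance counting on dense $u$-ranks with a
  v-sorted two-pointer merge.

The permutation loop uses a dedicated path of the tree backend that
pre-sorts $u$ once and re-uses marginal ranks across replicates —
permuting one margin changes the joint counts but only permutes each
marginal ecdf as a multiset.

## Calibrating the null

Under the null of bivariate independence, the distribution of $D$ is not
well approximated by the originally proposed transformation
$1/D^2 \sim \mathrm{Exp}(1)$: p-values computed that way are visibly
non-uniform under permutation. The package therefore fits a generalised
extreme value (GEV) null, $D \sim \mathrm{GEV}(a, b, c)$, to statistics
recomputed on random permutations of one margin. The GEV cdf convention is

$$G(x) = \exp\!\left(-\left[1 + c\,\frac{x-a}{b}\right]^{-1/c}\right),
\qquad 1 + c\,\frac{x-a}{b} > 0,$$

with the $c \to 0$ Gumbel limit; no internal sign flip is used, so fitted
shapes read directly in this convention. Fitting is by maximum likelihood:
Nelder-Mead on $(a, b, c)$ with an infinite barrier outside the support
constraint, started from probability-weighted-moments and Gumbel
method-of-moments estimates with up to five jittered restarts, relative
log-likelihood tolerance $10^{-8}$. Standard errors come from the
numerically inverted observed information at the optimum.

Key defaults, and why:

* `n_perm = 3000` for single-pair analyses — the point at which parameter
  estimates stabilise relative to their confidence intervals — reduced to
  1,000 inside simulation grids where thousands of fits are needed.
* Fits are **per pair**: GEV parameters vary materially with the number of
  variants, so no global reference null is cached (a test asserts fits at
  1,000 and 10,000 variants differ).
* The GPS-GEV p-value is exactly $1 - G(D)$, floored at 0 with a
  `"p beyond fitted support"` flag when a negative-shape fit places the
  observed statistic beyond the finite upper endpoint $a - b/c$. No
  pseudo-count floor is applied.
* The GPS-Exp p-value is oriented as $p = 1 - \exp(-1/D^2)$ so that larger
  $D$ gives smaller $p$; note its resolution is bounded below by
  $\approx \ln n / n$, one reason the GEV calibration is preferred for
  strong signals.
* One master seed drives the permutation stream; the same seed reproduces
  the null sample exactly.

The fitted GEV diverges from the permutation sample only in the far right
tail, where the empirical tail is lighter; the practical consequence —
asserted in the suite — is that extreme quantiles of the fitted null are
conservative, so GPS-GEV p-values for strongly non-null statistics err on
the safe side. Goodness of fit is checked with an Anderson–Darling test
against the fitted cdf; the p-value treats the parameters as fixed, which
is itself mildly conservative for a composite null (it over-accepts), an
acceptable direction for a diagnostic of fit adequacy.

Uniformity diagnostics follow the "score fresh permutations" design: the
GEV is fitted on 3,000 permutation realisations of a pair and applied to a
further 500 realisations of the same pair, whose p-values are then tested
against Uniform(0,1). Refitting the null on hundreds of independently
simulated pairs would test the same property at several-hundred-fold cost.

## Hoeffding's test as comparator

Hoeffding's classical D statistic (with the conventional $\times 30$
scaling, midranks, and half-credit for ties in the dominance counts) is
included as the canonical general-purpose test of bivariate independence.
Its p-value is computed by permutation — the same machinery as the GPS
null — rather than from asymptotic tables, for exactness at any $n$ and
symmetry of comparison. Hoeffding's test assumes independent observations;
when the SNP panel retains residual LD (pruning at high $r^2$), that
assumption fails and its type-1 error inflates, while the GPS permutation
null — which preserves each margin exactly — does not suffer the same way.
The suite reproduces this contrast with the block simulator below.

## Sample-overlap correlation

Biobank GWAS pairs share controls (and often cases), inducing correlation
$\rho$ between effect estimates at null SNPs. Following Lin and Sullivan,

$$\rho = \left[ n_0 \sqrt{\frac{n_{k1} n_{l1}}{n_{k0} n_{l0}}}
 + n_1 \sqrt{\frac{n_{k0} n_{l0}}{n_{k1} n_{l1}}} \right]
 \Big/ \sqrt{(n_{k0}+n_{k1})(n_{l0}+n_{l1})},$$

with $n_0, n_1$ shared controls/cases and $n_{k0}, n_{k1}$ the controls
and cases of study $k$. The published rendering of this formula is
typographically ambiguous about grouping and mixes subscript orders; the
package fixes the study-then-status order above, which reproduces the
required algebraic endpoints exactly ($\rho = 0$ with no overlap,
$\rho = 1$ for identical studies) and stays in $[0,1]$ over randomised
valid designs. A study paired with itself is defined to have $\rho = 1$,
used only for matrix diagonals.

## What the synthetic generator does and does not emulate

The generator draws per-SNP Z-score pairs $(z_a, z_b)$ bivariate standard
normal with correlation $\rho$ (the sample-overlap effect), adds
$N(\mathrm{zmean}, \mathrm{zsd})$ addends to a fraction $\pi_1$ of SNPs
per trait (identical, sign-aligned addends at the `n_shared` SNPs
associated in both), optionally imposes within-trait equicorrelated blocks
(`block_size`, `block_r`) to emulate residual post-pruning LD, and maps to
two-sided p-values $p = 2\Phi(-|z|)$. Signs are not tracked because the
test is direction-agnostic. Underflowing p-values are clamped to the
smallest positive double and the clamping is recorded in metadata.

Defaults are chosen once to represent a realistic pruned panel: 10,000
SNPs, $\pi_1 = 0.01$ (a percent of the panel truly associated),
$\mathrm{zmean} = 4$, $\mathrm{zsd} = 1$ (marginal signals around
genome-wide-suggestive strength), $\rho = 0$. The closed form
`expected_gws_fraction()` gives the expected genome-wide-significant
fraction $\pi_1 P(|N(\mathrm{zmean}, \sqrt{1+\mathrm{zsd}^2})| > z_{thr})
+ (1-\pi_1)\,thr$, used to classify scenarios as low- or adequately
powered.

What this design captures: marginal signal strength, sharing of signals,
overlap-induced null correlation, and residual LD as exchangeable blocks —
the features the rank-based tests respond to. What it does not: realistic
LD structure from haplotypes (block sizes and correlations vary along the
genome), allele-frequency-dependent power, linkage between causal and
tagging variants, or case-control ascertainment. Passing the simulation
suite therefore demonstrates correctness of the statistical machinery and
qualitative behaviour (conservatism, power ordering, failure modes of the
comparator), not calibrated performance on any particular real cohort.

## Reference experiments and problem sizes

The package's end-to-end checks run at sizes chosen as a compromise
between Monte-Carlo resolution and a single-CPU run: type-1 experiments
use 200 replicate pairs of 10,000 variants with 1,000 permutations each;
the power grid uses 100 replicates per point over
$\mathrm{zmean} \in \{4, 5\}$ and `n_shared` $\in \{25, 100, 200\}$ of 200
associated SNPs per trait (mirroring designs in which the shared count
rises toward the full causal set); the residual-LD comparison uses blocks
of 10 SNPs at $r = 0.8$ versus $r = 0$; the overlap study compares a
scenario with expected genome-wide-significant count below one
($\mathrm{zmean} = 1$) against one with dozens expected
($\mathrm{zmean} = 5$) at $\rho = 0.2$. Rejection proportions are reported
with Wilson 95% intervals throughout.

## A worked example

```{r example, eval = FALSE}
library(gpstest)

# a pair with genuinely shared architecture
spec <- sim_spec(n_snps = 10000, pi1_a = 0.02, pi1_b = 0.02,
                 n_shared = 100, zmean = 5, seed = 1)
pair <- simulate_shared_effects(spec)

report <- gps_gev_test(pair, n_perm = 3000, seed = 2)
report
tidy(report)

# the null machinery behind it
null <- permutation_null(pair, n_perm = 3000, seed = 3)
fit <- fit_gev(null)
tidy(fit)
autoplot(null, fit = fit)
```

## Known limitations

* Inputs must be LD-pruned upstream; the package records but does not
  verify the pruning threshold.
* Variant matching is by exact ID after whitespace trimming; no
  chrom:pos:allele harmonisation or liftover.
* Exactly two traits; no multi-trait extension.
* The permutation null is exchangeability-based: it preserves margins but
  destroys *all* cross-trait dependence, including benign
  overlap-induced correlation — hence the documented type-1 inflation in
  the low-power, high-$\rho$ corner, which disappears once each trait
  carries at least one expected genome-wide-significant effect.
* The supremum-norm construction favours a few strong shared signals over
  pervasive weak sharing; a quadratic-functional statistic with an
  Anderson–Darling-style weight is a natural future variant and is not
  implemented here.
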