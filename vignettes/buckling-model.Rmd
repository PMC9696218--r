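---
title: "An Euler-buckling model of DNA persistence length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An Euler-buckling model of DNA persistence length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnabuckle)
```

## The physical picture

Double-stranded DNA is a semi-flexible polyelectrolyte: locally stiff (its
persistence length $l_p$ is about 50 nm at standard conditions), globally
flexible, and negatively charged along the phosphate backbone.  A short
fragment isolated from a longer chain is held at both ends by the adjacent
fragments, pushed axially by the electrostatic self-repulsion of its own
charges, and shaken by thermal fluctuation.  `dnabuckle` treats the
transition of such a fragment from straight to bent as Euler column
buckling: the fragment's length is the *critical buckling length* $l_{cb}$
at which the combined axial force first reaches the Euler threshold of its
end constraint.

Three ingredients define the model.

**End constraints.**  The mechanical boundary conditions enter through the
classical *effective length factor* $\mu$: the Euler load of a column of
length $L$ is $P = \pi^2 EI / (\mu L)^2$, with $\mu = 1$ for hinge-hinge,
$0.5$ for clamp-clamp, $\approx 0.699$ for clamp-hinge and $2$ for
clamp-free ends.  `mu_from_springs()` generalises these anchors to elastic
restraints: each end carries a rotational spring, the right end additionally
a lateral spring, and the lowest root of the resulting $4 \times 4$
boundary-condition determinant gives $\mu$.  The determinant is scanned on a
fine grid of the dimensionless load parameter and the bracketed root is
bisected to $10^{-12}$ relative; stiffnesses above $10^{8}$ in dimensionless
form are replaced by the exact rigid-limit boundary rows to avoid overflow.
Because only $\mu$ is consumed downstream, the spring layer is a convenience
for interpreting fitted $\mu$ values against the classical anchors.

**Electrostatic force.**  Manning's counterion-condensation expression gives
the axial support reaction generated by backbone self-repulsion,

$$F_{ele} = \frac{k_B T}{Z^2 l_B}\left[(2 Z \xi - 1)\,
\frac{\kappa b\, e^{-\kappa b}}{1 - e^{-\kappa b}} - 1 -
\ln(1 - e^{-\kappa b})\right],$$

with $l_B = q^2 / (4 \pi \varepsilon_0 \varepsilon_r k_B T)$ the Bjerrum
length, $\xi = l_B / b$ the Manning charge density at charge spacing
$b = 0.17$ nm, and $\kappa = 1/\lambda_D$ the inverse Debye length
$\lambda_D = [\varepsilon_0 \varepsilon_r k_B T / (c N_A q^2 Z^2)]^{1/2}$
(molar $c$ converted to a number density with $N_A \times 1000$; the
counterion-only convention, without the factor-of-two ionic-strength sum, is
used deliberately because the force law is formulated against it).  The
prefactor is $k_B T / (Z^2 l_B)$: it yields forces of tens of pN at 0.1 M
monovalent salt and predictions inside the experimental band, whereas the
alternative reading $k_B T Z^2 / l_B$ does not.  The dielectric constant
follows the linear law $\varepsilon_r = 87.74 - 0.4 (T - 293)$, valid for
278–313 K (outside the window the package warns but still extrapolates).

**Thermal force.**  The axial reaction contributed by thermal fluctuation is
$F_{tf} = \sqrt{E A k_B T / l_{cb}}$.  The square-root form is the
internally consistent one: eliminating the stretching modulus through the
worm-like-chain rigidity $EI = k_B T l_p$ (with $I = A R^2/4$, so
$E A = 4 k_B T l_p / R^2$), substituting both forces into the Euler
relation and squaring reproduces term-by-term the explicit persistence-length
expression below, together with both of its degenerate limits.  A linear
reading is dimensionally a squared force over length and reproduces neither.

## The persistence-length map

Setting $P = F_{ele} + F_{tf}$ in the Euler relation and writing
$f = F_{ele}/(k_B T)$ gives, after squaring, a polynomial that is quartic in
$l_{cb}$ and quadratic in $l_p$:

$$f^2 l_{cb}^4 - \frac{4 l_p}{R^2} l_{cb}^3
- \frac{2 \pi^2 l_p}{\mu^2} f\, l_{cb}^2
+ \frac{\pi^4 l_p^2}{\mu^4} = 0.$$

`persistence_from_buckling()` solves this as a quadratic in $l_p$ in closed
form, taking the larger root, which equals the explicit expansion

$$l_p = \frac{1}{\pi^4 R^2}\left[2 \mu^4 l_{cb}^3
+ 2 \mu^3 l_{cb}^{5/2} \sqrt{\mu^2 l_{cb} + \pi^2 R^2 f}
+ \pi^2 R^2 \mu^2 l_{cb}^2 f\right].$$

Two limits pin the coefficients.  With $F_{ele} = 0$ and $\mu = 0.5$ the
expression collapses to the null-isomer law $l_p = l_{cb}^3/(4\pi^4 R^2)$
(an uncharged DNA buckling under the thermal force alone); with the thermal
term dropped it collapses to $l_p = \mu^2 l_{cb}^2 f / \pi^2$.  Both hold
identically in the implementation and are asserted in the tests.

`buckling_from_persistence()` inverts the quartic with the companion-matrix
solver (`polyroot()`), conditioned by rescaling lengths to nm.  Squaring
during the derivation introduces one spurious positive root, so the physical
branch is selected by *round-trip consistency*: the returned root is the one
that maps back to the input $l_p$ within $10^{-6}$ relative.  This is
deterministic and self-validating, unlike smallest-root heuristics.  At
$f = 0$ the closed-form cube root is used directly.  No iterative solver
appears anywhere in the forward/inverse path.

### The three-term decomposition

The bracket above is a sum of three additive contributions, exposed by
`decompose_persistence()`:

* **TODC** ($2\mu^4 l_{cb}^3 / (\pi^4 R^2)$) depends only on the constraint
  pair $(\mu, l_{cb})$ — it is the same at every salt concentration;
* **TWDE** couples constraint and environment weakly: the electrostatic
  scale $f$ enters only under a square root added to $\mu^2 l_{cb}$, so the
  term varies mildly with salt (and equals TODC when $f = 0$ — it does not
  vanish, because the square root retains its constraint part);
* **TSDE** ($\mu^2 l_{cb}^2 f / \pi^2$) is linear in $f$ and dominates the
  salt and temperature dependence.

```{r decomposition}
decompose_persistence(1.021, 5.95e-9, medium(c(0.01, 0.1, 1)))
```

## Fitting salt-dependence data

`fit_dataset()` fits $(\mu, l_{cb})$ to a `(concentration, persistence
length)` table by bounded nonlinear least squares on the nm scale, with the
goodness of fit $r^2 = 1 - \mathrm{SSR}/\mathrm{TSS}$.  Default bounds
($\mu \in [0.3, 2.5]$, $l_{cb} \in [1, 30]$ nm) bracket the full range of
values fitted across the published experiments collected in
`experiment_table()`.  The SSR surface is a shallow curved valley — raising
either parameter inflates the prediction, so the two trade off — and the
optimiser therefore restarts from a seed-deterministic Latin-hypercube
design (`n_starts` points, default 8) and polishes the winner with a tight
gradient pass followed by a simplex refine.  The unweighted SSR is used
because the source datasets report no uncertainties.

A consequence worth stating plainly: at realistic noise levels the
*individual* parameters are weakly identified even though the fitted curve
is excellent.  In the package's own recovery study (5% multiplicative noise,
12 concentrations, 200 replicates — the conditions exercised by the
acceptance suite) the median absolute error is about 0.4 on $\mu$ and 3 nm
on $l_{cb}$, while $r^2$ stays above 0.95.  The same trade-off is visible in
the spread of fitted $\mu$ across the published experiments of a single
constraint class.  Class-level averages (`aggregate_class()`, sample
standard deviation with the $n-1$ denominator, which is the form that
reproduces the published aggregate table from the per-experiment values) are
the robust quantity, not single-dataset estimates.

## The temperature procedure

Temperature enters three ways: through $k_B T$, through
$\varepsilon_r(T)$ inside $F_{ele}$, and through the temperature dependence
of $l_{cb}$ itself.  The last is obtained by a three-step transfer:

1. `fit_lcb_vs_T()` inverts an empirical persistence-length law — by default
   the cyclization result $l_p(T) = (3.19 - 0.00414\,T) \times 10^{-19} /
   (k_B T)$ nm, about 47.6 nm at 298 K — through the buckling polynomial at
   $\mu = 0.5$ (a short circularised molecule is symmetrically constrained,
   hence clamp-clamp) and fits an OLS line $l_{cb}(T) = a + gT$.  The ionic
   condition behind the original cyclization buffer is not recorded with the
   law, so the medium is a required argument here and the fitted gradient is
   condition-dependent; the reference gradient used downstream is
   $-0.0359$ nm/K.
2. `transfer_gradient()` assumes that gradient applies to other constraint
   classes and anchors the line at each class's mean $l_{cb}$ at 298 K,
   giving intercepts of 16.65 nm (suspended, $l_{cb} = 5.95$ nm) and
   19.13 nm (fix-bead, $l_{cb} = 8.43$ nm).
3. `lp_vs_temperature()` maps $l_{cb}(T)$ back to $l_p(T)$, re-evaluating
   $\varepsilon_r$ and $F_{ele}$ at each temperature.

Over 278–313 K (the window where DNA does not denature, also the validity
window of the dielectric law; the default grid is 1 K steps) the predicted
$l_p(T)$ decreases approximately linearly, and the suspended class declines
more steeply than fix-bead — the strongly coupled TSDE term drives both.

## Persistence length from conformation ensembles

For ensembles of chain-axis conformations (in practice: helical axes
extracted from simulation frames; here: synthetic chains), the worm-like
chain end-to-end relation

$$\langle h^2 \rangle = 2 l_p L \left[1 - \frac{l_p}{L}
\left(1 - e^{-L/l_p}\right)\right]$$

is strictly increasing in $l_p$ at fixed contour length $L$, so
`lp_from_msee()` inverts it by bracketed monotone root finding ($10^{-10}$
relative).  Inputs above $L^2$ are unreachable and rejected; inputs at the
rigid-rod limit return `Inf` as an explicit divergence sentinel.

`sample_wlc()` is the synthetic stand-in for trajectory data: a discrete
chain of fixed bond length $\Delta s = L/n$ whose successive tangents
deflect with $p(\cos\theta) \propto e^{\lambda \cos\theta}$, $\lambda$
chosen by Langevin-function inversion so that $\langle\cos\theta\rangle =
e^{-\Delta s / l_p}$, and uniform azimuth.  Its tangent autocorrelation
decays exactly as $e^{-s/l_p}$ in expectation, which the tests verify by
regression on sampled chains.  What it does *not* emulate: sequence-dependent
flexibility, intra-chain electrostatics or excluded volume, and the
correlated frames of a real trajectory (each sampled conformation is
independent).  Estimator behaviour on real trajectory data — including the
known downward bias of apparent $l_p$ for short contour lengths — is
therefore only partially probed by these tests.  For trajectory-ordered
input, `estimate_lp()` accepts a burn-in index to drop unequilibrated
leading frames, and offers both ensemble-level inversion (default) and
per-frame inversion with averaging, since either convention appears in
practice.

Default study sizes (100 segments, 2000 chains at $L = 17$ nm — the scale
of a 50-bp fragment at 0.34 nm/bp) recover an input $l_p = 50$ nm to within
a few percent; the sampling error of the ensemble mean dominates the
discretisation bias at these settings.

## Defaults and numerical choices

| Quantity | Default | Why |
|---|---|---|
| $R$ | 1 nm | DNA cross-section radius used throughout the model |
| $b$ | 0.17 nm | backbone charge spacing in Manning's force law |
| $T$ | 298 K | reference temperature of most source experiments |
| concentration grid | 12–40 log-spaced points, 0.001–4 M | experimental coverage of the salt-dependence data |
| fit bounds | $\mu \in [0.3, 2.5]$, $l_{cb} \in [1, 30]$ nm | brackets all published fitted values (0.489–1.256; 4.18–15.83 nm) |
| noise model | lognormal, CV 5%, mean 1 | multiplicative, unbiased on the natural scale; typical experimental scatter |
| WLC sampler | 100 segments, $\Delta s \ll l_p$ | keeps discretisation bias below sampling error |
| root tolerances | $10^{-12}$ (buckling $\beta$), $10^{-10}$ (WLC), $10^{-6}$ (branch filter) | each an order below the precision any downstream use needs |

Degenerate inputs are handled explicitly rather than by numerical accident:
zero concentration (no screening), non-positive lengths and loads, constant
observation vectors (TSS $= 0$ reports `NA` rather than dividing), a column
with no end restraint (a mechanism, not a buckling problem), and end-to-end
distances beyond the rigid rod all raise informative errors or sentinels.

## Limitations

The model is deliberately coarse: Debye–Hückel/Manning electrostatics (no
Poisson–Boltzmann solver, single salt species per medium), no sequence
dependence, no post-buckling shapes, and no treatment of distributed
substrate adsorption — the adsorbed-DNA experiment in `experiment_table()`
carries the weakest goodness of fit precisely because adsorption acts along
the whole contour rather than at the ends, and its fitted parameters are
excluded from the class aggregates for that reason.  The synthetic data
generator defines the package's test conditions; agreement under those
conditions demonstrates internal correctness and the stated statistical
behaviour, not the fidelity of any particular laboratory dataset.
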