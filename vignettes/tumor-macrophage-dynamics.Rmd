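---
title: "Population dynamics of tumor-cell plasticity and macrophage polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population dynamics of tumor-cell plasticity and macrophage polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtmac)
```

## The system being modelled

`emtmac` implements in-silico co-culture models of two plastic cell
populations in a tumor microenvironment: cancer cells that interconvert
between an epithelial (E) and a mesenchymal (M) phenotype, and macrophages
that are polarized from monocytes (M0) into the classically activated,
tumor-suppressive M1 state or the alternatively activated, tumor-promoting
M2 state.  All populations are fractions of a common carrying capacity
$N_{\max}$ (default 1), and macrophages neither divide nor die, so the total
$M_0 + M_1 + M_2 = M_c$ is conserved exactly along every trajectory; it is
set by the initial condition and acts as a bifurcation parameter in its own
right.

The interactions, taken from the co-culture literature, are:

* logistic growth of E and M limited by the total cell density, with
  M1-induced senescence damping $1/(1+\alpha M_1/(M_1+K_1))$ acting on
  epithelial growth only;
* M1-assisted MET and M2-assisted EMT, each a Hill function of the
  assisting macrophage population (cooperativities $n$ and $m$) competing
  against a saturating *resistance* term: mesenchymal cells resist MET via
  secreted maintenance factors ($M/(M+K_{M0})$), epithelial cells resist EMT
  cooperatively via cell-cell contact ($E^k/(E^k+K_{E0}^k)$, $k = 4$ by
  default);
* polarization of monocytes into M1 by epithelial cells and into M2 by
  mesenchymal cells, with saturating stimuli.

Three nested variants add successively more macrophage plasticity:

* **Variant I** — no M1/M2 interconversion.  The macrophage populations
  freeze once monocytes are exhausted, so equilibria form a *continuum*
  parameterized by the M2 level.
* **Variant II** — constant ($\eta_{120}, \eta_{210}$) plus
  cancer-cell-enhanced ($\eta_{12}, \eta_{21}$) M1/M2 interconversion.
  Equilibria become discrete and the system is bistable in the MET rate
  $\eta_{me}$.
* **Variant III** — M1 macrophages kill epithelial cells (rate $\beta$), and
  the apoptotic factors released (compartment $C$, decay $\beta_c$) convert
  M1 to M2; M2 is converted back to M1 at the constant therapeutic rate
  $\eta_{21}$.  This breaks the E/M symmetry of the network and creates a
  stable cancer-extinction state.

The apoptotic-factor level $C$ is a soluble-species concentration, not a
cell population, so it does not count toward the carrying capacity.

Default rates follow the published co-culture estimates: growth
$\lambda_E = \lambda_M = 1/72\,\mathrm{h}^{-1}$ (three-day doubling), MET
$\eta_{me} = 1/120\,\mathrm{h}^{-1}$, EMT $\eta_{em} = 1/72\,\mathrm{h}^{-1}$,
polarization $\eta_1 = \eta_2 = 1/24\,\mathrm{h}^{-1}$, interconversion and
apoptosis rates $1/72$ and $1/36\,\mathrm{h}^{-1}$, half-saturations $0.1$
in capacity units (1 for the apoptosis-related constants, which are order-of-
magnitude estimates taken at face value).  `model_parameters()` documents
every field; `model3_reference_params()` bundles the variant III
configuration used in the threshold analyses ($m = n = 2$, $k = 4$, with
$M_c = 0.3$ carried by the equilibrium problem).

## Reading of the conversion-flux denominators

The typeset form of the conversion terms admits more than one grouping.  We
fix the reading in which each resistance term is a saturating function of
the resisting population that competes with the macrophage Hill term in the
denominator,

$$\mathrm{met} = \eta_{me} M \frac{M_1^n}{M_1^n + \frac{M}{M+K_{M0}}},
\qquad
\mathrm{emt} = \eta_{em} E \frac{M_2^m}{M_2^m + \frac{E^k}{E^k+K_{E0}^k}},$$

because the accompanying prose states that each resistance "saturates to a
finite value" with half-saturation constants $K_{M0}$ and $K_{E0}$.  We
verified numerically that the plausible alternative grouping (resistance
*decreasing* in the resisting population) destroys the multistability that
is the models' central phenomenon, which supports the reading above.  At
boundary states a flux is defined as zero whenever its leading population
factor is zero, evaluated before any division: conversion is proportional to
the population being converted, so the 0/0 corners are removable.

An open question in the epithelial resistance term is whether its
mesenchymal counterpart should carry a cooperativity of exactly 1; the prose
describes the mesenchymal resistance as non-cooperative and we implement it
as written ($M/(M+K_{M0})$, i.e. cooperativity 1), leaving $k$ free on the
epithelial side.  With $k = 1$ and symmetric constants the two conversion
terms become exactly mirror images, which the test suite exploits as an
exchange-symmetry check.

## Numerical machinery

**Integration.** `integrate_model()` uses `deSolve::lsoda` with tight
tolerances (`rtol` $10^{-9}$, `atol` $10^{-12}$) so the macrophage
conservation law holds to $10^{-8} M_c$ over $5000$-hour runs.  The
derivative is evaluated on the state clamped to the nonnegative orthant, and
small boundary undershoots (below $10^{-8}$ in magnitude, observed when
populations decay to extinction across the flux cut-off at zero) are clipped
to zero; anything larger aborts as a genuine inconsistency.
`run_to_steady()` integrates in 2000-hour chunks until the right-hand-side
residual falls below $10^{-10}\,\mathrm{h}^{-1}$.

**Equilibria.** `find_equilibria()` runs a damped Newton iteration on the
right-hand side with the redundant monocyte row replaced by the conservation
constraint $M_0+M_1+M_2 = M_c$ (the macrophage rows sum to zero identically,
so the unmodified Jacobian is singular).  Seeds cover a lattice of cancer
loads — quarters of the available capacity plus two low-cancer fractions
(1/32, 1/8), added because the low-cancer branches of variant III are
narrow — with M1 at $\{0, \tfrac12, 1\} M_c$, monocytes at zero (cancer-bearing
equilibria require $M_0 = 0$) and $C$ at its quasi-steady value
$\beta E (M_1/(M_1+K_2))/\beta_c$.  Duplicates are merged below $10^{-6}$ in
max norm.  Completeness is empirical, by seed density plus continuation; no
global root certification is attempted.  For variant I the continuum is
represented by `model1_branch()`: on the invariant set
$E + M = N_{\max}-M_c$, $M_1+M_2 = M_c$, $M_0 = 0$, equilibria are the roots
of the one-dimensional MET/EMT flux balance, found by a sign scan refined
with `uniroot`; along the branch the reduced dynamics are gradient-like, so
the $(+,-)$ sign pattern of the balance gives branch stability, which the
tests check against the full Jacobian classification.

**Stability.** Jacobians are central finite differences (relative step
$10^{-6}$), falling back to a second-order one-sided stencil at boundary
coordinates — the second-order stencil matters: a first-order one-sided
difference produces spurious $O(10^{-4})$ eigenvalue errors at the
extinction state.  One structurally zero eigenvalue (conservation) is
expected and discarded at every equilibrium of every variant; variant I
carries a second neutral direction along its continuum, identified by the
eigenvector with the largest projection onto the M1/M2 exchange direction;
fully cancer-free states freeze the monocyte coordinate and add a third.
Classification uses `zero_tol` $= 10^{-7}\,\mathrm{h}^{-1}$; equilibria with
more near-zero eigenvalues than the structural expectation are flagged
marginal rather than silently classified.  Exact ties $E = M$ in the
category labels go to the epithelial-dominated category and are flagged.

**Critical points.** `critical_value()` refines four event types by
bisection to $10^{-4}\,\mathrm{h}^{-1}$: extinction stabilization (sign
change of the extinction state's leading non-neutral eigenvalue), folds
(loss of a continuation-tracked branch; the tracker walks in sub-steps so
only a genuine branch loss fails), Hopf points (sign change of the leading
complex-pair real part along a tracked branch) and the sole-extinction
threshold (largest parameter at which any stable cancer-bearing equilibrium
exists, multi-start at every probe).  Continuation is natural-parameter with
nearest-neighbour branch stitching — the system is five- or six-dimensional,
so robustness was preferred over pseudo-arclength elegance.
`critical_point_catalog()` combines probing, branch walking and bisection
into a single sweep summary.

## What the reference analysis finds

Under the variant III reference configuration the catalog contains, in
increasing order: the extinction-stabilization point at
$\eta_{me}^a = \lambda_M (1 - M_c) \approx 0.0097\,\mathrm{h}^{-1}$ (this
value is *exact*: at the extinction state the mesenchymal row of the
Jacobian is diagonal, because the MET resistance vanishes as $M \to 0$ and
the $M_1^n$ factors cancel for every $n$), a pair of folds bounding a
low-cancer branch pair near $0.045$–$0.048\,\mathrm{h}^{-1}$ with a Hopf
point at $\approx 0.0464\,\mathrm{h}^{-1}$ between them, and the
sole-extinction threshold at $\approx 0.0861\,\mathrm{h}^{-1}$ where the
last stable cancer-bearing state collides with the low-cancer saddle.  The
low-cancer intermediate branch exists but never stabilizes under this
configuration (a real eigenvalue stays positive through the Hopf crossing),
so at most two attractors — extinction and the mesenchymal-dominated state —
coexist.  The `analysis/03` script reports the same catalog for all four
$(m, n)$ cooperativity combinations.

Lowering the mesenchymal growth rate pulls the sole-extinction threshold
down monotonically across the probed grid
$\lambda_M \in \{1/72, 1/100, 1/150, 1/500, 1/1000\}\,\mathrm{h}^{-1}$,
crossing below the experimentally estimated MET rate
$1/120\,\mathrm{h}^{-1}$ by $\lambda_M = 1/1000\,\mathrm{h}^{-1}$; raising
the macrophage load $M_c$ acts in the same direction.  The therapeutic
reading — combine MET induction with growth suppression — survives the
quantitative caveat below.

**Caveat on printed thresholds.**  Published analyses of this model family
report the corresponding thresholds at larger values (extinction
stabilization near $0.063\,\mathrm{h}^{-1}$ and a sole-extinction threshold
near $0.15\,\mathrm{h}^{-1}$), with a stable low-cancer window in between.
Those numbers are not reproducible from the equations as typeset: the
extinction-stabilization point is analytically pinned at
$\lambda_M(1-M_c)$ for *any* choice of the cooperativities or $M_c$, which
rules the printed value out by a factor of six.  This package implements the
equations as written; its thresholds are self-consistent (ordering,
stability changes and relaxation dynamics all agree across independent code
paths) but differ numerically from the printed ones.

## The synthetic-data generator and the association stage

The association stage mirrors a standard tumor-cohort analysis: per-gene
Pearson correlation with a per-sample EMT score on $[0, 2]$ (0 fully
epithelial, 2 fully mesenchymal; the score itself is an external input, not
computed here), a median split of samples into EMT-high (strictly above the
median — ties go to the low group, following the "higher than the median"
definition) and EMT-low, an unpaired two-sided t-test per gene with a 95%
confidence interval of the mean difference, and gene-set counts of
significantly up/down members.  Welch's test is the default (the
equal-variance assumption is not stated in the source procedure; Welch is
the safer choice and the pooled version is available via `var_equal`); raw
p-values are reported at $\alpha = 0.05$ with no multiple-testing
correction, matching the procedure being emulated, and a Benjamini-Hochberg
adjustment can be applied downstream via `p.adjust` if desired.

`generate_expression_dataset()` plants either an exact population
correlation $\rho$ (gene $= \rho z_{\mathrm{score}} + \sqrt{1-\rho^2}
\varepsilon$ on standardized scores) or a standardized mean shift $\delta$
between the median-split halves, on log-scale values with Gaussian noise and
a mandatory seed.  Scores are uniform on $[0, 2]$ by default, with a bimodal
truncated-normal mixture available to mimic epithelial/mesenchymal
subpopulations.  The generator emulates *only* the statistical contract the
association stage consumes — continuous scores, per-gene linear signal,
independent Gaussian noise.  It does not mimic real tumor cohorts: no
heavy-tailed expression, no gene-gene correlation, no batch effects, no
tumor-purity dilution.  Passing calibration tests therefore validates the
statistical machinery, not robustness to those real-data features.

`sample_initial_conditions()` draws dynamical starting points on the
conserved manifold: cancer load uniform in a chosen range split uniformly
between E and M, and $M_c$ split over (M0, M1, M2) by a uniform simplex
draw.

## Problem sizes used in the bundled runs

The analysis scripts and the acceptance script run on one CPU in a few
minutes each: critical-point catalogs probe 11–13 parameter values with a
$4\times10^{-4}$ continuation step and $10^{-4}$ bisection width; variant I
sweeps use 121–201 M2 grid points; association calibration uses 1000 null
genes at 286 samples, 200 genes for correlation recovery at 500 samples,
and 500 genes for the power check.  These sizes put Monte-Carlo noise well
inside the asserted bands; they can be scaled up freely.

## Known limitations

Beyond the quantitative caveat above: no spatial structure (migrating
mesenchymal cells would change the contact interactions), no senescent-cell
bookkeeping (senescence only damps epithelial growth), binary EMT and
polarization states rather than a continuum, no limit-cycle continuation
(the unstable cycle born at the Hopf point is detected only via its origin),
and empirical rather than certified equilibrium completeness.
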