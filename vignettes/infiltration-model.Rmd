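---
title: "Modelling immune-cell infiltration in a gut-on-a-chip: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling immune-cell infiltration in a gut-on-a-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infilsim)
```

## The system

Three-channel microfluidic gut chips place a pool of peripheral blood
mononuclear cells (PBMCs) in a bottom channel, a collagen matrix with
resident macrophages in the middle channel, and an epithelial tube in the
top channel. Time-lapse imaging every 2 h tracks PBMCs as they infiltrate
the matrix towards the epithelium, with or without a cytotoxic T-cell
bispecific antibody. `infilsim` models this infiltration mechanistically,
quantifies segmented imaging exports into binned cell counts, and
calibrates the model to those counts with a surrogate-based global
optimiser.

## The model

We track a 1-D PBMC density $\rho(x,t)$ and a generic chemoattractant
concentration $\alpha(x,t)$ on $x \in [0,1]$ (bottom-channel interface at
$x=0$, top of the epithelium at $x=1$, matrix/epithelium interface at
$x_t$; 350 µm in physical coordinates, mapped through a configurable ROI
length):

$$\rho_t = (D_\rho(x)\,\rho_x)_x - (\chi(x,\alpha)\,\rho\,\alpha_x)_x - \xi\rho,$$
$$\alpha_t = (D_\alpha(x)\,\alpha_x)_x + \eta_1 \mathbf{1}_{x<x_t}
  + \eta_2\,\rho\,\mathbf{1}_{x>x_t} - \kappa\rho\alpha - \nu\alpha.$$

Motilities are piecewise constant — in the epithelium $D_\rho$ and the
chemotactic scale are divided by $\mu_\rho>1$, and $D_\alpha$ by
$\mu_\alpha>1$ — reflecting that both cells and cytokines move less
freely through tissue than through matrix. The chemotactic sensitivity
follows the receptor law $\chi = \tilde\chi(x)\,k/(k+\alpha)^2$: at
concentrations far above the saturation constant $k$, cells can no
longer resolve the gradient. $\xi$ absorbs the small sideways loss of
cells out of the imaged region. Boundary conditions: zero total flux for
both species at $x=1$; at $x=0$ the attractant leaks diffusively
($\alpha_x = \zeta\alpha$) and PBMCs enter at the chemotactically driven
rate $\chi(0,\alpha_0)\,\zeta\,\alpha_0\,\tilde\rho$, where $\tilde\rho$
is the constant pool density in the bottom channel. The initial state is
an empty domain with $\alpha$ at the steady state sustained by
macrophage production alone.

The production indicators are closed at $x_t$ in the continuum statement;
since $x_t$ lies on a cell face of the discretisation (a measure-zero
set), production is assigned by cell-centre position and no cell is
ambiguous.

## Discretisation

The solver is a conservative finite-volume scheme on a uniform grid
(default 200 cells), chosen because every boundary condition is a flux
statement:

* the interface $x_t$ is snapped to the nearest interior face, so the
  coefficient jump coincides with a face;
* diffusive face fluxes use the harmonic mean of the adjacent cell
  diffusivities, which is exact for a piecewise-constant jump;
* the chemotactic term is treated as advection with face velocity
  $\chi\,\alpha_x$ (central difference of $\alpha$) and first-order
  upwinding of $\rho$, which keeps the density nonnegative;
* time integration is method-of-lines with `deSolve::lsoda`
  (`rtol = 1e-6`, `atol = 1e-9`); states are interleaved
  $(\rho_1,\alpha_1,\rho_2,\dots)$ so the Jacobian is banded (bandwidth
  3), which is what makes a single 48 h solve take well under a second;
* integrator undershoots more negative than $-10^{-8}$ never occur in
  practice; anything smaller is clamped to zero on output.

The initial attractant profile is obtained by solving the linear steady
problem *on the same stencil* (not by time marching), so its discrete
time derivative vanishes identically at $t=0$. An independently derived
closed form for the two-region steady problem (cosh/sinh bases joined by
continuity of value and diffusive flux, with the top-channel branch
normalised to stay well conditioned for steep epithelial decay) serves
as the convergence oracle: the finite-volume profile matches it to
better than $10^{-3}$ relative error at 200 cells with observed order
close to 2.

## Quantification

Watershed segmentation occasionally leaves clumps of touching cells as
one region. `declump()` converts region area to a cell count by rounding
area/50 µm² half-up, never below one cell, so any region above 75 µm²
counts as at least two; the half-up convention at exactly 75 µm² is the
one that makes that boundary statement self-consistent. Counts are
binned into 20 equal-width, half-open bins over the ROI (last bin
closed). Distance travelled is the recorded position coordinate, with
clumps weighted by their declumped count — whether the original analysis
weighted clumps this way is not documented, so the choice is stated here
rather than hidden.

## Calibration

The objective is the unweighted sum over all frames and bins of squared
differences between observed counts and the model's bin integrals
$\int_{bin}\rho\,dx$ (exact for the piecewise-constant FV density). No
amplitude factor is introduced: $\tilde\rho$ already absorbs overall
scale. Scale-type parameters are searched in $\log_{10}$ space,
geometric ones ($x_t$, $\zeta$) linearly. A failed simulation returns
$10^3\times$ the all-zero-prediction objective instead of raising, so
the optimiser's surrogate stays finite and learns to avoid the region.

The optimiser (`krig_optimize()`) is an efficient-global-optimisation
loop: a Latin hypercube design of $10d$ points, an ordinary-Kriging
surrogate with anisotropic Matérn-5/2 kernel fitted by profile maximum
likelihood (5 restarts, length scales in $[0.05, 2]$ on the unit box,
nugget $10^{-10}$ with automatic escalation), and batches of four
proposals per iteration: the expected-improvement maximiser found by
differential evolution (rand/1/bin, population $15d$, $F=0.8$,
$CR=0.9$, 100 generations), the predictive-mean minimiser, the
predictive-sd maximiser, and constant-liar EI repeats. Proposals closer
than $10^{-3}$ to each other or to training points are replaced by
uniform draws. The surrogate is fitted to $\log_{10}$ of the objective,
which spans decades for sum-of-squares landscapes. After five stagnant
batches (relative improvement $<10^{-3}$) the search box is halved
around the incumbent, at most four times; the run stops at the
evaluation budget or when the maximal EI falls below
$10^{-6}\,|f_{\min}|$ on the transformed scale. On a 4-D convex
benchmark the incumbent reaches $10^{-5}$ within 120 evaluations; on a
bimodal 2-D landscape the deeper well is located within 80.

## Synthetic study data

Because the raw imaging exports are available only on request, the
package generates study-shaped data itself: 8 control + 8 targeted
wells, imaged every 2 h to 48 h, ROI 1000 µm with the interface at
350 µm. Counts are drawn independently per frame and bin as Poisson
around the model's expected bin integrals (noise-free mode rounds them
instead); cells are placed uniformly within their bin; singleton areas
are lognormal (median 40 µm², $\sigma_{\log}=0.25$) and each cell is
merged into a clump with a same-bin partner with probability 0.1, areas
adding, so declumping is genuinely exercised. Two things this generator
deliberately does not emulate: frame-to-frame persistence of individual
cells (only binned counts feed the objective, so track-level structure
is irrelevant to calibration but means the data cannot test tracking
statistics), and the exact total-count contrast between antibody
conditions (see below).

The ground-truth parameters (`default_params()`) were fixed once to
reproduce the qualitative phases reported for this class of experiment:
entry and transit through the matrix over the first day, accumulation of
the leading cells in the grid cell adjacent to the interface, and
saturation of the total count (<1% change per 2 h frame by 48 h), with
per-well totals of order $10^2$. Two of the choices deserve comment.
First, $\mu_\alpha = 10^6$ treats the epithelium as essentially
impermeable to the attractant. The steady attractant maximum always
lies strictly inside the matrix channel (the epithelial side drains it),
and the drain scales with $\sqrt{D_\alpha\nu/\mu_\alpha}$; only a
near-impermeable barrier moves the maximum — and with it the cell
swarm — to within one grid cell of the interface. Second, the targeted
condition differs from control only through $\eta_2>0$. With an
impermeable barrier, epithelium-released attractant cannot diffuse back
to $x=0$, so the target-engagement effect appears mainly as a
redistribution (cells pulled across the interface, raising the mean
infiltration distance by ~80 µm) and a mild total increase, not the
several-fold total contrast seen in vitro. The divergence-timing
signature — no between-condition difference before the leading cells
reach the interface, growth afterwards — is preserved, and that is the
property the analysis layer tests.

## Identifiability

The boundary influx $\chi(0,\alpha_0)\,\zeta\,\alpha_0\,\tilde\rho$
depends on $\zeta$ and $\tilde\rho$ essentially through their product
whenever the $x=0$ leak is a minor term in the attractant budget (here
the influx scales as $\zeta^{0.89}$ at fixed $\tilde\rho$), so without
direct cytokine measurements only $\zeta\tilde\rho$ is practically
identifiable. `contour_scan()` exposes this: on a $10\times10$ grid over
$\tilde\rho\in[0,250]$, $\zeta\in[0,1]$ the per-row best $\zeta$ is
nonincreasing in $\tilde\rho$ — a reciprocal valley of equally good
fits. The round-trip test quantifies the flip side: fitting
$(\tilde\rho,\zeta)$ to noise-free synthetic data recovers the *product*
to within a few per cent (the individual parameters only to the valley).
Raw sum-of-squares is scanned; a $\log_{10}$ view with a $10^{-12}$
floor is provided for display. Residual maps and condition-difference
surfaces aggregate by raw sums, so consistent misfit accumulates rather
than averaging away.

## Problem sizes and numerical guards in the test suite

The suite runs entirely on generated data: steady-state convergence on
50–400 cells; dynamics on 80–200 cells over 16–80 h; positivity over 50
random admissible parameter draws; optimiser benchmarks over 10 seeds at
budgets 80–120; one noise-free and one Poisson calibration at budgets
120–200; a $10\times10$ identifiability scan; Monte-Carlo checks of the
generator with 200–400 replicates (the expected declumped total uses a
brute-force expectation of the clump-merge model as its oracle, since
merging two small cells can legitimately lose a count). These sizes keep
the default run in the minutes range on one core while leaving every
tolerance at the value stated by the corresponding analysis.

## Known limitations

* One spatial dimension: no lateral structure within channels.
* Epithelial cells and their apoptosis are not modelled; target-induced
  release is a density-proportional source, which overstates release
  once widespread epithelial death would deplete the target.
* The independent-Poisson count model cannot represent cell tracks or
  overdispersion from clustered entry.
* The impermeable-epithelium idealisation trades the between-condition
  total contrast for correct interface accumulation; modelling the
  epithelial compartment explicitly would be the way to recover both.
* $\zeta$ and $\tilde\rho$ are individually unidentifiable from count
  data by construction; fits should be read through the product.
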