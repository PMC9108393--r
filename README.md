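# infilsim

Mechanistic modelling and calibration of immune-cell infiltration in a
three-channel gut-on-a-chip.

Microphysiological gut chips recapitulate T-cell infiltration into
epithelial tissue: peripheral blood mononuclear cells (PBMCs) in a
bottom channel migrate through a macrophage-laden collagen matrix
towards an epithelial tube, imaged every 2 h. Whether a cytotoxic
T-cell bispecific antibody changes those spatiotemporal dynamics — and
through which mechanism — is hard to read off summary statistics alone.
`infilsim` provides the quantitative layer: a chemotaxis
partial-differential-equation model of the infiltrating cell density, a
pipeline that turns segmented-particle imaging exports into binned cell
counts, a Kriging-surrogate global optimiser that fits the model to
those counts, and identifiability/condition-difference analyses. A
synthetic-data generator reproduces the 16-well study structure so every
stage is testable without access to raw imaging data.

## The model

PBMC density ρ(x, t) and chemoattractant α(x, t) on the unit interval
(bottom-channel interface at x = 0, matrix/epithelium interface at
x_t, top of the epithelium at x = 1):

    ρ_t = (D_ρ(x) ρ_x)_x − (χ(x, α) ρ α_x)_x − ξρ
    α_t = (D_α(x) α_x)_x + η₁·1{x<x_t} + η₂ρ·1{x>x_t} − κρα − να

with receptor-law sensitivity χ = χ̃(x)·k/(k+α)², piecewise-constant
motilities (divided by μ_ρ, μ_α > 1 in the epithelium), no flux at
x = 1, attractant leak α_x = ζα at x = 0, and chemotactically driven
influx χ(0, α₀)·ζ·α₀·ρ̃ from the bottom-channel pool ρ̃. The system is
solved by a conservative finite-volume scheme (harmonic-mean face
diffusivities, upwinded chemotactic flux, stiff method-of-lines
integration) from an empty domain with α at its macrophage-sustained
steady state. Details and design rationale are in the methods vignette
(`vignettes/infiltration-model.Rmd`).

## Worked example

```r
library(infilsim)

## forward simulation of the control (non-targeting antibody) condition
p <- default_params("control")
sol <- simulate_infiltration(p, 200, seq(0, 48, by = 2))
sol
#> <infil_solution> 25 times (0..48 h), 200 cells; final total = 154.28 cells
round(sol$total_cells[c(7, 13, 25)], 1)   # totals at 12, 24, 48 h
#> [1] 100.5 136.6 154.3

## a full synthetic 16-well study, quantified at 48 h
ds  <- study_design(seed = 1)
dat <- generate_dataset(ds)
summarize_infiltration(dat$table, 48)
#>   condition n_experiments mean_total_cells mean_distance_um
#> 1      DP47             8           147.75         220.4263
#> 2   D66-ESK             8           152.50         307.7014
```

The totals rise steeply over the first day and then saturate (154.3
cells at 48 h, less than 1% change per frame late on), with the density
maximum sitting in the grid cell adjacent to the 350 µm interface — the
accumulation phase seen in the imaging. In the synthetic study the
targeted condition (`D66-ESK`) pulls cells across the interface: its
mean infiltration distance is ~87 µm larger than control at 48 h.

Fitting uses a fit specification plus the surrogate optimiser:

```r
bc   <- bin_counts(dat$table[dat$table$experiment_id == "ctrl_1", ], 1000)
spec <- fit_spec(
  free  = list(rho_tilde = list(lower = 10, upper = 400, log10 = TRUE),
               zeta      = list(lower = 0.05, upper = 1)),
  fixed = ds$params_control, roi_length_um = 1000)
fit <- fit_infiltration(bc, spec, budget = 200, seed = 1)
```

Only the product ζρ̃ is practically identifiable from count data;
`contour_scan()` draws the reciprocal valley that shows why.

## Command line

A thin wrapper over the `run_*()` pipeline functions is installed at
`inst/cli/infilsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/infilsim.R", package="infilsim"))')" \
    synth --config study.yaml
```

Subcommands `simulate`, `synth`, `quantify`, `fit`, `scan` each read a
YAML/JSON config, write CSV/JSON artifacts plus a manifest (config
hash, seed, package version), and exit 0/1/2 for success / config
error / runtime failure.
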