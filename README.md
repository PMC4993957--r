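# fermga

Surrogate-assisted optimization of a submerged-fermentation medium for
flavonoid production by the medicinal fungus *Phellinus igniarius*.

Flavones are secondary metabolites of *P. igniarius* with antioxidant and
anticancer value, and their yield depends on nine medium components:
glucose, maltose, mannitol, corn powder, yeast extract, cupric sulfate,
sodium chloride, ferrous sulfate and vitamin B1. Screening that
nine-dimensional concentration space in the wet lab is impractical, so
`fermga` implements the hybrid strategy used in fermentation-design
studies: train a small neural-network surrogate on measured
condition→yield records, then maximize the surrogate with a genetic
algorithm. It is aimed at bioprocess researchers who want a reproducible,
seed-auditable implementation of that workflow, including its validation
against synthetic ground truth.

## Method

* **Surrogate.** A 9–11–1 feedforward network
  `ŷ = W₂ tanh(W₁x + b₁) + b₂` on min–max-scaled inputs/targets
  (`y = (x − x_min)/(x_max − x_min)`, per training column), trained by
  Levenberg–Marquardt backpropagation — damped Gauss–Newton steps
  `(JᵀJ + λI)δ = −Jᵀr` with adaptive λ — or by Møller's scaled conjugate
  gradient. Default stopping: scaled MSE ≤ 0.019 or 1000 epochs. The
  linear output is unbounded on purpose: optimization requires
  extrapolation above the training maximum.
* **Optimizer.** A real-coded GA over the bounded concentration box
  (g/L: 0–40, 0–40, 0–40, 0–100, 0–100, 0–0.5, 0–10, 0–0.5, 0–0.1):
  roulette-wheel selection `P(xᵢ) = f(xᵢ)/Σⱼf(xⱼ)` (generation-shifted to
  non-negative fitness), whole-arithmetic crossover (p = 0.8),
  uniform-reset mutation (p = 0.05 per gene), one elite, population 300,
  200 generations.
* **Pipeline.** Multi-seed ensembles of (train → optimize), per-component
  summaries of the resulting optima, a synthetic concave response-surface
  generator with known optimum for end-to-end recovery validation, and a
  CLI. The 25-record training table and the 10 published optimized
  conditions ship as plain-CSV fixtures.

## Worked example

```r
library(fermga)

fit <- fit_surrogate(table1_fixture(), seed = 1)
fit
#> Flavonoid-yield surrogate: 9-11-1 network (tanh/linear), 25 training records
#>   trainer: levenberg_marquardt, 21 epochs, final scaled MSE 0.0189703 (reached target)
#>   init seed 1; scaler range [0, 1]
```

The fit reaches the conventional scaled-error target (0.019) in 21
Levenberg–Marquardt epochs; with 122 parameters for 25 records this is an
interpolating surrogate, not a generalizing model. The usual methods work:
`predict(fit, newdata)`, `fitted`, `residuals`, `coef`, `summary`,
`plot` (convergence trace and observed-vs-fitted).

```r
ens <- run_hybrid(table1_fixture(), hybrid_config(n_runs = 10, seed = 1))
ens
#> Hybrid surrogate + GA ensemble: 10 runs (0 failed)
#>   surrogate-predicted best yield (ug/mL): median 5136.3, mean 5879.4, range [4493.6, 7930.3]
#>   coefficient of variation: 0.231
#>   note: every run predicts above the training maximum (1610 ug/mL);
#>   these are surrogate extrapolations, not measurements
```

Every optimized yield is a surrogate prediction far above the training
maximum because the stated search box lies entirely outside the training
envelope in three components (cupric sulfate, ferrous sulfate, vitamin
B1); the ensemble reports that extrapolation per run
(`ens[[1]]$extrapolation`) instead of hiding it. See the vignette
(`vignettes/medium-optimization.Rmd`) for why the extrapolated magnitude
is not identifiable from the training data.

Published summaries of the optimized conditions can be checked against the
packaged table:

```r
summarize_results(table2_fixture(), reported = table2_reported_means())
#>              column     mean reported matches_printed
#> 1           glucose   15.102   15.100            TRUE
#> 2           maltose   15.264   15.264            TRUE
#> 3          mannitol   29.827   29.830            TRUE
#> 4       corn_powder    5.241    5.230           FALSE
#> ...
```

Glucose (15.1), maltose (15.264) and mannitol (29.83) reproduce the
printed averages exactly; the remaining printed averages are
arithmetically inconsistent with the printed table cells and are flagged,
including the sodium-chloride/ferrous-sulfate pair whose printed column
headers are evidently swapped.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fermga.R",package="fermga"))')" reproduce --runs 10 --seed 1
```

Subcommands: `train`, `optimize`, `select-hidden`, `synth`, `reproduce`;
each logs every seed and writes CSV/JSON artifacts.

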