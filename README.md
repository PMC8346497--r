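# indiref — indirect reference intervals from real-world laboratory data

Clinical reference intervals (the 2.5th–97.5th percentiles of an analyte in
a non-pathological population) are conventionally established by sampling
at least 120 healthy individuals — expensive, slow, and often infeasible in
pediatrics and geriatrics. Routine laboratory databases hold the same
information, mixed with an unknown share of pathological results. `indiref`
separates the two: it models the non-pathological component as a Box–Cox
transformed normal distribution

> t<sub>λ</sub>(X) = (X<sup>λ</sup> − 1)/λ ~ Normal(μ, σ²),  λ ∈ [0, 1.5]

and fits it by *inverse modelling* — candidate models predict expected
counts in an overlapping-bin histogram of the original measurement units,
are screened by an asymmetric 99% Poisson confidence band (pathological
admixture can only inflate counts, so the band tightens upward as the
estimated contamination grows), and are scored by a regularized Poisson
negative log-likelihood

> LL = − Σ<sub>i∈S</sub> [ln f(h<sub>i</sub> | m<sub>i</sub>) + ln h<sub>i</sub>] / √s

over the selected bins S, minimized by a multi-level grid search over
(λ, μ, σ) and the non-pathological fraction P. Reference limits are the
quantiles of the fitted component; bootstrap resampling yields confidence
intervals. A mixture simulator, a simulated direct-method baseline, and
benchmark scoring (mean percentage error, relative bias, total-error
categories) reproduce the method's evaluation end to end.

## Worked example

The package ships a small synthetic creatinine dataset: 2,500 values from a
non-pathological component with true limits (49, 73) µmol/L, contaminated
with 15% pathologically low (25–50) and 20% pathologically high (70–126)
results — about a third of the data are disease.

```r
library(indiref)
f   <- system.file("extdata", "crea_synthetic.csv", package = "indiref")
imp <- read_values(f)
#> 2500 usable values from '...' (excluded: 0 non-numeric, 0 non-finite, 0 non-positive)
est <- estimate_reference_interval(imp$values)
print(est)
#> Reference interval (2.5% - 97.5% of the non-pathological distribution)
#>   lower limit: 49.76
#>   upper limit: 71.93
#>   fitted model: lambda = 0.714, mu = 24.82, sigma = 1.75, P = 0.585
#>   n used: 2500 (0 excluded)
```

Despite 35% contamination the estimated limits land within ~1.5% of the
generating component's true quantiles; `P` is the fraction of the dataset
the fit attributes to the non-pathological component. Add bootstrap
confidence intervals with `bootstrap_ci(imp$values, n_boot = 200, seed = 1)`
(each replicate refits the whole pipeline, so expect a few seconds per
replicate at this lattice resolution).

The same operations are scriptable from a shell:

```sh
exec/indiref estimate  --input results.csv --boot 200 --seed 1 --format json
exec/indiref simulate  --analyte TSH --cell 3 --seed 7 --out tsh.csv
exec/indiref benchmark --analytes TSH,CREA --seeds 5 --out bench
```

## Simulation benchmark

`analyte_specs()` loads six synthetic analyte designs (ALP, CREA, Hb, FT4,
TSH, GGT) spanning log-normal to Gaussian shapes, each with a matrix of
pathological contamination cells (0–30% per side). `run_benchmark()`
estimates reference intervals on every cell × seed with the indirect
method and with simulated direct-method cohorts (N = 120/400), and scores
every limit against the generating component's quantiles by total-error
category, mean percentage error and relative bias. See the vignette
(`vignettes/indirect-reference-intervals.Rmd`) for the model, the design
decisions and the limitations.

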