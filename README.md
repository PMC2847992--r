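# respflux

Quantifying the degree of respiration in budding yeast and ranking the
transcription factors that regulate it.

Yeast shifts between fermentation and respiration depending on the carbon
source (glucose → almost pure fermentation, pyruvate → pure respiration,
galactose in between). `respflux` implements the full quantitative chain
for studying that shift, aimed at systems biologists working with
small-scale batch cultures, ¹³C labeling and GFP-reporter libraries:

* **physiology** — maximum specific growth rate μ from sliding-window
  regression of log OD₆₀₀, uptake/secretion rates q = s·μ from
  concentration-vs-CDW slopes, biomass yields 1/(|s|·MW);
* **isotopomer** — correction of GC-MS mass-isotopomer distributions
  (MDVs) for natural isotope abundance (convolution matrix + non-negative
  least squares) and unlabeled biomass;
* **flux ratios** — the fraction R of a pool fed by one of two converging
  pathways from MDV mixing, and the respiratory TCA flux
  v_TCA = v_ana·(1−R)/R from the anaplerosis/TCA split;
* **net fluxes** — constrained weighted least squares on a stoichiometric
  model (exact mass balance, irreversibility bounds, ratio ranges) and the
  *degree of respiration*: the uptake-normalized net flux from
  mitochondrial malate to mitochondrial oxaloacetate;
* **abundance** — enzyme levels from GFP-vs-biomass slopes corrected for
  autofluorescence, Welch-test fold changes vs glucose (α = 0.12),
  expression-pattern classes, correlation with the degree of respiration;
* **TF enrichment** — per-transcription-factor upper-tail hypergeometric
  probability
  f = Σᵢ₌ₖ C(m,i)·C(N−m,n−i)/C(N,n),
  ranked, five lowest values (ties expanded) reported;
* **synthetic data** — generators for every input with known ground truth.

## Worked example

```r
library(respflux)

## recover a planted anaplerosis/TCA split from simulated GC-MS data
sim  <- simulateMDVs(syntheticTruth(seed = 1))        # R* = 0.35
corr <- correctMDV(sim$product, sim$composition, sim$experiment)
estimateMixingFraction(corr, sim$precursorA, sim$precursorB)$value
#> [1] 0.3540115

## respiratory TCA flux and degree of respiration from that split
tcaFluxFromSplit(0.354, vAna = 0.5, uptake = -2.5)
#> RespirationEstimate: v_ana = 0.5, R = 0.354, v_tca = 0.9124,
#>   degree of respiration = 0.365

## headline differential-expression statistics from the bundled tables
rep <- suppressWarnings(respirationReport())
unlist(rep$counts)
#>              up_gal              up_pyr   up_tca_resp_union
#>            18.00000            21.00000            20.00000
#> down_tca_resp_union         pct_changed
#>             5.00000            65.95745
```

The counts read: 18 enzymes up-regulated on galactose and 21 on pyruvate
relative to glucose, 20 of the 40 TCA-cycle + respiratory-chain enzymes up
on galactose and/or pyruvate with 5 down, and 66 % of all 47 investigated
enzymes changed on at least one carbon source. The recovered mixing
fraction 0.354 sits within noise of the planted 0.35, and the implied
respiratory flux of 0.91 mmol g⁻¹ h⁻¹ normalizes to a degree of
respiration of 0.365 at an uptake of 2.5 mmol g⁻¹ h⁻¹.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline end to end against the installed package: the
counting and yield arithmetic from the bundled reference tables, and
seeded synthetic recoveries of the growth rate, the mixing ratio, the
net-flux degree of respiration and the planted regulators. Progress is
logged to stderr and the machine-readable result object is written to
`--out`.
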