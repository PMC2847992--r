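---
title: "From 13C labeling and GFP reporters to the regulators of respiration"
author: "respflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 13C labeling and GFP reporters to the regulators of respiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respflux)
```

# The scientific question

Budding yeast tunes the balance between fermentation and respiration to the
carbon source it grows on: almost pure fermentation on glucose, almost pure
respiration on non-fermentable substrates such as pyruvate, and intermediate
states on sugars like galactose.  This package implements the quantitative
chain that links three layers of that adaptation:

1. **Physiology** — specific growth rates, substrate uptake and by-product
   secretion rates, biomass yields.
2. **Metabolic flux** — the respiratory flux through the TCA cycle,
   quantified from ¹³C labeling patterns and a constrained stoichiometric
   model, summarized as a single *degree of respiration*.
3. **Regulation** — enzyme abundances from GFP-reporter strains, their fold
   changes across carbon sources, and a hypergeometric ranking of the
   transcription factors most likely to orchestrate those changes.

Every stage also has a synthetic-data generator with known ground truth, so
the whole chain is testable without any external data.

# Models and procedures

## Growth rates and uptake rates

Specific growth rates are fit by linear regression of $\log \mathrm{OD}_{600}$
against time over the contiguous window of at least 6 points at maximum
rate.  "At maximum rate" is operationalized as: among all contiguous
windows of length $\ge$ `minPoints`, take the steepest slope among windows
with $R^2 \ge 0.99$; if no window is that clean, take the best-fitting
window.  The $R^2$ gate stops the fit from latching onto noisy two-phase
stretches; the threshold is configurable.

Uptake/secretion rates come from the slope $s$ of concentration against
cell dry weight (CDW): $1/|s|$ is the molar biomass yield (g/mmol),
$q = s\,\mu$ the specific rate (mmol g⁻¹ h⁻¹, negative for consumption),
and yield$_\mathrm{mass}$ = $1/(|s|\,\mathrm{MW})$.  The three outputs obey
the identity yield$_\mathrm{mass}\cdot|q|\cdot \mathrm{MW} = \mu$, which the
tests assert exactly.  The OD→CDW factor (default 0.5 g l⁻¹ per OD unit) is
an instrument-specific placeholder and must be calibrated; molecular
weights default to the free sugar/free acid (glucose-family 180.16,
pyruvate 88.06 g mol⁻¹) because published tables rarely state whether salt
masses were used.

## Mass-isotopomer correction

GC-MS fragments of protein-bound amino acids carry, besides the
biologically informative backbone carbons, dozens of derivatization atoms
(TBDMS contributes C, H, Si; the backbone brings N, O).  Their natural
heavy isotopes smear the measured mass distribution.  The correction
builds, by convolution of per-element isotope distributions (standard
IUPAC abundances, e.g. ¹³C 1.07 %, ²⁹Si 4.685 %), a lower-triangular matrix
$M$ whose column $j$ is the natural mass-shift distribution on top of $j$
tracer-derived mass units, and solves $Mx = y$ for the backbone pattern.

Non-negative least squares (a hand-rolled Lawson–Hanson implementation; no
QP package is assumed) is the default solver because plain inversion can
return negative abundances on noisy data; exact inversion remains
available for algebra checks.  The unlabeled-biomass fraction $w$ (carry-over
from a naturally labeled inoculum) is then removed as
$x' = (x - w\,e_0)/(1-w)$, clipped at zero and renormalized.  Tracer
impurity (e.g. 99 % ¹³C) is deliberately *not* part of the correction: it
belongs to the forward measurement model, and the synthetic generator
applies it there as binomial thinning of the nominal tracer atoms.

## Flux ratios and the respiratory TCA flux

A metabolite pool fed by two pathways carries the flux-weighted mixture of
its precursors' labeling patterns.  The generic estimator solves
$\mathrm{MDV}_p \approx R\,\mathrm{MDV}_a + (1-R)\,\mathrm{MDV}_b$ by
closed-form projection clipped to $[0,1]$, with first-order error
propagation from per-channel measurement SDs (default 0.005).  The original
analysis used a catalogue of published algebraic ratio equations that are
not reproduced here; this package instead ships the generic two-precursor
estimator plus one fully worked configuration — mitochondrial oxaloacetate
made either by anaplerotic pyruvate carboxylation or by a turn of the TCA
cycle.  Because the TCA-derived precursor depends on the OAA pool itself,
its pattern is computed as the fixed point of the mixing map (iterated to
$10^{-8}$), treating carbon positions within a fragment as exchangeable so
that decarboxylation becomes hypergeometric carbon removal.  This
mass-level approximation is adequate for a two-precursor split; it does not
attempt positional (EMU/cumomer) resolution, which is out of scope.

On gluconeogenic substrates only this one split is identifiable, and the
respiratory TCA flux follows from the anaplerotic flux (equal to the
biosynthetic drain of oxaloacetate/2-oxoglutarate):
$v_\mathrm{TCA} = v_\mathrm{ana}(1-R)/R$.  Uncertainty can be propagated
through $\partial v_\mathrm{TCA}/\partial R = -v_\mathrm{ana}/R^2$, or the
flat 20 % relative-SD convention used in the original analysis for this
flux can be applied.

## Net fluxes and the degree of respiration

`solveNetFluxes()` minimizes the weighted squared deviation from measured
rates and ratio equations subject to exact mass balance ($Sv = 0$ via
null-space parametrization), irreversibility bounds, and ratio ranges as
hard inequalities.  The inequality-constrained least-squares problem is
solved exactly by the classical transformation to least distance
programming and then non-negative least squares — a deliberate choice over
iterative penalty methods so that active bounds are satisfied to machine
precision.  Rank deficiency is detected on singular values with an absolute
floor; the default is an error listing the free flux directions, with a
minimum-norm option for degenerate sanity cases (a closed network solves to
$v = 0$).

The bundled ~25-reaction model of central yeast carbon metabolism (lumped
glycolysis and pentose phosphate pathway, pyruvate branch point, cytosolic
and mitochondrial oxaloacetate/malate, lumped TCA cycle, fermentation
products, biomass drain) is a package-authored stand-in: the original
model lives in supplementary material that the package does not reproduce,
so absolute flux maps are not comparison targets.  Biomass drain
coefficients follow standard yeast biomass composition, rounded, and are
configurable.

The **degree of respiration** is the uptake-normalized net flux through
mitochondrial malate dehydrogenase (`mdh_mit`, mal_mit → oaa_mit), floored
at zero.  The published values are in arbitrary units whose absolute scale
is not derivable from the stated normalizations; the scale factor is
therefore configurable (default 1) and nothing downstream depends on it.

## Enzyme abundances and differential expression

A GFP-fusion strain's fluorescence rises proportionally to biomass during
exponential growth; the OLS slope of GFP against the biomass signal, minus
the same slope in a TAP-tagged autofluorescence control, quantifies the
enzyme level in arbitrary units.  The exponential window keeps points with
biomass between 10 % and 60 % of the plateau (the published fit is "during
exponential growth" without bounds; these limits avoid lag and stationary
artefacts).  Strains whose biomass never doubles are flagged `ng`
(no growth); negative corrected slopes become `below_detection` with level
0.  Levels are *not* invariant to detector gain — doubling the GFP gain
doubles levels — which is fine because all comparisons are within one
calibrated instrument.

Fold changes against glucose use a two-sided Welch t-test on replicate
levels; the original analysis states only the significance threshold
(p ≤ 0.12, chosen there so that error ranges of truly changed enzymes do
not overlap), not the test, so Welch is this package's documented choice.
Pattern classification applies five ordered rules (up on galactose AND
pyruvate; up on pyruvate only; down or below detection on either; changed
on mannose only; unchanged), which makes the partition exhaustive and
mutually exclusive; `ng` on a respiratory substrate counts as
respiration-important, i.e. as up.  In the headline counts, `ng` strains
are included in the per-condition up counts but excluded from the
fold-change-based TCA+respiratory-chain union — both rules are needed to
reconcile the published sentences, and both are fixture-tested.

The correlation screen recomputes Pearson correlations between expression
and the degree of respiration across the four carbon sources.  Since only
fold changes are portable, glucose is fixed at 1 and non-significant
changes are taken as 1 — an approximation to the original screen on
measured levels, which is why the published list of six enzymes at
$r \ge 0.90$ is reported but not asserted.

## Transcription-factor ranking

For each TF with at least one literature-curated target among the $N$
investigated enzymes, the probability that it hits at least $k$ of the $n$
differential enzymes by chance is the upper hypergeometric tail
$$f = \sum_{i=k}^{\min(m,n)} \binom{m}{i}\binom{N-m}{n-i}\Big/\binom{N}{n},$$
computed by log-sum-exp over log pmf values.  No multiple-testing
correction is applied — the original analysis explicitly uses rank, not the
absolute value of $f$ — and the five lowest $f$ values are reported, with
ties at the fifth value expanded (the published galactose list has six
entries for exactly this reason).  Ties are broken by larger $k$, then
alphabetically.  The universe defaults to all 47 investigated enzymes; it
is configurable because one could argue for excluding the two no-growth
strains.

# The synthetic world

The generator defaults are the stated experimental conditions: growth at
$\mu^* = 0.33$ h⁻¹ after a 2 h lag with 2 % multiplicative log-normal
optical noise; eight replicate cultures; a 20 %/80 % mixture of uniformly
¹³C-labeled and natural substrate at 99 % tracer purity with additive MDV
channel noise of 0.005; a 47-enzyme universe with an 18-enzyme differential
set; two planted regulators whose targets hit the differential set with
probability 0.9 against eight uniform decoys and ten targets per TF.
Values the sources do not state (OD plateau 4, inoculation OD 0.05,
scatter gain 100 AU/OD, expression 3 with autofluorescence 1, anaplerotic
fraction 0.35 with $v_\mathrm{ana}$ = 0.5 mmol g⁻¹ h⁻¹) were chosen once as
typical for small-scale aerobic batch cultures and are not tuned.

What a green recovery test establishes is parameter identifiability under
these idealized noise models — it does not establish robustness to plate
effects, drift, evaporation, or misassigned fragments, none of which the
generator emulates.  All generators are deterministic given a seed.

```{r example}
g <- simulateGrowth(syntheticTruth(seed = 1))
fitGrowthRate(g$time, g$od600)$mu

sim <- simulateMDVs(syntheticTruth(seed = 1))
corr <- correctMDV(sim$product, sim$composition, sim$experiment)
estimateMixingFraction(corr, sim$precursorA, sim$precursorB)$value
```

# Numerical choices and degenerate inputs

* Mixing problems with indistinguishable precursors
  ($\lVert a-b\rVert < 10^{-6}$) raise an unidentifiability error, as does
  $R = 0$ with positive anaplerotic flux (infinite TCA flux).
* NNLS corrections that clip more than $10^{-3}$ of negative mass warn and
  report diagnostics; corrected MDVs are always renormalized distributions.
* The net-flux solver floors numerical dust ($|v| < 10^{-9}$) on
  irreversible reactions at zero and guarantees
  $\lVert Sv\rVert_\infty < 10^{-8}$ at balanced metabolites.
* TF ranking with $n = N$ (everything differential) yields all $f = 1$ and
  is flagged degenerate rather than silently ranked.
* Zero-variance expression profiles are excluded from the correlation
  screen with a warning naming the enzymes.

# The bundled reference tables

`loadTable1Fixture()` and `loadTable2Fixture()` ship the printed
physiology and fold-change reference tables (four carbon sources; 47
enzymes with significance codes `nsc`/`ng`/`bd` and p-value bins).  The
headline claims recomputed from them — 18 enzymes up on galactose, 21 up on
pyruvate, 20 of 40 TCA+respiratory-chain enzymes up on galactose and/or
pyruvate, 5 down, 66 % changed overall, and yields consistent with
$\mu/(|q|\,\mathrm{MW})$ to two decimals — are exactly what the acceptance
tests assert:

```{r report}
rep <- suppressWarnings(respirationReport())
unlist(rep$counts)
```

# Known limitations

* Flux ratios beyond the two-precursor OAA split (the published catalogue
  of eight ratios) are out of scope; so is global isotopomer fitting.
* The bundled stoichiometric model is faithful-but-not-identical to the
  original supplementary model; absolute flux values are therefore not
  comparable, only the machinery is.
* The correlation screen operates on fold-change proxies, not absolute
  levels.
* Deletion-strain phenotypes are documentation, not recomputed results.
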