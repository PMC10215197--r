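---
title: "Models and methods in cysredox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cysredox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysredox)
```

# The measurement problem

Mitochondrial cysteines are oxidized by reactive oxygen species, and the
oxidation of a given thiol is both site-specific and dose-dependent. Two
complementary mass-spectrometry platforms quantify this:

* **Competition profiling (isoTOP-ABPP style).** An untreated sample is
  labeled with a light isotopic iodoacetamide probe, an oxidant-treated
  sample with the heavy probe, and the two are mixed. Oxidation destroys
  thiol reactivity, so the treated channel loses signal and the
  light:heavy (L:H) ratio rises above 1. The platform sees reversible and
  irreversible oxidation alike, but a cysteine that is fully oxidized in
  the treated sample produces no heavy signal at all and is simply never
  identified.
* **Differential alkylation (OxICAT style).** Within a single denatured
  sample, free thiols take the light label; reversibly oxidized thiols are
  then reduced and take the heavy label. The heavy share of the summed
  signal is directly the reversibly oxidized fraction. Irreversibly
  oxidized thiols (sulfinic/sulfonic acids) accept neither label and are
  invisible — which *inflates* the apparent percent oxidation.

`cysredox` implements the complete analysis for both platforms plus a
synthetic-data generator that emulates them from one shared ground truth,
so every aggregation, filter, and classification step can be verified by
parameter recovery.

# The generative model

Each cysteine site carries a latent dose response for its total oxidized
fraction at oxidant concentration $c$ (mM):

$$ f_{\mathrm{total}}(c) \;=\; f_0 + f_{\max}\,
   \frac{c^{h}}{K^{h} + c^{h}}, \qquad f_0 + f_{\max} \le 1 $$

with basal (zero-dose) oxidation $f_0$, maximal induced reversible
oxidation $f_{\max}$, half-effect concentration $K$, and Hill exponent
$h$ (default 1). The source data show only qualitative, monotone,
saturating dose trends, so the Hill family is used as the minimal
monotone saturating form; it is a modeling convention of this package,
not an inferred mechanism. A fraction `firr_frac` of the total oxidation
at any dose is irreversible.

The two platforms observe this truth differently:

* competition ratio: $E[L{:}H] = 1/(1 - f_{\mathrm{total}}(c))$, with
  sites censored (emitted as missing) when $f_{\mathrm{total}} \ge 0.98$;
* differential alkylation channels: $L \propto 1 - f_{\mathrm{rev}} -
  f_{\mathrm{irr}}$, $H \propto f_{\mathrm{rev}}$, so the percent
  oxidation is $100\,f_{\mathrm{rev}}/(1-f_{\mathrm{irr}})$.

Channel intensities carry independent multiplicative log-normal noise
parameterized by a CV (default 0.2, a typical replicate-level spread for
isotopic ratio quantification); log-normality keeps intensities positive
and makes ratio noise symmetric on the log scale. Detection is a per-site
Bernoulli property drawn once per run — not per condition — so the
observed site set is stable along a dose series; per-replicate dropout
(default 0.05) is drawn independently. An early version redrew detection
per condition, which made per-condition medians non-monotone even at
zero noise purely through set changes; the per-site reading matches the
semantics of a site-level detectability and was adopted.

## Default truth population

`simulate_truth()` draws three generative sensitivity classes in
proportions 42% resistant / 50% moderate / 8% high, matching the strata
observed at the top dose in the mitochondrial lysate experiment the
package emulates (58% of sites at least two-fold changed, 8% more than
five-fold). The parameter windows put the noiseless top-dose ratios at
$\le 1.3$, $2.5$–$4.2$, and $\ge 8$ — separated by at least two-fold
across class boundaries — so that class recovery is a meaningful test of
the pipeline rather than a coin flip at the boundaries. A further 8% of
sites receive high basal oxidation (0.88–0.97), emulating structural
disulfides: these appear near-fully oxidized in the differential
alkylation control arm (reproducing the observed "small subset over 50%
oxidized") and are prone to censoring on the competition platform — the
platform-contrast the two methods are known for.

The endogenous-stress arm (complex III inhibition) has no quantitative
dose; it is modeled as an effective concentration on the same axis
(`ama_dose`, default 2 mM, chosen to give a proteome-wide median ratio
well below the top peroxide dose, matching the reported qualitative
contrast). This is a simulator knob, not an estimate.

# The analysis pipeline

## Quantification

`integrate_eic()` integrates traces by the trapezoid rule after
subtracting a robust baseline (median of the lowest decile of
intensities — parameter-free and exact for flat offsets).
`coelution_qc()` resamples a light/heavy pair onto the union grid of
their overlapping time domain by linear interpolation (deterministic and
order-preserving) and requires apex agreement within 10 s and Pearson
shape correlation of at least 0.8; constant traces fail with an explicit
reason code because their correlation is undefined. `compute_ratio()`
clamps ratios to $[1/\mathrm{cap}, \mathrm{cap}]$ with cap 20 — just
above the largest ratio the emulated experiments report (19.1) — so a
vanishing heavy channel yields a finite, flagged value.

## Replicate aggregation and filters

`aggregate_replicates()` enforces a presence rule (2-of-2 for the
peroxide arm, 2-of-3 for the endogenous arm) and computes the arithmetic
mean ratio and its CV on linear ratios (the conventional reading of a
"coefficient of variation"; a log-scale CV is available via `log_cv`).
`filter_changed()` implements the **conjunction reading** of the removal
rule: a site is dropped only if its mean ratio exceeds two-fold AND its
CV exceeds 50%. The source protocol states the rule twice with slightly
different grammar; the restatement ("average ratios of a >2-fold change
were filtered by a coefficient of variation cut-off of 50%") supports
the conjunction, which is the default; `mode = "cv_only"` gives the
stricter alternative rather than choosing silently.

The `CAPPED` flag is informational: capped sites participate in medians
and classification like ordinary ratios (the emulated experiments report
near-cap ratios as results, not artifacts). Only `PRESENCE_FAIL`,
`CV_FAIL` and `DISPERSION_FAIL` exclude a row from downstream use.

## Classification and implied oxidation

`classify_sensitivity()` reads the class off the top-dose ratio —
`high` at $\ge$ 5-fold, `moderate` at $\ge$ 2-fold, `resistant` below —
mirroring the strata the emulated study reports; the enum names are this
package's convention. A log-log least-squares slope across available
doses is reported for inspection but deliberately kept out of the class
rule. `implied_oxidation()` inverts the generative ratio model exactly:
$\%\mathrm{ox} = 100\,(1 - 1/R)$, floored at 0 for ratios below 1.

## Differential alkylation

`percent_oxidation()` applies $100\,(1 - R/(R+1))$ for L:H input or
$100\,R/(R+1)$ for H:L; the two orientations agree on reciprocal inputs
to 1e-12 and sum to 100 on the same input. Aggregation averages
**per-replicate percents** (not ratios — the order of operations is
documented since the source leaves it open) and removes records whose
sample standard deviation across replicates exceeds 30 percentage
points. "Standard deviation of mean of >30%" is read as the sample SD of
the percent values in points — not the SEM and not a relative SD —
because percents already live on a 0–100 scale; the alternatives are
available behind `sd_mode`. Condition contrasts call a site `increased`
at a delta of +20 points or more — a convention of this package, since
the emulated study makes qualitative calls only.

## Annotation and enrichment

Mitochondrial filtering joins against a single-snapshot annotation TSV
(a toy MitoCarta-like table ships as a fixture; live database queries
are out of scope). Pathway binning uses a fixed 12-label vocabulary plus
`"other"`. Overrepresentation is a generic upper-tail hypergeometric
test with Benjamini–Hochberg adjustment — a stand-in for ontology-based
tools, not a clone of any.

# What the synthetic data does and does not establish

The generator reproduces the *statistical structure* the analysis
assumes: multiplicative channel noise, replicate dropout, per-site
detectability, censoring of fully oxidized sites, and the
reversible/irreversible split. It does not emulate spectra, isotope
envelopes, chimeric peptides, retention-time drift between runs, or
peptide-to-protein inference ambiguity. A green parameter-recovery test
therefore establishes that the aggregation, filtering and classification
logic is faithful to the stated model — not that the model captures
every failure mode of real LC-MS data. The headline identification
counts of the emulated study (hundreds of cysteines, specific per-site
ratios) derive from real instrument data that were not deposited with an
accession; they are used here as fixtures and qualitative shape targets
only.

# Numerical choices and degenerate inputs

* Ratios are serialized at 6 significant digits; all internal arithmetic
  is double precision.
* Medians and quartiles use the default (type 7) quantile with midpoint
  ties.
* A replicate set of size 1 under a `required_k = 1` rule has CV 0.
* Both channel areas zero means no observation (missing), not a ratio.
* Chromatogram simulation refuses a sampling interval at or above the
  peak sigma (undersampled peak); integration windows with fewer than
  two points in the trace are errors.
* Seeds: every stochastic entry point takes an explicit integer seed;
  pipeline stages derive distinct seeds by small fixed offsets from the
  run seed, so a whole run is reproducible byte-for-byte from one
  integer.

# Known limitations

* The competition ratio model assumes a fully reduced control channel;
  for sites with very high basal oxidation the control channel is itself
  attenuated in reality, which the model folds into detectability
  rather than the ratio.
* The effective-dose treatment of the endogenous-stress arm collapses
  spatial and kinetic detail of mitochondrial ROS production into one
  number per run.
* Annotation is a single boolean snapshot; reconciling annotation
  database versions is not modeled.
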