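---
title: "Absolute proteome quantification with SIL anchors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute proteome quantification with SIL anchors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorlfq)
```

This vignette records the quantitative model behind `anchorlfq`, the
assumptions it makes, and the design decisions taken where the underlying
methodology leaves room — in enough detail that a maintainer can judge
every numerical choice.

## 1. Anchor quantification model

A stable-isotope-labeled (SIL) full-length protein standard is spiked into
the light cell lysate *before* cleanup and digestion, so losses in those
steps cancel in the light-to-heavy (L/H) ratio of every proteotypic
peptide. With a spike of $S$ nmol into an aliquot representing $g$ grams
dry cell weight, a peptide with ratio $r$ estimates the intracellular
concentration

$$ c = r \cdot S / g \quad [\text{nmol/gDCW}], $$

and a protein's per-sample concentration is the mean over its surviving
peptides. The SIL stock itself is quantified from the heavy/light ratio of
an N-terminal quantification tag against a known amount of unlabeled
reference peptide (`quantify_sil_stock`); a missing light reference signal
is a hard error because nothing downstream can be normalized without it.

**Assumptions.** Unique peptide-to-protein mapping; complete isotope
labeling of the standard; equal digestion efficiency of the standard and
the endogenous protein (the reason protein-level rather than peptide-level
spike-ins are used); and an externally supplied biomass equivalent $g$ per
sample. The mapping from a digested aliquot to gDCW is deliberately an
explicit input (`biomass` table) rather than a hidden constant so the
unit conversion stays auditable.

## 2. Dilution-series calibration and the LLOQ

Each peptide must prove it quantifies linearly. In the dilution series the
heavy spike starts at twice the endogenous level (level 0, "DS01") and
halves per level across ten samples (512-fold span) in a constant lysate
background, so the expected L/H doubles per level. Because the endogenous
amount is unknown, the expected series is anchored at the *measured* DS01
ratio: we regress

$$ y_k = \log_2 (r_k / r_0) \quad\text{on}\quad x_k = k $$

by ordinary least squares. In this space perfect dilution behavior is
slope 1 and intercept 0, which makes the published acceptance bands
directly interpretable: $r^2 > 0.95$, slope in $(0.95, 1.05)$, intercept
in $(-0.1, 0.1)$, at least 3 points. Whether such criteria are meant in
linear or log space is ambiguous in general; log space is the only choice
under which "slope 1" is scale-free across a 512-fold range, so log2 was
chosen and is flagged here as a design decision.

While the criteria fail, the lowest-spike (highest-level) point is dropped
and the model refit — the mechanism that excises the nonlinear tail caused
by background interference at low heavy signal. The **LLOQ** is
operationalized as the heavy intensity at the lowest retained level: the
smallest signal inside the validated linear range. One deliberate
deviation from a naive two-channel reading: the light channel of the
series is a *constant* lysate background sitting at the typical endogenous
level, so "the light intensity at the LLOQ level" is not a quantification
floor — using it as one would mask roughly half of all sample
measurements (every sample whose light signal fluctuates below its own
expectation). `anchorlfq` therefore carries a single validated intensity
floor per peptide (`lloq`), and a sample measurement is masked when
*either* channel falls below it.

**Degenerate inputs.** Fewer than 3 usable points, or no usable level-0
point, yield `pass = FALSE` with a reason code rather than an error: a
failed calibration is a data property, not a bug. "At least three
continuous dilution samples with heavy signal" is read as levels
$0, 1, 2, \dots$ consecutively from the top of the series.

## 3. Peptide filtering

Filters run in a fixed order, each removal logged with a rule identifier
(`rule1_precursor` … `rule8_outlier`): best precursor per peptide (highest
DS01 heavy; ties broken by lower charge, then lexicographically), the
replicate-presence rule (≥ 3 biological replicates in *every* condition,
applied before and after LLOQ masking), DS01-heavy and continuous-series
rules, the calibration pass, LLOQ masking, and finally the outlier rule: a
peptide is removed when its mean absolute percent deviation from the
protein's all-peptide mean ratio exceeds 50% across all samples or within
any condition. The outlier statistic includes the candidate peptide in the
protein mean (the most direct reading) and is applied in a single
non-iterative pass. A condition whose replicate concentrations have
CV > 50% is reported `NQ`; "varied more than 50%" could also be read as a
max-pairwise-difference rule, but CV = sd/mean is the most direct
statistical reading and is the implemented one (threshold configurable via
`cv_max`).

## 4. Label-free calibration and CV-MFE

Protein intensity summarizations on offer: `topN` (sum of the N most
intense peptides, N ∈ {1, 2, 3, 5}), `iBAQ` (summed peptide intensity over
the count of theoretically observable peptides), and `all_pep_sum`.
Peptide intensity is the sum of its five most intense fragment ions; at
least two quantified peptides are required per protein. iBAQ observable
peptides are fully tryptic (cleavage after K/R, not before P), zero missed
cleavages, length 7–30 — standard iBAQ practice, configurable. The grid is
small by design: model selection is only meaningful when the candidates
differ structurally.

Each candidate is fit by OLS of $\log_{10}(\text{conc})$ on
$\log_{10}(\text{intensity})$ over the anchors, one fit per sample (run
intensity scales differ between injections). Selection is by bootstrapped
cross-validation: resample the anchors with replacement, refit, predict
the out-of-bag anchors, and score every prediction with its fold error
$FE = 10^{|\log_{10} \hat c - \log_{10} c|}$. The **CV-MFE** is the
arithmetic mean of the pooled fold errors ("mean fold error" read
literally; a geometric alternative is exposed via `fe_aggregate`), and
`ci95` is the half-width of the normal-approximation 95% interval of the
FE distribution. CV-MFE is 1 exactly when every out-of-bag prediction is
exact and cannot be smaller. Defaults: 100 bootstrap iterations, a
mandatory seed, and a redraw guard for degenerate resamples with fewer
than three distinct anchors. Anchors themselves are reported at their SIL
values by default (`report_anchor_sil`), since the SIL route is the more
accurate one where available.

## 5. Flux integration

$k_{app} = v \times 10^6 / (3600 \, E)$ converts flux $v$ (mmol/gDCW/h)
over enzyme concentration $E$ (nmol/gDCW) to s⁻¹, assuming every protein
chain is catalytically active. Isoenzymes: within each condition the
alternatives are ranked by concentration (complexes by the mean of their
quantified subunits, sd by error propagation $\sqrt{\sum s_j^2}/m$); the
alternative with the smallest mean rank across conditions carries the
whole flux (ties: higher overall mean, then lexicographic — the ranking
must be deterministic). Eligibility requires nonzero flux somewhere, flux
above 0.1% of the reference carbon-fixation reaction in at least one
condition (compared within condition), concentrations measured under all
conditions, and no membrane-flagged subunit (membrane protein extraction
is potentially incomplete, which would inflate $k_{app}$). A shared enzyme
pool is split between its reactions proportionally to flux, conserving the
total. Flux magnitude is used for thresholds and $k_{app}$; direction is
kept as metadata. $k_{app}$ uncertainty uses first-order ratio
propagation, $s_k/k = \sqrt{(s_v/v)^2 + (s_E/E)^2}$ — a choice, since the
source methodology is silent on $k_{app}$ uncertainty.

Flux–concentration and flux–$k_{app}$ associations are Kendall τ-b with
tie correction and a two-sided normal-approximation p value, pooled over
reaction × condition pairs (per-condition values are also reported; the
pooled form is the primary one because the heatmap-style comparison pools
conditions).

## 6. Regulation classification

Stage one: per reaction and unordered condition pair, a two-sided
pooled-variance t test on replicate fluxes, BH-FDR over all tested pairs;
`flux_q < α` (default 0.05) marks a significant flux change. Stage two
asks whether the enzyme followed. The exact construction of a
"left-tailed t comparison of the flux change with the expression change"
is underdetermined, so the implemented reading — flagged prominently as a
design decision — is: orient the pair so the flux log2 fold change is
positive; form replicate-level log2 fold changes for flux and for relative
enzyme expression (each replicate of the high condition against the low
condition's mean); then a one-sided two-sample equal-variance t test of
H₀ "enzyme change ≥ flux change" against "enzyme change smaller". BH-FDR
across stage-two tests; `regulation_q < α` ⇒ posttranslational. The
orientation rule makes the classification invariant to swapping condition
labels. Zero-variance degenerate groups give p = 1 (equal means) or p = 0
(unequal), logged rather than erroring. Enzyme expression is *relative*
(normalized intensities); only its fold change enters, never its scale.

## 7. Allocation and stoichiometry

Proteome allocation aggregates $c_i \times MW_i$ shares over a three-level
functional hierarchy; mass weighting is the default because treemap-style
visualizations scale tile area with protein amount × size (molar
weighting is available via `weight = "molar"`). Unmapped proteins fall
into an explicit fallback category so fractions always sum to 1, and
coarser levels are exact sums of their children. Complex stoichiometry
checks compare member/reference concentration ratios with expectation via
the fold deviation $\max(\text{obs}/\text{exp}, \text{exp}/\text{obs})$,
within tolerance at ≤ 1.5-fold by default — the magnitude of the
label-free calibration error, which is the natural yardstick for ratios
of label-free concentrations. Unquantified members are reported `missing`,
not failed.

## 8. The synthetic-data generator

The generator emulates the study design the pipeline targets: 3
conditions × 4 biological replicates, 16 anchors among ~1,000 proteins,
concentrations log-uniform over ≥ 3 orders of magnitude with anchors
stratified so every concentration decade contains one, random protein
sequences (100–800 aa, realistic amino-acid frequencies) digested in
silico, and a 10-level 2-fold dilution series.

The intensity model is multiplicative:
$I = c \cdot g \cdot \kappa_s \cdot \varphi_p \cdot \varepsilon$ with a
fixed per-peptide response factor $\varphi_p$ (lognormal, σ = 0.4 log10 —
peptides "fly" very differently), a per-sample factor $\kappa_s$, and
lognormal measurement noise $\varepsilon$. Noise defaults are derived from
the variability a well-run DIA study reports, fixed a priori:

- `sigma_noise = 0.068` log10, so an L/H ratio has
  CV ≈ √2 · ln 10 · σ ≈ 22% — the inter-peptide variability of anchor
  concentration estimates;
- `sigma_bio = 0.028` log10 biological replicate variation, so replicate
  protein concentrations (ratio noise averaged over ~6 peptides per
  protein) have CV ≈ 11% — the inter-replicate variability;
- the dilution series is a single technical injection sequence, so its
  noise is far smaller (`sigma_noise = 0.01` log10).

The LLOQ-generating mechanism is an additive instrument background on
both channels: once the heavy signal approaches the background, the
measured ratio bends away from linearity. Because the pass criteria are
bands, a peptide whose noise-free calibration sits *on* a band edge has no
stable truth; the generator therefore records the planted LLOQ as the
calibration outcome on the noise-free curve and marks peptides within two
standard errors (under the configured noise) of a decision boundary as
indeterminate. Recovery tests require the noisy calibration to reproduce
the planted level for the determinate peptides — the honest closure for a
threshold-based procedure. Of note, a single lowest-spike point deviating
by only 5–10% does **not** get dropped by the published bands on a
512-fold series (its leverage on slope and intercept is far smaller than
the band widths); substantial backgrounds are required before points fall.

Flux scenarios plant the regulation ground truth: `null` (no change),
`translational` (flux and expression change together, fold change 3 by
default), `posttranslational` (flux changes, expression flat), with
default counts 20/2/18 — i.e. 90% of changed reactions posttranslational,
the study condition of interest. Planted $k_{app}$ values scale with
$v^{0.5}$ times lognormal spread, so enzyme concentrations and catalytic
rates both increase with flux, reproducing the rank correlations real
metabolism shows; this is a generator design choice, not an emergent
result.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: chromatographic and identification errors,
interference and shared peptides, missingness that is correlated with
hydrophobicity or charge rather than pure intensity, run-order drift,
membrane-protein extraction bias, and flux-estimation error structure
(replicate flux noise is i.i.d. normal here). Conclusions about those
failure modes need real data.

## 9. Problem sizes and numerical tolerances used in the tests

The test suite runs generators at 25–400 proteins and the acceptance
script at the full 1,000-protein study scale with 100 bootstrap
iterations — sizes chosen so the whole suite exercises every stage in
about a minute while keeping Monte-Carlo error well below the asserted
tolerances. Closure tests at zero noise assert exact recovery (1e-9
relative); stochastic assertions use three binomial standard errors or
precomputed Monte-Carlo oracle bands. The CV-MFE oracle
$E[10^{|\epsilon|}]$ with $\epsilon \sim N(0, \sigma\sqrt{1 + 1/n})$ is a
first-order approximation that ignores out-of-bag fit uncertainty, so the
bootstrap value is expected to sit slightly above it; the test asserts the
band [0.95, 1.35] × oracle.

## 10. Known limitations

- The biomass-equivalent mapping is an input; the pipeline cannot detect a
  wrong gDCW conversion (it rescales all concentrations linearly).
- Summing lognormally distributed concentration estimates biases the total
  proteome mass upward (retransformation bias), by roughly the mean fold
  error; the mass check is therefore a consistency band, not a sharp test.
- The stage-two regulation test inherits the replicate structure of the
  flux estimates; strongly correlated flux replicates would miscalibrate
  its type-I error.
- Isoenzyme selection is winner-take-all by concentration ranking; a true
  flux split between isoenzymes is not modeled.
- Protein inference is assumed resolved upstream (unique peptides only).
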