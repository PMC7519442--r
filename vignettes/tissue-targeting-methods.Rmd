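---
title: "Methods: weighted calibration, sparse-sampling NCA, and relative targeting efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted calibration, sparse-sampling NCA, and relative targeting efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuerte)
```

## The problem this package addresses

Tissue-distribution studies of herbal preparations ask whether a processing
step (here, salt-frying of the source herbs) redirects the preparation's
active compounds toward particular organs. The experiment behind this
package's design doses two groups of rats — one with the crude extract, one
with the salt-processed extract — sacrifices six animals per group (three
per sex) at each of seven times between 10 and 720 minutes, and quantifies
twelve compounds in eight tissues by LC-MS/MS against matrix-matched
calibration curves. The pipeline implemented here starts where peak
integration ends (analyte and internal-standard areas) and ends at a
per-tissue targeting statistic.

## Calibration

Responses are analyte/IS peak-area ratios $y$ against spiked concentration
$x$ (ng/mL of homogenate). The fit is weighted linear least squares with
$w_i = 1/x_i^2$, minimizing $\sum_i w_i (y_i - a x_i - b)^2$. With ranges
spanning up to four orders of magnitude, unweighted least squares is
dominated by the highest standards; $1/x^2$ weighting equalises *relative*
error, which is what a bioanalytical assay is judged on. Two consequences
are load-bearing and tested as properties: the fit is exactly
scale-equivariant in $y$, and with equal weights it reduces to ordinary
least squares.

The reported correlation coefficient is the *weighted* Pearson correlation
under the same weights. The source tables print $r$ without defining it; we
use the weighted form for consistency with the fitting criterion.

Back-calculation inverts the line, never clamps, and flags each value
`below_lloq`, `in_range`, or `above_range`. Negative inversions (ratios
below the intercept) are retained with the `below_lloq` flag so that the
censoring decision is made exactly once, downstream.

Two LLOQ notions coexist deliberately. At study time the LLOQ is the
curve's lowest calibration level — the operational convention of the
published curve table. The signal-to-noise procedure (`estimate_lloq_llod`,
LLOQ at S/N $\ge$ 10, LLOD at S/N $\ge$ 3) serves method development and
synthetic validation runs; the *net* signal of a level is `slope * level`,
treating the intercept as baseline. Published tables list no numeric LLODs,
so LLOD output is unvalidated against any external value.

## Method validation

The validation report follows the usual regulatory structure:

* **Accuracy**: $RE = 100(\bar x - x_{nom})/x_{nom}$.
* **Precision**: $RSD = 100\, s/\bar x$ (sample SD).
* **Recovery**: mean extracted-QC response over mean neat-standard
  response; **matrix effect**: mean post-extraction-spiked response over
  mean neat response. Their SDs pair replicates in input order, since
  source tables print mean ± SD without stating a pairing.
* **Stability**: RE per condition (three freeze–thaw cycles, 4 h at 25 °C,
  30 d at −20 °C, pre-injection residence).

Intra-day metrics use the first day's replicates (the "six times within a
single day" design); inter-day metrics pool all replicates across days into
a grand mean/SD rather than ANOVA variance components, because that is the
single mean ± SD such tables print. Acceptance bands are |RE| ≤ 15 % and
RSD ≤ 15 %, relaxed to 20 % at the LLOQ level — the cited FDA guidance's
de-facto definitions; the QC placement is low = 2.5 × LLOQ, mid = 0.5 ×
upper range limit, high = 0.8 × upper limit, which reproduces the published
QC levels (e.g. 5/500/800 ng/mL for a 2–1000 ng/mL curve).

## Quantification and censoring

Study records are back-calculated per animal and summarised to mean, SD and
n per compound × tissue × group × time. Concentrations remain in ng/mL of
homogenate throughout (the published unit); the homogenate dilution factor
(3: one volume tissue + two volumes saline) is carried on the design for an
optional per-gram conversion but never applied silently, since the source
study reports uncorrected values.

Below-LLOQ values default to zero (`policy = "zero"`), the conservative
and conventional choice for tissue AUC; `lloq2` (LLOQ/2 imputation) and
`drop` are selectable. Above-range values are never extrapolation-silenced:
they are kept and counted. Sexes are pooled for shared organs (n = 6) and
sex-specific organs use the matching sex only (n = 3); whether the original
analysis pooled sexes is unstated, so pooling is the default and a
`per_sex` switch exists.

## Noncompartmental AUC under destructive sampling

AUC is the linear trapezoid over $[0, t_{last}]$ on time-point means with
$C(0) = 0$ prepended. No $\lambda_z$ extrapolation to infinity is
attempted: with seven destructive points a terminal-slope fit is fragile,
and the targeting statistic needs only relative AUCs on a common window.

Each animal contributes one time point, so no per-animal AUC exists and a
t-test on animals is not constructible. The variance estimate is Bailer's
sparse-sampling formula, $SE^2 = \sum_i c_i^2 s_i^2 / n_i$ with $c_i$ the
trapezoid weight of point $i$. The group comparison uses
$z = (AUC_a - AUC_b)/\sqrt{SE_a^2 + SE_b^2}$.

**Design choice — t reference by default.** Bailer's original test reads
$z$ against a normal reference. With six animals per point each per-point
variance carries five degrees of freedom, and the normal reference is
measurably anticonservative here: across 4000 null simulations of the
default design the normal reference rejected at 0.065 at nominal 0.05,
while a t reference with Satterthwaite-combined degrees of freedom (the
standard small-sample refinement for sparse-sampling NCA) held 0.049. The
package therefore reports the Bailer $z$ statistic unchanged but computes
the two-sided p from the Satterthwaite t by default; `method = "z"`
restores the normal reference. Flags: `*` p < 0.05, `**` p < 0.01.

## Relative targeting efficiency

Because the two extracts contain different amounts of each compound, the
salt-processed group's AUC is first content-normalized:
$AUC_{salt}' = AUC_{salt} / (content_{salt}/content_{crude})$, removing the
in-vitro dose difference. Then, per group, every tissue's AUC is expressed
as a fraction of the summed multi-tissue AUC (heart + liver + spleen +
lung + kidney + gonads + uterus), and

$$RTE = \frac{AUC'_{salt,tissue}/AUC'_{salt,sum}}{AUC_{crude,tissue}/AUC_{crude,sum}} - 1 .$$

RTE > 0 means the tissue's *share* of total exposure increased after
processing; the statistic is scale-free, so any common factor (dose,
content, unit) cancels. Fractions sum to one per group by construction
(tested to 1e-9), and shifts are zero-sum: whenever the groups differ, at
least one tissue has RTE ≤ 0 and at least one RTE ≥ 0.

Two conventions needed deciding. First, the gonadal term: ovary (females)
and testes (males) are distinct organs of disjoint animals; the summed AUC
treats "an organ absent in one sex" as contributing zero, which makes the
sum simply the total over all collected tissues, while RTE is still
reported per organ. Second, the published rendering of the RTE formula is
typographically garbled; the implemented reading (fraction ratio minus
one) is the one consistent with the study's own usage (RTE > 0 =
increased targeting, values like liver 0.50 > testes 0.32 > uterus 0.14
used as an ordering) and with the equations it cites as previously
described. RTE is computed on point estimates, matching the source
presentation; no interval is attached by default.

Classification: tissues with RTE above a threshold (default 0), ranked
descending per compound.

## The synthetic-data generator

No raw animal data are published, so the generator *is* the test bed. It
emulates the stated design exactly: 8 tissues with sex rules, 7 sacrifice
times, 6 animals (3 per sex) per point per group, 2 groups, and the
published calibration curves (12 compounds × 8 tissues) as the forward
model from concentration to peak areas (IS area fixed at 1e5 counts).

The kinetic truth is a one-compartment extravascular shape
$C(t) = scale\,(e^{-k_e t} - e^{-k_a t})$ — chosen only because tissue
profiles must rise and fall across 10–720 min and the shape has an
analytic AUC ($scale\,(1/k_e - 1/k_a)$) for oracle checks. It is a
simulation device, not a claim about rat physiology. Defaults: $k_a =
0.03\,\mathrm{min^{-1}}$ (absorption half-life ≈ 23 min), $k_e =
0.008\,\mathrm{min^{-1}}$ (elimination half-life ≈ 87 min, peak near 60
min), per-tissue scales of 150–700 ng/mL that keep peaks inside the
calibrated ranges while letting late-time concentrations fall below
typical LLOQs, so the censoring policy is genuinely exercised.

Noise is multiplicative mean-1 lognormal at two levels: between-animal
(`cv_between`) and analytical (`cv_analytical`, default 0.05, the
mid-range RSD of the validated assay). `cv_between` defaults to 0.15,
fixed once at design time: it sits inside the realistic 10–30 % range for
rodent tissue kinetics, is consistent with the low validated assay RSDs,
and keeps the null-case RTE noise floor (≈ 0.045 mean |RTE| at n = 6) under
the 0.05 design criterion for the no-effect simulation. Targeting effects
are injected as per-tissue `salt_shift` multipliers on `scale` in the salt
group, so the expected RTE sign is known by construction. Between-animal
multipliers are drawn independently per animal × compound × tissue; real
animals would correlate tissues within an animal, which the generator does
not emulate.

What a green test does and does not establish: the simulations validate
the *arithmetic and statistical calibration* of the pipeline under a
stated noise model — they cannot validate the kinetic model against real
rats (none of the published per-animal data exist), nor the published AUC
magnitudes (figure-only) or RTE values, which are used solely as
ordering/classification fixtures.

## Numerical choices

* WLS is solved in closed form from the weighted normal equations
  (centred form, numerically stable for these magnitudes); tests compare
  against an independent solver to 1e-9 relative.
* Trapezoid AUC is exact for the piecewise-linear interpolant; the oracle
  is adaptive quadrature of `approxfun`, compared to 1e-9 relative.
* Flat calibration responses (zero weighted variance in y) report r = 0
  rather than NaN; zero variance in x is a hard degenerate-design error.
* Zero-variance group comparisons: equal AUCs give z = 0/`ns`; unequal
  AUCs with zero SE give an explicit infinite-z degenerate flag.
* `frac_crude = 0` with `frac_salt > 0` yields an explicit `Inf` RTE, not
  an error, so one undetectable-in-crude compound does not take down a
  whole report.
* Seeded generation saves and restores the caller's RNG state.

## Known limitations

* No $AUC_{0-\infty}$, $C_{max}$/$T_{max}$, or compartmental fitting — out
  of scope for a share-of-exposure statistic.
* Recovery/matrix-effect SD depends on replicate input order (pairing
  convention).
* The RTE carries no uncertainty interval by default; sparse destructive
  sampling makes a bootstrap-over-animals only approximate.
* Config and exchange formats are deliberately minimal (YAML design, CSV
  tables); no vendor raw-file or chromatogram support — the pipeline
  begins at integrated peak areas.
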