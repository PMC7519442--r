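# tissuerte

Quantification-through-targeting pipeline for LC-MS/MS multi-tissue drug
distribution studies in R.

Tissue-distribution studies of processed herbal preparations ask a
deceptively simple question: after a processing step (such as salt-frying),
does a compound's exposure *shift* toward particular organs — kidney,
uterus, ovary, testes — relative to the unprocessed preparation? Answering
it well requires a full bioanalytical chain: matrix-matched weighted
calibration, method validation, quantification of destructively sampled
animals, a sparse-sampling noncompartmental AUC, and a scale-free targeting
statistic. `tissuerte` implements that chain end to end for analysts
working from integrated peak areas (analyte + internal standard), plus a
synthetic-study generator with known kinetic ground truth so every stage is
testable without animal data.

## The statistics at the core

* **Calibration** — weighted linear least squares on area ratios,
  $\min_{a,b}\sum_i w_i (y_i - a x_i - b)^2$ with $w_i = 1/x_i^2$, the
  bioanalytical convention that equalises relative error across a
  1–1000 ng/mL range; weighted Pearson $r$; back-calculation with
  `below_lloq` / `in_range` / `above_range` flags.
* **Validation** — accuracy $RE\% = 100(\bar x - x_{nom})/x_{nom}$,
  precision $RSD\% = 100\,s/\bar x$, extraction recovery and matrix effect
  as paired response ratios, stability RE under four storage conditions;
  pass bands 15 % (20 % at LLOQ).
* **NCA under destructive sampling** — linear trapezoid AUC over
  $[0,t_{last}]$ with $C(0)=0$, Bailer's sparse-sampling standard error
  $SE^2 = \sum_i c_i^2 s_i^2/n_i$, and a group test
  $z = \Delta AUC/\sqrt{SE_a^2+SE_b^2}$ read against a Satterthwaite t
  reference (the small-sample refinement; a plain normal reference is one
  argument away).
* **Relative targeting efficiency** — after content normalization
  $AUC'_{salt} = AUC_{salt}/(content_{salt}/content_{crude})$, each
  tissue's share of summed multi-tissue AUC is compared across groups:
  $RTE = \dfrac{frac_{salt}}{frac_{crude}} - 1$, with $RTE>0$ indicating
  increased targeting, ranked per compound.

## Worked example

Simulate the default study design (8 tissues, 7 sacrifice times, 6 rats
per point per group) for one compound with a 1.5× kidney shift injected
into the salt-processed group, then run the analysis:

```r
library(tissuerte)
design <- load_design()              # packaged default design
curves <- reference_curves()         # published 12 x 8 calibration curves
truth  <- sim_truth("psoralen", design, salt_shift = c(kidney = 1.5))
peaks  <- generate_study(design, truth, curves, seed = 42)

prof <- quantify_study(peaks, curves, design)
#> Concentration profiles: 1 compound(s) x 8 tissue(s) x 2 group(s), 112 points
#>   censoring policy: zero; 0 record(s) above calibrated range

tab <- auc_table(prof)
rte <- rte_table(tab, contents = truth$contents)
classify_targets(rte)
#>   compound tissue       rte rank
#> 1 psoralen kidney 0.3360077    1

cmp <- compare_groups_table(tab)
cmp[cmp$flag != "ns", ]
#>   compound tissue auc_a auc_b    z        p flag
#> 2 psoralen kidney 93835 62916 10.5 1.94e-09   **
```

The kidney is the only tissue classified as targeted (RTE 0.34: its share
of total exposure rose from 0.27 to 0.37 after normalization), and the
group AUC difference is significant at p < 0.01 — the injected effect,
recovered. All other tissues show small negative RTEs, as they must:
fractions sum to one, so a gain in one tissue's share is other tissues'
loss.

`run_pipeline()` chains every stage and writes the curve table, validation
report, profiles, AUC table, RTE table, a markdown summary, and a
`MANIFEST.json`; `inst/cli/tissuerte.R` exposes the stages as subcommands
(`simulate`, `calibrate`, `validate`, `quantify`, `nca`, `rte`,
`run-all`).

## Layout

* `R/` — design/IO, calibration, validation, quantification, NCA,
  targeting, synthetic data, pipeline.
* `inst/extdata/` — default study design (YAML) and the published
  reference calibration curves (CSV).
* `vignettes/tissue-targeting-methods.Rmd` — model, assumptions,
  parameter choices, and what the synthetic tests do and do not establish.
* `tests/testthat/` — unit, property, and acceptance suites.
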