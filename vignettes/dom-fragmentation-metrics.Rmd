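---
title: "Retention and fragmentation metrics for carboxyl-rich DOM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention and fragmentation metrics for carboxyl-rich DOM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domfrag)
```

## The problem

Dissolved organic matter (DOM) is a mixture of an enormous number of
carboxyl-rich small molecules; at every molecular formula a natural
sample hides an undefined and large number of isomers. Because no
individual structure can be isolated, the practical way to constrain
what those molecules look like is comparative: run synthetic probe
compounds and DOM standards under identical negative-mode LC-MS and HCD
MS2 conditions, and compare summary metrics of retention and
fragmentation behavior. `domfrag` implements those metrics as a tested
pipeline, together with a seeded synthetic-data generator so that every
metric can be validated against known ground truth.

## The retention metric: %CI

For a probe compound with neutral CHO formula $f$ eluting at retention
time $t$, the cumulative-intensity metric is

$$\%\mathrm{CI}(t) \;=\; 100 \cdot
  \frac{\int_{t_0}^{t} I_f(\tau)\, d\tau}{\int_{t_0}^{t_1} I_f(\tau)\, d\tau},$$

where $I_f$ is the extracted-ion chromatogram (XIC) of the
$[M-H]^-$ ion of $f$ in a reference DOM sample. A compound at 50%&nbsp;CI
elutes at exactly half of the DOM intensity for its own formula; a
compound at 100%&nbsp;CI elutes at or after the end of the DOM elution
window. The same cumulative curve, inverted, yields the percentile
elution profile (the 5, 10, 25, 50, 75, 90 and 95% points) used to
compare whole DOM samples with each other.

Numerical choices:

* The cumulative curve is the trapezoid integral of the XIC on the scan
  grid, taken piecewise-linear between scan points. Forward evaluation
  (`percent_ci()`) and inversion (`ci_profile()`) use the *same* curve,
  so the 50th percentile is exactly the retention time at which
  `percent_ci()` returns 50. Whether the original metric summed discrete
  scans or integrated areas is not observable from its definition; the
  trapezoid is robust to uneven scan spacing, and on an even grid the
  two differ only at the peak edges.
* Probes before the first scan clamp to 0, after the last scan to 100.
* Flat stretches of the cumulative curve (regions of zero intensity)
  resolve to the earliest qualifying retention time, which makes the
  profile deterministic.
* A zero-total XIC is an error ("formula absent from DOM sample"), and
  `compound_ci()` converts that error into a flagged row so a batch of
  compounds survives individual absences.

%CI values are only comparable within a single reference run: column
replacement or flow-rate changes shift absolute retention, so
cross-column comparisons are reported side by side, never corrected.

## Formula arithmetic and assignment

All masses are monoisotopic, hard-coded from the IUPAC/CODATA tables to
keep results bit-stable. The deprotonated ion mass is
$m_{[M-H]^-} = M - m_H + m_e = M - 1.0072765$ Da; a radical anion is the
intact composition plus one electron.

`assign_formula()` searches CHO (optionally N/S/Cl/Br) compositions
within element bounds (defaults C&nbsp;&le;&nbsp;40, H&nbsp;&le;&nbsp;60,
O&nbsp;&le;&nbsp;25) under both electron configurations, with three
filters:

1. a ppm tolerance (default 5&nbsp;ppm, typical for Orbitrap data, and
   configurable everywhere a tolerance appears);
2. rings-plus-double-bond-equivalents of the neutral reading &ge; 0;
3. the electron-parity rule: valence-valid neutral (and intact radical)
   compositions carry an even H&nbsp;+&nbsp;Cl&nbsp;+&nbsp;Br&nbsp;+&nbsp;N
   count.

The parity rule deserves emphasis because it is what makes radical
detection possible at all: the radical reading of composition $x$ and
the deprotonated reading of $x + \mathrm{H}$ have *identical* m/z, so no
mass accuracy can separate them. Parity can: a closed-shell
$[M-H]^-$ fragment of a CHO molecule has an odd hydrogen count, while an
observed CHO anion with an even hydrogen count is only consistent with
an odd-electron radical. `is_radical_assignment()` exposes exactly this
test, and the test suite checks it against an independent
electron-count oracle. A consequence worth knowing: only valence-valid
neutrals (even H for CHO) are assignable, which is the correct behavior
for molecular ions. Heteroatom-bearing compositions are never considered
for the radical metric itself; whether halogenated radicals should count
is unknowable from the metric's definition, so the scope is restricted
to CHO and stated here.

Ties in assignment are broken by lower absolute ppm error, then fewer
heteroatoms, then lower RDBE, making results deterministic.

## The four MS2 metrics

For a spectrum acquired by parallel reaction monitoring at normalized
collision energy 35 or 75&nbsp;V:

* **%Parent** — intensity surviving at the parent ion m/z.
* **%FG** — intensity at m/z values reachable from the parent by
  combinations of CO2, H2O and CH4O neutral losses (carboxylic acid,
  alcohol and methyl-ether chemistry).
* **Avg Frag** — intensity-weighted mean m/z over non-parent peaks.
* **%Radical** — intensity of peaks whose best formula assignment is an
  odd-electron radical anion.

`enumerate_losses()` generates every combination
$(a \times \mathrm{CO_2}, b \times \mathrm{H_2O}, c \times \mathrm{CH_4O})$
with $1 \le a+b+c \le$ `max_total` (default 8, giving headroom over the
deepest ladders seen in natural spectra, e.g. 5&times;CO2 with
accompanying water losses) whose residual fragment is feasible:
non-negative element counts, at least one hydrogen — the fragment must
be observable as a closed-shell $[\mathrm{frag}-\mathrm{H}]^-$ anion,
which is why acetic acid supports a CO2 and an H2O loss but not the
CH4O loss that would leave CO — and fragment RDBE &ge; 0. All
combinations are treated as reachable rather than only connected
sequential chains; with feasibility filtering the two readings coincide
for the shallow ladders that carry most intensity, and the
all-combinations semantics is the one that can be checked against a
brute-force oracle.

Percentages share one denominator: the total intensity of the spectrum
after the mass-defect filter (both raw and filtered totals are recorded
in each result). Assignment precedence is parent &gt; FG &gt; radical,
so the per-peak categories — together with `unassigned` and
`excluded_halogen` — are disjoint and sum exactly to the raw spectrum
total. That conservation is asserted on every synthetic spectrum in the
test suite. The parent peak is excluded from Avg Frag (it is an average
of *fragment* masses); a parent-only spectrum therefore has an undefined
Avg Frag, reported as `NA`.

**DOM mode.** For a natural sample no single parent formula exists.
`compute_metrics_dom()` takes every MS1 peak in the isolation window
(default &plusmn;0.7 Da — a typical PRM width; the acquisition width is
not recoverable from the data, so it is configurable) around the nominal
mass, above a noise floor of 0.1% of the window's base peak, that admits
a formula assignment. Parent intensity is MS2 intensity matching *any*
precursor m/z — so parents completely labile to fragmentation still
anchor their loss ladders — and FG targets are the union of loss
enumerations over all assigned precursors, deduplicated within
tolerance so a target shared by two precursors is never counted twice.

**Mass-defect filter.** CHO ions in the 150–1000 Da range have
fractional m/z below 0.5, while chlorinated/brominated anthropogenic
pollutants fall between x.5 and x.0. `halogen_mass_defect_filter()`
keeps fractional parts in [0.0,&nbsp;0.5) (half-open: exactly .5 is
excluded) and reports exclusions with their intensities. The pipeline
emits metrics both with and without the filter, since the difference
localizes contaminant-driven outliers.

## The synthetic generator

`simulate_run()` emulates the features of real DOM runs that the
metrics respond to, with per-peak ground truth:

* **MS1/XICs** — per-formula chromatograms composed of Gaussian isomer
  peaks on a 0–11 min grid at 0.02 min spacing (a 10-min-class
  reverse-phase gradient, sampled so %CI resolution is far below the
  1-min bins used in cross-sample comparisons).
* **MS2 channels** — parent, loss-ladder rungs, a backbone C–C cleavage
  fragment (an even-electron anion outside the ladder), a demethylation
  radical channel ($[M-H-CH_3]^{\bullet-}$, the methoxy-ether signature,
  composition parent&nbsp;&minus;&nbsp;CH4), and halogenated contaminant
  peaks synthesized from real Cl/Br-bearing pollutant compositions so
  the mass-defect rule is exercised with realistic values, not arbitrary
  fractions.
* **Noise** — Gaussian m/z jitter in ppm and multiplicative log-normal
  intensity noise (mean-preserving), the standard error structure of
  centroided MS data; both default to zero so closed-loop tests are
  exact, and are switched on for recovery experiments.
* **Determinism** — a fixed seed makes the emitted run byte-identical.

`make_dom_mixture()` draws many isomers per formula from configurable
elution populations (default an even split between a hydrophilic
0.5–3 min and a hydrophobic 4–10 min window, reproducing the bimodal
XICs seen for masses with both polar and apolar isomer pools).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: physically realistic fragmentation
energetics (channel fractions are configured, not predicted), isotope
envelopes, chimeric co-isolation, detector saturation, and retention
alignment between columns. The generator validates the *metrics*, not
any chemical hypothesis.

Recovery experiments (`recovery_experiment()`) regenerate a run under
incremented seeds and summarize a metric across replicates; with noise
off the recovery is exact with zero spread, and with realistic noise
(2 ppm jitter, 10% intensity CV, 50 replicates in the shipped checks)
the estimate stays within three replicate standard deviations of the
configured channel fraction.

## Worked example

```{r example}
cfg <- sim_config(
  seed = 42,
  formulas = list(list(
    formula = "C14H14O6",
    isomers = list(list(rt = 5.5, width = 0.3, height = 1e6)),
    ms2 = list(
      "35" = ms2_channels(
        parent = 0.2,
        fg = list(list(n_co2 = 1, n_h2o = 0, n_ch4o = 0, fraction = 0.5),
                  list(n_co2 = 1, n_h2o = 1, n_ch4o = 0, fraction = 0.2)),
        backbone = 0.1),
      "75" = ms2_channels(radical = 0.9, backbone = 0.1)))))
run <- simulate_run(cfg)

x <- extract_xic(run$ms1, mz_deprotonated("C14H14O6"), tol_ppm = 5)
percent_ci(x, 5.5)            # probe at the apex: 50
ci_profile(x)

compute_metrics_single(run$ms2[[1]], "C14H14O6")  # 35 V
compute_metrics_single(run$ms2[[2]], "C14H14O6")  # 75 V

acetate_transition_check(327) # acetyl-ester loss: nominal 327 -> 267
```

## Design decisions and limitations

* The fixture CSV dialect (`scan_type, rt, precursor_mz, nce, mz,
  intensity`) exists so the full test suite runs with no binary
  dependencies; mzML ingestion is available through `mzR` and the data
  model is centroid-only — profile data is out of scope.
* The report layer writes JSON-lines logs with the seed and every
  tolerance, and each metric row carries a reference into the per-peak
  ledger, so every number in a report is recomputable from its inputs.
* Problem sizes in the shipped validation suite (551-scan grids,
  150-isomer mixtures, 50-replicate recovery runs, formula grids to
  C&nbsp;&le;&nbsp;15) were chosen so each property is established well
  beyond its Monte-Carlo error while the whole suite stays fast enough
  to run on every change.
* Known limitations: no isotope-pattern scoring, no adducts beyond
  $[M-H]^-$, no multiply charged ions, no retention-time prediction or
  cross-column alignment, and no structure elucidation from fragments —
  the metrics summarize spectra; interpreting them remains the
  scientist's job.
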