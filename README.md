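# CaMPARIquant

Quantification of CaMPARI2 photoconversion in 96-well high-content
calcium assays — including parabolic-flight campaigns where plates of
transfected chondrocytes are illuminated with 405 nm light during
specific gravity phases and imaged afterwards.

CaMPARI2 converts irreversibly from green to red fluorescence under
405 nm light, preferentially when Ca2+-bound, so an 8 s illumination
freezes a snapshot of cytosolic Ca2+ into a permanent two-colour
label. The package provides the full quantification chain for such
screens:

* **Photoconversion model** — Hill occupancy
  `f(C) = C^n / (C^n + K_D^n)` (K_D = 199.2 nM for CaMPARI2, 109.7 nM
  for CaMPARI2-F391W) driving a saturating conversion hazard
  `p(t) = 1 − exp(−k_eff t)`, `k_eff = k_free (1−f) + k_bound f`, with
  empirical and two-point calibrations.
* **Flight model** — the five-phase parabola profile (Pre-Parabola,
  Pull-Up 20 s/1.8 g, Zero-G 22 s/1e-5 g, Pull-Out 20 s/1.8 g,
  Post-Parabola), the per-parabola illumination schedule (1 GFP + 10
  CaMPARI wells per condition, ≤4 LEDs concurrent) and the LED heat
  budget (44 × 2.8 W × 8 s = 985.6 J per unit and parabola).
* **Synthetic imaging** — a ground-truthed two-channel scene generator
  emulating transfected monolayers (log-normal cell areas within
  150–5500 µm², non-fluorescent nuclear holes ≤200 µm²,
  red-autofluorescent debris, Bernoulli conversion), rendered with
  background and read noise.
* **Segmentation mask** — grayscale top-hat background removal (disc
  radius 25 µm, compiled running min/max filters), thresholding at
  4 GCU / 0.3 RCU with segmentation-adjustment and edge-sensitivity
  knobs, selective nuclear hole fill, area filtering, and green/red
  object classification into green-only / red-only / merged.
* **Metrics** — the four per-well photoconversion metrics (conversion
  rate = % of green cells also red; three red-intensity statistics)
  and Pre-Parabola baseline subtraction.
* **Statistics** — one-way ANOVA with Tukey–Kramer post-test,
  Z'-factor `1 − 3(σ_pos + σ_neg)/|µ_pos − µ_neg|` per flight, and the
  saturation fit `R(t) = r_max (1 − exp(−k t))` with a seeded
  parametric-bootstrap 90% band.

## Worked example

A small simulated campaign — one untreated plate, four illuminated
parabolas, demo-scale wells — runs end to end with:

```r
library(CaMPARIquant)
cfg <- defaultRunConfig(seed = 42, outDir = "demo")
rep <- runPipeline(cfg)
```

which schedules 88 illumination events (1971.2 J across the four
parabolas of one plate; 985.6 J per two-plate unit and parabola) and
prints per-condition mean conversion rates:

```
      condition          role conversionRate
       CaMPARI2     Histamine          56.67
       CaMPARI2  Pre-Parabola           1.25
       CaMPARI2        Zero-G           0.83
 CaMPARI2-F391W     Histamine          67.50
 CaMPARI2-F391W  Pre-Parabola          15.42
 CaMPARI2-F391W        Zero-G          12.08
 ...
Z'-factor: 0.3885
  positive: 67.5 +/- 5
  negative: 15.42 +/- 5.617
ANOVA across F391W flight phases: p = 0.495
```

Reading the output: simulated F391W wells convert at ~13–15% basally
and ~65% under histamine (CaMPARI2: ~2% and ~55%), the ANOVA finds no
phase effect (ground truth sets none — gravity does not move Ca2+ in
these cells), and the demo-scale Z' between stimulated and basal wells
is positive but below the ≥0.5 "excellent assay" mark because only
four histamine wells per condition are simulated at 30 cells each.
`runPipeline()` writes `schedule.csv`, `well_metrics.csv`,
`well_metrics_adjusted.csv` (baseline-subtracted) and `run_log.txt`
into `outDir`; identical seeds give byte-identical tables.

The model alone:

```r
v <- campariVariants()[["CaMPARI2-F391W"]]
hillOccupancy(109.7, v)        # 0.5 at K_D
calibrateEmpirical(0.65, 8)    # 0.1312 per s reproduces 65% in 8 s
```

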