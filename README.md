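# respirhythm

Real-time metabolic biomonitoring turns a fish's physiology into a water
quality sensor: sublethal contamination shows up in oxygen consumption,
carbon dioxide excretion and ammonia excretion long before overt
toxicity.  `respirhythm` implements the complete analysis chain for such
a study — juvenile zebrafish (*Danio rerio*) held in intermittent-flow
respirometry chambers under a 16 h light : 8 h dark photoperiod, exposed
for seven days to the polycyclic aromatic hydrocarbons phenanthrene
(102 µg/mL) or pyrene (70.6 µg/mL) — together with a calibrated
synthetic instrument simulator, so the whole pipeline is testable
without access to the original instrument data.

## What it computes

**Rates.** Each 450-s chamber cycle flushes, seals, and records
concentrations every 15 s over its final 300 s.  The slope at the
window centre is a weighted average of nested central differences
(stencil *n* ∈ {3, 5, 7}; weights 1 / {2,1} / {3,2,1}, normalised by the
weight sum), and converts to a mass-specific rate via the chamber
equation

```
VO2 = DOslope × (RespirVol − FishVol) × 3600 / FishWeight   [mg/kg/h]
```

(sign flipped for O₂ depletion; the analogous equations give VCO₂ from
chamber CO₂ accumulation and VN from bi-hourly tank ammonia samples,
the latter with the tank water volume).  Hourly aggregation yields the
five parameters: OR, CR, AE and the molar quotients

```
RQ = (VCO2/44)/(VO2/32)        AQ = (VN/18)/(VO2/32)
```

**Circadian structure.** Photophase/scotophase labelling and contrasts,
normalised autocorrelation of the detrended hourly series with the
dominant period taken as the largest positive local ACF maximum in the
18–30 h band, and a natively implemented Kohonen self-organizing map
(8×6 grid) over z-scored hourly metabolic fingerprints, summarised by
Ward's-linkage clusters (k = 6) and their photoperiod purity.

**Group statistics.** Mann–Whitney U (exact by enumeration for small
samples, tie-corrected normal otherwise) and classical one-way ANOVA,
assembled into the study-style summary grid with significance stars.

**Simulator.** `generate_dataset()` produces triplicate-tank sensor
traces whose true rates carry a smoothed square-wave diel rhythm, an
ammonia surge over the first 48 h and late-stage CO₂ suppression under
treatment, per-tank biological variation and per-reading sensor noise;
preset bases are calibrated by quadrature so each group's noiseless
7-day mean hits the study's reported value.

## Worked example

```r
library(respirhythm)

ts <- generate_dataset("phe", days = 7, tanks = 3, seed = 102)
rs <- estimate_rates(ts, n = 7)
group_means(rs)
#>   parameter         mean           sd n_tanks
#> 1        OR 4.377787e+02 1.471952e+00       3
#> 2        CR 7.333688e+01 8.314042e-01       3
#> 3        AE 6.893046e+02 1.141024e+01       3
#> 4        RQ 1.207694e-01 1.396112e-03       3
#> 5        AQ 2.754829e+00 3.328276e-02       3

rhythm_summary(rs)$dominant_period_h
#> [1] 24 24 24 24 24
```

The recovered 7-day means sit within ~1.5 % of the phenanthrene group's
reported values (OR 444.46, CR 73.92, AE 690.60 mg/kg/h): oxygen
consumption is suppressed roughly four-fold relative to the control
preset (1778.57 mg/kg/h) while ammonia excretion is elevated an order
of magnitude — yet every parameter keeps a clean 24-h rhythm, the
study's central observation.

The numbered drivers under `analysis/` run the full study —
`01_simulate.R` (traces), `02_rates.R` (rate tables and recovery
summary), `03_circadian.R` (rhythm + SOM/Ward cluster tables),
`04_group_stats.R` (summary grid) — writing their tables under
`results/`.

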