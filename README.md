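# o2supply

Analysis of intermittent-flow respirometry for aquatic animals: turns
sealed-chamber oxygen traces into **maximum metabolic rate (MMR)**,
**oxygen supply capacity (α)** and the **critical oxygen pressure for
maximum metabolism (P_cMax)**, with a mechanistic trace simulator for
validation and a permutation-based statistical layer. It is aimed at
comparative and conservation physiologists comparing metabolic endpoints
across treatments (here, salinity groups of a euryhaline species).

## The science in brief

During a sealed measurement period an animal of mass *W* in a chamber of
effective volume *V_eff* = *V* − *W*/1000 depletes oxygen; the uptake rate
follows from the decline slope and the water's oxygen solubility β
(µmol L⁻¹ kPa⁻¹):

    MO2 = −(dPO2/dt) · β · V_eff / W        [µmol O2 g⁻¹ h⁻¹]

* **MMR** is taken from the measurement period in which PO₂ declined most
  rapidly, after an exhaustive chase.
* **α** is estimated from a closed hypoxia trial: the per-bin supply ratio
  α₀ = MO2/PO₂ rises as oxygen falls and saturates at the supply capacity;
  α is the mean of the three largest α₀, with the slope-bin width chosen
  automatically from a sensitivity scan (α is inflated at small widths).
* **P_cMax = MMR/α** — the PO₂ below which maximum metabolism becomes
  oxygen limited.
* Rates are mass-corrected via the allometric fit MO2 = c·W^b (nonlinear
  least squares) to a common mass.
* Microbial background from blank (empty-chamber) trials is subtracted as
  a whole-chamber rate; its share of total uptake is reported per trial.
* Group comparisons use permutation one-way ANOVA (+ Tukey), permutation
  linear regression against salinity, Lilliefors and Levene tests; each
  reports both permutation and classical p-values.

Because raw field traces are rarely shareable, the package ships a
simulator (`simulate_trial()`, `simulate_cohort()`) whose ground truth
(per-animal α, peak demand, P_c) makes every estimator testable; see the
methods vignette (`vignettes/oxygen-supply-capacity.Rmd`).

## Worked example

```r
library(o2supply)
cond    <- water_conditions(26, 6)            # 26 degC, 6 psu
animal  <- animal_model(mass_g = 800, smr = 8/3, mmr0 = 8, alpha_true = 0.68)
chamber <- chamber_spec(volume_L = 40, microbial_rate_umol_L_h = 2)

hyp   <- simulate_trial(animal, trial_protocol("hypoxia", start_po2_kpa = 11.7),
                        chamber, cond, seed = 42)
blank <- simulate_microbial_check(chamber, cond, seed = 43)
micro <- microbial_rate(blank$trace, chamber, cond)$rate_chamber_umol_h

est <- alpha_from_hypoxia(hyp$trace, chamber, mass = 800, cond,
                          microbial_chamber_umol_h = micro)
mmr <- mmr_from_trial(hyp$trace, trial_protocol("hypoxia", start_po2_kpa = 11.7),
                      chamber, 800, cond, microbial_chamber_umol_h = micro)
```

This prints (seeds as above):

```
alpha = 0.681 umol O2 g-1 h-1 kPa-1 (selected bin width 600 s)
MMR at 11.7 kPa = 6.88 umol O2 g-1 h-1
PcMax = 10.11 kPa
microbial background = 79.9 umol O2 h-1 whole chamber
```

The estimated α (0.681) recovers the generating value (0.68) to 0.2%; the
MMR at 11.7 kPa is below peak demand (8) because uptake at that PO₂ is
already partially supply limited — exactly the situation P_cMax describes
(here 10.1 kPa ≈ 8/0.68 ≈ 11.8 kPa within the period-averaging bias
discussed in the vignette). The blank recovers the simulated background
(2 µmol L⁻¹ h⁻¹ × 40 L = 80 µmol h⁻¹).

A full cohort run:

```r
simulate_cohort(cohort_config(), seed = 1, outdir = "cohort")
run_pipeline(run_config("cohort", "run1", seed = 1))
# -> run1/metrics.csv, trials.csv, group_stats.csv, stats_report.json,
#    scan_<trial>.csv, run.log, output_manifest.csv (MD5 per file)
```

or from a shell: `Rscript inst/cli/o2supply.R all --seed 1 --outdir run1`.

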