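# radtlc

Radio thin-layer chromatography (radio-TLC) scanning, analysis and
qualification — in software.

## The problem

Radiochemical purity (RCP) is one of the release-critical quality-control
parameters of technetium-99m radiopharmaceuticals: the fraction of total
radioactivity present as the intended chemical species. The standard assay
spots a few microlitres of product onto a chromatographic strip, develops it
in a mobile phase, and scans the strip with a collimated scintillation
detector. The resulting chromatogram is integrated by region: the main
species and each impurity are identified by their retention factor
(Rf = distance migrated by the species / distance migrated by the solvent
front) and quantified by background-subtracted peak area.

`radtlc` implements the complete computational core of such a scanner for
radiopharmacy QC work and for method-development studies where the hardware
is replaced by a statistical simulator:

* **simulator** — a detector with a Gaussian line-spread response (default
  σ = 1.486 mm, i.e. a point-source FWHM of ≈ 3.5 mm) steps in 0.5 mm
  increments along a strip (software-limited to 120 mm → 240 channels),
  counting Poisson-distributed pulses from exponentially decaying spots
  (half-life 6.0067 h for Tc-99m) over a configurable background
  (default 0.31 cps);
* **acquisition records** — the instrument's raw-data contract: a CSV with a
  fixed metadata header (batch, operator, scan range, acquisition time,
  solvent origin/front, timestamp), a `position_mm,counts` table, and a
  SHA-256 footprint line that seals the file against undetected alteration;
* **analytics** — per-region net areas and relative percentages after flat
  background subtraction, Rf, the pharmacopoeial signal-to-noise ratio
  SNR = 2H/h (twice the net peak height over the peak-to-peak baseline
  noise), FWHM by linear interpolation of the half-maximum crossings, strip
  RCP and the dual-strip combination RCP = 100 − Σ impurities;
* **qualification** — background, linearity (Pearson r of net count rate vs
  decay-corrected activity, target r ≥ 0.99), repeatability (CV of the
  impurity percentage over six scans, target ≤ 5%), limit of quantification
  (lowest concentration with SNR ≥ 10), working range (200 × LOQ up to the
  highest verified concentration), positional accuracy (observed vs
  calculated Rf, target ≤ 10%), and Bland–Altman method comparison
  (bias ± 1.96 SD limits of agreement, Pearson r ≥ 0.95, Shapiro–Wilk
  normality of the differences).

## Worked example

Simulate the repeatability strip — 7.4 MBq of Tc-99m spotted at one end and
0.4 MBq at the other, a designed impurity of 100·0.4/7.8 = 5.13% — scan it
for 2 minutes, and integrate:

```r
library(radtlc)
scen <- make_scenario("repeatability")
cfg <- scen$config; cfg$seed <- 42
ch <- simulate_scan(scen$model, cfg)
ch
#> <chromatogram> 240 channels, pitch 0.5 mm, dwell 0.5 s, total 19469 counts
#>   batch SIM / operator simulator / integrity unhashed

regions <- region_set(c("main", "impurity", "bg"),
                      c(5, 85, 50), c(45, 115, 80),
                      c("peak", "peak", "background"))
analyze_strip(ch, regions, main_label = "main")
#> <analysis_report> RCP = 95.22% (main region 'main', integrity unhashed)
#>     label net_area_counts percent    rf    snr fwhm_mm peak_position_mm
#>      main         18509.7   95.22 0.098 4853.8    3.65            19.75
#>  impurity           930.0    4.78 0.897  257.8    3.38            99.75
#> baseline: mean 0.117 counts/channel, noise (p-p) 1 counts
```

The measured impurity (4.78%) scatters around the designed 5.13% with the
≈ 0.16 percentage-point standard deviation expected from the ~10³ counts in
the impurity peak. The main peak's FWHM of 3.65 mm reflects the detector's
3.5 mm point-source resolution. Running the full qualification suite:

```r
run_qualification(seed = 1)
#> Qualification report (seed 1)
#>  parameter               criterion                            result                pass
#>  Background              -                                    0.33 +/- 0.05 cps     TRUE
#>  Linearity               R > 0.99                             R = 1.0000            TRUE
#>  Repeatability           CV < 5%                              CV = 2.7%             TRUE
#>  Limit of quantification SNR >= 10                            4 MBq/ml (SNR = 16.7) TRUE
#>  Range                   -                                    3700-800 MBq/ml       TRUE
#>  Position accuracy       Deviation from calculated RF <= 10%  max deviation = 2.5%  TRUE
```

Every row is recomputed end to end from seeded simulations: triplicate
5-minute blanks; nine 2-minute scans of an 18.5 MBq spot as it decays to
2.5 kBq; six consecutive scans of the repeatability strip; an LOQ grid
search at SNR ≥ 10 (expressed as activity concentration via the 5 µl sample
volume); the 200 × LOQ working-range rule; and nine spots at 10 mm spacing
on a 100 mm strip.

## Command line

```sh
Rscript inst/cli/rtlc simulate --scenario repeatability --seed 7 --out rep
Rscript inst/cli/rtlc analyze rep-01.csv --regions regions.csv --out report
Rscript inst/cli/rtlc verify rep-01.csv        # exit 0 verified / 1 tampered / 2 unhashed
Rscript inst/cli/rtlc qualify all --seed 1 --out qualification
Rscript inst/cli/rtlc report qualification.csv
Rscript inst/cli/rtlc --show-config
```

All stochastic subcommands take an explicit `--seed`; outputs carry
provenance (tool version, configuration digest, seed) in-file or in a
sidecar manifest.

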