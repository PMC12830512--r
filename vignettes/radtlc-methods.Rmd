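---
title: "radtlc: simulation model, analytics and qualification methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radtlc: simulation model, analytics and qualification methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtlc)
```

## Scope

`radtlc` re-implements the computational side of a radio-TLC scanner used
for radiochemical purity (RCP) testing of technetium-99m
radiopharmaceuticals: a scan simulator that stands in for the hardware, the
hashed acquisition-record format, the chromatogram analytics, and the
instrument-qualification suite. The hardware itself — detector biasing,
pulse electronics, motor control — and the live acquisition GUI are out of
scope; the simulator reproduces the *statistical* structure of the signal
the hardware would deliver.

## The counting model

A strip bears $K$ spots, spot $k$ centred at $\mu_k$ (mm) with activity
$A_k$ (MBq) at the reference time and a deposit spread $\sigma_{d,k}$ (mm).
The detector is collimated by a narrow slit; its response to a point source
is modelled as a Gaussian line-spread with standard deviation $\sigma_r$.
A channel centred at $x$ receives the dimensionless weight

$$ w(x - \mu_k) = \Delta x \, \varphi(x-\mu_k;\, 0,\, \sigma_{\mathrm{eff},k}),
\qquad \sigma_{\mathrm{eff},k}^2 = \sigma_r^2 + \sigma_{d,k}^2, $$

with $\Delta x$ the channel pitch and $\varphi$ the normal density. Summed
over a grid wide enough to cover the response, the weights add to one, so
the configured efficiency $\varepsilon$ (cps/MBq) is a *whole-spot*
quantity: a 1 MBq spot well inside the scan range contributes
$\varepsilon$ counts per second summed over all channels, regardless of the
pitch.

The expected rate at position $x$ and elapsed time $t$ (hours) is

$$ r(x, t) = b + \sum_k \varepsilon\, A_k\, 2^{-t/T_{1/2}}\, w(x-\mu_k), $$

with $b$ the per-channel background rate and $T_{1/2}$ the half-life. A
scan of total duration $T$ over $n = \lfloor R/\Delta x\rfloor$ channels
(channel centres at $(i+\tfrac12)\Delta x$, $i = 0..n-1$) assigns each
channel the dwell $\tau = T/n$ and draws

$$ c_i \sim \mathrm{Poisson}\!\left(\tau\, r(x_i,\, t_0 + i\tau/3600)\right), $$

i.e. decay is evaluated at each channel's own dwell start rather than frozen
at scan start. For 2-minute technetium scans the difference is negligible
(<0.4% across the strip); it matters for hypothetical multi-hour scans and
is fixed here for reproducibility.

### Parameters, defaults and their calibration

| parameter | default | why |
|---|---|---|
| scan range | 120 mm | firmware safety limit of the travel |
| step | 0.5 mm | stepper increment; 240 channels over 120 mm |
| response σ | 1.486 mm | gives point-source FWHM $2\sqrt{2\ln 2}\,\sigma \approx 3.5$ mm, the instrument's reported resolution; the true slit ⊗ crystal response is unpublished |
| efficiency ε | 5000 cps/MBq | chosen so the 0.4 MBq repeatability impurity accumulates ~10³ counts in a 2-min scan, reproducing the instrument's ~3% impurity CV; absolute count rates are unpublished |
| background b | 0.31 cps | the measured instrument background |
| half-life | 6.0067 h | technetium-99m; configurable for other isotopes |
| deposit σ | 0 mm | point-like drop; the detector response dominates the recorded width |

The defaults are the package's *stated world*: they were fixed once from
the documented instrument characteristics (resolution, background,
precision), not adjusted to make any test pass. Dead time, pile-up and
SiPM temperature drift are deliberately absent — the hardware compensates
for them upstream of the data the software ever sees.

### What the simulator does and does not emulate

A green qualification run establishes that the *analysis chain* behaves
correctly on data with the right Poisson statistics, decay behaviour,
geometry and resolution. It does not establish anything about real
detector pathologies the model excludes: baseline drift, chromatographic
tailing (peaks here are symmetric Gaussians), strip inhomogeneity, or
operator variability in spotting and integration bounds. The method
comparison in particular replaces 100 real paired kit measurements with
paired simulations of two virtual instruments (the reference having ten
times the test efficiency), so it validates the Bland–Altman machinery and
the expected Poisson-limited agreement, not the field agreement of two
physical scanners.

## Acquisition records and integrity

Records are CSV files: seven `# key=value` metadata lines in fixed order,
a `position_mm,counts` table, and a final `# sha256=<hex>` footprint over
all preceding bytes. LF newlines, UTF-8, period decimal marks and a
deterministic shortest-form numeric rendering make the digest platform
independent; positions are written in exact decimal form because channel
centres sit at half-pitch offsets (0.25, 0.75, … mm) that a fixed
one-decimal rendering would corrupt. The hash covers the metadata header as
well as the data: the origin/front values determine every Rf, so their
integrity is as release-critical as the counts. Parsers accept footprint-
free records (third-party instruments) but flag them `unhashed`;
`analyze_strip()` *refuses* records whose footprint fails verification
rather than warning, since a tampered raw-data file must not produce a QC
result.

## Analytics conventions

Several estimator choices are conventions the upstream description leaves
open; they are fixed here as follows.

* **Baseline**: flat mean of the background region. No sloped-baseline fit
  — the instrument's baselines are stable, and a flat model keeps net areas
  additive over adjacent regions.
* **Noise**: peak-to-peak (max − min) of the background region, the
  pharmacopoeial convention paired with the SNR $= 2H/h$ definition.
* **Peak position**: channel of maximum net counts; ties break toward the
  lower position, so results are deterministic.
* **Region membership**: a channel belongs to `[start, end)` by its centre
  — half-open so adjacent regions never double-count a channel.
* **Negative net areas** (blank regions fluctuating below baseline) are
  clamped to zero with a warning before percentage normalization, keeping
  percentages in [0, 100] and summing to 100.
* **FWHM**: linear interpolation of the two half-maximum crossings of the
  net profile; undefined (error, or `NA` within a full report) when the
  peak does not rise above baseline or a crossing leaves the region.
* **Dual-strip RCP**: $100 - \sum \text{impurities}$, floored at zero —
  the standard kit-monograph combination; which species counts as the
  impurity on each strip is the caller's choice via `main_label`.

## Qualification methodology

Each test mirrors the instrument's qualification protocol and scores
against its printed criterion:

* **Background** — triplicate 5-min blanks; per-record rate = total counts
  / total time; mean ± sample SD. No acceptance criterion; the value
  feeds baseline expectations.
* **Linearity** — nine 2-min scans of an 18.5 MBq spot at elapsed times
  spaced evenly from 0 to the moment the sample reaches 2.5 kBq
  (77.21 h at $T_{1/2}$ = 6.0067 h; the protocol states only "nine times
  over three days", and even spacing of a fixed, taped strip is the
  natural reading). Pearson r on the raw scale between the *peak-region*
  net count rate and the calculated activity; pass at r ≥ 0.99.
  Peak-region rather than whole-strip counts was chosen because it is what
  the integration spreadsheet measures; at these count levels the two are
  indistinguishable.
* **Repeatability** — six consecutive 2-min scans of the 7.4 + 0.4 MBq
  strip; CV of the impurity percentage; pass at ≤ 5%. The design value of
  the impurity is $100 \cdot 0.4 / 7.8 = 5.13\%$.
* **LOQ** — grid search over a user-supplied descending concentration list
  (spot activity = concentration × 5 µl volume), median SNR over
  replicates, threshold exactly 10. Median (not mean) over replicates
  keeps a single outlier replicate from moving the LOQ. The simulated LOQ
  lands where the stated-world efficiency and background put it — the
  physical instrument's 0.5 MBq/ml is a hardware fact the calibration does
  not target.
* **Working range** — 200 × LOQ up to the highest linearity concentration
  (3700 MBq/ml for 18.5 MBq in 5 µl), guaranteeing impurities of 0.5% of
  the lower limit remain quantifiable.
* **Positional accuracy** — nine spots at 10 mm spacing on a 100 mm strip;
  each observed peak is the count maximum within a ±5 mm half-open window
  around its expected position (the windows tile the strip exactly at this
  spacing); pass when the largest relative Rf deviation is ≤ 10%. On the
  0.5 mm grid a spot centred between two channels is located half a pitch
  away at worst, a 2.5% deviation at Rf 0.1.
* **Method comparison** — paired RCP values from the two virtual
  instruments; Pearson r (target ≥ 0.95), Bland–Altman bias and limits of
  agreement at bias ± 1.96 SD of the differences, Shapiro–Wilk normality
  of the differences at α = 0.05 (delegated to `stats::shapiro.test`, the
  standard published algorithm).

All stochastic tests draw their seeds from one master seed recorded in the
consolidated report, so any row can be reproduced exactly.

```{r qualification}
run_qualification(seed = 1)
```

## Numerical and degenerate-input choices

* σ = 0 line spread uses the delta convention (all weight on the nearest
  channel) instead of dividing by zero.
* Zero baseline noise yields an infinite SNR with a warning — an idealized
  noiseless input, not an error.
* An all-blank strip under forced peak regions raises an
  undefined-percentage error rather than returning 0/0.
* Seeded simulation restores the caller's RNG stream afterwards, so
  embedding `radtlc` calls in a larger seeded analysis does not perturb it.
* Pitch constancy of parsed positions is checked to 10⁻⁹ mm; metadata
  numbers round-trip through a shortest-form decimal rendering (`%.10g`).

## Known limitations

* Symmetric Gaussian peaks only; no tailing, no overlapping-peak
  deconvolution, and no automatic peak detection — integration bounds are
  always user-supplied, as on the instrument.
* The efficiency and response defaults are calibrated to reported
  resolution and precision, not measured; absolute simulated count rates
  should not be compared against a physical detector.
* The comparison study is simulation-paired; interchangeability claims
  about two real instruments require real paired data.
* Single-isotope counting: no spectral discrimination, no multi-isotope
  strips.
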