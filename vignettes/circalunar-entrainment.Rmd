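---
title: "Circalunar entrainment of menstrual records: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circalunar entrainment of menstrual records: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaluna)
```

## The scientific problem

The human menstrual cycle has a period close to the Moon's months, and
long-term menses diaries show stretches in which onsets keep a stable
phase relative to lunar events — behaviour characteristic of a weakly
coupled endogenous oscillator (a *circalunar clock*) rather than of
coincidence. Three lunar cycles are candidate zeitgebers:

* the **synodic month** (full moon to full moon, 29.5306 d) — moonlight
  and gravity;
* the **anomalistic month** (perigee to perigee, 27.5545 d) — gravity;
* the **tropical month** (northernmost to northernmost declination,
  27.3216 d) — gravity.

This package provides the full analysis chain for testing such
synchronization on per-woman onset records: a self-contained lunar
ephemeris, circular phase statistics with axial duplication, automated
detection of entrained runs and limits-of-entrainment curves, and a
stochastic circle-map generator for synthetic cohorts with ground
truth. Long-term menses diaries of the kind this pipeline targets are
generally access-restricted, so the generator doubles as the package's
reference data source: its defaults emulate the published demographic
structure of such cohorts (see below).

## The lunar ephemeris

Events are computed, not downloaded. `moon_position()` evaluates a
truncated periodic series of the modern lunar theory (44
longitude/distance terms, 30 latitude terms, plus the standard additive
corrections), giving geocentric ecliptic longitude and latitude to a few
hundredths of a degree, distance to tens of kilometres, and declination
via the mean obliquity. A low-precision solar longitude (three-term
equation of centre) supplies the Moon--Sun elongation.

All six event kinds are then found the same way: an hourly scan of the
relevant scalar (elongation, distance, declination) over the requested
window, followed by local refinement — linear inverse interpolation for
the syzygy crossings (elongation through 0°/180°), parabolic
interpolation for the apsis and standstill extrema — and rounding to the
whole hour, the resolution of classical printed lunar almanacs. Using
one position model for all three cycles keeps them mutually consistent;
we deliberately did not use separate closed-form syzygy/apsis series.
Verified accuracy (tests): syzygies within ±2 h of published almanac
instants, apsides within ±6 h (apsis extrema are flat), declination
within ±0.3°.

ΔT (the offset between Terrestrial Time and UTC) is interpolated from a
decadal table; between 1950 and 2024 it is under 70 s and thus
irrelevant at hour resolution, but it is applied for correctness. All
times are UTC; menses onsets carry day resolution and are anchored at
00:00 UTC, a single representative choice that shifts all phases
identically and therefore does not affect any test statistic.

### Standstill epochs

Monthly standstills ride an 18.61-year envelope (lunar nodal
precession) whose peaks and troughs are the Major and Minor Lunar
Standstills. `standstill_epochs()` computes monthly maxima of
|declination|, smooths them with a **centred 13-month moving mean**, and
reports interior turning points of the envelope. A moving mean (rather
than a moving maximum) is used because it has a unique smooth extremum;
a 13-sample moving maximum produces 13-window plateaus of tied values
and an ambiguous epoch year. Six months at each edge of the smoothed
range are excluded so that monotone run-in behaviour at a window edge is
never reported as an epoch. The computed epochs reproduce the
documented sequence: minors 1959, 1978, 1997, 2015; majors 1969, 1987,
2006, 2025. (Some sources give 1978, others 1979, for that minor epoch;
the envelope minimum computed here falls in 1978.)

## Phases and circular statistics

An onset between consecutive reference events at $t_{prev}$ and
$t_{next}$ gets phase

$$\theta = 2\pi\,\frac{t - t_{prev}}{t_{next} - t_{prev}},$$

i.e. position is normalised to the *actual* bracketing interval, not the
nominal month. An onset exactly at a reference event gets $\theta = 0$
(assigned to the interval it starts).

Because a cycle may lock to either the reference event or its
anti-event (full *or* new moon), pooled distributions are axial-bimodal.
**Phase duplication** ($\theta \mapsto 2\theta \bmod 2\pi$) folds the
two modes together before testing; every result records whether it was
applied. Two tests are run on the (optionally doubled) phases:

* the **Rayleigh test** against the uniform null, $Z = nS^2$ with the
  standard small-sample exponential p-value correction;
* the **directed V test** with hypothesised direction $\mu_0 = 0$ (the
  reference event), $u = S\cos(\bar\theta - \mu_0)\sqrt{2n}$ referred to
  the upper normal tail.

$S$ is the mean resultant length; pooled distributions with
$S \ge 0.10$ are flagged *highly peaked*, following the conventional
threshold for these data. Histograms use 30 equal sectors (about one
day per sector for the synodic month). Per-subset tests are reported
raw, without multiplicity correction, matching standard practice for
these figure-by-figure analyses; the JSON report states this.

## Segmentation, period estimation, run detection

**Segmentation** replaces the traditional by-eye phase-jump calls with
penalised binary segmentation of the interval-length series
(piecewise-constant mean, penalty $\beta\hat\sigma^2\log n$ with
$\beta = 3$, minimum segment six intervals, $\hat\sigma^2$ from
first differences). A segment is *consistent* when its interval SD is
≤ 3 d and its mean lies in 20--40 d. On i.i.d. N(29, 1) intervals the
default penalty yields no spurious changepoints in ≈99% of replicates.

**Period estimation** uses the event-time (Schuster) form of the
Lomb--Scargle periodogram: power at trial period $P$ is the Rayleigh
power $n S(P)^2$ of the onset phases $2\pi t_k / P$, scanned over
20--40 d at 0.01-d resolution. We evaluated the more common binarized
daily-series periodogram and found its peak biased upward by order
$P/n$ days (0.03 d at 20 cycles) through the spectral-window cross-term;
the event-time form peaks exactly at the true period for a noise-free
train and is origin-shift equivariant. With i.i.d. cycle-to-cycle
timing noise of SD $\sigma$ the information bound on any period
estimator over $n$ cycles is $\sigma/\sqrt{n}$: at the generator's
default $\sigma = 0.8$ d, ±0.2 d coverage at 95% requires ≥ 62 cycles,
which is why the period-recovery check uses 120-cycle uncoupled
segments.

**Run detection** declares entrainment when ≥ 4 consecutive onsets keep
their phase within 0.1 cycle (36°, ≈ 3 d synodic) of the *run's own
circular mean* — so a stable phase two days before full moon counts,
exactly like a stable phase one day before. Four, not three, is the
threshold because two- and three-month coincidences are common after
phase jumps. Reference and anti events are scanned separately; since a
reference-locked stretch appears almost identically in the anti
framing, runs whose index ranges coincide by ≥ 50% of the longer run
are deduplicated keeping the smaller circular variance. The 0.1-cycle
tolerance is exposed as an argument (`tolerance`), as is the minimum
run length.

A fundamental limitation documented here rather than hidden: over only
four cycles, *slow relative drift* near resonance
($|\tau - T| \lesssim 2$ d) stays within any such tolerance without
coupling. A 4-cycle phase-coherence criterion therefore fires on
uncoupled records near resonance at the permutation-null rate (several
runs per 100 cycles); the tests verify that the detector matches that
permutation null rather than pretending a near-zero false-positive rate
is achievable.

**Limits of entrainment**: each consistent segment is one episode; it
counts as entrained for a cycle when a detected run of that cycle
overlaps it or sits within one onset of it (the synchrony may precede
or follow the consistent free-run). The curve reports the percentage of
entrained episodes per 1-day bin of the episode's free-running period;
empty bins carry no value rather than zero.

## The synthetic cohort generator

No suitable public long-term records exist, so the generator is a
first-class module, not a fixture. Each woman is a stochastic circle
map: with $\tau(t)$ her free-running period,

$$t_{n+1} = t_n + \tau(t_n)
  - \sum_c A_c \sin\!\big(\Phi_c(t_n) - \psi_c\big) + \varepsilon_n,
  \qquad \varepsilon_n \sim N(0, \sigma^2),$$

where $\Phi_c$ is the zeitgeber phase of cycle $c$ (from the computed
ephemeris, or idealized strictly periodic cycles) and $\psi_c$ the
preferred phase (default: about one day before the reference event, the
classic phase relation). The additive-sine map is the minimal model
with the three behaviours the data show: free-run, 1:1 locking on a
limited range (the Arnold tongue $|\tau - T_c| \le A_c$, exact for this
map and verified by sweep), and relative coordination at the tongue
edges (alternating plateaus and drifts; with the deterministic map
0.1 d outside the tongue, the fraction of steps slower than half the
mean drift is ≈ 0.56).

Defaults are fixed at the cohort conditions the package emulates and
are not tuned per analysis: recording starts at age N(25.9, 6.4) years;
spans 2--37 years with mean ≈ 6 (left-skewed gamma); free-running
period 32 d at menarche, shortening by 0.25 d/year (≈ 33 → 24.5 d over
three decades), per-woman slope jitter SD 0.05 d/y; cycle noise
$\sigma = 0.8$ d; coupling defaults $A = (1.5, 0.5, 0.5)$ d for
(synodic, anomalistic, tropical), reflecting the synodic month being
the strongest zeitgeber; pregnancy interruptions at 0.03/woman-year
pausing recording 270--420 d. Internal state is continuous; dates are
rounded to days only on output, avoiding quantization locking. Each
woman uses a counter-derived substream of the root seed, so cohorts are
byte-reproducible and stable under partial regeneration.

Ground truth labels an onset as locked to cycle $c$ when realized
intervals stay within ±0.5 d of $T_c$ for ≥ 4 consecutive cycles. Note
this is an *output-side* definition: with $\sigma = 0.8$ d it labels
only the quietest locked stretches, which is intentional — truth labels
mark stretches that are unambiguously locked.

What the generator does *not* emulate: hormonal dynamics, seasonal or
light-pollution modulation of coupling (era effects are emulated by
lowering $A_c$), Southern-Hemisphere seasonality, and recording errors.
Consequently, passing tests demonstrate that the pipeline recovers what
the model puts in; they cannot certify behaviour on features real data
may have that the model lacks.

## Numerical and design choices

* Period grid 20--40 d at 0.01 d; peaks on the grid boundary warn.
* Gap threshold 60 d (≈ twice the longest entrainable period)
  separates cycles from pregnancy/lactation/missing-data pauses; gaps
  split records into blocks for segmentation and run detection, but
  onsets adjacent to gaps still contribute to phase plots.
* Era boundary 2010-01-01 on the onset date; winter subset {Dec, Jan},
  summer {Jun, Jul}; standstill windows are the centre year ±1 calendar
  year, except centre 2025 which uses 2023--2024 (the epoch falls at
  the data-era edge).
* Records spanning < 2 years are excluded by default, loadable with
  `keep_short = TRUE`.
* Onset exactly at a reference event → phase 0; histogram bins are
  half-open $[2\pi k/30, 2\pi(k+1)/30)$.
* Mensograms fold from the first onset (configurable), one row per
  started fold window, repeated three times horizontally.
* Problem sizes in the test-suite simulations (cohorts of 10--50 women,
  8--12-year records, 100--10,000 Monte-Carlo replicates) were chosen
  as the smallest sizes at which the tested properties are
  statistically decidable.

## Known limitations

* The ephemeris is geocentric and truncated: fine for hour-level event
  timing, not for topocentric work, eclipse prediction, or tides.
* The 4-cycle run criterion cannot separate near-resonant drift from
  genuine weak coupling (see above); limits-of-entrainment curves
  inherit the corresponding null rate, which is why zero-coupling
  cohorts are compared against a permutation oracle rather than
  against zero.
* The directed-test p-value uses the normal approximation of the V
  statistic; for n < 10 it is rough (the package requires n ≥ 4).
* Segmentation assumes piecewise-constant mean intervals; slow
  continuous period change within a segment inflates the interval SD
  and is flagged inconsistent rather than split.
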