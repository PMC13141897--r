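# circaluna

Analysis of synchronization between menstrual cycles and the Moon's
three months, for chronobiologists and biostatisticians working with
long-term menses diaries.

Some long-term records show stretches in which menses onsets hold a
stable phase relative to lunar events — the signature of a weakly
coupled endogenous oscillator (*circalunar clock*) with a limited range
of entrainment, rather than coincidence. Three lunar cycles are
candidate zeitgebers: the **synodic month** (full → full moon,
29.5306 d), the **anomalistic month** (perigee → perigee, 27.5545 d),
and the **tropical month** (northern lunistice → northern lunistice,
27.3216 d). `circaluna` provides the whole analysis chain:

* **Ephemeris** — computed (not downloaded) hourly-resolution series of
  full/new moons, perigees/apogees, monthly declination standstills;
  the 18.61-year standstill envelope and its Major/Minor epochs; the
  derived constants (Saros 18.03 y, nodal cycle 18.61 y, lunar day
  24.8 h, semidiurnal tide 12.4 h).
* **Circular statistics** — onset phases normalised to the bracketing
  interval between reference events
  (θ = 2π·(t − t_prev)/(t_next − t_prev)), axial phase duplication
  (θ → 2θ mod 2π) for full-or-new-moon bimodality, Rayleigh and
  directed V tests, 30-sector rose plots.
* **Entrainment** — changepoint segmentation of interval series,
  free-running period τ by event-time Lomb–Scargle periodogram
  (20–40 d), detection of runs of ≥ 4 consecutive onsets with stable
  phase (±0.1 cycle), limits-of-entrainment curves (% entrained
  episodes vs τ).
* **Synthetic cohorts** — a stochastic circle-map oscillator
  t(n+1) = t(n) + τ − Σ A_c·sin(Φ_c − ψ_c) + ε with aging τ, gaps, and
  ground-truth lock labels; reproduces free-run, 1:1 locking on the
  Arnold tongue |τ − T| ≤ A, and relative coordination at the tongue
  edges.
* **Reporting** — mensograms (actogram-style folded rasters with lunar
  overlay lines), annotated polar plots, and a deterministic
  end-to-end pipeline writing CSV/JSON reports.

Everything is tibble-in/tibble-out and pipe-friendly; results have
`tidy()`/`glance()` and `autoplot()` methods.

## Worked example

```r
library(circaluna)

# lunar events for a decade, computed from the built-in ephemeris
ev <- lunar_events("1995-01-01", "2003-12-31")

# synthetic cohort: 20 women, default coupling A = (1.5, 0.5, 0.5) d
cfg <- sim_config(n_women = 20, seed = 42, record_span_years = c(3, 7),
                  zeitgeber_mode = "ephemeris", events = ev,
                  start_date = as.Date("1996-01-01"))
coh <- simulate_cohort(cfg)
nrow(coh$records)
#> [1] 1427

# population-level phase analysis against the synodic month
pooled_phase_analysis(coh$records, ev, cycle = "synodic", doubled = TRUE)
#> Pooled phase analysis: synodic cycle, subset = all (phases doubled)
#>   n = 1427, S = 0.1789 (highly peaked)
#>   Rayleigh p = 1.02e-20, V-test p = 0.02454
```

The cohort's 1427 pooled onsets are far from uniform on the doubled
synodic phase circle (Rayleigh p ≈ 10⁻²⁰), and the mean resultant
length S = 0.18 exceeds the 0.10 convention for a highly peaked
distribution — as expected for records generated with synodic coupling
stronger than the gravimetric couplings. Per-woman entrained runs:

```r
detect_runs(coh$records[coh$records$woman_id == "sim001", ], ev, "synodic")
#> # A tibble: 3 × 9 — locked stretches of 10, 21 and 14 consecutive cycles
```

`locked_kind` names the event framing the run was scored in (a
full-moon-locked stretch is equally coherent relative to new moons, at
a half-cycle offset; `mean_offset_days` gives the phase).

Mensograms and rose plots:

```r
plot_mensogram(coh$records[coh$records$woman_id == "sim001", ], ev)
autoplot(pooled_phase_analysis(coh$records, ev, "synodic"))
```

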