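# tcanon

An R toolkit for anonymizing **time-continuous physiological data** —
ECG and other patient-monitor signals — and for measuring what
anonymization does to such data. It is aimed at researchers who need to
release or share waveform data and want the privacy–utility tradeoff to
be something they compute rather than assert.

The package makes three things executable:

1. **A data model with testable structural properties.** A record is a
   strictly ordered sequence of `(t, v)` samples on a declared channel
   domain. Practical continuity is checked as three conditions (small
   enough steps, an interpolate exists, the interpolate introduces no
   jumps), and sample-order preservation under an index-stable
   anonymizer α is checked pairwise. The safety statements for whole
   mechanism classes — e.g. that perturbation `v ↦ v + V_r` is a domain
   endomorphism and hence continuity-preserving, while noise on the time
   axis with `|noise| > min(Δt)/2` can invert sample order — run as an
   empirical verification matrix (`theorem_matrix()`).

2. **Curve-level utility metrics.** Discrete Fréchet distance (C++
   dynamic program), Hausdorff and STED baselines, a Fourier curve norm
   `|c| = ||FFT(c)||_p` (p ≥ 2), the region-corrected aligned curve
   difference `d(c1, c2, τ, ω) = F(G(E(c1, c2, τ, ω), c2), c2)`, the
   normalized time-continuous mean relative error
   `MRE = (1/N) Σ d(c1, c2, τ, ω) / |c1|` with `N = Σ d`, decision
   utility `U = (1/|D|) Σ 1[d(e) = d(α(e))]`, and the width-based
   information loss (0 on raw data).

3. **Concrete attacks and a privacy estimate.** A rule-based ECG event
   detector (R peaks, deep Q, shallow S/R, missing U, pacemaker spikes,
   ST elevation at the clinical ≥ 0.1 mV / ≥ 80 ms infarction
   criterion); Δt linkage matching records by median inter-beat interval
   within a tolerance ε_Δ, optionally verified by U-wave presence;
   event-signature linkage by edit distance; and a Monte-Carlo estimator
   of the privacy ratio `P_{ε,a}(i, S) = Pr_{ε,a}(S∖i, i) / Pr_{ε,a}(S, i) ≤ 1`.

All fixtures come from a built-in synthetic generator: an annotated
P-QRS-T-U ECG with exact ground truth, auxiliary monitor channels
(SPO2, HF, pulse, BF, NIBP, IBP, PPG), injectable diagnostic events and
multi-person databases with linkage ground truth.

## Worked example

Generate a small multi-person database, run the timing-linkage attack
before and after bounded perturbation, and measure the utility cost:

```r
library(tcanon)

db <- generate_database(n_persons = 4, records_per_person = 2, seed = 7)
baseline <- attack_evaluate(db, eps_delta = 0.01)

anon <- lapply(db$records, function(r) {
  out <- perturb_record(r, noise_spec("both", scale_v = 0.05, bound_v = 0.15,
                                      scale_t = 0.02, bound_t = 0.06), seed = 1)
  ord <- order(out$t); out$t <- out$t[ord]; out$v <- out$v[ord]
  out
})
after <- attack_evaluate(tc_database(anon), eps_delta = 0.01)

pairs <- pair_records(db, tc_database(anon))
mre <- tc_mre(pairs, correction_params(tau = 0.05, omega = 0.1),
              alignment_family(character(0)), norm_params(p = 2, resample_fs = 250))
```

This prints:

```
baseline linkage: precision 1.00 recall 1.00
after perturbation: precision 1 recall 0.75
time-continuous MRE: 0.00352
```

Read: on the unprotected database the attacker links every same-person
record pair by inter-beat timing alone (the fixture's heart rates are
deliberately disjoint). The bounded time/value noise breaks a quarter of
those links while costing very little utility — the time-continuous MRE
of the released curves is ~0.0035 relative to the raw curve norms. The
mechanism-property matrix for the same build:

```r
theorem_matrix(trials = 50, seed = 1)
#>                mechanism   property       expected violations matches_expected
#> 1        generalize_time      order     guaranteed          0             TRUE
#> 2                   swap      order     guaranteed          0             TRUE
#> 3                   swap continuity     guaranteed          0             TRUE
#> 4          perturb_value continuity     guaranteed          0             TRUE
#> 5             dp_laplace continuity     guaranteed          0             TRUE
#> 6   perturb_time_bounded      order     guaranteed          0             TRUE
#> 7 perturb_time_unbounded      order not_guaranteed        150             TRUE
#> 8       generalize_label continuity not_guaranteed        150             TRUE
```

## Command line

A thin CLI ships at `inst/cli/tcanon` (subcommands `simulate`,
`anonymize`, `evaluate`, `attack`, `verify`, `report`), e.g.

```sh
Rscript inst/cli/tcanon simulate --persons 5 --records 2 --seed 7 --out data/
Rscript inst/cli/tcanon verify --trials 100 --seed 1 --out matrix.json
```

## Acceptance script

`scripts/acceptance.R` recomputes the detector's infarction-criterion
boundary from scratch: it generates the default synthetic ECG template,
injects ST elevations swept over magnitudes (0.02–0.20 mV at 120 ms
width) and widths (20–160 ms at 0.15 mV), runs the default event
detector on each, and reports the smallest flagged magnitude (`t3`, mV)
and width (`t4`, ms) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/tcanon-methods.Rmd` documents the model and its assumptions,
the generator's stated world and what it does not emulate, the metric
operationalizations, numerical edge cases, and known limitations.
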