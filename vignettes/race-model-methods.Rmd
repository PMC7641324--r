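---
title: "The two-helicase race model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-helicase race model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirace)
```

## The mechanism being modeled

RecBCD binds a duplex DNA end and unwinds with two motors: RecD, the faster
helicase, travels the 5′-ended strand toward the far end; RecB, the slower
one, travels the 3′-ended strand. Because RecB lags, single-stranded DNA
loops out between the motors at rate $v_D - v_B$ (`loop_size()`). Two events
can trigger the RecB nuclease:

* **Chi-triggered cutting.** A Chi hotspot (5′-GCTGGTGG-3′), read in only
  one orientation, triggers a cut a few nucleotides 3′ of the 8-mer. The
  nuclease domain reaches its cutting position quickly (about 1 ms), so the
  cut is tightly localized — observed over only a 2–3 nt window.
* **End-stop cutting.** An ATP-competitive inhibitor of RecB sensitizes the
  enzyme so that when RecD stops at the far end, RecB cuts where it then
  is. The nuclease swing after an end stop is slow (roughly 200–300 ms), so
  RecB advances 200–300 nt past the naive position $S \cdot x/y$ before the
  cut, and the product band is correspondingly smeared.

The two triggers race. With the Chi site at distance $c$ from the entry end,
Chi wins when $c / v_B < S / v_D$, i.e. $c < S \cdot x/y$ with
$x/y = v_B/v_D$. Since the inhibitor lowers $x/y$ with concentration, a
substrate switches from Chi-dominated to end-stop-dominated cutting as the
dose rises — on the packaged 2270-nt substrate (Chi 1300 nt from entry,
threshold $x/y = 0.573$) the switch falls between 50 and 100 μM, exactly as
in the gels the generator emulates.

## Rate laws and the inhibition model

Each motor follows the single-substrate competitive-inhibition law

$$v = \frac{v_{\max}\,[\mathrm{ATP}]}{K_m\left(1 + [I]/K_i\right) + [\mathrm{ATP}]},$$

whose signature is the Cheng–Prusoff relation
$IC_{50} = K_i\,(1 + [\mathrm{ATP}]/K_m)$: potency falls linearly with ATP.
The assayed IC50 pair (10 μM at 25 μM ATP, 100 μM at 4 mM ATP) pins down
$K_i = 9.43$ μM and $K_m = 417$ μM via `solve_ki_km()`; these are the
packaged kinetic defaults. RecD's inhibition constant defaults to 7.3-fold
weaker than RecB's — the ratio of the computed docking affinities at the two
ATP sites — so the inhibitor slows RecB *relative to* RecD; only the
direction of that asymmetry matters for the race, and the magnitude is a
configuration knob. Whether RecD is inhibited at all in solution is not
established; the default encodes "less inhibited", not "uninhibited".

Nuclease activity in the solubilization assay is taken proportional to RecB
velocity (`relative_activity()`), an interpretation — the experiments
establish competition, not which subunit's ATPase limits solubilization.

## Table mode versus kinetic mode

The reproduction targets use **table mode**: a per-concentration calibration
$(x/y, \text{advance})$ looked up directly, because the source experiments
report per-concentration fits, not motor velocities. The packaged table is

```{r}
default_calibration()
```

The 25 and 400 μM ratios are the observed ~70% and ~30% cut positions; the
50–400 μM advances are the magnitudes of the measured negative intercepts;
the 50–200 μM ratios are linear interpolation (no per-concentration slopes
are printed); and the 0 μM ratio (0.80) back-extrapolates the same trend,
consistent with Chi cutting being observed on the 4350-nt substrate without
inhibitor (the race needs $x/y > 3380/4350 = 0.78$ there). **Kinetic mode**
computes $x/y$ from the rate laws instead and is the right tool for
exploring hypothetical kinetic parameters.

Two places where the race model knowingly diverges from the gels it
emulates: at 25 μM on the 4350-nt substrate the table gives $x/y = 0.70$,
below the 0.78 race threshold, so the generator produces an end-stop band
where the experiment still shows the Chi band; and on the 1340-nt substrate
(threshold 0.276) the model keeps Chi cutting up to 400 μM whereas the
experiment loses the Chi band above 100 μM. Both reflect the model's sharp
either/or race; the experimentally anchored 2270-nt switch is reproduced
exactly.

## Stochastic components

* **End-stop swing delay**: gamma-distributed with mean `tau_stop_ms`
  (default 250 ms, the middle of the 200–300 ms range) and coefficient of
  variation `cv` (default 0.2, giving the observed 200–300 nt smear at
  $v_B \approx 1$ nt/ms). The data constrain only the mean; the gamma family
  is our choice of a positive, unimodal delay law.
* **Chi-cut position**: pinned at the scanned Chi cut distance with ±1 nt
  uniform jitter (a 3-nt window). The alternative reading — RecB advancing
  during the ~1 ms fast swing — moves the cut by ≤1 nt at ~1 nt/ms, so both
  interpretations give the same sharp band.
* **End-stop sensitization**: hyperbolic occupancy
  $p = [I]/([I] + k_{sens})$ with $k_{sens} = 75$ μM, the midpoint of the
  observed ~50–100 μM half-maximal range. At $[I] = 0$, $p = 0$: no cut
  without drug on Chi-free DNA.
* **Chi recognition probability**: default 1 (cutting efficiency per
  encounter is not quantified); configurable.
* **Velocity scale**: $v_D = 1$ nt/ms, the canonical unwinding rate, so
  nucleotides and milliseconds interchange numerically.

All randomness flows from a single integer seed per generator call; a fixed
seed reproduces output exactly.

## The measurement layer

Migration is log-linear, $d = a - b\log_{10} L$ (defaults $a = 120$ mm,
$b = 30$ mm/decade, chosen so the whole 100–6000 nt validity range maps to
positive distances on a 22-cm-class gel), with Gaussian bands of
point-spread $\sigma = 0.8$ mm and **molar** weighting — the substrates are
end-labeled, so band area tracks molecule count, not mass. Fragments
shorter than the validity floor electrophorese off the gel and are dropped
with bookkeeping (`metadata$n_off_gel`); this genuinely happens to the
smeared low-dose product on the shortest substrate. The default marker
ladder {4350, 2270, 1340, 1000, 500, 250, 100} nt spans the boiled
substrates and generic standards (the original digest-fragment ladders are
not published) and is configurable.

Band detection takes local maxima above a relative threshold, bounds each
peak at its flanking valleys, centers it at the intensity-weighted centroid
("middle of the band"), and reports the full width at half maximum. Two
species closer than about one point-spread merge into one band — documented
behavior, matching what a densitometrist would resolve. Interpolation back
to length is piecewise-linear in $(d, \log_{10} L)$, exact at markers, and
refuses to extrapolate outside the ladder span; bands at the span edge are
snapped within a 0.05-mm tolerance rather than discarded.

## Inference choices

* Product-vs-substrate fits use ordinary least squares with uniform
  weights: three substrate lengths per concentration, with band-position
  uncertainty similar across lanes, give errors-in-variables methods
  nothing to work with. The full-length band (within 2% of the substrate
  length) is excluded; only Chi-free lanes contribute, since the Chi band
  sits at a fixed 970 nt and is not a linear function of $S$.
* Recovery is definitional: ratio $= 1 -$ slope, advance $= -$intercept,
  swing time $=$ advance$/v_B$. A positive intercept clamps the advance to
  zero with a warning rather than failing.
* Dose-response fitting is a four-parameter logistic with free Hill
  coefficient (initialized at 1; the assays fit no explicit model, so the
  shape is left free). Optional inverse-squared-activity weighting matches
  the multiplicative noise of counting-based assays and is used for the
  reproduction script; the default remains unweighted least squares.
* The synthetic assay's dose grid is a 2-fold serial dilution
  0/1.25/2.5/5/10/20/40/80 μM — the standard bench design bracketing the
  expected IC50.

## Problem sizes and what the tests show

The packaged experiment sizes are modest by design: 2000 molecules per lane
for generation defaults, 5000–10000 for population summaries, 200
replicates for coverage checks — enough that Monte-Carlo error is small
against the tolerances tested (band positions to 1%, coverage to a few
percent). The test suite establishes: closed-form/simulation agreement when
noise is switched off; migration/interpolation round trips within 1%;
Cheng–Prusoff versus numeric half-inhibition roots to $10^{-6}$;
end-to-end parameter recovery from noiseless lanes to within 1% and
classical CI coverage ≥90% under 30-nt band noise; and the dose-dependent
Chi/end-stop switch.

What passing these tests does **not** show: that real gels obey log-linear
migration over this range, that real swing delays are gamma, or that
solubilization tracks RecB velocity — the generator encodes the model's own
assumptions, so recovery tests validate the inference machinery and the
internal consistency of the model, not the biology. Reaction-time
truncation is ignored by default (at ~1 nt/ms every substrate finishes in
under 5 s of a 60-s reaction); enzyme dissociation, RecA loading, loop/tail
annealing products and buffer-regime effects on nuclease mode are out of
scope.
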