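---
title: "Models and methods: force-ramp analysis of polymorphic G-quadruplex folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: force-ramp analysis of polymorphic G-quadruplex folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4tweezers)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, and the design choices
made where the design was genuinely open.

## The experiment being modelled

A G4-forming DNA sequence is held between a surface and a magnetic bead via
double-stranded handles. Force is ramped linearly (default 2 pN/s from 1 to
60 pN); if a folded structure is present it ruptures at a random force,
producing an abrupt extension jump. The force is then dropped to 1 pN for a
hold time so the molecule can refold, and the cycle repeats. Three kinds of
information come out of many such cycles: the distribution of rupture
forces (mechanical stability of each conformation and its population), the
extension jumps (how many nucleotides each conformation sequesters), and
the dependence of the folded fraction on hold time (refolding kinetics).
Thermal melting curves provide an independent, ensemble measure of
stability.

Sequences with a bulge between guanine tracts are polymorphic: besides the
fully-folded G4 they populate partially-folded intermediates. When the
bulge sits next to a terminal guanine, the dominant intermediate is a
guanine-vacancy-bearing quadruplex (GVBQ) in which that terminal guanine is
flipped out of the tetrad core.

## Bell kinetics under a force ramp

Each folded conformation is a Bell state: rupture is a single barrier
crossing with force-dependent rate `k(F) = k_u exp(F Δx‡ / k_BT)`, where
`k_u` is the zero-force unfolding rate (1/s) and `Δx‡` the distance to the
transition state (nm). Because the ramp is deterministic, time and force
are interchangeable and everything is formulated in force. Integrating the
hazard along the ramp gives the closed-form survival, density, and modal
force implemented in `ramp_survival()`, `ramp_pdf()` and `modal_force()`;
`sample_force()` inverts the CDF exactly, so simulated rupture forces
follow the model to machine precision rather than through discretised
time stepping.

Assumptions worth stating: the barrier is stationary over the ramp
(ν = 1; no Dudko-style corrections), refolding during the seconds-long
ramp is neglected, and each cycle carries at most one rupture. These match
how force-ramp data of this kind are conventionally analysed.

At the default 2 pN/s, a state rupturing near 55 pN with `Δx‡ ≈ 1 nm`
corresponds to `k_u` between 1e-7 and 1e-5 1/s — the mechanically stable,
slowly-unfolding regime characteristic of fully-folded parallel G4s.

## The censored mixture likelihood

`fit_bell_mixture()` maximises, over K Bell components with weights `w_i`
and a never-folded weight `w0`,

```
sum_j log( sum_i w_i p_i(F_j) )  +  n_norupt * log( w0 + sum_i w_i S_i(F_end) )
```

A cycle without a rupture below the 60 pN ceiling is ambiguous: the
molecule may never have folded, or a folded state may have survived the
ramp. The two are experimentally indistinguishable, so both routes appear
in the no-rupture term; the fitted `w0` is exactly the no-rupture mass the
Bell survival cannot explain (reported as `w_censored_excess`). A design
consequence we consider a feature: fitted component weights are fractions
of *cycles*, so they are directly comparable to per-peak percentages that
sum to less than 100% — the shortfall is the never-folded fraction. The
`weight_events` column renormalises over detected events for the other
convention.

Numerical choices: parameters are `(log k_u, Δx‡, weight logits)` with
`Δx‡` box-constrained to [0.2, 5] nm (the log-k/Δx anticorrelation is
otherwise unbounded); the likelihood has an analytic gradient;
initialisation is a k-means split of the forces with moment starts
(cluster mean → modal force; cluster sd → `Δx‡` via the Gumbel-like scale
`k_BT/Δx‡ · π/√6`), and 10 jittered restarts are run, best likelihood
kept, all seeded. `select_K()` chooses K by BIC with ties to the smaller
model. MLE on raw forces (not histogram least squares) is the default
because it is bin-free and handles censoring; a histogram-based fit is
retained in the test suite as an independent oracle, where the two agree
on peak positions within 1 pN.

## From extension jumps to nucleotides

Released single-stranded DNA is modelled as an inextensible Marko–Siggia
worm-like chain, `F(z) = (k_BT/L_p)[1/(4(1−z)²) − 1/4 + z]`. A rupture
releasing `n` nucleotides at force `F` produces a jump
`Δx = n·l_c·z(F) − d_fold`, where `z(F)` is the numerically inverted
relative extension, `l_c` the contour per nucleotide, and `d_fold` the
end-to-end extent the folded structure already spanned. `nt_from_step()`
inverts this per event at its own rupture force; per-population averages
follow the posterior component assignment of a mixture fit.

Defaults (`polymer_params()`): `L_p = 0.8 nm`, `l_c = 0.56 nm/nt`,
`d_fold = 2.0 nm`, `k_BT = 4.11 pN·nm` (room temperature, 23–25 °C). These
are standard literature values for ssDNA, exposed in configuration rather
than hard-coded, and the package's claims about nucleotide counts are
roundtrip-consistent under them rather than dependent on absolute
calibration. The inextensible (no stretch modulus) form is adequate below
60 pN at this precision.

The sequence side: `parse_tract_sequence()` reads a tract-grouped sequence
string (whitespace separates the four G-tracts; every guanine in a group
is a core guanine, non-G bases between them are the bulge) and
`expected_step_nt()` counts the inclusive span between the outermost
*structured* core guanines — all of them for the fully-folded topology,
dropping the terminal one for a 5′- or 3′-peeled GVBQ. Loops and internal
bulges are inside the span; dangling tails are not. This single convention
reproduces every tabulated value for the packaged 27-sequence panel
(e.g. 16 nt full vs 14 nt GVBQ for both the 5′-bulge and 3′-bulge
single-nucleotide designs, 15 nt for the bulge-free reference). The ~13 nt
minor intermediate seen for the 5′-bulge design is not assigned a topology
(none is established); scenarios carry it as a free `step_nt`.

## Step detection in traces

`detect_step()` slides a two-window statistic along the extension trace.
Within each window the baseline is fitted by a straight line and the step
is the jump between the two fits at the window boundary. The local *linear*
(not constant) baseline matters: along the ramp the handle extension rises
at up to ~1.5 nm/s, which would bias a plain difference-of-means statistic
by more than half a nanometre at the default window — comparable to the
smallest steps of interest. With linear side-fits the estimate is exact on
linearly drifting baselines and the residual WLC curvature bias is below
a few thousandths of a nanometre. Detection is thresholded on an SNR whose
noise scale comes robustly from first differences (`mad(diff(x))/√2`);
with the default `min_snr = 5` the false-positive rate on pure-noise
traces is below 1%, and 5 nm steps under 1 nm bead noise are detected
essentially always with |bias| < 0.2 nm.

## Folding kinetics

Refolding at low force is first-order towards an incomplete plateau:
`p_fold(t) = p_st[1 − exp(−k_fold t)]`. `fit_pfold()` fits folded/unfolded
counts by binomial MLE on `(logit p_st, log k_fold)` — counts per time
point are small and heteroscedastic, so unweighted least squares on
proportions would misweight the plateau — with delta-method standard
errors, and a per-tether mode (fit each tether, report mean ± SD across
tethers) mirroring how replicate tethers are usually summarised. Hold
times are the programmed times at the 1 pN hold; ramp duration is
excluded. The canonical six-point design used throughout the package
places early points (3–9 s) to resolve the rate of fast folders and late
points (30–60 s) to anchor the plateau; slow folders
(`k_fold < 0.05 1/s`) instead use holds up to 300 s, since a 60 s ceiling
leaves their plateau — and hence `p_st` — unidentified.
`split_pst_by_stability()` apportions the folded fraction at the 40 pN
threshold; ramp-surviving (censored) cycles count as mechanically stable.

## Melting curves

`fit_melting()` fits the phenomenological four-parameter sigmoid
`y(T) = y_f + (y_u − y_f)/(1 + exp(−(T − T_m)/w))` by Levenberg–Marquardt
least squares, multi-started over a grid of candidate `T_m` values. A
phenomenological sigmoid (rather than a van 't Hoff two-state form with
ΔH) is used deliberately: only the inflection point `T_m` is consumed
downstream, and the fit is affine-invariant in the signal, so raw
ellipticity, absorbance at 265 nm, or normalised fraction folded all give
the same `T_m`. Flat curves (amplitude indistinguishable from noise) are
rejected as non-identifiable rather than fitted.

## The simulator and what it does (not) emulate

`simulate_cycles()` draws, per cycle, a conformational outcome from the
scenario's categorical mixture, a rupture force by exact inverse-CDF
sampling (draws beyond 60 pN become censored cycles), and an extension
jump from the WLC forward model plus Gaussian recording noise
(`sigma_step`, default 0.6 nm — typical bead-tracking precision).
Unfolded/misfolded molecules produce no rupture; mechanically weak
species that would rupture below ~4 pN are merged into this class, since
their steps are undetectable against the ssDNA baseline. State identity
is redrawn independently every cycle: the pooled-cycles analysis this
package implements has no molecule memory, so per-molecule kinetic
partitioning is intentionally out of scope. `simulate_trace()` adds a
dsDNA-handle WLC baseline (default 1000 nt, `L_p = 50 nm`,
0.34 nm/nt) and per-sample bead noise for exercising the detector.

Packaged scenarios (`load_scenario()`) encode reported ensembles of the
bulged-G4 panel — e.g. the 5′-end-bulge design with peaks at 22/36/47 pN
and fractions 62/25/7% plus 6% never folded; the 3′-end design at
31/46 pN with 33/63%; mid-bulge designs dominated by a ~55 pN state; and
vacancy-filled (guanine–peptide conjugate) variants whose ~20 pN GVBQ
peak moves to ~53–55 pN. Where only a peak force and fraction are
reported, scenarios fix `Δx‡ = 1.0 nm` and solve `k_u` from the modal
force: any point on the iso-mode curve reproduces the peak, and 1 nm sits
mid-box for fitted transition distances of G4 unfolding. The `step_nt` of
the unassigned ~16 pN weak species (10 nt) is a synthetic choice, flagged
as such.

What passing recovery tests does *not* show about real data: real traces
drift, beads wobble anisotropically, loading rates wander, conformations
can interconvert within a cycle, and per-molecule heterogeneity exists.
The simulator models none of these, so recovery here demonstrates the
estimators are correct and well-calibrated under the stated models, not
that the models exhaust real measurements.

## Problem sizes and determinism

Simulated studies use 5000 cycles for mixture recovery (the scale of a
pooled multi-molecule data set), 120 cycles per hold time across six times
for kinetics, 66-point melting grids (20–85 °C at 1 °C), and a few hundred
seeded replicates for detector calibration. Every stochastic function
takes an integer seed and is bit-reproducible given it. Degenerate inputs
(no events, all-censored, flat melting curves, single hold times,
zero-spread bootstrap) raise informative errors rather than returning
numbers.

## Known limitations

* Single loading rate: `(k_u, Δx‡)` are identified from one ramp speed via
  the distribution's location *and* width; a loading-rate series would
  constrain them more strongly.
* The Bell (ν = 1) form is assumed exact; soft barriers would bias `Δx‡`.
* Elasticity constants are literature defaults, not instrument
  calibrations; absolute nucleotide counts inherit their uncertainty even
  though roundtrip consistency is exact.
* The never-folded class is a single force-independent weight; it cannot
  represent weakly structured species with low but nonzero rupture forces.
* `expected_step_nt()` presumes three-tetrad parallel topologies with
  exactly twelve core guanines, as in the packaged panel.
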