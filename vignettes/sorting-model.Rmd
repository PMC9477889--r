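---
title: "The sorting model: joint discriminant subspaces and density peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sorting model: joint discriminant subspaces and density peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldadp)
```

## The problem and the model

Extracellular electrodes record the superimposed action potentials of the
few neurons near the tip, plus background activity from many distant
ones. Spike sorting recovers the single-unit trains: detect spikes, cut
and align their waveforms, embed them in a low-dimensional feature space
and cluster. The two classic failure modes are highly similar waveforms
(different neurons, nearly identical shapes at the electrode) and high
background noise; both blur the cluster boundaries in any fixed,
unsupervised feature space.

The sorter implemented here couples the two stages so they repair each
other. The feature space is a supervised linear discriminant (LDA)
subspace: given labels it maximizes between-class relative to
within-class scatter, so it concentrates exactly on the contrasts that
separate the current clusters. The labels come from density-peaks (DP)
clustering, which makes no distributional assumption: cluster centers are
points of high local density lying far from any denser point, and all
other points follow their nearest denser neighbor. Starting from a PCA
subspace, the loop

1. project the waveforms,
2. cluster the projection with DP (always seeding `K_init` clusters),
3. refit the discriminant projection from the fresh labels,

runs until the labeling reproduces itself (or an iteration cap), after
which similar clusters are merged by a compactness/separation criterion.
The merge step is what turns the fixed working `K_init` into a
data-determined number of units.

The underlying assumptions are worth stating. The model assumes spikes
are already well aligned (one peak per waveform at a fixed sample),
that units are stationary over the sorted window (no electrode drift),
and that overlapping spikes are rare enough to ignore; it resolves
neither drift nor overlap. DP assumes that a unit's spikes form one
density mode in the projection; bursting units with strong amplitude
decay violate this and will be over-split (then possibly re-merged).

## Parameters

All defaults live in `run_config()`:

* `K_init = 4` — clusters seeded per iteration. Sparse electrodes rarely
  carry more than 4 separable units per channel; the merge step can only
  reduce the count, so `K_init` is an upper bound on reportable units.
* `d = 3` — subspace dimension. Matches the feature budget customarily
  given to sorters on single channels, and keeps `d ≤ K_init − 1`, the
  rank of the between-class scatter, so no discriminant direction is
  wasted.
* `t = 0.015` (dimensionless) — cutoff-distance index: `d_c` is the
  `round(M·t)`-th smallest of the `M = n(n−1)/2` pairwise distances. The
  density-peaks rule of thumb is 1–2% of neighbors; 0.015 is the
  midpoint, and values outside `[0.01, 0.02]` trigger a warning.
* `alpha = 1.6` — merge-threshold coefficient, `R_th = α · mean(R)` over
  cluster pairs. Must exceed 1 (otherwise the largest similarity always
  exceeds the mean and merging cannot stop); values at or below 1.4 warn.
  A structural consequence: at `K = 2` the single pair's threshold is
  `α R_12 > R_12`, so two-cluster solutions never merge to one.
* `min_ite = 5`, `max_ite = 50` — iteration bounds. The minimum forces
  the subspace to actually adapt before convergence is declared; the
  maximum guarantees termination (non-convergence is recorded, not an
  error — the last labeling is merged and returned).
* `convergence = 0.99` — label agreement declaring a fixed point,
  measured as the maximum fraction of identically assigned spikes over
  one-to-one matchings of cluster ids (DP can permute center order
  between iterations, so raw equality would never trigger).
* Detection: `band = c(300, 3000)` Hz (4th-order Butterworth, applied
  forward–backward for zero phase), `thresh_mult = 4` on the robust noise
  scale `median(|x|)/0.6745`, `wave_len = 64` samples, `peak_index = 20`,
  1 ms refractory suppression.
* `match_tol_ms = 0.3` — tolerance for matching extracellular spike times
  to intracellular ground-truth peaks, the partial-ground-truth
  evaluation used with paired recordings.

## Numerical and design choices

**Discriminant solver.** The trace-ratio objective
`J = tr(W'S_bW)/tr(W'S_wW)` has no closed-form optimum; the package
solves the standard ratio-trace relaxation — the generalized eigenproblem
of `(S_w + εI, S_b)` via Cholesky whitening — and returns an orthonormal
basis of the top-`d` eigenvector span. Orthonormality matters twice: the
trace-ratio problem is conventionally posed under `W'W = I` (and `J`
depends only on the span, so the basis choice is free), and an
orthonormal `W` keeps feature-space geometry commensurate with waveform
space. Returning `S_w`-whitened eigenvectors instead would stretch
low-variance directions enormously, and the compactness/separation
ratios driving the merge step would inherit that distortion.
`lda_fit(trace_ratio = TRUE)` refines the solution with Dinkelbach
iterations (eigenproblems of `S_b − λS_w`) for users who want the exact
trace-ratio optimum; in our testing it changes results marginally.
The ridge `ε = 10⁻⁶ · tr(S_w)/p` guards against singular within-class
scatter (tight clusters, `p > n`).

**Distance convention.** The DP stage uses squared Euclidean distances
literally, and `d_c` is drawn from the same squared-distance list, so the
kernel argument `d_ij/d_c` is internally consistent;
`pairwise_distances(squared = FALSE)` restores the root convention of the
original DP formulation. The density shift `−1` is likewise implemented
literally; it never changes the density ordering but does enter
`λ = ρδ`. `local_density(shift = FALSE)` drops it. Squared distances are
accumulated coordinate-wise in column order so the matrix is
bitwise-identical to a naive double loop — density tie-breaks therefore
cannot flip on rounding noise, and the whole DP state is reproducible
against a brute-force reference (the test suite holds it to that).

**Tie-breaks and degenerate cases.** Density ties are broken by point
index (lower index counts as denser), making the density maximum unique;
center selection breaks `λ` ties by larger density, then lower index.
If the density maximum is not selected as a center, it is assigned to its
nearest center with a warning. If all pairwise distances are zero, `d_c`
falls back to machine epsilon with a warning. Coincident cluster centers
produce infinite similarity and merge unconditionally. Merging absorbs
the smaller cluster into the larger (ties: lower label) and keeps the
absorber's exemplar as the merged center — the merge loop works on DP
exemplar points, not centroids (`use_centroid = TRUE` switches), whereas
the Davies–Bouldin index in `dbi()` uses centroids, as is standard.
Two printed-formula ambiguities are resolved as options: the cutoff rank
is based on the pair count (`rank_basis = "points"` gives the literal
small-index reading), and the merge threshold averages over the
`K(K−1)/2` cluster pairs (`denominator = "points"` gives the
spike-count reading, which would make the threshold vanish for any
realistic `n` and merge everything — retained only for replication).

**Label matching.** Sorting accuracy and label agreement use exact
optimal one-to-one matching of cluster ids, by exhaustive permutation up
to 8×8 contingency tables (spike-sorting cluster counts are small);
beyond that a greedy matching stands in. Indices throughout the package
are 1-based, R's native convention; file formats use 1-based sample
indices too.

## What the simulator emulates — and what it does not

`make_templates()` models the waveforms of co-recorded neurons as a
common biphasic spike shape plus per-neuron deviations: the deviation
components are orthonormalized against the base shape and placed at
equal angles in a 2-D deviation plane, so all pairwise template
distances are comparable — the balanced geometry of the classic
simulated benchmarks, where each test set holds three distinct templates
of graded similarity. The deviation radius is bisected until the mean
pairwise Pearson correlation hits a target drawn in the requested
regime: `"low"` similarity targets 0.4–0.65 (all pairs below 0.7),
`"high"` targets 0.86–0.92 (all pairs within 0.85–0.98; a cap keeps
templates distinct shapes rather than near-copies). Templates are
zero-mean (AC-coupled recordings carry no DC), peak-normalized to 1 at
sample 20, and constrained to be peak-dominant (|amplitude| ≤ 0.85 away
from the peak, troughs well above the peak magnitude) so that noisy peak
alignment cannot flip between peak and trough and masquerade shifted
copies as extra units. Deviation lobes are sharper (1–2.5 samples) than
the background shapes: neurons seen by one electrode differ mostly in
fine temporal detail, while the summed background is comparatively
smooth — this is also precisely the regime in which a supervised
subspace can outperform a variance-ranked one, since the discriminative
directions are not the high-variance directions.

Background noise is built the way the classic simulated benchmark builds
it: a dense superposition (about six overlapping shapes per sample, so
the amplitude distribution is near-Gaussian) of randomly timed,
randomly chosen spike shapes from a 24-shape catalog, plus a broadband
noise floor at 30% of the total standard deviation. The catalog is
distinct from the unit templates — background activity comes from other
neurons — and the white floor reflects electrode/amplifier noise; a
purely spike-shaped background would leave directions of waveform space
with essentially zero noise, which no real recording has (and in which a
regularized discriminant would degenerately hide). The noise is rescaled
to the requested standard deviation exactly, quoted relative to the unit
spike peak of 1, at the benchmark's graded levels (0.05–0.40).

`generate_recording()` produces continuous traces: per-unit Poisson
trains (default 5 Hz) with a 2 ms refractory deletion, templates added
at the event times, noise added on top, ground truth recorded before
overlap. `generate_waveform_set()` is the detection-free shortcut: it
cuts waveforms at the known ground-truth times, so the template peak
sits exactly at sample 20 and detection-based alignment jitter is
deliberately absent — the benchmark this emulates likewise extracts
waveforms at known spike times. The jittered path exists too:
`generate_recording()` followed by `detect_and_align()`.

Features of real data the simulator does **not** produce: electrode
drift, burst-driven amplitude decay, overlapping-spike superposition
within a window (overlaps occur in recordings but ground truth is logged
pre-overlap), multi-channel geometry, and non-stationary noise. Passing
tests on this generator therefore demonstrates correctness of the
algorithmic chain and robustness to noise level and waveform similarity
as modeled — not robustness to drift or overlap, which the method does
not attempt to address.

## Problem sizes used in the checks

The bundled tests and `scripts/acceptance.R` run the full sorter on
waveform sets of 450–600 spikes (150–200 per unit, three units), ten
simulation seeds per condition, noise levels 0.05–0.20, and continuous
recordings of 10–20 s at 24 kHz; the brute-force DP equivalence check
uses 100 random instances of up to 12 points, where exhaustive double
loops are exact. These sizes were chosen so every property is exercised
at realistic per-channel scale while the whole suite stays quick to run.

## Known limitations

* The merge threshold is relative (`α · mean R`); when one pair of true
  units is dramatically more similar than the others, a correct
  three-cluster solution can still exceed it and over-merge. This is
  inherent to the thresholding rule, visible at the hardest
  similarity/noise corners.
* The iteration has no restarts; on hard instances it can converge to a
  poor fixed point that supervised refitting then entrenches. The PCA
  ablation (`refine_subspace = FALSE`) is the cheap diagnostic.
* `K_init` bounds the number of reportable units from above; channels
  with more separable units need a larger `K_init` (at some cost in
  runtime and over-splitting to be merged back).
* Overlapping spikes are detected as single events aligned to the larger
  peak; close doublets within one window can be absorbed.
* The MAT-file reader supports the v5 dialect (including compressed
  elements); v7.3/HDF5 files are detected and must be re-saved as v5.
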