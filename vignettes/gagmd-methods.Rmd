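---
title: "Methods and design notes for gagmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gagmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagmd)
```

gagmd collects the analysis machinery used to compare molecular-dynamics
force fields on protein–glycosaminoglycan (GAG) systems: proxy energy
landscapes rendered as disconnectivity graphs, ring-pucker and
glycosidic-torsion conformational analysis, RMSF/B-factor flexibility
comparison with paired statistics, and WHAM reconstruction of potentials
of mean force from umbrella-sampling windows. This vignette records the
models, the tunable parameters and their defaults, the numerical choices
made where the design was genuinely open, and what the synthetic
validation does and does not demonstrate.

Units everywhere: Å for distances, kcal/mol for energies, ns for times,
K for temperatures, degrees for angles (torsions on (−180, 180], pucker
phase on [0, 360)).

## Proxy energy landscapes (MDDG)

A saved MD trajectory visits a sequence of conformational basins; its
per-frame potential-energy trace carries a coarse image of the landscape
actually sampled. The construction here treats local minima of the
(smoothed) energy time series as *proxy minima* and the intervening
maxima as *proxy transition states*. This is a fast visualization of the
sampled landscape, not a stationary-point analysis: with frames saved
every nanosecond, adjacent configurations skip intermediate minima, so
basins are coarse-grained and apparent barriers are inflated.

**Smoothing.** Gentle Savitzky–Golay smoothing (default: 5-frame window,
cubic polynomial) attenuates that barrier inflation while leaving basin
assignments essentially unchanged. The filter is the standard local
least-squares polynomial; the first and last `(window−1)/2` frames are
fitted over the truncated asymmetric window rather than padded with
invented data. When the truncated window holds fewer than `order + 1`
points the degree is reduced to `n − 1` there, which makes those fits
interpolating — for the default 5/cubic setting the two frames at each
edge pass through unchanged.

**Cutoff time scale.** The degree of smoothing is summarized by the
reciprocal of the filter's approximate −3 dB cutoff frequency. The
package evaluates the least-squares closed form
`f3dB = (p + 1) / (3.2 W − 4.6)` per sampling interval, reading the
window variable `W` as the full window length (the reading under which
the default 5-frame cubic filter at 1 ns sampling gives 2.85 ns, i.e. a
3 ns effective cutoff at nearest-ns rounding — consistent with how the
setting is quoted in the field). The identity filter (window 1) has no
−3 dB point; `cutoff_timescale()` returns the Nyquist period
`2·Δt` with a warning.

**Extrema.** `detect_proxy_extrema()` is a plain alternating scan.
Plateau runs of equal smoothed values collapse to a single extremum at
their first frame (deterministic and order-preserving). Boundary frames
may be minima but never transition states: a trajectory is assumed to
start and end inside a basin. A strictly monotone series therefore has a
single minimum at its lower endpoint.

**Barrier tree.** Because barriers along a 1-D time axis satisfy
`barrier(i,k) = max(barrier(i,j), barrier(j,k))` for `i<j<k`, the
single-linkage agglomeration of minima in ascending order of separating
maxima reproduces every pairwise barrier exactly; `n` minima give
`n − 1` merges whose heights are the sorted maxima energies, monotone
toward the root and ultrametric. The test suite checks the construction
against an independent brute-force enumeration of intervening maxima on
randomly generated series. Each recurrence of a basin is a distinct
leaf — on a 1000-frame gently smoothed trace this yields on the order of
200–250 proxy minima, most of them shallow within-basin noise wiggles
(white noise smoothed by the default filter has a local-minima rate of
about 0.24 per frame). `coarse_grain_minima()` optionally merges minima
whose separating barrier prominence falls below a threshold; with the
threshold placed between the noise scale and the smallest physical
barrier this recovers genuine basin visits (see the synthetic section).

**Rendering.** `layout_tree()` emits the classic picture: the vertical
axis is energy, each leaf descends from its first merge height to its
minimum energy, internal nodes are horizontal connectors at their
barrier heights with risers toward the parent. Within each internal node
the subtree containing the lower-energy minimum goes left, which makes
the layout deterministic. Leaves are colored by an order parameter
(typically the GAG heavy-atom RMSD to the first frame) through a stated
colormap (`hcl.colors`, Viridis by default), mapped linearly over the
observed range.

## Conformational analysis

**Torsions.** `dihedral_angle()` implements the IUPAC signed torsion
(cis = 0°, positive clockwise viewed from the second toward the third
atom); the convention satisfies `d(p1,p2,p3,p4) = d(p4,p3,p2,p1)` and is
cross-checked in the tests against an independent projection
construction and against `bio3d::torsion.xyz`.

**Glycosidic linkages.** For a 1→4 bond between consecutive GAG residues
(numbered 1-based from the reducing toward the nonreducing end),
φ = O5(n+1)–C1(n+1)–O4(n)–C4(n) and ψ = C1(n+1)–O4(n)–C4(n)–C3(n); 1→3
bonds use the O3/C3/C2 variants. Heatmaps are accumulated on a fixed
5° × 5° grid over (−180, 180]², which resolves the ~50–170° separations
between torsional states at typical 10³-frame statistics; counts per
linkage always sum to the frame count.

**Ring puckering.** `cremer_pople()` follows the standard construction:
geometric-centre origin, mean plane from the two weighted lattice
vectors, out-of-plane displacements `z_j`, the m = 2 Fourier pair
(q2, φ2) and the alternating q3, with `Q² = q2² + q3² = Σ z_j²`,
`θ = atan2(q2, q3)`. Atom order O5, C1, …, C5 puts the 4C1 chair at the
north pole. The 38 canonical conformers (2 chairs, 6 boats, 6
skew-boats, 12 envelopes, 12 half-chairs) are generated internally from
idealized displacement patterns passed through the same formulas, so
classification (`assign_conformer_cp()`, nearest vertex by great-circle
distance) is exactly consistent with measurement; rings with
`Q < 0.1 Å` are called planar, far below pyranose amplitudes
(~0.5–0.6 Å).

The alternative two-dihedral rule classifies by the ring torsions
C1–C2–C3–C4 and C1–O5–C5–C4 against reference signatures measured on the
same ideal geometries, with a ±30° tolerance per dihedral. Two torsions
cannot separate every canonical form — symmetry pairs such as 3S1/1S5 or
O,3B/B2,5 share identical signatures — so the default reference covers
the four mutually separated forms that GAG ring analysis reports (4C1,
1C4, 2SO, 1S3); anything else maps to "other".

**RMSD/superposition and contacts.** Kabsch superposition is computed by
SVD with the usual reflection guard; RMSD defaults to heavy atoms after
alignment to the first frame. Contact maps average, over frames, the
distance between mass-weighted residue centres of mass (hydrogens
included in the COM; standard atomic masses by element). Input
coordinates are assumed whole/imaged — no periodic re-imaging is
performed.

## Flexibility comparison

`rmsf_profile()` aligns all frames to the first (Cα fit, falling back to
heavy atoms; configurable), computes the time-average structure, takes
per-atom fluctuations about that average without re-alignment iteration,
and averages per residue with mass weights:
`RMSF_res = sqrt(Σ m_a ⟨Δr_a²⟩ / Σ m_a)`.

Experimental profiles come from crystallographic B-factors through the
Debye–Waller relation `RMSF = sqrt(3B/(8π²))` (per-residue mean of the
atomic B column), or, for NMR-style ensembles without B-factors, from
the per-residue RMSF across ensemble models. Profiles are normalized to
unit Euclidean norm (`Σ RMSFN² = 1`); Pearson and Spearman correlations
are invariant to that scaling, so correlation-based comparisons do not
depend on which convention a study used.

Force fields are compared on paired per-system correlation coefficients
with a paired Student's t test and a Wilcoxon signed-rank test. The
Wilcoxon statistic is `W = min(W+, W−)` on mean-tie ranks of |x − y|
after dropping zero differences; for n ≤ 25 the two-sided p-value is
exact, `p = min(1, 2·P(W+ ≤ W))`, computed over all 2ⁿ sign assignments
via the generating-function convolution (the tests verify it against a
literal 2ⁿ enumeration and against `stats::wilcox.test` in the tie-free
case); larger n uses the normal approximation with continuity and tie
corrections. Feeding the published six-system Pearson and Spearman
columns reproduces the printed p-values (0.2850/0.5625 and
0.2803/0.4375) to four decimals, which the acceptance tests assert.

## Energetics (WHAM)

Umbrella windows restrain the protein–GAG COM distance on a 1.0 Å
spacing with harmonic constant k = 4 kcal·mol⁻¹·Å⁻². The restraint
energy convention matters: the default `full-k` reads
`U_i(x) = k (x − x_i)²` (AMBER-style); `half-k` (`U = k/2 (x − x_i)²`)
is available, and `half-k` with `k′ = 2k` is verified to reproduce
`full-k` with `k` exactly.

`wham_solve()` iterates the standard self-consistent equations on binned
histograms until the largest change in any window shift `f_i` drops
below the tolerance (gauge fixed to `mean(f) = 0`, which makes the
iteration exactly invariant to window order). Empty bins are excluded
rather than interpolated, and an unsampled interior bin separating
populated regions raises an error naming the gap, since the equations
cannot connect disjoint histogram islands. The temperature default is
298.15 K and configurable.

Two numerical points deserve emphasis:

* **Bin resolution.** The production default (21 bins over 20 Å)
  mirrors the reported analysis settings, but at k = 4 the biased
  windows have width `σ = sqrt(kT/2k) ≈ 0.27 Å`, much narrower than a
  0.95 Å bin. With bins that coarse, the bias Boltzmann factor varies
  several-fold within a bin and the reconstruction systematically
  compresses the profile (about 0.55× on the reference double-well,
  independent of sample size). Quantitative work should use bins that
  resolve σ; the package's validation uses 201 bins (0.0995 Å ≈ σ/2.7),
  at which the reference profile is recovered to <0.05 kcal/mol RMS.
* **Stopping rule.** The per-iteration `max|Δf| < tol` criterion with
  the conventional 0.01 kcal/mol stops visibly short of the fixed point
  on the reference problem; the validation tightens the solver tolerance
  to 10⁻⁵ so the measured recovery error reflects statistical noise
  rather than an early stop. This is a stopping rule for the iteration,
  not a tolerance applied to any compared quantity.

`dissociation_free_energy()` reads the dissociated-plateau value as the
mean of the last three populated bins of the min-shifted profile (the
profile is min-shifted, so this equals plateau minus global minimum).
Experimental reference values come from `delta_g_from_kd()`:
`ΔG° = RT ln(K_D / 1 M)` with R = 1.98720425×10⁻³ kcal·mol⁻¹·K⁻¹.

## Synthetic ground truth

The generators produce inputs with the statistical structure the
analyses assume, so every stage is testable without external data. All
are pure functions of (parameters, seed) and leave the caller's RNG
state untouched.

* `gen_basin_energy_series()` emulates a 1000-frame, 1 ns-spaced energy
  trace hopping between Gaussian basins. Defaults: within-basin sd
  0.2 kcal/mol, mean dwell 20 frames, +8 kcal/mol spike at switch
  frames. Dwells are geometric with an optional guaranteed minimum;
  basin-visit recovery is validated at `min_dwell = 5`, because visits
  shorter than the 5-frame smoothing window are genuinely unresolvable
  after smoothing. The recovery test thresholds barrier prominence at
  1.8 kcal/mol — midway between the largest smoothed-noise prominence
  (~1.4 over 10³ frames at sd 0.2) and the smallest real switching
  barrier (~2.3, the +8 spike seen from the upper basin after
  smoothing) — and recovers the visit count within ±10%. Raw
  (unthresholded) proxy-minima counts are noise-dominated by design,
  matching what gently smoothed real traces show.
* `gen_ring_coords()` inverts the Cremer–Pople construction onto a
  regular ring of 1.52 Å bonds; at zero noise the round trip through
  `cremer_pople()` is exact to below 10⁻⁶ in (Q, θ, φ), and conformer
  mixtures are recovered within binomial confidence intervals.
* `gen_umbrella_samples()` draws each window from the exact biased
  density by inverse-CDF sampling on a 4001-point grid. WHAM recovery is
  judged against the *bin-integrated* truth
  `F_b = −kT ln ⟨e^{−βF}⟩_bin` — the estimand of a binned analysis —
  rather than F at bin centres, which would add a discretization term
  unrelated to solver correctness.
* `gen_correlated_profiles()` produces positive profile pairs with a
  target population Pearson correlation (bivariate Gaussian, shifted to
  mean 1 Å, sd 0.15 Å, floored at 10⁻⁶ — the floor triggers with
  probability ~10⁻¹¹ and exists only to make strict positivity a hard
  guarantee).

What the synthetic validation does **not** show: the generators contain
no force-field physics, no correlated solvent noise, no real GAG
geometry beyond a single idealized ring, and no protein. Passing these
tests demonstrates that the analysis machinery is numerically correct on
data satisfying its assumptions, not that any particular force field or
simulation protocol is accurate. Reproducing published per-system
correlation tables, PMF magnitudes, or proxy-minima counts for real
complexes requires the underlying microsecond trajectories and is out of
scope.

## Problem sizes used in the shipped tests

Chosen to exercise the production-scale regime while keeping the default test
run fast: 1000-frame energy traces (5 seeds) for basin recovery;
100–200 random series (length ≤ 500) for the extrema/tree oracles;
21 umbrella windows × 10⁴ samples for the headline WHAM recovery plus
smaller sweeps for invariances; 10³-frame ring trajectories for pucker
populations; n = 6 pairs for the published-statistics checks (their
exact null spaces are enumerated in full).

## Known limitations

* No trajectory re-imaging, solvent handling, or binary trajectory
  formats (DCD/XTC); coordinates arrive as (multi-model) PDB or arrays.
* The two-dihedral pucker rule is intrinsically degenerate outside its
  default four-conformer scope.
* Coarse-grained disconnectivity graphs inherit the saving interval:
  sub-interval barriers and minima are invisible, and apparent barriers
  are upper bounds.
* WHAM error bars (bootstrap) are not implemented.
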