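---
title: "Reweighting accelerated-MD ensembles: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reweighting accelerated-MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelMD)
```

## The model

Accelerated MD biases a simulation by adding a boost

$$\Delta V(V) = \frac{(E - V)^2}{\alpha + E - V}, \qquad V < E,$$

to the potential whenever it falls below the threshold $E$, leaving the
dynamics untouched above it. The boost is non-negative, continuous at
$V = E$ and monotone, so barriers are flattened but the landscape's
topology is preserved. Thresholds come from system size and the average
energies of a short conventional run: $E_\mathrm{dihed} = V_\mathrm{avg,dihed} +
a_1 N_\mathrm{res}$ with $\alpha_\mathrm{dihed} = a_2 N_\mathrm{res}/5$ for the
torsional channel, and $E_\mathrm{total} = V_\mathrm{avg,total} + b_1
N_\mathrm{atoms}$ with $\alpha_\mathrm{total} = b_2 N_\mathrm{atoms}$ for the
whole potential (`computeBoostParameters()`). Three boost modes exist:
total-only, dihedral-only, and dual; the effective per-frame boost used in
reweighting is the sum of whatever channels were active
(`effectiveBoost()`). This matters for dihedral-only runs, where only
$\Delta V_\mathrm{dihed}$ may enter the exponent.

The biased ensemble samples $\propto e^{-(V+\Delta V)/k_BT}$; multiplying
each frame by $w_i = e^{\Delta V_i/k_BT}$ and histogramming recovers the
canonical probability per bin, from which the potential of mean force is
$\mu = -k_BT\ln p$, anchored so its minimum over populated bins is zero.
Empty bins are masked (`NA`), never reported as zero energy — a bin with
no samples carries no free-energy information.

## The three estimators

* **Exponential**: exact but noisy — a handful of high-boost frames can
  dominate the weighted histogram.
* **Maclaurin, order $k$** (default $k = 10$): $w_i = \sum_{j=0}^{k}
  (\Delta V_i/k_BT)^j/j!$. A small truncation bias buys a large variance
  reduction; at $\Delta V/k_BT \le 1$ the order-10 series is within
  $10^{-6}$ relative of the exponential, and the bias stays negligible for
  the boost magnitudes the synthetic system produces ($\Delta V/k_BT
  \lesssim 5$, relative truncation error below 2%, i.e. $< 0.02$ kcal/mol
  on a PMF).
* **Second-order cumulant**: applied bin-wise in `reweightHistogram()` —
  the raw bin probability is corrected by $\exp(\beta\langle\Delta
  V\rangle_\mathrm{bin} + \beta^2\sigma^2_\mathrm{bin}/2)$. It is accurate
  when the boost distribution within a bin is near-Gaussian and degrades
  when it is not; the third-order term is deliberately not implemented.

All three agree on the synthetic double-well to well under 0.1 kcal/mol
mean absolute error at $5\times10^5$ Metropolis steps, against the exact
analytic surface.

## The synthetic system, and what it does not emulate

The generator samples sums of Gaussian basins on the 2D dihedral torus by
Metropolis Monte Carlo (Gaussian proposals, default width 10°, periodic
wrapping), with the aMD boost applied to the basin potential and logged
per frame — exactly the information an `amd.log` carries. Monte Carlo
realises the same stationary Boltzmann distribution that reweighting
assumes, which is all the analysis stack consumes; it does not emulate
inertial dynamics, solvent friction, kinetics, or the multi-dimensional
coupling of a real solvated peptide. Passing tests therefore validate the
*estimators and geometry code*, not force fields or sampling kinetics.

Default study conditions: temperature 300 K ($k_BT$ = 0.59616 kcal/mol
with $k_B$ = 0.0019872041 kcal mol⁻¹ K⁻¹), double-well centers at the
right-handed helical (−63, −43) and extended (−157, 161) regions, depths
4 and 3 kcal/mol with 30° widths. The 4 kcal/mol deepest barrier sits
inside the 4–6 kcal/mol range typical of small-peptide backbone
transitions; replica-separation scenarios use 10 kcal/mol wells (high
enough that $10^5$-step runs never mix), and well-mixing scenarios use
2/1.5 kcal/mol wells. The default synthetic boost (E = 0.5 kcal/mol,
just above the potential's supremum so every frame is boosted; α = 3)
flattens the 4 kcal/mol barrier to roughly 1.5 kcal/mol — an aggressive
boost in the spirit of aMD parameter choices that actually accelerate
folding, while keeping $\Delta V/k_BT$ small enough for all three
estimators to remain well-conditioned.

The toy backbone builder places N, H, Cα, C, O atoms with ideal
Engh–Huber-like geometry (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å,
angles 111.2/116.2/121.7°, ω fixed at 180°) from supplied IUPAC φ/ψ
series; rebuilding dihedrals from the coordinates reproduces the input to
$10^{-6}$ degrees. Residue 1 carries no amide hydrogen (no preceding
carbonyl), mirroring an acetyl-capped N-terminus's donor gap. A rigid
ideal helix at exactly (−63, −43) places the i+4→i O···N pair at 3.04 Å —
marginally outside the default 3.0 Å cutoff — so helical H-bond tests use
a thermally wobbling ensemble (Gaussian dihedral noise, σ ≈ 10°), which
is also the physically meaningful construction.

## Dihedral analysis

φ/ψ extraction follows the IUPAC convention (φ = C(i−1)–N–Cα–C,
ψ = N–Cα–C–N(i+1)), degrees in [−180, 180); chain-end angles are `NA`,
never zero-filled. Ramachandran classification assigns the nearest
tabulated center under periodic Euclidean distance: α_R (−63, −43), α_L
(+63, +43), β (−157.2, 161.9), PII (−65, +145), γ (+80, −80), γ′ (−80,
+80), ζ (−130, +80). The tables that define these centers give no
region boundaries, and the bridge (δ) region between helix and strand is
described only verbally; we therefore classify a point as δ (δ′ for the
mirror) when it is nearest a helical center but its distance to the
corresponding strand center comes within 25° of the helical distance.
The 25° band width is a design choice: wide enough that the β-turn band
between α and β is non-empty, narrow enough that the tabulated centers
keep their own labels. α_L is the mirror of α_R — the tables list no
left-handed center, but achiral and D-residues populate it, so the
mirror convention makes left-handed states classifiable without special
cases. Ties between centers resolve in table row order. Angles are
wrapped to [−180, 180) everywhere; classification is invariant under
360° shifts by construction and by test.

## PCA and free-energy landscapes

Dihedral PCA uses the (cos φ, sin φ, cos ψ, sin ψ) transform per residue:
raw angles are discontinuous at ±180° and PCA on them mixes wrap
artefacts into the leading modes. Cartesian PCA follows the two-pass
superposition recipe: fit every frame to frame 1 (optimal Kabsch
rotation), average, refit to the average, then eigendecompose the
covariance of the fitted coordinates. The default atom selection is the
backbone heavy atoms (N, Cα, C, O) — sidechain-free, so the landscape
reflects backbone folding. Eigenvector signs are fixed (largest loading
positive) for reproducibility. Free-energy landscapes reuse the same
weighted-histogram machinery as every other PMF in the package, so
FEL plots of biased runs are reweighted identically.

Density clustering histograms the top-k projections (default 3 PCs,
50 bins/axis, threshold 0.1 of the maximum density). Cells above
threshold are grouped into connected components (adjacency within one
cell per axis) and each component is one cluster, peaked at its densest
cell. A literal "every local maximum is a peak" rule would shatter a
noisy histogram into single-frame clusters; connected thresholded
regions are what grid-density clustering tools actually select. Frames
in a component's cells or within a one-cell halo join it (nearest peak
wins on overlap); leftovers within two cells (Euclidean, cell units) of
a component's region join the nearest region; the rest stay unassigned.
Occupancies are fractions of *all* frames, so they sum to at most 1 and
unassigned tail mass is visible rather than silently renormalised away.

## Convergence by Kullback–Leibler divergence

For each replica pair, PC-projection distributions are estimated at
growing horizons t (every 5% of the run) with a Gaussian KDE — Silverman
bandwidth per sample per horizon, a shared 512-point grid spanning both
full samples padded by three bandwidths — and compared with
$\mathrm{KLD}(t) = \sum_i P_i \ln(P_i/Q_i)$ over the grid points where
both densities are positive, renormalised over that common support. The
support convention matters in the tails; excluding unpopulated points
mirrors the histogram-bin exclusion the KDE exists to enable, and a pair
of genuinely disjoint distributions is reported as an explicit error
rather than an arbitrary large number.

The convergence call uses the KLD *value* cutoff of 0.025: a pair is
converged from the first horizon after which KLD stays below cutoff
through the end of the run. A slope-based reading of the same cutoff
would carry units of 1/time and depend on the horizon spacing, so the
value reading is implemented, with finite-difference slopes reported
alongside. A replica that dips under the cutoff and later rises — the
signature of a late jump into a previously unvisited basin — loses the
flag, and the synthetic basin-switch scenario reproduces exactly that
dip-then-rise pattern.

## Structure metrics

Backbone hydrogen bonds use a heavy-atom O···N distance ≤ 3.0 Å and an
N–H···O angle (at H) ≥ 135°. Reported backbone H-bond statistics for
helical peptaibols typically average 2.78–2.91 Å and 146–163°, which
these cutoffs bracket with margin; both knobs are exposed, and occupancy
is monotone in each (tested). The acceptor is the carbonyl
oxygen — the convention that makes donor−acceptor offsets of 2, 3 and 4
correspond to γ-turn, 3₁₀ and α-helical turns respectively. Donors
lacking an amide H are skipped with a notice, not an error. The
C-terminal amino-alcohol residue appears in the literature both as
"Pheol18" and "Pol18"; the label parser accepts any alphabetic prefix,
so both resolve to residue 18. End-to-end distance runs from the first
residue's backbone N to the last residue's final heavy atom.

## Numerical choices and degenerate inputs

* Bins: 72×72 over [−180, 180)² (5° bins) for dihedral PMFs; 50 bins for
  1D distance PMFs and FEL axes. No source prescribes these; 5° matches
  the resolution at which Ramachandran basins are typically drawn.
* Torsions of collinear atom triples have no defined plane; they raise an
  error naming the frame rather than returning a convention value.
* PCA of an exactly constant dihedral series errors (zero covariance);
  Cartesian PCA of pure rigid-body motion is *not* an error — it returns
  eigenvalues at numerical zero (< 10⁻¹⁰ Å²), which is itself a tested
  invariant of the superposition.
* All-zero weight vectors and zero-coefficient boost channels error
  early with explicit messages.
* Determinism: the Metropolis core draws from R's RNG, so a seed fixes
  trajectories bit-for-bit across platforms; eigenvector signs and
  cluster orderings are canonicalised.

## Problem sizes

The test suite and acceptance script use 5×10⁵-step reweighting runs,
10⁶-step sampler-consistency checks, 2×10⁴–5×10⁴-step replica pairs (20
KLD horizons), 10-seed mixture-clustering repeats and 40–60-frame toy
trajectories — sizes chosen so the full validation cycle completes in
about a minute while keeping Monte Carlo noise an order of magnitude
below every tolerance asserted.

## Known limitations

* The sampler is 2D (one φ/ψ pair); multi-residue coupling is exercised
  only through the toy-chain geometry, not through the sampler.
* The cumulant estimator is second-order only and inherits its known
  sensitivity to non-Gaussian boost distributions.
* KDE bandwidths follow Silverman's rule, which oversmooths strongly
  multimodal projections at small n; the KLD cutoff behaviour near 0.025
  then depends weakly on bandwidth.
* The PDB writer emits a minimal single-chain ATOM dialect (sufficient
  for round-tripping the package's own trajectories); occupancy,
  B-factors and connectivity are not modelled.
* Ramachandran δ/δ′ extent is a band-width convention (25°), not a
  fitted boundary; sensitivity to this width is confined to points near
  the α–β watershed.
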