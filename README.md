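# accelMD

Reweighting and folding analysis for accelerated molecular dynamics (aMD)
ensembles of small peptides, with a synthetic ground-truth system for
validating every stage.

## The problem

aMD flattens energy barriers by adding a non-negative boost to the
potential whenever it falls below a threshold *E*:

    dV(V) = (E − V)² / (α + E − V)   for V < E,   0 otherwise

with channel thresholds derived from per-residue / per-atom coefficients:

    E_dihed = V_avg_dihed + a₁·N_res     α_dihed = a₂·N_res / 5
    E_total = V_avg_total + b₁·N_atoms   α_total = b₂·N_atoms

The biased ensemble samples rare folding events orders of magnitude
faster, but its populations are wrong until each frame is reweighted by
the Boltzmann factor of its boost, exp(ΔV/k_BT). `accelMD` implements the
three standard estimators of that factor — exact exponential, Maclaurin
series truncated at order *k* (default 10), and a bin-wise second-order
cumulant expansion — and turns weighted histograms into potentials of
mean force, μ(q₁,q₂) = −k_BT ln P(q₁,q₂), anchored at zero.

Around that core it provides the analysis stack a peptide-folding study
needs: IUPAC φ/ψ extraction and Ramachandran region classification
(nearest tabulated center with a δ bridge band), per-residue reweighted
φ/ψ PMF maps, dihedral PCA on (cos, sin)-transformed angles and
two-pass-superposed Cartesian PCA, free-energy landscapes over PC1/PC2,
density-peak clustering with occupancy timelines, time-dependent
Kullback–Leibler divergence between replicas (KLD = Σ P ln(P/Q), with a
0.025 convergence cutoff), backbone N–H···O=C hydrogen-bond occupancy
tables with γ/3₁₀/α turn classes, and end-to-end-distance PMF profiles.

Because real multi-microsecond trajectories are too large to ship, the
package includes a first-class synthetic system: Metropolis samplers on
analytic periodic basin potentials (with the aMD boost applied and
logged), replica generators with controllable overlap, and an
ideal-geometry backbone builder that turns (φ,ψ) series into coordinates
— so samplers, reweighting, PCA, clustering, convergence and H-bond
detection are all testable against exact ground truth.

## Worked example

Recover the canonical free-energy surface of a double-well dihedral
potential from a boosted run:

```r
library(accelMD)

pot <- doubleWellPotential()          # wells at (-63,-43) and (-157,161)
run <- sampleBiased(pot, 5e5, seed = 1, boost = list(E = 0.5, alpha = 3))
run$log
#> BoostLog (iamd2_dihedral), 500000 frames, effective dV mean 0.539 kcal/mol (max 2.7)

w <- computeWeights(run$log, estimator = "maclaurin", k = 10)
g <- reweightHistogram(cbind(phiAngles(run$series)[, 1],
                             psiAngles(run$series)[, 1]),
                       w, breaks = 72L, angular = TRUE)
g
#> PMFGrid phi[72] x psi[72] at 300 K, 5184/5184 populated bins, max PMF 4.38 kcal/mol

ana <- analyticPmf(pot)
sel <- g@mask & ana < 4
mean(abs(pmfValues(g)[sel] - ana[sel]))
#> [1] 0.0652003
```

The reweighted surface reproduces the analytic one to 0.065 kcal/mol
mean absolute error over all low-energy bins; the raw biased histogram
is off by ~2.5 kcal/mol. Boost parameterisation and convergence
assessment:

```r
computeBoostParameters(a1 = 3.5, a2 = 3.5, nRes = 19,
                       vAvgDihed = 210, mode = "iamd2_dihedral")
#> AMDParameters, mode iamd2_dihedral
#>   N_res 19, N_atoms 1
#>   dihedral channel: E 276.5, alpha 13.3 kcal/mol

reps <- makeReplicas(doubleWellPotential(depths = c(2, 1.5)), 2,
                     seeds = c(11, 12), overlapMode = "same_basin",
                     nSteps = 5e4)
kldTimeseries(lapply(reps, function(r) phiAngles(r)[, 1]))
#> KLDSeries: 20 horizons, pairs 1-2; converged: yes (cutoff 0.025)
```

A command-line wrapper (`exec/amdreweight`) exposes the pipeline stages
(`simulate`, `reweight`, `kld`, `hbond`, `endtoend`, `pipeline`) for
shell use, and `pipelineRun()` drives an end-to-end run with a
provenance record.

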