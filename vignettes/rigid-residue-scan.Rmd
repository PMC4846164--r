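---
title: "Quasi-harmonic entropy and the rigid-residue scan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-harmonic entropy and the rigid-residue scan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrscan)
```

## The quasi-harmonic model

The package models the sampled fluctuation distribution of a protein (or any
atomistic system) as a multivariate Gaussian on an effective harmonic
potential.  After least-squares superposition of every frame onto a
reference, the 3N-dimensional coordinate covariance **C** determines the
effective force constants, $F = k_B T\, C^{-1}$, and the vibrational
frequencies solve $\det(F - \omega^2 M) = 0$ with **M** the diagonal mass
matrix.  The configurational entropy is the quantum-oscillator sum over the
retained modes,
$$S = k_B \sum_i \left[\frac{x_i}{e^{x_i}-1} - \ln(1-e^{-x_i})\right],
\qquad x_i = \frac{\hbar\omega_i}{k_B T},$$
which is exact for a harmonic system and a harmonic-limit approximation for
real trajectories.  Anharmonicity and higher-order correlations are known
blind spots of this estimator and are deliberately out of scope.

Assumptions worth keeping in mind:

* frames must be superposed first — the covariance of unaligned frames mixes
  internal fluctuation with external motion, and the package refuses it;
* the Gaussian picture ignores multimodality: a two-basin ensemble yields a
  single inflated covariance and an entropy between the basins' values;
* results are equilibrium-ensemble statements, so equilibration frames must
  be discarded before analysis (`select_frames()`).

## Numerical route

**C** is almost always rank-deficient (3N typically exceeds the frame count,
and the fit removes six degrees of freedom), so $C^{-1}$ is never formed.
Instead the mass-weighted covariance $\sigma = M^{1/2} C M^{1/2}$ is
diagonalized: its eigenvalues give $\omega_k = \sqrt{k_B T / \lambda_k}$ and
its eigenvectors are the modes.  The algebraic equivalence of the two routes
is asserted by a test that performs the explicit inverse-and-secular solve on
full-rank 5-atom covariances and requires agreement to $10^{-8}$ relative.

Mode retention: eigenvalues below $10^{-6}\lambda_{max}$ are treated as
numerically zero.  For whole-system scope exactly $3n-6$ modes are kept — if
more survive the tolerance cut (as on full-rank toy matrices), the smallest
surplus eigenvalues are dropped as residual external motion.  For residue
sub-blocks *all* above-tolerance modes are kept, up to $3m$: the subsystem is
never re-aligned, so its rigid-body motion inside the protein frame is
genuine fluctuation.  Whether the original formulation removed external
modes at residue scope is not documented anywhere we know of; retaining them
is the physically consistent reading, and `residue_entropy(drop_external =
TRUE)` provides the other convention.

Covariances use the population divisor $F$ (immaterial at $F = 15{,}000$,
fixed for reproducibility) and a two-pass mean-then-deviation accumulation in
double precision.  Eigenvector signs are fixed so the largest-magnitude
component is positive — serialization becomes reproducible while all overlap
comparisons remain unsigned.

Internal units are amu, Å, ps, in which $k_B = 0.8314463$ amu Å²/(ps² K) and
$\hbar = 6.35078$ amu Å²/ps (molar); frequencies are reported as
$\tilde\nu = \omega / 2\pi c$ in cm$^{-1}$ and entropies in kcal/(mol K)
with $k_B = 1.987204\times10^{-3}$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `temperature` | 300 K | enters both $F = k_BT C^{-1}$ and the oscillator sum |
| `tol` | $10^{-6}$ | relative eigenvalue floor for mode dropping |
| `discard_ns`, `interval_ps` | per run | equilibration discard and analysis stride; the first retained frame sits at `discard + interval` (half-open window), so a 30 ns window at 2 ps gives exactly 15,000 frames |
| `level` (`mean_ci`) | 0.85 | two-sided Student-t confidence level for block error bars |
| `cutoff`, `spring_k` (generator) | 8 Å, 1 amu/ps² | elastic-network contact radius and uniform spring constant; the defaults put mode frequencies in the low-wavenumber range typical of collective protein motion |

Other conventions that were genuinely open and had to be decided:

* **Relaxation time** of the velocity autocorrelation is the first $1/e$
  crossing (linearly interpolated); an integral-of-VACF alternative sits
  behind `method = "integral"`.  All atoms enter by default, with an `atoms`
  subset argument for heavy-atom-only analyses.
* **Cross-correlation subset** defaults to Cα atoms when atom names are
  available (the usual heat-map convention), full-atom otherwise or by flag.
  Hydrogens are included in covariances whenever they are present in the
  topology; strip them upstream if a heavy-atom analysis is wanted.
* **RMSD fits are mass-unweighted** over all atoms, matching the unweighted
  definition of the deviation itself.
* **Ensemble separation** in the 2D PC1×PC1 chart is the Euclidean distance
  between cloud centroids; a density-mode variant (2D histogram peak
  distance) is available via `method = "mode"`.  The two PC1 axes are used
  as-is — they are generally slightly oblique — because that is the chart in
  which the clouds are actually plotted; no Gram–Schmidt step is applied.
* **ΔS reference**: by default each state is differenced against its own
  unperturbed run; `reference = "unbound"` uses the unperturbed unbound run
  for both states.  Both conventions appear in practice and the choice is
  explicit in every call.
* **Average residue response** includes the self-rigid (diminished) diagonal
  cell by default, since the average is taken over *all* rigid runs;
  `include_self = FALSE` excludes it.
* **Key-residue screen** uses strict inequality against the unperturbed-pair
  $|\Delta\Delta S|$; boundary ties are excluded.
* **Run indexing**: `rigid_residue = 0` denotes the unperturbed run
  throughout the ledger.

## What the synthetic generator does and does not emulate

`build_enm_model()` constructs an isotropic-spring (anisotropic-network)
Hessian from contacts within the cutoff, mass-weights it, and keeps the
above-tolerance modes; the model covariance is $k_BT$ times the
pseudo-inverse with external modes removed, and the entropy is known in
closed form.  `sample_frames()` draws exact multivariate-Gaussian frames,
`apply_rigid_residue()` projects a residue's block onto its 3-translation +
3-rotation subspace in mass-weighted coordinates (rank ≤ 6 by construction),
and `two_state_shift()` displaces the mean along a mode at fixed covariance.

This emulates: Gaussian atomic fluctuation with prescribed covariance, the
loss of internal degrees of freedom under a rigid-residue constraint, and a
pure population shift between two states.  It does **not** emulate the
re-equilibration of a constrained MD system — in real constrained
simulations the rest of the protein responds, frequently *gaining* enough
entropy to raise the whole-protein total.  That compensation arises from
dynamics the analytic projection cannot produce, so passing tests here
validate the analysis machinery, not that empirical observation; a test
asserting a total-entropy increase would need an MD engine.  For the same
reason the generator makes no attempt to reproduce any specific protein's
entropy values.

The default validation scale — a 12-atom, 3-residue chain analyzed at
15,000 frames, with 5- and 7-block coherence checks at 1,500–2,000 frames
per block and moment checks at $10^4$–$10^5$ draws — was chosen so that
every oracle is exhaustive and the entire suite stays interactive; entropy
recovery on this system is accurate to ~0.01% and all stochastic tolerances
(2% entropy, 5% projection variance, 3 SE distances) are met with wide
margin.

## Degenerate inputs and edge cases

* Frozen (zero-variance) residue blocks report $S = 0$ with a warning rather
  than erroring — a scan over a rigid ensemble must be able to tabulate the
  constrained residue itself.
* Zero-variance atoms yield `NA` cross-correlations with a warning
  (variances below $10^{-12}$ Å² count as zero).
* Superposition requires at least 3 non-collinear reference atoms; best-fit
  RMSD remains defined below that via the SVD closed form.
* Disconnected elastic networks are rejected with a component report;
  collinear geometries (e.g. the diatomic) simply have 5 rather than 6
  external zero modes, determined by tolerance.
* A single spring between equal masses gives the closed-form
  $\omega = \sqrt{2k/m}$ — the standard sanity check for the network
  builder.

## Known limitations

* Harmonic-limit entropy only; no anharmonic or supralinear correlation
  corrections.
* Trajectory input is multi-model PDB and DCD; no XTC reader, and matrices
  persist as CSV rather than HDF5.
* The ensemble-distance measures operate on the 2D PC1 chart only; no
  free-energy-surface estimation or basin clustering.
* The scan manifest enumerates and budgets jobs for an external MD engine
  but does not generate engine input files.
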