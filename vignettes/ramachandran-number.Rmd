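---
title: "The Ramachandran number: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Ramachandran number: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanum)
```

## The model

A residue's backbone conformation is summarized by the dihedral pair
(φ, ψ), both taken on the half-open canonical domain [−180°, 180°).
`ramanum` collapses the pair into one scalar by (i) rotating the
Ramachandran plane clockwise by 45°, so that the negative-sloping
diagonal — along which the sense of backbone twist flips and contours of
polymer extension run — becomes horizontal; (ii) shifting so both rotated
coordinates are non-negative; (iii) rescaling by a resolution σ
(reciprocal degrees) and rounding to integers; and (iv) raster-indexing
the resulting grid:

$$\phi' = \Big\lfloor (\phi-\psi+\lambda)\,\sigma/\sqrt2 \Big\rceil,\qquad
  \psi' = \Big\lfloor (\phi+\psi+\lambda)\,\sigma/\sqrt2 \Big\rceil,\qquad
  R_Z = \phi' + \lambda'\,\psi'$$

with λ = 360° and stride $\lambda' = \lfloor \sqrt2\,\lambda\sigma \rceil$.
The normalized number $R = (R_Z - R_{Z,\min})/(R_{Z,\max}-R_{Z,\min})$
lies in [0, 1), with $R_{Z,\min} = R_Z(-180,-180) = \lfloor
\lambda\sigma/\sqrt2 \rceil$ and $R_{Z,\max} = R_{Z,\min} + \lambda'^2$.
For large σ the ψ′ term dominates, so $R \approx (\phi+\psi+360)/720$: R
is, to within $10^{-6}$ at the default σ, an affine function of φ + ψ.
That makes its structure transparent — R interpolates from the
right-handed-twist corner (R < 0.5) through the twist-free diagonal
(R = 0.5) to the left-handed corner — and explains both its power (the
major secondary-structure classes separate along it) and its intrinsic
coarse-graining (states far apart along the diagonal share one R; the
conditional spread of end-to-end distance given R is widest at R = 0.5,
which `re_stats_by_r()` computes directly).

The raster index is exactly invertible up to grid rounding:
$\tilde\phi' = R_Z \bmod \lambda'$, $\tilde\psi' = \lfloor R_Z/\lambda'
\rfloor$, and undoing the rotation gives back-mapped angles within 1/σ
degrees of the originals. Assumptions worth stating: the codec treats
the plane as a flat torus cut at ±180° (no wrap-around smoothing), and
it is purely geometric — no energetics, no notion of which regions are
sterically allowed.

### Why σ/√2, and the rounding convention

A genuine 45° rotation scales coordinates by 1/√2. This is also the only
reading under which the printed identity $R_{Z,\max} = R_{Z,\min} +
\lambda'^2$ is self-consistent: ψ′ at the (180, 180) corner must equal
the stride λ′, which forces the same √2 in the definitions of φ′, ψ′ and
λ′. Nearest-integer rounding is implemented as `floor(x + 0.5)`
(half-up); every rounded quantity is non-negative, so this coincides
with half-away-from-zero. Ties are measure-zero for real-valued inputs
and irrelevant at σ = 10⁵. In the inverse, ⌊·⌋ is floor division with
the matching non-negative remainder.

### Integer exactness

At σ = 10⁵, $R_Z$ reaches ≈ 2.6 × 10¹⁵. These values are stored as R
doubles, which represent integers exactly below 2⁵³; the quotient and
remainder in the decoder are computed with an explicitly corrected floor
division because `%/%`/`%%` on doubles of that magnitude can slip by one
ulp at exact multiples. `make_grid()` refuses σ large enough to cross
2⁵³.

### Boundary caveat

Within ~0.7/σ degrees of the excluded raster corner (φ → 180⁻ with
ψ = −180), φ′ can round up to λ′ itself and alias into the next raster
row, breaking the 1/σ round-trip bound on a set of measure ~10⁻¹¹ of the
domain at the default σ. This is inherent to raster indexing; the
package documents rather than patches it.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma` | 1e5 | 1/degrees | back-mapping error 1/σ ≪ the ~1 Å coordinate uncertainty of deposited structures |
| `bin_width` (R-codes) | 0.01 | — | resolves the α (0.36) / β (0.52) / loop (0.62) landmarks with room to spare |
| landmark interval half-width | 0.03 | — | point landmarks only are available; ±0.03 keeps α and β disjoint |
| `delta` (alternation score) | 0.05 | — | about half the α–β landmark separation; steps smaller than this are treated as noise |
| chain-break C–N cutoff | 2.5 | Å | ~1.9× the peptide bond; separates bonded (1.33 Å) from gapped residues robustly |
| builder geometry | Engh–Huber-type ideal values | Å, degrees | conclusions are insensitive to the exact ideal geometry; ω defaults to trans (180°) |

## The backbone builder

`build_chain()` is deterministic forward kinematics: residue 1 in a
canonical frame (N at the origin, Cα on +x, C in the xy plane), every
later atom placed from (bond length, bond angle, torsion). Only N, Cα
and C are built — φ, ψ, ω, end-to-end distance and the gyration radius
need nothing else — and glycine is written in emitted PDBs. End-to-end
distance is defined Cα(first)–Cα(last), the stable polymer convention.
The round-trip validation rebuilds original and decoded chains from the
*same* canonical frame and reports Cα RMSD **without** superposition:
superposition could only shrink the number, so the reported value is the
conservative bound on propagated dihedral error (the CLI `validate`
report prints the superposed variant alongside, to bracket the
convention).

## What the synthetic generators emulate — and what they do not

The fixture module generates: Gaussian dihedral clouds around textbook
motif centers (α (−63, −43), β (−135, 135), ppII (−75, 145), left-handed
α (63, 43); default spread 10°), mixed-motif chains (per-residue uniform
motif choice), two-state Σ-strand chains alternating (φ₀, ψ₀) with its
twist-opposed mirror (−φ₀, −ψ₀), and multi-frame trajectories that
switch generator at a chosen frame (default "before" state: the β
center, which sits on the twist-free diagonal like an extended chain).
All generators are pure functions of (parameters, seed) and restore the
session RNG.

They emulate clustered occupancy, two-state alternation and an abrupt
conformational transition — enough to exercise every code path from PDB
file to time-resolved R-code. They do **not** emulate: empirical
per-motif spreads or correlations between φ and ψ within a motif,
sequence-dependent propensities, sterics (disallowed regions are sampled
and built without complaint), or dynamics (trajectory frames are
statistically independent, not time-correlated). A green test therefore
establishes that the machinery is correct on its stated world, not that
real proteins have any particular R distribution. The two Σ-state
centers are a parameter (default (−60, 150)) because no tabulated pair
ships with the package's sources. Real-data landmark recovery (helix
peak near 0.36, etc.) needs a downloaded nonredundant structure set and
is deliberately outside the offline test suite.

## Other numerical and design choices

- **Histogram bins** are left-closed on [0, 1); r = 1.0 (possible only
  at the excluded corner) is clamped into the last bin so counts are
  always conserved. Peak reporting breaks ties toward the lowest-r bin.
- **Trajectory windows** are non-overlapping and left-aligned; a
  trailing partial window is kept (its counts conserve residues ×
  actual window size).
- **Degenerate inputs**: empty r vectors give a valid all-zero R-code
  (normalization skipped); conditional bins that receive fewer than 2
  samples report `NA` spread rather than a fabricated value; residues
  missing a backbone atom, at segment termini, or across a break get
  `NA` dihedrals, never imputed ones.
- **PDB altloc**: highest occupancy wins, ties toward blank/'A';
  residues keep file order and insertion codes verbatim.
- **DSSP coarsening**: H/G/I → helix, E/B → sheet, everything else →
  loop; the mapping is an argument, since reasonable analyses disagree
  about B (isolated bridge).
- **CLI config**: JSON (parsed with `jsonlite`), because it is the one
  structured format guaranteed by the package's dependency set;
  precedence is flags > file > defaults, and outputs are written
  atomically (temp file + rename) so failures leave no partial files.
- **Monotonicity fine print**: r is non-decreasing in φ + ψ at fixed
  φ − ψ; strictness is guaranteed when each angle moves in steps of at
  least 1/σ (so ψ′ advances by ≥ 1 grid unit).

## Known limitations

- R is a lossy projection by construction; distinct conformations with
  equal φ + ψ are indistinguishable at large σ. Use the (φ′, ψ′) pair or
  the original angles when that distinction matters.
- The builder has no energy model and no clash detection; it will
  happily build sterically impossible chains (that is a feature for
  mapping the full plane, a caveat for anything else).
- The PDB reader is scoped to backbone N/Cα/C in ATOM records
  (MODEL-aware); mmCIF and binary trajectory formats are out of scope.
- cis/trans ω and D-residue chemistry are passed through untouched: R is
  computed for every residue with defined φ and ψ, and any filtering is
  the caller's responsibility.
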