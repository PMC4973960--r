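# ramanum

Protein secondary structure is local backbone geometry, and backbone
geometry near a residue is essentially two dihedral angles, φ and ψ.
Helices, sheets and loops occupy characteristic patches of the (φ, ψ)
Ramachandran plot — but a 2D plot cannot label *each residue* of a chain
with a compact geometric state, which is what you want when scanning a
whole protein, a whole protein class, or every frame of a trajectory.
Peptoid materials sharpen the need: the Σ-strand motif of peptoid
nanosheets alternates residues between **two** twist-opposed rotational
states, something a single Ramachandran cloud cannot express per residue.

`ramanum` collapses (φ, ψ) into a single scalar, the **Ramachandran
number** R, and builds the analysis layer around it. The package targets
structural bioinformaticians and simulators who want per-residue,
per-frame geometric order parameters from PDB files or dihedral tables.

## The statistic

With λ = 360° and both angles in [−λ/2, λ/2), rotate the plot clockwise
by 45°, shift, and rescale by a grid resolution σ (reciprocal degrees):

    φ′ = ⌊(φ − ψ + λ) σ/√2⌉        ψ′ = ⌊(φ + ψ + λ) σ/√2⌉

(⌊·⌉ = nearest integer). Raster-indexing the rotated grid with stride
λ′ = ⌊√2 λσ⌉ gives the exact integer index and its normalization

    R_Z = φ′ + λ′ ψ′               R = (R_Z − R_Z,min) / (R_Z,max − R_Z,min)

with R_Z,min = R_Z(−180, −180) = ⌊λσ/√2⌉ and R_Z,max = R_Z,min + λ′²,
so R ∈ [0, 1). Because the sweep runs perpendicular to the negative-
sloping diagonal, R tracks both the sense of backbone twist
(right-handed below the diagonal, left-handed above, twist-free at
R = 0.5) and the compactness of the chain (end-to-end distance contours
run parallel to that diagonal). The map is invertible up to grid
rounding: back-mapped angles (φ̃, ψ̃) are within 1/σ degrees of the
originals, so at the default σ = 10⁵ the information loss is far below
the coordinate uncertainty of deposited structures. Useful landmarks:
α-helix R ≈ 0.36, β-sheet R ≈ 0.52, loops R ≈ 0.62.

## Worked example

```r
library(ramanum)

# encode the alpha-helical center at the default sigma = 1e5
encode_rz(-63, -43, make_grid(1e5))
#>          rz         r
#> 1 9.144e+14 0.3527778

# a sigma-strand chain: residues alternate two twist-opposed states,
# giving an R trace that flips symmetrically about the twist-free 0.5
ch <- make_sigma_chain(8, state = c(-60, 150))
tr <- residue_trace(trajectory_records(list(ch)))
round(tr[, 1], 4)
#>     1     2     3     4     5     6     7     8
#> 0.625 0.375 0.625 0.375 0.625 0.375 0.625 0.375
alternation_score(tr[, 1])
#> [1] 1
```

The 0.3528 above is the helix center's normalized number (≈ (φ+ψ+360)/720
for large σ); the alternating 0.625/0.375 trace is the Σ-strand signature,
and the alternation score of 1 flags perfect two-state alternation.

## Command line

An `rnum` executable is installed under the package's `exec/` directory
(run it with `Rscript exec/rnum ...` from a source checkout). Subcommands:
`encode`, `decode`, `compute` (PDB → per-residue R table, optional DSSP
labels), `rcode`, `trace`, `timeseries`, `remap`, `build`, `validate`,
`fixtures`. Options come from flags or a JSON config file
(`--config run.json`; flags > file > defaults). For example, the codec
round-trip validation report on 5 synthetic 50-residue chains:

```
$ Rscript exec/rnum validate --chains 5 --len 50 --seed 7 --quiet
sigma   100000
chains  5
residues        250
angle_rmsd_deg  2.94497e-06
ca_rmsd_A       4.94157e-06
ca_rmsd_superposed_A    1.75111e-06
```

Both RMSDs are orders of magnitude below the ~1 Å coordinate uncertainty
typical of deposited structures: encoding a structure's dihedrals as
integers and rebuilding from the decoded angles is effectively lossless
at σ = 10⁵.

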