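---
title: "The LIP method: model, parameters and implementation notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The LIP method: model, parameters and implementation notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipscan)
```

## The model

A *LIP* (Light Interface of high Polarity) is an intramolecular or
inter-chain interface that is atypical in two coupled ways: the surface it
buries is unusually polar, and the atoms across it are packed unusually
loosely.  Such interfaces are mechanically "light": the segment forming
them can peel off its scaffold at low energetic cost, which is why they
concentrate around active sites, hinges and cryptic pockets.

`lipscan` detects them with a sliding-probe construction:

1. **Probe.** An 8-residue window slides along every contiguous solved
   segment of a chain.  The *environment* is either the rest of the same
   chain with the probe cropped out (*intra* mode) or the entirety of a
   partner chain (*inter* mode).  For a dimer A--B the full analysis
   therefore comprises four calculations: intra-A, intra-B, inter-A:B and
   inter-B:A.
2. **Polarity ratio (PR).**  For every atom of probe and environment the
   buried area is `b = SASA(own component isolated) − SASA(complex)`.
   Atoms with `b` above a small cut-off (0.1 Å², parameter
   `interface_cutoff`) constitute the interface.  PR is the summed buried
   area of polar interface atoms (N, O) divided by the summed buried area
   of apolar ones (C, S, Se).  An interface with no apolar buried area is
   treated as "above any threshold" (internally capped at `pr_cap`); an
   empty interface leaves the profile point undefined.
3. **Packing density (ρ).**  Over the same interface atoms, ρ is the sum
   of tabulated standard atomic volumes divided by the sum of the atoms'
   actual Voronoi cell volumes.  ρ ≈ 1 means packing as tight as reference
   protein interiors; ρ < 1 means looser packing.
4. **Profile assignment.**  Both window values are assigned to the
   window's 4th residue, so a segment of length *n* produces *n* − 7
   defined points at positions 4 … *n* − 4 (in segment coordinates).
   Windows never span structural gaps.
5. **mLIP rule.**  A candidate region starts at a local PR maximum above
   `pr_peak` (0.8) and is extended over adjacent defined points while PR
   stays above `pr_base` (0.5); overlapping candidates merge.  The region
   is kept only if at least one of its residues has ρ strictly below the
   *profile's* mean minus one standard deviation (both statistics computed
   over the defined points of that profile only).
6. **cLIP rule.**  The mLIP span is cropped out of the analysis structure
   and all-atom SASA is recomputed.  Every remaining residue whose
   per-residue SASA increases by strictly more than `dsasa` (1.0 Å²) is a
   cLIP member.  Members need not be contiguous and, by construction,
   exclude the mLIP span.  The *full LIP* is the union of mLIP and cLIP,
   each residue counted once.

## Parameters

| name               | default | unit | meaning                                   |
|--------------------|--------:|------|-------------------------------------------|
| `window`           | 8       | aa   | probe length                              |
| `pr_peak`          | 0.8     | —    | PR local-maximum threshold                |
| `pr_base`          | 0.5     | —    | PR baseline for region extension          |
| `rho_k`            | 1.0     | —    | ρ must dip below mean − `rho_k`·sd        |
| `dsasa`            | 1.0     | Å²   | strict cLIP membership threshold          |
| `probe`            | 1.4     | Å    | solvent probe radius                      |
| `n_points`         | 960     | —    | quadrature points per atom                |
| `interface_cutoff` | 0.1     | Å²   | per-atom buried-area interface membership |
| `voronoi_box`      | 12.0    | Å    | clipping half-width for unbounded cells   |

All are held in `lip_params()` and are overridable per run (and from the
CLI or a `key=value` config file, with flag precedence).

## Implementation decisions worth knowing

**Sign of ΔSASA.**  `delta_sasa()` reports `sasa_cropped − sasa_full`, so
residues that packed against the removed segment have *positive* values
and the `> 1.0 Å²` membership threshold reads naturally.  Equivalent
formulations elsewhere print the same quantity with the opposite sign
convention; only the sign differs, the member set is identical.

**SASA engine.**  Shrake–Rupley with a deterministic golden-spiral
(Fibonacci) point lattice: no random rotations, hence bit-reproducible
results without seeds.  An isolated atom reproduces 4π(r + 1.4)² to
machine precision; a two-sphere configuration matches the spherical-cap
closed form within 1%; a 20-residue fixture agrees with an independent
implementation within 0.2%.  One caveat of a *fixed* lattice is a small
orientation dependence: rigidly rotating a structure changes per-atom
values by up to a few tenths of Å².  On an exact C2 homodimer the two
chains' profiles therefore agree only to ≈0.01 in PR, not exactly; tests
compare symmetric profiles with a tolerance rather than bit equality.

**Voronoi engine.**  Plain (unweighted, bisector-plane) Voronoi cells,
computed per atom from the nearest 48 neighbours and clipped to a cube of
half-width `voronoi_box`.  A cell still touching that cube is unbounded in
the true tessellation (surface atoms); such atoms are flagged and enter
neither the numerator nor the denominator of ρ, so ρ is always a ratio
over the same atom set.  Interior cells are exact: on a cubic lattice with
spacing *a* each interior volume is *a*³ to machine precision, and
jittered lattices match a Monte-Carlo nearest-centre oracle within its
sampling error.

**Standard volumes.**  The reference volume table is an editable TSV
(`inst/extdata/standard_volumes.tsv`) in the Tsai/Gerstein style of
atom-type classes (for example C3H0 9.7 Å³ … S2H1 36.7 Å³) mapped to
(residue, atom) pairs, with `element:X` fallback rows used (with a
warning) for atoms outside the table.  Different volume dialects shift ρ
by a few percent globally; since the detection rule is relative (profile
mean − sd), detections are robust to the dialect, but absolute ρ values
printed in reports should be compared only within one table.

**ρ statistics per profile.**  The dip rule uses the mean and standard
deviation of ρ over the profile being scanned — not global constants — so
a uniformly loose structure does not light up everywhere, and one tightly
packed chain does not suppress detections on its looser partner.

**Chain continuity.**  Two consecutive residues belong to the same
segment when their C–N distance is a plausible peptide bond (≤ 2 Å).
Author-numbering jumps across an intact bond (renumbering artifacts) do
not split windows; they are still reported as numbering gaps in the
summary.  Missing backbone atoms fall back to consecutive numbering.

**Polarity bookkeeping.**  Element-based: N and O (and their charged
forms) are polar; C, S and Se are apolar.  Sulfur is deliberately apolar,
matching the hydrophobicity scales the method's thresholds were tuned on.

## Fixtures, not downloads

The package tests against a deterministic internal-coordinate generator
(`fixture_spec()` / `make_structure()`): ideal helices (φ/ψ = −60/−47,
rise ≈ 1.5 Å, 3.6–3.7 residues per turn), extended strands, one-chain
two-helix bundles with a designed numbering + structural gap, and exact C2
symmetric dimers.  Side chains are idealized stubs up to the γ (plus the
amide/carboxylate δ atoms of Asn/Asp), enough to differentiate polar from
apolar buried surface.  These are *not* physically realistic structures —
no rotamers, no minimization — but their geometry is exactly known, which
is what oracle tests need.  The designed smoke-test pair is built in: a
serine/asparagine-faced bundle at loose spacing yields intra-chain mLIPs
under default thresholds; an all-leucine, tightly packed control yields
none.

## Scale and cost

Typical desk-scale inputs (fixtures of 16–30 residues, small dimers) run
in seconds; the dominant cost is the O(N²) pairwise SASA with
960-point quadrature, called once per complex per profile plus once per
cLIP crop.  A 4-calculation dimer analysis of a 2 × 16-mer takes ≈6 s on
one CPU.  Real single-domain proteins (100–300 residues) are minutes, not
hours; reproducing a 50-domain survey is an offline batch job, and the
acceptance test for it stays red unless a local copy of the domain set is
supplied (environment variable `LIPSCAN_CATH_DIR`).

## Statistics module conventions

Enrichment factors are frequency ratios with binomial error propagation
and are *undefined* (NA), not infinite, for residue types absent outside
the region.  The polarity grouping partitions all twenty amino acids
(negative = D, E).  The two-proportion test is the pooled Z-test;
mean-difference reports use pooled-variance Student's t by default (Welch
optional) and carry the point-biserial r, which satisfies
r² = t²/(t² + df) identically, and Cohen's d on the pooled standard
deviation.  Exposure classes are buried < 10%, intermediate 10–40%
(inclusive), exposed > 40% of the residue-type maximum SASA; residues
without a tabulated maximum are excluded from class counts but kept in
totals, so class percentages can sum below 100%.
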