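---
title: "Methods and conventions in structkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions in structkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structkit)
```

structkit is a toolkit for the structural side of protein modeling and
engineering: reading and writing macromolecular coordinates, assigning
secondary structure, describing super-secondary structure (smotifs) by
quantitative loop geometry, grafting loops between proteins, mapping
residue-contact interfaces, and preparing homology-modeling inputs
(hit filtering, PIR alignments). This vignette records the models,
conventions and numerical choices the package commits to, and what its
synthetic test fixtures do and do not demonstrate about real data.

## The structure model

A structure is an atom-level tibble: one row per atom with chain, residue
number, insertion code, residue name, atom name, coordinates (Å), occupancy,
B-factor, alt-loc and element. Residue identity is the pair (author number,
insertion code), and ranges such as 19–38 are inclusive in file order — the
convention used when naming antibody loops. Chains are typed protein /
nucleic / hetero by majority residue classification (ties resolved protein >
nucleic > hetero); MSE counts as protein and reads as M.

Parsing commits to these policies:

* **Alt-locs** are resolved to a single conformer at parse time: within each
  (chain, residue, atom-name) group the highest occupancy wins, ties broken
  alphabetically by alt-loc identifier. This is the usual single-conformer
  convention; the discarded conformers are not recoverable downstream.
* **Multi-model files** yield the first model unless another is requested.
  NMR ensembles are never averaged.
* **mmCIF** identity uses the author fields (`auth_asym_id`, `auth_seq_id`)
  so that the PDB and mmCIF renderings of one entry parse to the same
  structure; `label_*` fields are a fallback only.
* **Hydrogens** are kept on parse but excluded from every distance-based
  computation (contacts, clashes, heavy-atom modes).

The PDB writer emits fixed-column ATOM/HETATM records with 3-decimal
coordinates, so a write/parse cycle reproduces coordinates to at worst
5×10⁻⁴ Å; hierarchy (chains, residues, atom names, numbering) round-trips
exactly.

## Rigid-body superposition

`kabsch()` computes the least-squares superposition by SVD of the 3×3
cross-covariance matrix, flipping the smallest singular direction whenever
the candidate rotation has negative determinant, so the result is always a
proper rotation (no mirror images). Collinear point sets leave the rotation
about the line undetermined and are rejected as rank-deficient rather than
silently resolved. The test suite checks the minimum RMSD against Horn's
closed-form quaternion solution and against direct numerical minimization
over quaternion parameters — two routes that share no code with the SVD
implementation.

## Secondary structure

`assign_secondary()` re-creates the hydrogen-bond electrostatics of the
Kabsch–Sander method. The amide hydrogen, absent from most crystal
structures, is imputed 1.01 Å from N opposite the bisector of the
C(prev)–N–CA angle. A CO(i)→NH(j) bond is declared when

E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol,

with bonds to the chain's first residue and to proline excluded (no amide
H), and |i−j| ≥ 2. Helix (H) is assigned to the residues covered by two
consecutive i→i+4 turns; strand (E) to residues in parallel or antiparallel
bridge patterns (|i−j| ≥ 3), with helix taking precedence; everything else
is coil (C). Residues with missing backbone atoms are forced to coil and
counted in an `n_incomplete` attribute rather than failing the whole chain.
This is deliberately a three-state assigner: π-helices, turns, bends and
β-bulges of the full 8-state scheme are out of scope, and `parse_dssp()`
collapses external DSSP output to the same three states ({H,G,I}→H,
{E,B}→E) so both sources feed the same downstream machinery.

SSE segmentation keeps maximal runs with length ≥ 4 for helices and ≥ 3 for
strands — the shortest physically meaningful helix turn and bridge-capable
strand — and fits each SSE a straight axis: the first principal component
of its Cα positions, oriented N→C, with endpoints given by projecting the
first/last Cα onto the axis line. A principal-component axis is exact for
ideal strands and accurate to a few degrees for helices of about three
turns; it degrades for 4–5 residue helices, which is acceptable for motif
geometry but not for, say, helix-kink analysis.

## Smotif loop geometry

A smotif is two consecutive SSEs plus the connecting loop (possibly of
length zero). With M1, M2 the unit axis directions and Dv the vector from
the first axis' C-terminal end to the second axis' N-terminal start, the
four descriptors are

* D = |Dv| — inter-SSE distance (Å),
* δ (hoist) = angle(M1, Dv) ∈ [0°, 180°],
* θ (packing) = angle(M1, M2) ∈ [0°, 180°],
* ρ (meridian) = azimuth of M2 about M1 ∈ [0°, 360°), measured right-handed
  about M1 with zero in the (M1, Dv) half-plane containing Dv.

The literature leaves the endpoint and reference-plane choices open; fixing
them this way removes the 2π ambiguity in ρ and makes all four parameters
exactly invariant under rigid motion, which the tests assert to 10⁻⁶. When
|Dv| ≈ 0 or Dv is parallel to M1 the reference half-plane vanishes; such
motifs are flagged degenerate and excluded from similarity searches instead
of being given arbitrary angles.

Similarity between motifs is a weighted Euclidean distance over
(ΔD, Δδ, Δθ, Δρ) with the meridian difference taken circularly. The default
weights (1 per Å; 1/15 per degree) make 15° trade against 1 Å, a scale at
which the generator grid's neighbors order sensibly; the weights are a
package convention — no published metric exists for this space — and are
exposed as an argument.

## Loop grafting

`graft_loop()` implements stem-superposition grafting: the `flank = 4`
residues on each side of the donor loop are superposed onto the acceptor's
flanks using backbone N, CA, C, O atoms (32 points for the default flank —
enough for a stable fit while staying within the structurally conserved
stems), the fitted transform is applied to the donor loop, and the loop
replaces the acceptor's. Side chains ride along unmodified; there is no
repacking, minimization or loop closure, so the flank RMSD and the clash
count (grafted heavy atom < 2.5 Å from any retained non-flank acceptor
heavy atom) are the honest quality signals. Grafted residues are renumbered
consecutively from the start of the replaced range with empty insertion
codes. When the donor loop is longer than the acceptor loop the numbering
deliberately runs past the old range end and downstream residues keep their
numbers; the splice then may reuse a number already present downstream.
Consumers that need unique residue keys after such a graft should renumber;
the package keeps the convention simple and predictable instead of
inventing insertion codes.

## Interfaces

An interface is the set of inter-chain residue pairs whose minimum
selected-atom distance is at or below a cutoff: all heavy atoms (default
cutoff 5 Å), Cα only (default 8 Å), or Cβ with Cα substituted for glycine.
These defaults are common literature values for defining residue contacts.
One contact is kept per residue pair, carrying the minimum distance; waters
and other hetero residues are excluded, as are hydrogens and intra-chain
pairs. The implementation is checked against exhaustive double-loop
enumeration, and the contact set is symmetric under chain swap, monotone in
the cutoff, and rigid-motion invariant.

## Homology-hit filtering and PIR output

BLAST tabular (12-column) output is parsed as-is; XML is out of scope.
Filtering combines E-value, query coverage — defined as
(q_end − q_start + 1)/query_length; the choice of the query side is a
package convention, configurable through the inputs — percent identity, and
optionally the Rost significance curve

p(L) = n + 480 · L^(−0.32·(1 + exp(−L/1000))),

with offset n = 5 by default. One caution: this closed form is the
canonical curve for homology-modeling template selection, but it is only
meaningful for the alignment lengths where it was fit — it decreases
steeply through the twilight zone, reaches its minimum near L ≈ 417, and
rises slowly for longer alignments (≈ n + 12 at L = 10⁵). The package
returns the formula's value for any L ≥ 1 and leaves domain judgment to the
caller; the shape guarantees in the tests are asserted over L = 10–400.

`write_pir()` emits the MODELLER-compatible dialect: a `structureX`
template entry (`structureX:<id>:<start>:<chain>:<end>:<chain>::::`)
followed by a `sequence` query entry, 60-character sequence lines, `*`
terminator appended to the final line (or alone on the next line when the
final line is exactly 60 characters). Aligned sequences must be
equal-length with `-` gaps; `*` is forbidden inside sequences.

## Synthetic fixtures: what they show and what they don't

All tests run on generated structures; nothing is downloaded. Chains are
built by sequential internal-coordinate placement (NeRF) from ideal bond
lengths and angles (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; angles
111.2°/116.2°/121.7°; ω = 180°), with the carbonyl O trans to the next
amide N and a Cβ placed at the L-configuration branch (improper dihedral
N–C–CA–Cβ = +120°). Helices use φ = −57°, ψ = −47°; strands φ = −120°,
ψ = +120°. The problem sizes are chosen to exercise every code path while
keeping the whole suite around a minute: 12-residue helices, 8-residue
strands, 6-per-strand hairpins, 12+loop+12 scaffolds, and 10–30-residue
synthetic dimers.

* `make_scaffold()` places two ideal SSEs at an exactly prescribed
  inter-axis distance D and packing angle θ (displacement fixed at 45° from
  the first axis so that δ and ρ are well defined) and interpolates a loop
  with small deterministic jitter. The generator's parameters are the
  ground truth the smotif geometry must recover (D within 1 Å, θ within 5°
  over D ∈ {5,10,15} Å × θ ∈ {30,90,150}°).
* `make_hairpin()` places the second strand by a deterministic rigid-body
  fit (BFGS from a fixed antiparallel starting placement) to ideal
  N···O = 2.9 Å hydrogen-bond distances on alternating cross-strand pairs,
  so the Kabsch–Sander assigner finds genuine antiparallel bridges.
* `make_dimer()` lays two poly-alanine chains on well-separated lattices
  and moves the first k residues of chain B toward their partners by root
  finding until the minimum heavy-atom distance equals the requested
  contact distance (to well under 0.01 Å), with every other pair at least
  2 Å clear. Contact counts are therefore exact by construction.
* Loop and turn pseudo-residues in scaffolds and hairpins carry plausible
  but not stereochemically ideal backbones; they exist to connect SSEs and
  to give grafting and clash code realistic atom counts.

Determinism: generators derive all jitter from a hash-style function of the
seed rather than the global RNG, so equal seeds give bit-identical
coordinates and the R session's random state is never touched.

Passing on these fixtures demonstrates correctness of the geometry,
bookkeeping and format contracts. It does not demonstrate robustness to
the pathologies of experimental files — missing atoms beyond single
backbone gaps, unusual residues, zero-occupancy regions, chain breaks,
symmetry copies — beyond the specific behaviors tested (alt-loc selection,
incomplete-backbone demotion, insertion-code ranges). Poly-alanine also
means side-chain-dependent behavior (other than the Gly/Cβ rule) is
untested by construction.

## Known limitations

* Three-state secondary structure only; no π-helix, turn or bend classes.
* Axis fitting assumes straight SSEs; long curved helices get a chord axis.
* Grafting performs no refinement; a clash count of zero on ideal
  scaffolds does not imply a packable interface on real proteins.
* No networked retrieval of any kind: files come from the local disk.
* Buried surface area, interface energetics and binding-affinity scoring
  are out of scope; the interface module stops at residue contacts.
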