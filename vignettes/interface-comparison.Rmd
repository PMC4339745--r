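---
title: "Comparing protein–protein interfaces with pcalign: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing protein–protein interfaces with pcalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcalign)
```

## The problem and the model

A protein–protein interface is the set of residues two chains contribute
to their mutual contact region. Interfaces with no sequence or fold
relationship can still be functionally interchangeable — a viral decoy
binding a host protein at the same site as the host's own partner — so we
want a similarity measure defined on the interfaces themselves. Two
obstacles shape the method. First, interfacial residues are discontinuous
fragments scattered along each chain, so the superposition must be
sequence-order-independent. Second, much of the growing pool of large
assemblies is solved at resolutions where only the Cα trace is reliable,
so the representation must survive the loss of side chains.

`pcalign` therefore reduces an interface to a labeled Cα point cloud: each
interfacial residue keeps its Cα position, a fragment label (side A or B
of the interface), and one of six coarse chemical classes derived from the
dominant side-chain functional groups — donor (K, R), acceptor (E, D),
mixed donor/acceptor (N, Q, S, T), aromatic (F, W), aliphatic (C, A, I, L,
M, P, V, G), and mixed donor/acceptor-or-aromatic (H, Y). The classes are
not mutually exclusive in the groups they expose; two residues are
*match-compatible* when their classes share a group, so asparagine can
stand in for arginine (donor) or for aspartate (acceptor).

### Interface extraction

At atomic resolution two residues are in contact when at least two heavy
atoms, one from each residue, are within 4.5 Å (boundary inclusive; the
contact rule speaks of atoms "within" a distance without stating
strictness, and ≤ keeps the rule closed under exact arithmetic). When side
chains are absent the criterion moves to Cα–Cα distances with a per-pair
cutoff

\[ \mathrm{cutoff}_{ij} = \mathrm{mean}_{ij} + \xi\,\mathrm{sd}_{ij}, \qquad \xi = 0.5, \]

acknowledging that a Ser–Lys contact holds its Cαs farther apart than an
Ala–Ala contact. `compute_cutoff_table()` regenerates the 20×20 statistics
from any user-supplied set of atomic structures (pair types with fewer
than two observations fall back to the global mean/sd, with a message);
`uniform_cutoff_table()` provides a documented flat fallback (8 Å, zero
spread) that the tests and the synthetic generator use so the package is
self-contained. A structure is treated as Cα-only when fewer than half of
its non-glycine residues carry any non-backbone heavy atom; the 0.5
threshold is our operational reading of "side-chain information not
available", and `extract_interface(mode = )` can force either criterion.

### Candidate superpositions: geometric hashing

Hashing expresses interface-1 points in local reference frames built from
ordered triplets of points within one fragment, bins the coordinates, and
stores them keyed by (bin, fragment label). Interface-2 frames probe the
table; a probe point votes for an interface-1 frame when bin and fragment
label agree and the chemical classes share a group. A frame pair with
enough votes proposes the rigid transform carrying interface 2 onto
interface 1. Both fragment pairings (A–A′/B–B′ and the swap) are tried,
since the correspondence of binding sides is unknown a priori.

The frame construction — origin at the first triplet point, x-axis toward
the second, z-axis along the triangle normal — is our own engineering
choice, as are its admission rules: triplet side lengths in [3, 13] Å and
triangle area ≥ 1 Å², which keep frames local and numerically stable.
Binning uses 2 Å cells with the 27-cell neighborhood probed, absorbing
boundary effects at Cα-scale precision. The vote threshold defaults to
`max(4, 25%)` of the smaller interface's residue count. Near-identical
("degenerate") transforms arising from different frame pairs are merged by
greedy leader clustering at 15° / 3 Å tolerances, votes summed, and the
top 100 representatives go to refinement. All of these live in
`hash_params()` and are logged per run rather than hard-coded.

Two numerical subtleties deserve a note. Because bins are 2 Å wide, a
transform a few degrees off an exact superposition can collect the same
votes as the exact one; equal-vote candidates are therefore re-ranked by a
smooth geometric quality score (summed proximity of transformed points to
compatible partners) before clustering, so exact transforms lead their
clusters. And the ranking deliberately avoids tie-breaking on the absolute
rotation angle: that quantity changes when either interface is rigidly
moved, which would break the equivariance of the candidate list under
rigid motion of the inputs.

### Refinement and scoring

Each candidate is refined by alternating two exact sub-steps: a
maximum-weight bipartite matching of residues under the current transform,
and a Kabsch superposition over the matched Cα pairs. The matching weight
is the equivalence score

\[ \mathrm{eq}_{ij} = \frac{1}{1 + 0.25\,(1 - I_{ij}) + d_{ij}^2/16}, \]

with \(I_{ij}\) indicating identical chemical class and \(d_{ij}\) the
post-superposition Cα distance in Å. Matching is solved separately within
each fragment block, which enforces structurally that matches never cross
binding sides. The assignment problem is solved exactly (shortest
augmenting path, deterministic tie-breaking); the Kabsch step includes the
determinant correction so reflections are never produced. Iteration stops
when the matched set repeats, when the summed equivalence score improves
by less than `tol` (default 1e-6), or at `max_iter` (default 100); the
best-scoring iterate seen is kept, so the refinement objective never
decreases. The objective tracked is the summed equivalence score: the
contact term and size normalization below are constants for a given
matched set, and tracking the sum is what "no further improvement" can
respond to within an iteration.

Scoring prunes pairs below eq = 0.20 (a same-class pair at exactly 8 Å)
and computes

\[ \text{PC-score}_{raw} = \frac{f_c}{L_{ave}} \sum_{i=1}^{L_{ali}} \mathrm{eq}_i,
   \qquad
   f_c = \frac{\langle N^1, N^2\rangle}{0.5\,(\langle N^1,N^1\rangle + \langle N^2,N^2\rangle)}, \]

where the \(N\) are the interfaces' contact maps restricted to the aligned
residues, in pair order, and \(L_{ave}\) is the mean total interfacial
residue count of the two interfaces (both fragments — consistent with the
sum running over aligned residues of both fragments). When both restricted
maps are empty we set \(f_c = 0\): no shared contacts means no contact
evidence, and the score should not benefit from the 0/0 case. The raw
score is finally size-rescaled,

\[ \text{PC-score} = \text{PC-score}_{raw}^{\;\ln 0.3 / \ln(0.14 + 0.29 \cdot 0.97^{L_{ave}})}, \]

with the printed constants adopted as given; the exponent is positive for
every \(L_{ave} > 0\), approaches \(\ln 0.3/\ln 0.14 \approx 0.612\) for
large interfaces, and fixes raw = 1 at 1, so identical interfaces score
exactly 1 at any size. The pruning threshold is applied at scoring time
only, not inside the iteration — pruning during iteration is a plausible
alternative reading, but scoring-time pruning keeps the refinement
objective smooth; the `eq_threshold` argument exposes the choice.

The candidate with the highest scaled score wins. Statistical
significance, when requested, is an add-one empirical rank
\((1 + \#\{b \ge s\})/(n+1)\) against a background of unrelated
synthetic-pair scores (`background_scores()`, seeded, default n = 1000) —
we do not hard-code any reference distribution.

### Q-score

For interfaces formed by copies of the same protein (quasi-equivalent
capsid subunits), the Q-score compares the two subunit-level contact maps
directly: \(Q = 2\langle N^a, N^b\rangle / (\langle N^a,N^a\rangle +
\langle N^b,N^b\rangle)\), indexed by residue position along the common
sequence (identical sequences are verified before scoring). Contacts use
the same extraction criteria as everywhere else in the package, since the
original criterion behind the published capsid maps is not restated in our
sources.

## The synthetic generator

`generate_synthetic_interface()` is first-class, tested code: it is the
package's model of what an interface looks like, and all pipeline-level
guarantees are stated against it. A fragment is a dart-throwing scatter
over a mixture of one to three anisotropic Gaussian blobs (irregular,
lumpy footprints rather than uniform discs), with a 3.8 Å minimum spacing,
bent by a random quadratic height field (coefficients uniform in ±0.06
Å⁻¹) and ±0.6 Å height noise. The partner fragment faces it across the
interface normal: each residue sits at a random in-plane offset of up to
2.5 Å from a distinct partner (resampled to keep B residues ≥ 3 Å apart),
following the partner's height. The patch separation is then tuned by
bisection so the realized contact fraction under the flat 8 Å criterion
approximates the 0.15 target, within the window (≤ 7 Å minus noise
budgets) that guarantees every residue keeps at least one cross-fragment
contact for equal-size fragments. These values were fixed once as
plausible for real interfaces (Cα packing distance, patch curvature on
the order of a few Å across a 30 Å patch, contact density of interfacial
residue pairs) and are deliberately not exposed as knobs.

What the generator does *not* emulate: chain connectivity (no backbone
between consecutive residues), realistic amino-acid neighbor correlations
(types are drawn independently, by default uniformly over the 20-letter
alphabet), multi-layer or deeply interdigitated interfaces, and the
density inhomogeneities of real packing. Consequently, passing tests show
that the algorithmic machinery is correct (exact self-scores, rigid
invariance, separability of noise-corrupted copies from unrelated pairs);
they do not certify score distributions on real PDB-derived interfaces.
One visible consequence: two *unrelated* generated interfaces of matched
size score around 0.3–0.5, higher than what random pairs of real
interfaces would give, because quasi-planar patches of matched point
density are genuinely easy to superpose. The separation that matters —
unrelated background (99th percentile ≈ 0.47 at these sizes) versus
σ = 1 Å noise-corrupted copies (median ≈ 0.95) versus identical copies
(exactly 1) — is what the test suite asserts.

`perturb_backbone()` models a noisy low-resolution trace: side chains are
dropped and each Cα moves along an independent uniform random direction by
a half-normal magnitude |N(0, σ²)|, σ = 1 Å by default — the literal
reading of "perturbed in a random direction by a Gaussian-distributed
magnitude", as opposed to per-coordinate Gaussian noise; the mean
displacement is σ√(2/π) ≈ 0.80 Å at σ = 1. For interfaces the annotated
contact map is kept (the topology is an attribute of the underlying
complex, observed through noisy coordinates).

## Numerical choices and degenerate inputs

* Distance boundaries are inclusive throughout.
* Hashing requires ≥ 3 non-collinear residues per fragment; collinear
  fragments raise a data error (CLI exit 2).
* Kabsch requires ≥ 3 pairs; a collinear matched set is detected from the
  rank of the cross-covariance (its second singular value vanishes) and
  flags the refinement result as degenerate rather than aborting the whole
  comparison.
* If no frame pair reaches the vote threshold the result is an empty
  alignment with PC-score 0 — comparison failure is a score, not an error.
* Altlocs resolve to the highest occupancy (ties toward "A"); only the
  first MODEL of an NMR-style file is used unless `model_index` says
  otherwise; MSE/SEC/PYL map to M/C/K and other nonstandard residues are
  dropped with a warning. These PDB-hygiene rules are our own, chosen to
  keep the 20-letter alphabet the cutoff table and chemical classes need.
* Reproducibility: every stochastic helper takes an explicit seed and
  restores the caller's RNG state; identical inputs give byte-identical
  results. Exact rank equivariance of the candidate *list* under rigid
  motion holds for the leading candidates; deep in the list, bin-boundary
  flips can regroup near-tied low-vote clusters, which is why score
  invariance under rigid motion is asserted tightly (1e-3) for related
  pairs and loosely (0.01) for unrelated ones, and score symmetry in
  argument order is tracked at 0.03.

## Problem sizes in the tests

The suite exercises interfaces of 3–60 residues per fragment. The
pipeline-level checks use 20 seeded self-comparisons at 5–60 residues per
fragment, 50 rigid-recovery fixtures, 50 noise-corrupted copies of a
20+20 interface against a background of 1000 unrelated pairs at 10–30
residues per fragment, 200 assignment instances against a brute-force
permutation oracle, and 50 random atomic structures against a brute-force
contact oracle. These sizes were chosen to cover the supported range while
keeping the default test run in a few minutes on one core.

## Known limitations

* Whole-interface comparison only: no partial/local motif search, no
  multiple-interface alignment, and no solvent-accessibility-based
  interface definition.
* The score targets physicochemical overlap, not evolutionary
  relatedness; a high score between unrelated proteins is a feature
  (mimicry detection), not a false positive, but this also means the
  score should not be used alone as a homology classifier.
* mmCIF input, assembly expansion (BIOMT) and occupancy-weighted
  ensembles are out of scope; convert to PDB first.
* The shipped fallback cutoff table is flat; for serious Cα-only work,
  regenerate the table from a current set of atomic structures with
  `compute_cutoff_table()` / `pcalign make-cutoff-table`.
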