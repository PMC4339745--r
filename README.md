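# pcalign

Coarse-grained, sequence-order-independent comparison of protein–protein
interfaces.

Two binding sites can do the same job without any sequence or fold
similarity between the proteins carrying them — viral proteins that mimic a
host interface are the classic case. Comparing the *interfaces* directly
requires superposing two sets of interfacial residues that are scattered
along their chains (so sequence alignment is useless) and scoring how well
their geometry and chemistry overlap. Because the method uses only Cα
positions plus a coarse chemical typing, it works equally on atomic-
resolution crystal structures and on Cα-only traces typical of low-
resolution cryo-EM models.

## Method

* **Interface extraction.** At atomic resolution, residues from the two
  sides are in contact when two heavy atoms, one per residue, lie within
  4.5 Å. For Cα-only models a per-amino-acid-pair cutoff is used instead,
  `cutoff_ij = mean_ij + ξ·sd_ij` (ξ = 0.5), where `mean_ij`/`sd_ij` are
  statistics of Cα–Cα distances of contacting residue pairs of types *i*,
  *j*; `compute_cutoff_table()` regenerates them from any set of atomic
  structures. An interface keeps only the Cα coordinates of its two
  fragments (A and B) and their inter-fragment contact map.
* **Chemical classes.** Residues are typed by dominant side-chain
  functional group: donor (K, R), acceptor (E, D), mixed donor/acceptor
  (N, Q, S, T), aromatic (F, W), aliphatic (C, A, I, L, M, P, V, G), mixed
  donor/acceptor-or-aromatic (H, Y). Classes match when they share a group
  (N matches R *and* D).
* **Candidate superpositions** come from geometric hashing: Cα points are
  expressed in local frames built from in-fragment point triplets, binned
  and voted on, with votes counted only when bin, fragment label and
  chemical class agree; both fragment pairings (A–A′/B–B′ and A–B′/B–A′)
  are tried and degenerate transforms are clustered.
* **Iterative refinement** alternates maximum-weight bipartite matching of
  residues (Hungarian algorithm, solved within each fragment block) with
  Kabsch superposition over the matched pairs, until the summed
  equivalence score stops improving. The per-pair weight is

  ```
  eq(i,j) = 1 / (1 + 0.25·(1 − I_same_chem) + d_ij² / 16)
  ```

* **PC-score.** With pairs pruned at eq ≥ 0.20,

  ```
  PC-score_raw = (f_c / L_ave) · Σ_i eq(i)
  PC-score     = PC-score_raw ^ (ln 0.3 / ln(0.14 + 0.29·0.97^L_ave))
  ```

  where `L_ali` pairs are retained, `L_ave` is the mean interfacial residue
  count of the two interfaces, and `f_c` is the normalized overlap of the
  aligned contact maps. The size scaling removes the dependence of the raw
  score on interface size; identical interfaces score exactly 1. Empirical
  p-values come from a seeded background of unrelated synthetic pairs.
* **Q-score** (validation metric for same-protein, quasi-equivalent capsid
  interfaces): `Q = 2⟨Nᵃ,Nᵇ⟩ / (⟨Nᵃ,Nᵃ⟩ + ⟨Nᵇ,Nᵇ⟩)` over the two
  subunit-level contact maps — 1 for identical maps, 0 for disjoint ones.

## Worked example

```r
library(pcalign)

pdb <- system.file("extdata", "toy_dimer.pdb", package = "pcalign")
s <- read_structure(pdb)
#> pc_structure 'toy_dimer.pdb': 2 chain(s), 12 residues, 59 atoms, mode=atomic
iface <- extract_interface(s, "A", "B")
#> pc_interface 'toy_dimer.pdb:A|B': 6 + 6 residues, 11 inter-fragment contacts

# a synthetic 20+20-residue interface vs a 1 Å noise-corrupted copy,
# with an empirical p-value from 200 unrelated background pairs
x     <- generate_synthetic_interface(fixture_spec(n_per_fragment = 20, seed = 1))
noisy <- perturb_backbone(x, sigma = 1, seed = 7)
bg    <- background_scores(n = 200, seed = 1)
align_and_score(x, noisy, background = bg)
#> pc_alignment: PC-score 0.9640 (raw 0.9557), f_c 1.000, L_ali 40, L_ave 40.0
#>   coverage 1.000, RMSD 0.881 A, mapping AB, p = 0.004975
```

All 40 residues are placed in correspondence (`coverage 1.000`) at 0.88 Å
RMSD; the noise lowers the PC-score from 1 to 0.96, still far above
anything the unrelated background produces (p ≈ 0.005, the add-one minimum
for 200 background pairs). `summary()` returns the same numbers as a
one-row data frame; `write_alignment()` writes the superposed Cα PDB and a
per-residue correspondence table.

A command-line front-end ships in `inst/exec/pcalign` with subcommands
`extract`, `align`, `qscore`, `perturb`, `background` and
`make-cutoff-table`; `align --json` prints a machine-readable one-line
summary (fields `pc`, `pc_raw`, `f_c`, `L_ali`, `L_ave`, `coverage`,
`rmsd`, `p_value`). Exit codes: 0 success, 1 usage error, 2 data error
(no interface, degenerate geometry).

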