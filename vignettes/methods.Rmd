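---
title: "Methods: in silico fragmentation and spectrum-to-structure translation"
author: "ms2mol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico fragmentation and spectrum-to-structure translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Identifying a small molecule from its positive-electrospray tandem mass
spectrum is the central unsolved problem of metabolomics: spectral libraries
cover a vanishing fraction of chemical space, so most reproducible features
in a serum run simply cannot be looked up. `ms2mol` implements the opposite
strategy: the *forward* problem (predicting fragment masses from a known
structure) is tractable, so millions of (structure, theoretical spectrum)
pairs can be generated in silico and used to train a sequence-to-sequence
model that *translates* a peak list into a SMILES string. Candidate
structures coming out of the model are then filtered by molecular formula,
re-fragmented, and ranked by how well their theoretical spectra match the
query ("round-tripping").

This vignette documents the model, the tunable parameters, the synthetic
data used by the test suite, and the numerical and design choices a
maintainer would want to know about.

## In silico fragmentation

A molecule is represented as a heavy-atom graph (hydrogens are folded into
per-atom counts; aromaticity is perceived at parse time). Fragmentation
breaks bonds serially and recursively:

* only **single, non-aromatic** bonds are eligible (amide bonds count as
  single bonds; all graph bonds join heavy atoms);
* a break either disconnects the fragment (two children partitioning the
  atoms) or opens a ring (one child, same atoms);
* hydrogen counts are **frozen** at their parent values — homolytic
  bookkeeping with no rearrangement or ±H transfer. This is the simplest
  reproducible rule; it necessarily misses rearrangement fragments, which
  is a property of the method, not a bug;
* recursion stops at `max_depth` (default 3) or when a fragment's neutral
  mass falls below `min_fragment_mass` (default 50 Da — below the smallest
  fragment mass one typically sees printed in worked peak lists, and
  configurable down to 0);
* each surviving fragment is shifted by each configured adduct (default
  protonation, +1.00727646 Da) and the resulting m/z values are
  deduplicated at 5 decimal places. The protonated molecular ion is always
  part of the spectrum.

**State deduplication.** Identical fragment states reached through
different break orders are expanded once. The state key is the *(atom set,
remaining bond set)* pair, visited at its minimal depth. The atom set alone
would be wrong: two different ring bonds broken in the same ring leave the
same atoms but different remaining bonds, and hence different descendants.
With the full-state key the engine provably emits the same peak set as
exhaustive recursion (the test suite checks this against a brute-force
enumerator that tries every sequence of bond removals).

**Depth-wise augmentation.** For each molecule, three training samples are
built, one per depth 1–3. Shallow depths emulate the high-intensity early
breaks of a real instrument; deeper generations add progressively noisier
secondary fragments. Samples whose peak list exceeds 100 distinct bins are
dropped individually.

## Encoding and vocabulary

Peaks are binned at 0.01 Da over [0, 500): `bin = floor(mz * 100)`,
50,000 bins. *Floor*, not round — the bin number is the integer index the
multiplication produces; rounding would shift about half of all bins by
one. At m/z 500 a 5 ppm instrument window is 0.0025 Da, so 0.01 Da bins do
not lose information relative to the assumed mass accuracy. Inputs are the
sorted (ascending) sequence of at most 100 distinct bin indices; intensity
is never used in the encoding (it only orders peaks in the top-k
protocol).

The output vocabulary is frozen at 69 tokens: `<sos>`, `<eos>`, `<unk>`,
`<pad>` at ids 0–3 plus 65 content tokens (aromatic and aliphatic element
symbols with `Cl`/`Br`/`Si`/... as single tokens, ring-closure digits,
brackets, bond/branch/charge punctuation, and a set of bracket-atom
element symbols). The size is part of the model contract (it fixes the
output dimensionality); the token list itself is a versioned artifact of
the package so the contract is testable. Tokenization round-trips exactly
for any string free of `<unk>`.

## The translation model

The model is the standard post-norm encoder–decoder attention architecture:
multi-head scaled dot-product attention, residual connections with layer
norm, position-wise ReLU feed-forward blocks, fixed sinusoidal positions,
and an output projection untied from the target embedding. Input tokens are
bin indices embedded through a dedicated 50,001-row table (50,000 bins plus
a padding row) — this "token sequence" reading is what reconciles a
maximum input length of 100 with the parameter budget, since the input
embedding alone holds 51.2 M weights. At the full-scale defaults (12 + 12
layers, width 1024, 16 heads, feed-forward 4096) the model holds
404,057,157 trainable parameters, which `count_parameters()` computes in
closed form and the test suite cross-checks against the summed sizes of
actually allocated arrays.

Training minimizes next-token cross-entropy (nats/token) with causal
masking in the decoder and padding masking throughout, using Adam
(β₁ = 0.9, β₂ = 0.98, ε = 1e-9) under the warmup/decay schedule

```
rate(step) = (batch/base_batch) * d_model^-0.5 * min(step^-0.5, step * warmup^-1.5)
```

with `warmup = 8000` by default and linear batch-size scaling (the
conventional reading of batch-dependent scaling; `base_batch` is
configurable). After every epoch the validation loss is computed and the
best-validation weights are checkpointed; training stops after `patience`
epochs without improvement. The network, reverse-mode gradients and
optimizer are implemented directly on base R matrices; every gradient path
is verified against central finite differences in the test suite.

**Label smoothing** is not used (the simplest faithful default; exposed
implicitly through the loss, which is plain cross-entropy). **Decoding at
prediction time is stochastic**: temperature-1 multinomial sampling, run
`n` times. Repeated sampling is what produces the model's qualitative
certainty signal — a confident model emits few distinct outputs across
runs (`uniqueness_ratio` near 0), an unsure one emits nearly as many
distinct strings as runs. Greedy argmax decoding is provided for
capacity checks.

## Candidate post-processing

* `formula_filter()` keeps predictions whose protonated monoisotopic mass
  lies within a ppm window of the precursor (or exactly matching a known
  formula). An empty result is the explicit "no prediction with the
  correct formula" outcome.
* `roundtrip_rank()` fragments each candidate, bins the theoretical
  spectrum, and scores binned cosine similarity against the query
  (binary occurrence vectors: `|a∩b| / √(|a|·|b|)`). Ordering is cosine
  descending, then prediction frequency, then canonical SMILES — the two
  tie-breaks are the package's own choice to make the ranking total and
  deterministic.
* `topk_procedure()` handles experimental spectra, where low-intensity
  peaks grow increasingly unreliable: for k = 1..n it samples predictions
  from the k most intense peaks (ties broken toward lower m/z — again a
  determinism choice), always sorted ascending in m/z, formula-filters
  each batch, pools survivors with summed frequencies, and reports the
  most frequent canonical SMILES as the final candidate.
* `typical_similarity()` scores molecular similarity as the maximum
  Tanimoto (Jaccard) coefficient over six fingerprint encodings:
  linear-path (FP2), atom-pair, topological-torsion, MACCS-type keys,
  circular radius-2 neighbourhoods, and SMARTS substructure-pattern keys
  (FP4). Path, MACCS and pattern keys come from OpenBabel and atom pairs
  from ChemmineR; torsion and circular fingerprints are computed
  in-package as identifier *sets* (unfolded), which leaves the Jaccard
  metric exact rather than subject to bit-folding collisions.
* Challenge-style evaluation (`casmi_filter()`, `casmi_score()`) retains
  positive-mode records with all peaks < 500 m/z, fewer than 100 peaks
  and SMILES shorter than 100 characters, and scores an outcome as
  `correct` on canonical-SMILES equality (same-formula candidates are
  isomers of one another, so equality after canonicalization is the
  decisive test), `no_prediction` when the formula-filtered set is empty,
  and `unknown` otherwise with the best Tanimoto similarity reported for
  diagnosis (path-based by default; the six-encoding maximum behind a
  flag).

## Synthetic data and what the tests show

`generate_fixture_molecules()` draws small C/H/N/O molecules (roughly 4–14
heavy atoms) from a scaffold/substituent grammar: benzene, pyridine,
furan, pyrrole, cyclohexane, tetrahydrofuran and pyrrolidine cores plus
short acyclic skeletons, decorated with alkyl, hydroxy, amino, carbonyl,
carboxyl, ester, amide and nitrile substituents. Every fixture is a valid
unique canonical SMILES with a protonated ion below 500 Da that tokenizes
without `<unk>` and fragments cleanly at depth 3.

The generator emulates the *composition* constraints of the study data
(C/H/N/O only, m/z < 500, short SMILES) and the presence/absence character
of theoretical spectra. It does **not** emulate instrument noise,
contaminant peaks, intensity structure, isotope patterns, adducts beyond
protonation, or the structural diversity of millions of purchasable
compounds. Passing tests therefore demonstrate that the pipeline's
machinery is correct and has the claimed capacity at desk scale — not that
a desk-scale model generalizes to real spectra, which requires full-scale
training explicitly outside this package's scope.

**Desk-scale problem sizes used by the test suite** (the package's own
choices): 50 fixture molecules (150 augmented samples); a toy model of
2 + 2 layers, width 64, 4 heads, feed-forward 256, no dropout; batch 30
with `base_batch = 30` and warmup 400 (chosen once from a pilot run on a
separate 20-molecule set); 200 training epochs; 20 decodes per top-k
iteration instead of the full protocol's 300. Under these conditions the
toy model memorizes its training set (loss < 0.1 nats/token), reconstructs
≥ 45/50 molecules greedily from their own depth-3 spectra, recovers
≥ 40/50 as the most frequent candidate through the full top-k pipeline,
and retrieves 50/50 molecules as rank-1 in round-trip self-retrieval.

## Numerical choices and degenerate inputs

* Atomic masses are most-abundant-isotope masses to ≥ 6 decimals
  (H 1.0078250319, C 12 exactly, N 14.0030740052, O 15.9949146221; proton
  1.00727646); reference monoisotopic masses only reproduce at full
  precision.
* Formula enumeration over {C,H,N,O} (S/P/halogens behind the `elements`
  argument) requires ring-plus-double-bond equivalents
  `C − H/2 + N/2 + 1 ≥ 0` and nothing else — no nitrogen rule, no isotope
  patterns. Output is sorted by absolute mass deviation; an empty result
  is valid.
* Canonicalization strips stereochemistry and isotope labels textually
  before perception, so `[C@@H]` keeps its explicit hydrogen and
  compositions are unchanged; a molecule with no eligible bonds (methane,
  benzene) yields exactly its protonated molecular ion.
* Softmax layers subtract the running maximum before exponentiation;
  fully-masked key positions receive −1e30 rather than −Inf so that
  padded rows stay finite.
* Layer norm uses ε = 1e-5; Glorot-uniform initialization for projections
  and N(0, d^-1/2) embeddings, all under a caller-supplied seed. Training,
  splitting, sampling and fixture generation restore the caller's RNG
  state afterwards.
* Ring-opening breaks consume one unit of depth even though they yield a
  single fragment — every bond break is counted uniformly.

## Known limitations

* No intensity prediction: the engine models presence/absence of peaks
  only, and cosine scoring is over binary occurrence vectors.
* No negative-ion mode, no adducts beyond protonation (the adduct table
  is a configuration hook), no isotope-pattern reasoning, no
  stereochemistry (canonical SMILES are stereo-free by construction).
* The bond-break rule set is fixed (single, non-aromatic, depth 3);
  tuning break statistics against spectral libraries is out of scope.
* The latent-space candidate expansion strategy is exposed only as the
  `expand_candidates()` plug-in hook; no generator ships with the
  package.
* Full-scale training (tens of millions of samples, ~400 M parameters) is
  architecturally supported — `build_model()` will allocate it — but far
  outside desk-scale compute; the package's empirical claims are limited
  to what its tests compute.
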