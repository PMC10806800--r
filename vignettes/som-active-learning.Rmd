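---
title: "Atom-level active learning for site-of-metabolism prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-level active learning for site-of-metabolism prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A site of metabolism (SoM) is an atom position at which a metabolic
biotransformation of a small molecule is initiated — the methyl carbon of an
aryl methyl ether that a P450 demethylates, the sulfur of a thioether that
gets oxidized, the para position of an activated aromatic ring. Annotating
SoMs experimentally (typically by HPLC-MS metabolite identification plus
expert interpretation) is slow and expensive, and SoM corpora are small and
strongly imbalanced: roughly one heavy atom in nine is a SoM, with two to
three SoMs per molecule on average.

`somal` treats SoM prediction as binary classification of heavy atoms and
wraps the classifier in an *active-learning* loop whose purpose is data
efficiency: instead of training on every annotated atom, the model itself
selects, iteration by iteration, the atoms whose annotation would be most
informative. The practical use case is prioritization — an experimentalist
with raw metabolism data can spend annotation effort only on the atom
environments the model is uncertain about.

## The model

Each heavy atom is described by a feature vector that concatenates, for
every topological distance (bond count) $d = 0, 1, \dots, D$:

* a 24-slot count vector over Sybyl-style atom types (element ×
  hybridization × environment: `C.3`, `C.ar`, `N.am`, `O.co2`, `S.o2`, …),
  counting the atoms of each type at exactly distance $d$ from the center;
* the element-wise sum, over the same distance-$d$ shell, of 14 electronic
  and topological base descriptors.

The vector length is therefore $38(D+1)$; the default bond depth $D = 5$
gives 228 features. $d = 0$ encodes the center atom itself. Alongside the
real-valued vector, a binary circular fingerprint of length $24(D+1)$
records which atom types are *present* at which distance; this fingerprint
(at depth 5) drives the similarity-based data splits.

The 14 base descriptors are: heavy-atom degree, total valence,
hybridization ordinal, implicit hydrogen count, effective polarizability
(additive atomic polarizabilities damped by $2^{-d}$ per bond), partial
σ charge, partial π charge, total charge, σ electronegativity,
π electronegativity, inductive effect, atom eccentricity, graph diameter
and relative span (eccentricity/diameter). Partial σ charges and σ
electronegativities come from the classic iterative
partial-equalization-of-orbital-electronegativity (PEOE) scheme run for six
damped cycles on the molecular graph with implicit hydrogens expanded to
pseudo-atoms; π charges delocalize formal charges uniformly over conjugated
components; the inductive-effect term is the $1/d^2$-weighted
electronegativity pull of the rest of the molecule. Everything is a pure
function of the 2D molecular graph — no conformers, no stereochemistry —
which keeps featurization around a millisecond per molecule. The descriptor
list is configurable (`descriptor_config()`), so an alternative set with
the same cardinality can be reconciled without code changes.

The classifier is a random forest of 250 probability trees with class
weights inversely proportional to class frequencies, `min.node.size = 1`
and `mtry = floor(sqrt(p))` (the common classifier defaults of the
reference ensemble libraries), trained with a fixed seed and one thread so
results are bit-reproducible. Class weighting is the package's stand-in for
per-bootstrap balanced reweighting, which the underlying forest
implementation does not expose; on the benchmark library the two schemes
are not distinguishable. The decision threshold is $\tau = 0.30$: an atom
is called a SoM when its predicted probability satisfies $p \ge \tau$
(boundary counted positive — a documented convention, as the tie case is
not otherwise specified anywhere).

## Curation

`curate_library()` implements the data-processing contract:

1. **Standardization** — keep the largest organic component (ties broken
   toward more carbons), neutralize simple ±1 charges on N/O/S/P where a
   hydrogen can absorb them, and put atoms into a canonical order. An
   annotation sitting on a *removed* salt component is an error rather than
   silent data loss.
2. **Eligibility** — at least one SoM; elements within
   {C, N, S, O, H, F, Cl, Br, I, P, B, Si}; molecular weight in
   [100, 1000] Da, inclusive at both ends ("between" is read inclusively,
   which discards less data); parsable.
3. **Duplicate merging** — records with identical standard InChI collapse
   into one; SoM flags are unioned (canonical atom order makes indices
   directly compatible) and then *closed under topological symmetry*: every
   flag expands to its full automorphism equivalence class. Equivalence is
   computed exactly, as orbits of the automorphism group of the colored
   molecular graph (vertices colored by element/charge/implicit-H, bonds by
   order with aromatic bonds mutually indistinguishable), via BLISS.

The pipeline is idempotent and reports its accounting
(`curation_report()`): output = input − rejected − merged.

Atom indices are 1-based everywhere (R convention), including the
`mol_id,atom_index,is_som` annotation CSV and the `SOM_INDICES` SDF
property.

## Atom deduplication and fold generation

Before splitting, atoms whose full descriptor vectors are *bit-exact*
identical are merged (`deduplicate_atoms()`). No tolerance is used: the
featurization copies each automorphism orbit from its first member, so
symmetry-equivalent atoms are exactly equal and unrelated atoms essentially
never are. A label conflict inside such a group would indicate
contradictory annotations and is an error by default.

Two fold generators are provided:

* `stratified_folds()` deals each class round-robin after a seeded
  shuffle, so per-fold class counts deviate from exact proportionality by
  at most one.
* `cluster_folds()` clusters the depth-5 fingerprints with Butina
  (leader-style sphere exclusion) at Tanimoto distance cutoff
  $1 - 0.80$, then packs whole clusters into folds greedily (largest
  first into the currently smallest fold). Plain Butina clustering does
  *not* by itself guarantee that every above-threshold pair is
  co-clustered — a point can neighbor two different centroids — so a
  union-find post-pass merges any clusters still linked by a pair at or
  above the ceiling. The resulting guarantee, verified by brute force in
  the tests: no cross-fold pair exceeds Tanimoto 0.80. The cluster→fold
  packing rule is the package's own choice (the guarantee constrains only
  the clustering, not the packing); greedy size-balancing keeps folds
  usable for cross-validation.

## The active-learning loop

With a training set $T_k$ and pooling set $P_k$ partitioning the
active-learning set:

1. $T_1$ = one randomly drawn SoM plus one randomly drawn non-SoM;
   $P_1$ = everything else.
2. Train the forest from scratch on $T_k$ (no incremental updates — the
   forest is cheap and retraining keeps every iteration exactly
   reproducible).
3. Score every pool atom and select the batch $a_k$: the $n$ atoms with the
   smallest informativeness score $|p - \tau|$ (ties broken by ascending
   record id). The selector sees record ids, probabilities and descriptor
   vectors only — never labels.
4. $T_{k+1} = T_k \cup a_k$, $P_{k+1} = P_k \setminus a_k$; repeat until
   the pool is exhausted. The final model, trained on the full accumulated
   set, is always evaluated, so the last history row is identical to a
   direct fit on all atoms with the same seed — an end-to-end equivalence
   the tests assert bit-exactly.

Variants: *random* selection (the baseline the uncertainty strategy must
beat), *mini-batch* ($n$ = 5, 10, 25, 100), and *diverse mini-batch*
(shortlist the $m$ most informative, k-means the shortlist's descriptor
vectors into $n$ clusters — 10 seeded restarts — and take the candidate
nearest each centroid; pairings 5-of-25 and 10-of-100). Evaluation against
the validation fold happens every `eval_every` iterations (default 10) plus
always at the first and last iteration; with single-atom batches,
evaluating every iteration is a cost knob, not a semantic one.

Learning curves track MCC, ROC AUC, precision, recall, Jaccard score and
the positive label ratio of $T_k$ against the fraction of the
active-learning set consumed. The top-2 success rate is only defined where
whole molecules are covered (the molecule-level test split), since
atom-level validation folds cover molecules partially.

## The synthetic benchmark library

Real SoM corpora are proprietary, so the package ships a generator
(`generate_library()`) whose output exercises every pipeline stage with no
external data. Molecules are assembled from a fixed grammar — one to three
rings (benzene, pyridine, pyrimidine, thiophene, furan, cyclohexane,
piperidine) joined directly or via methylene, plus one to four substituents
(alkyl, O/N/S ethers and amines, halogens, carbonyl groups) drawn with
fixed weights — and labeled by deterministic substructure rules mimicking
common metabolic hotspots: carbons alpha to ether oxygens or amine
nitrogens (O/N-dealkylation), divalent sulfur (S-oxidation), and aromatic
CH para to an O/N donor (aromatic hydroxylation). Ineligible draws are
resampled.

The grammar's weights were chosen once so that a 200-molecule library
reproduces the statistical shape of expert-curated SoM data — mean heavy
atoms ≈ 19, SoMs per molecule ≈ 2.5 (target regime 2.6), heavy-atom SoM
fraction ≈ 0.13 (target 0.11, accepted band 0.08–0.15) — and are not
tuned thereafter.

What the fixture does *not* emulate: annotation noise and inter-expert
disagreement (labels are a noiseless function of the graph), enzyme-class
structure (one binary label), tautomerism, stereochemistry-dependent
metabolism and genuinely out-of-grammar chemistry. Consequently absolute
metric values on the fixture are optimistic — the learnable signal is
clean — and passing benchmarks demonstrates the machinery (selection
really concentrates on informative atoms, splits really respect similarity
ceilings), not real-world accuracy. Directional results (uncertainty
sampling beating random selection at equal budget; stability across
initial pairs) are the meaningful comparisons.

## Numerical choices and degenerate inputs

* Metric conventions: MCC is 0 when any confusion-matrix marginal is zero
  (computed in log space to avoid overflow); Jaccard and precision/recall
  are 0 on zero denominators; AUC uses average ranks (ties count half) and
  is undefined (NA) with one class.
* Probability ties in atom ranking break by ascending atom index, making
  top-2 rates reproducible.
* Two-atom molecules with a SoM always count as top-2 successes.
* k-means for diverse batches uses 10 restarts under the run seed;
  cluster representatives tie-break by record id.
* A pool smaller than the batch returns the whole pool; a two-record pool
  terminates after the initial training.
* Single-atom and disconnected inputs are handled (eccentricity/diameter
  fall back to 0, relative span to 1).
* Aromatic input is preferred kekulized (orders 1/2 with an aromatic
  flag); order-4 aromatic bonds are accepted with the 1.5-bonds-per-
  aromatic-bond valence rule, which assigns pyrrole-type NH one hydrogen
  too few — curation via the SMILES/OpenBabel path avoids this entirely.

## Problem sizes used in the shipped benchmarks

The test-suite benchmarks run on a 200-molecule library (~3 400
deduplicated atoms), batch size 25, five repeat seeds, evaluating at the
20 %- and 25 %-of-pool marks; the fold-ceiling verification uses 500 atoms
with all ~125 000 cross-pairs checked by brute force. These sizes were
chosen as the smallest at which the directional comparisons are stable
across seeds; larger libraries sharpen, but do not change, the
conclusions.

## Known limitations

* The exact reference descriptor list and 24-type table exist only in a
  proprietary supplement; the defaults here match their cardinalities and
  intent (and are configurable), but individual descriptor values are not
  numerically comparable to other implementations.
* Balanced class weights approximate per-bootstrap reweighting.
* The charge model is a fast graph-based scheme, not a quantum-chemical
  one; π charges in particular are a coarse heuristic.
* InChI-based duplicate detection assumes no tautomer collisions (none
  arise from the generator grammar); colliding records with non-identical
  graphs are left unmerged with a warning.
* Molecule-level splitting of the active-learning pool itself is out of
  scope (atom-level splits are the supported schemes).
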