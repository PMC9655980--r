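---
title: "Methods: molecule curation, descriptors and nearest-neighbour QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecule curation, descriptors and nearest-neighbour QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarkit)
```

qsarkit implements a complete binary-QSAR workflow: structure curation,
descriptor and fingerprint generation, k-nearest-neighbour (KNN) and
consensus classification, validation, applicability domains, and a
portable deployment format. This vignette is the package's account of the
science in each stage: the models, their assumptions, the tunable
parameters, the numerical conventions, and what the test suite does and
does not demonstrate.

## Molecular graphs and their normal forms

Every computation runs on a hydrogen-suppressed molecular graph
(`mol_graph`): atoms carry element, formal charge, isotope label,
attached-hydrogen count, aromatic flag and tetrahedral tag; bonds carry
order (1–3), an aromatic flag and an optional cis/trans direction mark.
SMILES input follows the Daylight implicit-hydrogen model; SDF input is
MDL V2000 (including `M CHG`/`M ISO` property lines and atom parities,
which several lighter readers drop).

Two normal forms matter:

* **Kekulized** (`kekulize()`): aromatic flags replaced by an explicit
  alternating single/double assignment. Lone-pair donors (pyrrole-type N,
  furan O, thiophene S, anionic C) and atoms with exocyclic double bonds
  are excluded from the double-bond matching; each aromatic ring is then
  checked against the Hückel 4n+2 electron count, so an aromatic-flagged
  cyclobutadiene is rejected rather than silently "fixed". The matching
  is a deterministic backtracking search; kekulization is idempotent.
* **Aromatized** (`aromatize()`): rings of sp2-compatible atoms whose π
  count satisfies 4n+2 are re-flagged aromatic. Canonical keys
  aromatize first so that Kekulé and aromatic spellings of one molecule
  agree.

**Canonical keys.** `canonical_key()` emits a canonical SMILES after
iterative neighbourhood refinement of atom invariants (element, degree,
charge, isotope, hydrogen count, aromaticity) with deterministic
tie-breaking. Identity is configurable: stereo marks, charges, isotopes
and hydrogen counts can each be erased before canonicalization, which is
exactly what duplicate analysis needs (two spellings that differ only in
a tetrahedral tag collapse once stereo is ignored). Tetrahedral parity is
stored relative to the ascending order of neighbour indices and
re-expressed for whatever output order the writer chooses, so parity
survives re-ordering, canonicalization and SDF round trips. Limitations:
directional (cis/trans) bond marks are preserved but not converted into
an abstract E/Z label, and the tie-breaking step — like every
refinement-based canonicalizer without a full automorphism search — could
in principle distinguish two atoms that a certificate-based scheme would
not; the invariance tests cover the molecule classes the package
targets (organic drug-like structures).

## Curation

`check_structures()` applies ten independent checkers. The valence model
is a table of allowed valences per element with charge adjustment (C 4;
N 3 or 5, +1 → 4; O 2, −1 → 1; S 2/4/6; P 3/5; halogens 1; B 3). The
neutral pentavalent nitro spelling N(=O)=O is deliberately *allowed*, as
it is the normal form one of the nitro standardizers produces. A radical
is an under-filled valence without a compensating charge, so a carbon
written with a missing hydrogen trips both `unusual_valence` and
`radical_atom`. `covalent_ionic_bond` flags single bonds between
alkali/alkaline-earth metals and electronegative atoms; the paired
standardizer rewrites them as charge-separated fragments.

`apply_standardizers()` runs an ordered rule list, each rule to a fixed
point per molecule. Seventeen built-ins cover the common repairs
(fragment filters, hydrogen repairs, nitro/azide/diazo normal forms,
charge and isotope clearing, neutralization); custom rules are
reaction-SMARTS (`reactant>>product`) in a small, explicit dialect —
element, degree `D`, hydrogen count `H`, charge, `~`/`-`/`=`/`#` bonds,
atom maps — matched by backtracking subgraph embedding. Rule *order*
matters across rules and this is intentional, not a defect: removing
mono-atomic fragments before splitting a covalent metal–oxygen bond
keeps the metal, the reverse order discards it. A fixed rule list applied
twice equals the list applied once.

`find_duplicates()` groups molecules by canonical key under the chosen
ignore-options (equivalence classes of size ≥ 2); loosening options can
only merge groups. `resolve_duplicates()` removes every member of a
group whose endpoint labels disagree (or are missing) and keeps the first
member, in file order, of agreeing groups — deterministic and
order-preserving. `curate_bbb()` chains the recipe used for
blood–brain-barrier data: kekulize, drop disconnected structures,
unusual valences and single-heavy-atom molecules, then resolve
duplicates with stereochemistry ignored (the descriptor set is
stereo-blind, so stereoisomers are one molecule for modelling purposes).
It returns a per-molecule removal log and is idempotent.

`murcko_scaffold()` prunes terminal heavy atoms iteratively, leaving ring
systems plus linkers. Exocyclic terminal atoms (e.g. a carbonyl oxygen on
a linker) are pruned with the side chains; scaffolds are compared as
stereo-blind canonical keys, and ring-free molecules are counted
separately rather than contributing an empty scaffold.

## Descriptors

The nine descriptors were chosen for interpretability; each is a pure
function of the graph.

* **Mp** — mean atomic polarizability scaled on carbon:
  $\mathrm{Mp} = \frac{1}{n}\sum_i p_i/p_C$ over *all* atoms including
  hydrogens. The polarizability table (units $10^{-24}\,\mathrm{cm}^3$:
  H 0.667, C 1.76, N 1.10, O 0.802, F 0.557, P 3.63, S 2.90, Cl 2.18,
  Br 3.05, I 5.35, B 3.03) is shipped as data
  (`polarizability_table()`) and swappable. Mp depends only on
  composition, not connectivity or size.
* **nN** — nitrogen count, regardless of charge or aromaticity.
* **MPC07** — molecular path count of order 7: the number of simple
  7-bond paths in the heavy-atom graph, each undirected path counted
  once, returned as $\ln(1 + \mathrm{count})$. The `1 +` makes the
  no-path case 0 instead of $-\infty$; the natural log keeps the scale
  consistent with the SHED entropy below.
* **NssssN+** — quaternary ammonium count: N with formal charge +1 and
  exactly four single bonds.
* **SHED_DL / SHED_AN** — Shannon entropy descriptors over pharmacophore
  point pairs. All topological distances between atoms of the two labels
  are collected, capped into bins $1..d_{max}$ with $d_{max}=20$
  (distances beyond 20 clamp into the last bin; disconnected pairs are
  absent), and the descriptor is $e^H$ with
  $H = -\sum_b p_b \ln p_b$. A single pair — or all pairs at one
  distance — gives exactly 1; uniform occupancy of all 20 bins
  approaches 20; no pair at all gives 0 by convention. The natural-log
  base is forced by the stated range $[1, 20]$ with 20 bins.
* **F09[C-C]** — the number of unordered carbon pairs at topological
  distance exactly 9.
* **TPSA(Tot)** — Ertl-style fragment-additive polar surface area with
  the published N/O *and* S/P environment contributions; environments
  outside the table contribute 0.
* **MLOGP / MLOGP2** — the Moriguchi 13-parameter regression
  (`calc_mlogp()` documents the coefficients). The structural parameters
  are computed topologically; two of the dummies are heuristic by
  necessity: the intramolecular hydrogen-bond flag (donor and acceptor
  three bonds apart across an unsaturated/aromatic path — the
  ortho-effect pattern) and the amphotericity flag (α-amino acid 1.0;
  amino-/aza-aromatic acid 0.5). These heuristics are deterministic and
  documented here so that values are reproducible; they may differ from
  other implementations on unusual structures.

**Pharmacophore typing.** The SHED descriptors need per-atom labels
{donor, acceptor, positive, negative, lipophilic}. No universally agreed
rule set exists, so the package publishes its own (`ppp_rules()`): D = N/O
bearing hydrogen; A = O with charge ≤ 0, and N excluding positive,
amide-like, nitro and pyrrole-type cases; P = positive formal charge;
N = negative formal charge, acid-group oxygens (carboxylic, sulfonic,
phosphoric) and tetrazole ring nitrogens; L = carbon or halogen not
bonded to any D/A/N atom. Values computed with any other rule set will
differ on edge cases; what matters for reproducibility is that the rules
are explicit, auditable data.

## Fingerprints

`maccs166()` evaluates the public 166-key MACCS SMARTS dictionary through
the OpenBabel command line tool and decodes its packed output so key *k*
is bit *k*. On probe molecules the bits agree exactly with an independent
implementation of the same dictionary; bit-level identity with any
*other* MACCS dialect is not promised — fingerprints are internally
consistent, which is what a distance-based model needs. `ecfp()` is an
in-package Morgan construction: atom invariants (element, degree,
hydrogen count, charge, aromaticity, ring membership) are iteratively
hashed with sorted neighbour (bond, invariant) lists up to the chosen
radius; duplicate environment hashes count once and survivors fold
modulo the fingerprint length (power of two). Radius 3 at 2048 bits is
the conventional ECFP6/2048 configuration. Environments at radius r are
a subset of those at r+1 before folding, and the hashing is
order-independent by construction. `tanimoto_distance()` is
$1 - |a \wedge b|/|a \vee b|$, with two empty fingerprints at distance 0
(identical objects).

## Models, validation, applicability domains

`knn_fit()` stores the training data (KNN is lazy). Euclidean features
are standardized by default with training-set mean/sd — refusing silently
unstandardized real-valued KNN is deliberate, since raw descriptor scales
would dominate the metric; fingerprints are used as-is. Ties are resolved
deterministically: at the k-th distance rank the first-sorting training
id is included, and an even-k vote tie falls back to the nearest
neighbour's class. Re-predicting a training molecule includes its own
stored copy at distance zero (the common training-score convention);
`exclude_self = TRUE` gives the honest leave-self-out variant, and
cross-validation is always the preferred estimate. `consensus_model()`
takes the majority vote; with three members no tie can occur, with an
even count a tie is an error unless a tie-breaking member is configured.

`cross_validate()` uses seeded *stratified* folds (class proportions
preserved — the BBB-style datasets are unbalanced, and unstratified folds
could lose a class entirely in a small fold); every sample is predicted
exactly once by a model fitted without it, and the pooled out-of-fold
confusion matrix gives the reported scores. `y_randomization()` refits on
permuted labels; a real model scores clearly above the permuted
distribution, which collapses to the majority-class rate.
`ga_select()` evolves feature subsets by tournament selection, uniform
crossover, per-gene mutation (default rate 1/n), elitism, and a repair
step enforcing the subset cap (default `max_features = 10`, chosen to
keep models interpretable). Package defaults are population 100 and 200
generations; the test suite and examples use smaller, faster
configurations (population 24, 15 generations on 60 molecules per class)
that already recover planted features reliably.

Two applicability domains are provided. The leverage domain uses
$h = x (X^TX)^{-1} x^T$ on the intercept-augmented standardized training
matrix with the conventional Williams-plot threshold $h^* = 3(p+1)/n$;
the training leverages sum to $p+1$ by the hat-matrix trace identity.
The distance domain scores a query by its mean distance to the $k$
nearest training molecules and accepts it below the 95th percentile of
the training set's own leave-self-out scores, so ~95% of training data
is inside by construction. Fingerprint models default to the distance
domain (leverage needs a real-valued design matrix), descriptor models
to leverage. A consensus prediction is inside its domain only if every
member agrees — the conjunction rule, which makes the consensus domain a
subset of each member's.

## Deployment

`qsar_project()` bundles models, feature recipes, pretreatment and
domains; `save_project()` writes versioned JSON with full-precision
numeric payloads, so `load_project()` reproduces predictions
bit-for-bit, and loading executes no code (unlike binary serialization
formats). `run_project()` recomputes each model's features for new
molecules, applies the stored pretreatment, predicts, and flags
molecules per model instead of failing globally — a molecule with an
element missing from the polarizability table gets `NA` from the
descriptor model but is still predicted by the fingerprint models.

## The synthetic generator, and what the tests show

`synthetic_classification()` draws class-conditional normal features:
`n_informative` columns shifted by `effect` standard deviations between
classes, `n_noise` columns identically distributed in both. The default
conditions — 200 molecules per class, 2 informative + 48 noise columns,
effect size 3 — emulate the situation feature selection faces: a strong
signal hidden in a much wider descriptor block. They do *not* emulate
real chemical data: features are uncorrelated and Gaussian, classes are
balanced, and there is no analogue of activity cliffs or assay noise.
Passing tests therefore demonstrate that the machinery is correct
(selection finds planted signal, CV is honest, permutation collapses to
chance), not that any particular accuracy is attainable on real
endpoints. One measured fact worth recording: with all 48 noise columns
left in, 5-fold CV accuracy of the KNN sits near 0.85, while on the
informative subspace (or the GA-selected subset) it exceeds 0.95 — noise
dimensions dilute Euclidean neighbourhoods, which is precisely why the
workflow places variable reduction and feature selection before model
fitting.

Test problem sizes are the package's choices: invariance properties run
on randomly generated graphs of 4–12 heavy atoms; enumeration oracles on
graphs up to 10 atoms; GA recovery on 60 molecules per class over five
seeds; Y-randomization with 10–12 permutations.

## Known limitations

* SMILES coverage is the organic subset plus bracket atoms; exotic
  features (quadruple bonds, polymeric markers, reaction SMILES) are out
  of scope, and unsupported input fails loudly with line numbers.
* Aromaticity perception targets the common 5–7-membered systems;
  unusual fused polycycles may stay in Kekulé form, which is harmless for
  identity comparisons (both spellings normalize identically) but means
  "aromatic" atom counts are conservative.
* MACCS bits depend on the public dictionary as implemented by
  OpenBabel; other dictionaries differ on a handful of keys.
* The MLOGP hydrogen-bond and amphotericity dummies are documented
  heuristics, not a re-derivation of the original training set's manual
  assignments.
* 3D structure, conformers and any descriptor requiring coordinates are
  deliberately out of scope.
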