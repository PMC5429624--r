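---
title: "Three-step prediction of RNA-protein binding sites: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-step prediction of RNA-protein binding sites: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the architecture

Most binding-site predictors answer only one of three questions about a
protein-RNA pair: which residues of the protein touch the RNA, which
nucleotides of the RNA touch the protein, and which residue-nucleotide pairs
are actually in contact. `rpibind` answers all three with a cascade of three
random-forest models:

1. **Step 1** scores every protein residue as RNA-binding or not.
2. **Step 2** scores every nucleotide as protein-binding or not.
3. **Step 3** scores residue-nucleotide *pairs* as contacts. In *cascade*
   mode its training positives are restricted to contacts whose residue and
   nucleotide were themselves recovered by steps 1 and 2, and at inference
   only pairs passing both gates are scored. In *flat* mode all contacts
   train the model and all pairs are scored.

The method's premise is that local *structure* carries information that
sequence alone does not. Both polymers are therefore encoded with structural
alphabets:

* **PLC** (protein local conformation): the 16-letter protein-block alphabet.
  Each position's five-residue fragment is described by eight backbone
  dihedrals — psi(i−2), phi(i−1), psi(i−1), phi(i), psi(i), phi(i+1),
  psi(i+1), phi(i+2) — and assigned the prototype block with minimal angular
  RMSD (RMSDA, circular differences; ties broken alphabetically). Positions
  without a full window of defined dihedrals get the placeholder `Z`, so the
  first/last two positions of a chain are always `Z`. The prototype table
  ships as `inst/extdata/pb_prototypes.tsv`.
* **RLC** (RNA local conformation): a 12-class alphabet assigned per
  nucleotide from secondary structure (dot-bracket input): `a` hairpin loop,
  `b` stem, `c` stem branch, `d`/`h` left/right internal loop, `e`/`i`
  left/right bulge, `f`/`j` and `g`/`k` their multiloop ("branch") variants,
  and `l` unknown.

## RLC junction conventions

The 12-class list does not by itself fix an operational rule for multiloop
junctions, so the package adopts explicit conventions (implemented in
`assign_rlc()`, exercised by a hand-derived golden file):

* Unpaired positions outside every base pair are *external* and map to the
  catch-all class `l` ("unknown"); exterior-loop helices keep `b` ends.
* In a loop with one enclosed helix, unpaired runs on both sides form an
  internal loop (`d`/`h` on the 5'/3' side); a run on one side only is a
  bulge (`e`/`i`).
* In a multiloop (two or more enclosed helices), only the junction-facing
  paired position of each entering helix becomes `c` (keeping `c` rare, as
  observed in real interface statistics); interior stem pairs stay `b`.
* Unpaired runs inside a multiloop take the *branch* variants: runs that
  precede an enclosed helix take the left (5') classes, the run after the
  last helix the right (3') classes; a single-nucleotide run is bulge-like
  (`g`/`k`), a longer run internal-loop-like (`f`/`j`).

Pseudoknots are rejected; if pairing comes from a 3D structure or an external
predictor, `rlc_from_pairs()` accepts a nested pair list directly.

## Interface definition and propensity statistics

A residue and a nucleotide are *in contact* when their minimum
heavy-atom-heavy-atom distance is at most 5.0 Å (configurable; hydrogens are
ignored). A position is *binding* iff it has at least one contact. Whether to
count atoms or residue centres is a genuine choice; minimum heavy-atom
distance at 5 Å is the dominant convention in the interface literature and is
this package's documented one.

From labeled chains the statistics layer computes, per symbol alphabet
(amino acids, bases, PLCs, RLCs) and optionally per functional class
(enzymes / structural / regulatory / other):

* **Compositions** at and outside the interface;
* **Log-odds preferences**
  ln((c_int+α)/(N_int+αK)) − ln((c_out+α)/(N_out+αK)), natural log,
  pseudocount α = 1 by default;
* **Mutual interaction propensity (MIP)** matrices over contacting symbol
  pairs, log-odds against the row-by-column independence expectation, zero
  for an exactly independent table at α = 0.

Natural log and α = 1 are conventions (the downstream feature layer consumes
these values; the base only rescales features uniformly).

## Windowed features

Every position becomes one sample: a five-position window centred on it
(window sizes 3/5/7/9 are supported; 5 is the default and the size that
performed best across the three steps). Protein features per window position:
the MIP profile of the residue's amino acid against the four bases, seven
physicochemical scales (Kyte-Doolittle hydropathy, Grantham polarity, charge,
volume, isoelectric point, Chou-Fasman helix and sheet propensities), the
Fauchère-Pliska hydrophobic index, relative solvent accessibility, a
conservation score, and a side-chain burial fraction; plus the triplet
log-odds of the (window−2) overlapping PLC triplets. RNA features: mono-, di-
and tri-nucleotide composition within the window plus RLC triplet log-odds.
Pair samples concatenate the two member vectors, protein first.

Conventions worth knowing:

* **Terminal padding** uses the chain mean of each scalar feature (so
  termini do not masquerade as extreme values); composition frequencies are
  computed over the in-chain part of the window; triplets that would extend
  past the chain contribute a neutral 0.
* **Triplet log-odds tables** are fitted on training folds only and looked
  up with a pseudocount-only default for unseen triplets. They are the
  "structure descriptor" of steps 1-3.
* **RSA** is computed on the unbound protein by an internal Shrake-Rupley
  routine (92 Fibonacci sphere points, 1.4 Å probe) normalised by Gly-X-Gly
  maxima. **Side-chain burial** is the fraction of side-chain heavy atoms
  within 8 Å of other residues' atoms. **Conservation** is a pluggable
  per-residue vector defaulting to a constant 0 (no signal, stable vector
  shape) since computing it requires external alignments. When a bundle
  carries no structure (synthetic bundles), RSA and burial default to a
  neutral 0.5.

## Training, evaluation, cascade

Models are random forests (500 trees, sqrt(p) features per split, seeded) by
default; SVM and a single-hidden-layer neural network sit behind the same
interface for classifier comparisons. Evaluation uses grouped k-fold
cross-validation: folds are assigned by *source complex*, so positions of one
complex never span training and test folds — stricter than plain position-level
CV and immune to within-complex leakage. All descriptor tables (MIP, triplet
log-odds) are refitted inside each training fold.

Step-3 datasets pair each contact's members with near-miss negatives:
non-binding nucleotides within the window radius of the contacted nucleotide
and vice versa, pooled and subsampled to a 1:1 ratio by default — near
negatives are the hardest and most practically relevant to separate. In
cascade mode the fold's training positives are gated by the *in-sample*
step-1/2 predictions (mirroring training-set construction), and the held-out
pairs by the *out-of-sample* predictions of the same fold models (mirroring
deployment, where gating is all a user can do). Decision thresholds default
to 0.5 everywhere and are configurable per step.

Metrics: SN, SP, ACC, PPV, NPV, MCC from the pooled confusion, and AUC as the
midrank Wilcoxon statistic (equal to trapezoidal ROC integration). With
single-class labels the AUC is reported as `NA` with a warning while the
other metrics are still returned.

## The synthetic study conditions

Real training corpora require curated structure downloads, so the package
ships a generator whose bundles emulate what the statistics observe on real
complexes: interface patches enriched in helix/sheet protein blocks (`m`,
`d`), stem RLCs (`b`), and Arg/Lys. Defaults are fixed as the package's study
conditions:

* interface fractions 0.48 (protein) and 0.65 (RNA), the proportions seen in
  curated complex sets;
* chains of 80 residues / 40 nucleotides, 30 complexes;
* enrichment factor 2 on the letters above, 10% noise (an interface position
  drawing from the background distribution).

Enrichment has *exact-ratio* semantics: a factor r sets the enriched
symbol's interface frequency to exactly r times its background frequency
(remaining mass spread over the other symbols), so the interface log-odds of
that symbol converges to ln(r) — the parameter-recovery contract the tests
assert. Patches are placed uniformly on the *circle* (wrap-around), so every
position has the same marginal interface probability and a null generator
(all factors 1) carries no positional signal; grouped CV AUC on null draws
sits at 0.5 ± 0.05. `strong_planted_spec()` is the calibrated strong-signal
preset (helix/sheet ×3, Arg/Lys ×5, stem ×2.5, noise 0.05): under an
independence approximation the Bayes-optimal accuracy of the
window likelihood-ratio classifier on the protein side is ≈ 0.95, and the
pipeline's cross-validated accuracy is required to reach 0.85.

What the generator does *not* emulate: real 3D geometry (its companion
`generate_toy_pdb()` writes schematic coordinates only for parser and
contact-extractor tests), autocorrelated conformation strings (letters are
drawn independently given the label), multi-patch or discontinuous
interfaces, and base-pairing consistency between the RNA sequence and its
RLC string. Passing tests therefore demonstrate correctness of the machinery
and the direction of the structure/cascade effects, not performance on real
complexes.

Problem sizes used by the test suite and the acceptance script (chosen to
keep a full run in minutes on one CPU): 12-40 complexes per condition,
5-fold (step 1-2) or 3-fold (step 3) grouped CV, 300 trees. The paper-scale
corpus is roughly one order of magnitude larger.

## Worked example

```{r}
library(rpibind)

bundles <- generate_bundles(strong_planted_spec(seed = 11, n_complexes = 15))
cv1 <- cross_validate(bundles, "protein", k = 5, seed = 1)
cv1          # SN/SP/ACC/MCC/AUC for RNA-binding residue prediction

cascade <- fit_cascade(bundles[1:14], seed = 1)
pred <- cascade_predict(bundles[[15]], cascade)
head(pred$pairs)   # top-scored residue-nucleotide contacts
```

For real structures, start from `read_complex("file.pdb", "A", "B")`,
attach a dot-bracket string, and build a bundle with `as_bundle()`.

## Known limitations

* Secondary structure must be supplied (or derived externally); the package
  classifies it but does not predict it, and pseudoknots are not classified.
* Conservation defaults to a constant; with a real alignment-derived vector
  the feature becomes informative, but no alignment machinery is included.
* The step-3 negative pool is near-miss pairs only; distinguishing contacts
  from *distant* non-contacts is easier than what is measured here.
* mmCIF, multi-model averaging and biological assemblies are out of scope
  (first model, single chains).
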