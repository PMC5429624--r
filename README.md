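# rpibind

Three-step, structure-aware prediction of RNA–protein binding sites in R.

Given a protein–RNA pair, `rpibind` answers three questions with a cascade of
random-forest models:

1. **Which protein residues bind the RNA?** (step 1)
2. **Which nucleotides bind the protein?** (step 2)
3. **Which residue–nucleotide pairs are in contact?** (step 3, optionally
   *gated* by the step-1/2 calls — the cascade)

Its premise is that local structure carries signal that sequence alone does
not. Protein backbones are encoded with the 16-letter protein-block
structural alphabet (PLC, letters *a*–*p* assigned by minimum angular RMSD of
the 8 dihedrals ψ(i−2)…φ(i+2) to prototype fragments), and RNA secondary
structure with a 12-class local-conformation alphabet (RLC: loop, stem, stem
branch, internal loops, bulges, their multiloop variants, unknown). From
labeled complexes the package estimates interface statistics — per-symbol
compositions, log-odds preferences

> s(a) = ln((c_int(a)+α)/(N_int+αK)) − ln((c_out(a)+α)/(N_out+αK)),

and mutual interaction propensity (MIP) matrices, the log-odds of observed
contact counts n(i,j) against the row×column independence expectation. These
feed five-position sliding-window feature vectors (physicochemical scales,
hydrophobicity, accessibility, burial, conservation, MIP profiles,
composition profiles, PLC/RLC triplet log-odds) classified by random forests
and evaluated with grouped cross-validation (folds split by source complex)
using SN/SP/ACC/PPV/NPV/MCC and midrank AUC. A contact is a residue–nucleotide
pair with minimum heavy-atom distance ≤ 5 Å.

Because real training corpora need curated structure downloads, the package
includes a seed-reproducible synthetic generator that plants the
qualitatively observed interface preferences (helix/sheet blocks, stem RLCs,
Arg/Lys) at controlled enrichment factors, plus a schematic PDB writer for
end-to-end tests of the structure readers and the contact extractor.

## Worked example

```r
library(rpibind)

# 15 synthetic complexes with the calibrated strong planted signal
bundles <- generate_bundles(strong_planted_spec(seed = 11, n_complexes = 15))

# Step 1: RNA-binding residue prediction, 5-fold grouped CV
cv1 <- cross_validate(bundles, "protein", k = 5, seed = 1)
cv1
#> <rpi_metrics> TP=528 FP=133 FN=42 TN=497
#>   SN=0.926 SP=0.789 ACC=0.854 PPV=0.799 NPV=0.922 MCC=0.718 AUC=0.942

# Full cascade on 14 complexes, applied to the held-out 15th
cascade <- fit_cascade(bundles[1:14], seed = 1)
pred <- cascade_predict(bundles[[15]], cascade)
head(pred$pairs, 3)
#>   residue nucleotide score
#> 1      16         26 0.998
#> 2      18         26 0.998
#> 3      16         27 0.994
```

The CV report says: of the 1,200 held-out residues, 92.6% of true binding
residues are recovered (SN) at 78.9% specificity, 85.4% accuracy overall,
with MCC 0.72 and AUC 0.94. The cascade's top-scored pair (residue 16,
nucleotide 26, probability 0.998) lies inside the planted interface patch of
the held-out complex.

For real structures:

```r
cx <- read_complex("complex.pdb", protein_chain = "A", rna_chain = "B")
cx$dot_bracket <- "(((((......)))))..."   # from experiment or an SS predictor
b  <- as_bundle(cx, cutoff = 5.0)
summarize_interface(b$contacts)
```

A thin command-line front end is installed as `exec/rpibind`
(`rpibind extract|contacts|encode|synth|stats`).

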