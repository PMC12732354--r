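---
title: "Modelling knockdown efficacy of chemically modified siRNA"
author: "siRNAstack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling knockdown efficacy of chemically modified siRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siRNAstack)
```

## The problem

Small interfering RNAs (siRNAs) silence a target gene by loading their
antisense (guide) strand into the RISC complex and directing cleavage of the
complementary mRNA. Therapeutic siRNAs are almost always chemically modified
— 2′-O-methyl, 2′-fluoro, locked nucleic acids (LNA), deoxythymidine
overhangs, inverted abasic caps — to survive nucleases and reduce immune
activation, and those modifications change knockdown efficacy in
position-dependent ways. Sequence-only models cannot see this chemistry.
siRNAstack represents each nucleotide of both strands by the molecular
descriptors of its (possibly modified) monomer SMILES, so the model input
reflects the actual chemical matter of the duplex.

The package covers the full path from heterogeneous experiment tables to a
deployable predictor: curation, sequence analysis, property-matrix
featurization, efficacy binning, leakage-controlled feature selection, a
probability-enhanced stacked regressor, and leave-one-gene-out (LOGO)
evaluation. A seeded synthetic-data generator with planted effects makes
every stage testable end to end without any external dataset.

## Data model and curation

A dataset row holds the sense/antisense sequences, per-position modification
annotations in the mini-format `"pos:name;pos:name"` (1-based, 5′→3′; the
simplest lossless serialization, chosen because public datasets report
modifications in free text), the knockdown efficacy in percent, and five
experimental covariates: siRNA concentration (nM), transfection method,
cell or organism, incubation time (hours) and assay type.

`parseDataset()` applies the curation rules a curated siRNA collection
needs: strand alphabets must be pure RNA (A,U,G,C) or DNA (A,T,G,C) with no
U/T mixing; concentrations are bounded to [0.01, 100] nM (outside this
range reported units are rarely trustworthy); durations parse from hour- or
day-valued text to integer hours; rows with missing fields are dropped with
a named rule in the rejection report. Two deliberate conventions:

* rows reporting an EC50/IC50 rather than a percentage are retained as
  *50% efficacy at the reported concentration* — by definition of a
  half-maximal measure;
* efficacies outside [0, 100] (reporting artifacts) are clipped to the
  bounds and flagged rather than dropped, keeping extreme-value records
  usable.

The modification registry maps canonical names and synonyms
(case/punctuation-insensitive) to per-base monomer SMILES. The bundled
registry covers the five chemistries above with curated,
stereochemistry-free nucleoside SMILES; anything further loads from a
JSON/YAML config. Whole-nucleotide modifications (inverted abasic) ignore
the base letter. Registry SMILES are vetted by the active descriptor
provider's own validity check.

## Sequence analysis

`reverseComplement()` chooses RNA (A–U) or DNA (A–T) complement rules from
the presence of T. Hybrid structure is quantified by a best local alignment
of the sense strand against the reverse-complemented antisense strand
(Biostrings Smith–Waterman). Scoring defaults — match 2, mismatch −1, gap
opening 2, gap extension 0.5 — are conventional nucleotide local-alignment
settings; the originating protocol does not pin them down, so they are
configurable in `alignScoring()`. Gap columns inside the aligned region are
counted as mismatches (the mismatch fraction is defined against the hybrid
region length and gaps break pairing just as substitutions do); terminal
overhangs outside the local alignment are not counted.

Melting temperature uses the linear GC/length/mismatch approximation

$$T_m = 81.5 + 0.41\,\mathrm{GC\%} - \frac{675}{L_\text{hybrid}} - \mathrm{mismatch\%}$$

and the normalized efficacy used for cross-experiment comparison is

$$E_\text{norm} = \log_{10}\!\left(1 + \frac{E}{C_\text{siRNA}\,t}\right)$$

with `lg` read as the base-10 logarithm and units fixed to nM and hours.
Because real dose–response is sigmoidal, this normalization is for
visualization and exploratory analysis only; it is never a training target.

## Property matrices and feature assembly

Each strand becomes a `refLen × D` **property matrix**: row *i* holds the D
descriptors of the *i*-th nucleotide's monomer SMILES; strands shorter than
the reference length (default 27 nt, the longest strand the data model
admits) are zero-padded on the 3′ side, matching the left-to-right
enumeration used in curation. The sense and antisense matrices are
flattened position-major (all descriptors of position 1, then position 2,
…) — any fixed order works; this one keeps a position's chemistry
contiguous — and concatenated to a `2 × refLen × D` vector. For descriptor
sets of size 43, 44 and 223 this gives 2322, 2376 and 12042 features per
pair, and the arithmetic is D-agnostic by construction.

Descriptor providers are pluggable. `chemDescriptorProvider()` computes
interpretable physicochemical/topological descriptors (MW, logP, TPSA,
molar refractivity, H-bond donors/acceptors, fluorine count, heavy atoms,
rings) through ChemmineR/OpenBabel, cached per unique SMILES.
`toyDescriptorProvider(d)` is a deterministic text-derived provider of
arbitrary dimension with no chemistry dependency; it exists so that tests
and dimensionality checks are fast and self-contained. Which specific
descriptor set a study uses matters less to the pipeline than its
dimension; all downstream logic only consumes `descriptorNames`.

Gene context enters either as a label-encoded gene id (1 column) or as a
fixed-length embedding of the full gene sequence through the
`EmbeddingProvider` contract ("the last hidden state of the last token" in
transformer terms). The bundled `mockEmbeddingProvider()` derives each
component from a seeded hash of (sequence, component index): deterministic,
collision-resistant in practice, and download-free. It carries no biology —
it behaves as a gene fingerprint, which is exactly what the LOGO analysis
needs to distinguish memorization from extrapolation. Adapters for real
sequence language models implement the same contract.

Label encoders for the categorical covariates are fitted on training rows
only; unseen categories at transform time map to the reserved code 0.

## Classifier tiers and feature selection

Efficacy is binned twice: a binary scheme (low [0, 45] vs high [55, 100],
the boundary band (45, 55) excluded for class separation) and a four-class
scheme ([0, 23], [27, 48], [52, 73], [77, 100] with open gap bands between
them). Endpoints stay inside classes — the ranges are printed without
open/closed notation, and keeping endpoints retains data. Binning is total
on [0, 100]: every value maps to exactly one class or to the excluded band.

Feature selection is two-staged per task (binary, multiclass, regression):
stage 1 keeps the top 100 features by gain importance from a boosted model
fitted on training rows only; stage 2 computes pairwise inter-feature
Pearson correlations — never feature–target correlations — and greedily
drops the lower-importance member of any pair with |r| > 0.95, the
higher-ranked feature winning and ties broken lexicographically. Stage-2
correlations are deliberately computed over the complete dataset (train and
test), replicating the protocol this pipeline standardizes; because the
target is never touched, no label information can leak, though the test
feature distribution is observed at this step — a documented trade-off of
the replicated protocol.

## The probability-enhanced stacked model

The training partition (80/20 split, seed 42) is divided into 10 folds
(seed 256). For each fold, binary and multiclass classifiers (gradient
boosted trees via xgboost; the model family is injected through
`boosterSpec()` so the pipeline is model-agnostic) are trained on the other
nine folds and predict class probabilities for the held-out fold. Each
training row therefore receives its 2 + 4 probability features from the
single model that never saw it — the out-of-fold (OOF) construction that
makes stacking leakage-free — while each test row receives the arithmetic
mean over the ten fold models. Rows in excluded boundary bands do not
contribute to classifier fitting but still receive probability features
from their fold's model, the only self-consistent way to let the final
regressor train across the whole activity range. Multiclass probability
rows are renormalized to sum exactly to one (float32 softmax sums can
deviate by ~1e−7); binary pairs are exact by construction.

The final regressor consumes the regression-selected base features plus the
six probability features; the vanilla baseline omits the probability block.
Predictions are clipped to [0, 100]%. For new records the fold-model
average rule is reused — averaging was preferred over refitting a single
classifier on the full training set because it keeps the deployed model
identical to the evaluated one.

Hyperparameter search (`tuneBooster()`) is a seeded random search (default
seed 48, 100 trials) over the boosted-tree space (learning rate, depth,
row/column subsampling, L1/L2, min child weight, max bin), maximizing
validation R² for regression or accuracy for classification. Knobs specific
to other boosting backends (num_leaves, cat_smooth, boosting_type) are not
exposed. Every fit runs single-threaded with a local seed, so identical
configs reproduce identical models bit for bit.

## The synthetic-data generator

`simulateDataset()` emulates the statistical shape of curated siRNA
collections: 19–25 nt strands (within the 18–27 nt range such collections
span), antisense strands as reverse complements with a 2% per-nucleotide
substitution rate, modifications placed per nucleotide at rate 0.15,
concentrations log-uniform over [0.1, 100] nM, incubation times in
{24, 48, 72} h. Efficacy follows a logistic link — the simplest form
consistent with sigmoidal dose–response — applied to a linear latent score
with planted, recoverable components:

| component | default weight | carrier in the features |
|---|---|---|
| standardized sense GC content | 1.2 | descriptor block |
| modified fraction of the duplex | −0.8 | descriptor block |
| mid-strand inverted abasic indicator | −2 | descriptor block |
| per-gene random offset | 0.8 | gene embedding only |
| log-concentration response | 0.8 | concentration covariate |

plus Gaussian noise (SD 6 on the percent scale), clipped to [0, 100].
Weights were chosen once so that no single component dominates, the
signal-to-noise ratio resembles a well-powered assay panel, and the
mid-strand abasic penalty mirrors the known strong loss of efficacy when
base pairing is abolished centrally. The gene component is visible to
models *only* through the gene representation, which is what makes the
LOGO degradation check meaningful: under random splits a model can learn
per-gene offsets from the embedding fingerprint, under LOGO it cannot.

What the generator does **not** emulate: real position-specific seed-region
rules, thermodynamic asymmetry, off-target dilution, batch effects between
labs, or genuinely informative gene embeddings. Green tests on synthetic
data therefore demonstrate that the machinery is correct (dimensions,
determinism, leakage-freedom, signal recovery), not that the model
generalizes to laboratory data.

## Numerical choices and degenerate inputs

* Train/test split takes `ceiling(0.8 n)` training rows; fold sizes differ
  by at most one.
* A fold whose classifier labels collapse to a single class raises a
  degenerate-label error rather than silently fitting a constant.
* Constant columns get correlation 0 (not NA) in stage-2 pruning.
* Single-class truth makes ROC-AUC undefined and is flagged, as is a
  constant target in R²/PCC.
* Efficacy predictions are clipped to [0, 100]; out-of-range ingest
  efficacies are clipped and flagged at curation.
* Alignment tie-breaking follows Biostrings' deterministic optimum.

## Problem sizes used in the validation suite

The suite exercises the full pipeline at n = 2000 with 10 generator seeds
for the recovery comparison (stacked vs vanilla), n = 1200 across 6 genes
for LOGO, and n = 500 for the leakage instrumentation — sizes at which the
planted effects are comfortably estimable while the whole suite stays
interactive. The stacked-vs-vanilla comparison asserts a majority direction
over seeds, not a fixed margin, mirroring how such an improvement is
reported in practice.

## Known limitations

* The bundled registry covers five modification chemistries; real curated
  collections use dozens. The registry is extensible by config, but SMILES
  correctness for exotic chemistries is the user's responsibility
  (`validateRegistry()` only checks parseability).
* The mock embedder is a fingerprint, not a language model; conclusions
  about embedding *quality* cannot be drawn from it.
* Stage-2 selection sees test-set feature distributions (deliberate
  protocol replication, documented above).
* The melting-temperature formula is a linear approximation; it is not a
  thermodynamic nearest-neighbour model.

## A worked example

```{r example, eval = FALSE}
sim <- simulateDataset(syntheticConfig(nRecords = 500, seed = 7))
fit <- trainKnockdownModel(sim$records, sim$genes,
                           provider = toyDescriptorProvider(8),
                           embedder = mockEmbeddingProvider(16))
fit$metrics$test$r2
predictEfficacy(fit$bundle, sim$records[1:3, ])
```
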