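---
title: "Re-engineering hERG-active molecules: models, assumptions and desk-scale conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-engineering hERG-active molecules: models, assumptions and desk-scale conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Blockade of the hERG potassium channel prolongs the cardiac QT interval and
can precipitate fatal arrhythmias, so hERG liability is screened early and
aggressively in drug discovery. The CiPA initiative additionally considers
the NaV1.5 sodium and CaV1.2 calcium channels, whose co-modulation can
offset hERG-driven risk. `hergforge` implements a two-stage workflow for
*re-engineering* a hERG-active molecule: generate analogues that share the
input's Murcko scaffold and physicochemical profile, discard those whose
predicted cardiac ion-channel activity violates user constraints, and rank
the survivors by descriptor-space similarity to the input.

## Components

### SMILES corpus machinery

SMILES strings are tokenized with a longest-match alphabet in which bracket
atoms (`[nH]`, `[N+]`, `[C@@H]`), `%nn` ring labels and the two-letter
elements `Cl`/`Br` are atomic tokens; concatenating tokens always
reproduces the input. A vocabulary keeps tokens with at least `min_count`
occurrences (rare-token molecules are dropped from the corpus rather than
patched), reserves `<pad>`, `[CLS]`, `[EOS]`, `<MASK>` at ids 0–3, and
every surviving molecule is laid out as `[CLS], tokens, [EOS], <pad>...`
with a fixed number of content slots (133 by default, the length that
covers 99.99% of drug-like corpora; the total block is therefore 135). We
read the published padding length as *content* length: the specials are
added on top, which is the only reading consistent with padding "to a
length of 133" and then augmenting with start/end tokens.

### Transformers

Both language models share one pre-norm stack: embeddings are the sum of
token and learned position tables (plus, for the generator, a scaffold
embedding table applied position-wise to the scaffold token sequence and a
linear projection of the ten physicochemical properties broadcast across
positions — the reading under which "all embeddings are summed"), followed
by blocks of LayerNorm → multi-head scaled-dot-product attention → residual
→ LayerNorm → two-layer GeLU feed-forward with 10% dropout → residual, a
final LayerNorm, and a linear projection to the vocabulary. The full-scale
configuration is 8 blocks, 8 heads, embedding dimension 256.

The **generator** is causal and trained for next-token prediction with
cross entropy over non-pad targets. The **featurizer** is bidirectional and
trained for masked-token recovery: each content token is selected with
probability 0.15; selected tokens are replaced by `<MASK>` (80%), a random
non-special vocabulary token (10%), or left unchanged (10%). Selection is a
per-token Bernoulli draw followed by an independent categorical draw, the
standard reading of that scheme. The molecular feature vector is the
`[CLS]`-position hidden state taken *after* the final LayerNorm and
*before* the vocabulary projection ("immediately prior to the final linear
transformation" taken literally).

Properties are z-scored with training-corpus statistics stored in the
checkpoint; raw scales (molecular weight vs. formal charge) would otherwise
swamp the linear projection. Sampling is multinomial at temperature 1.0
with optional top-k; a temperature of 0 is greedy argmax. Sampled strings
pass a validity filter (tokenizability, balanced branches and ring labels,
and a successful OpenBabel parse) before anything downstream sees them.
The published training recipe used a second-order optimizer; optimizer
identity is not load-bearing for the method, so training here uses AdamW
with the published learning rate (3e-4) and weight decay (0.1 for the
transformers). Final-epoch weights are returned, as published.

All neural components run on a small reverse-mode tape written for this
package (`R/autodiff.R`) — dense-matrix operations with hand-derived
backward passes, verified against central differences and against
hand-rolled attention/GAT oracles in the test suite. Batches are stacked
into single matrices with block-diagonal attention masks so the heavy
lifting happens in BLAS.

### Discriminative models

Each molecule is represented three ways: the 256-d transformer feature,
a 1024-bit ECFP4 fingerprint (Morgan radius 2, folded), and a molecular
graph whose nodes carry 14 features in a documented order: C/N/O/P/S
indicators, hydrophobicity, aromaticity, H-bond acceptor/donor, ring
membership, bonds to heavy atoms, bonds to heteroatoms, Gasteiger partial
charge, and atomic mass. Three conventions had to be pinned down where the
sources are silent: *hydrophobic* means a carbon with no bonded heteroatom
(the simplest defensible atomic proxy); partial charges are Gasteiger-type
empirical charges (the standard fast 2D method); acceptor/donor are
Lipinski-style atomic definitions (N or O; donor additionally bears a
hydrogen). Bond orders are stored on the edges; the attention layers as
specified aggregate node features only, so edge orders are carried in the
data model but unused by default.

The transformer and fingerprint branches are two-layer
(linear → batch-norm → ReLU → 50% dropout) encoders; the graph branch is a
two-layer graph attention network over the self-loop-augmented
neighborhood (per-edge additive attention, softmax over each node's
neighborhood, heads concatenated, ReLU between layers) followed by global
add pooling. The branch encodings are concatenated and passed through one
more (linear → batch-norm → ReLU → dropout) layer and a final linear map;
classification applies a sigmoid. Batch normalization always uses running
statistics at inference, so single-molecule prediction is well defined.
Hidden widths were tuned (and unreported) in the original; the defaults
here (branch 128, GAT 64 with 8 heads, fused 256) are config-exposed, and
the desk-scale tests use smaller widths.

The output bias is initialized at the training-label mean (regression) or
the base-rate logit (classification), so optimization starts from the
marginal prediction and spends its steps on structure rather than on
locating the label scale — at desk-scale step budgets this matters.
Training otherwise follows the published recipe: AdamW (lr 3e-4, weight decay 1e-4),
L1 penalty 1e-4 added to the loss, batch 32, gradient clipping at global
norm 5.0, learning-rate halving after 10 epochs without validation
improvement, BCE or MSE, 200/100 epochs for classification/regression at
full scale, and snapshot selection by best validation accuracy or Pearson
correlation. Replicate pIC50 labels are aggregated by discarding values
above the replicate set's 95th percentile and averaging the rest — read as
a one-sided upper trim because high outliers dominate IC50 replicates. A
compound is a blocker when pIC50 ≥ 5.0; the sources disagree at the exact
boundary (one section says ≥ 5.0 is a blocker, another says ≤ 5.0 is a
non-blocker) and we follow the dataset-definition reading (≥ 5.0 is a
blocker) everywhere.

### Descriptors, pruning and ranking

Candidates are ranked in a 209-descriptor 2D space. The published
descriptor list is bound to a specific toolkit version that has no R
binding here, so the package pins its own 209-name set of standard 2D
descriptors — the ten conditioning properties, constitutional and
functional-group counts, topological indices (Wiener, Zagreb, Balaban J,
chi and kappa indices, distance statistics), Moreau-Broto / centered /
Geary autocorrelations over topological lags 1–8 for mass, partial charge,
electronegativity and degree, and distance-distribution counts — frozen in
`inst/extdata/descriptor_names.json` and asserted at run time. Columns are
z-scored over {input ∪ candidates} before anything else; cosine similarity
on raw mixed-unit descriptors would be dominated by large-magnitude
columns.

Redundant descriptors are removed by pairwise mutual information. The
estimator and threshold are unstated in the sources, so the package makes
deterministic choices: each column is discretized into up to 32
equal-frequency bins, normalized MI is `I(X;Y)/sqrt(H(X)H(Y))`, the
default threshold is 0.9, and a greedy left-to-right scan drops the
later-indexed member of any offending pair (constant columns are dropped
first). This is order-stable and invariant to row order. Survivors are
ranked by descending cosine similarity to the input, ties broken by
lexicographic canonical SMILES.

### The re-engineering loop

`reengineer()` conditions generation on the input's scaffold and
properties and loops sample → validity check → canonicalize → deduplicate
→ predict → constrain until the requested number of candidates is accepted
or an attempt cap (default 1000 × n) is hit, in which case a partial set
is returned with a warning. Duplicates (by canonical SMILES) and the input
itself never count toward the total. Range constraints accept
`min ≤ p < max`: the upper bound is strict because a filter described as
removing predictions "greater than or equal to" a threshold must exclude
the threshold itself, even though displayed maxima are rounded to two
decimals. Improvement-by-k-log-units objectives are expressed as ranges
relative to the input's predicted value. The chemical-space view is a PCA
of the standardized ten-property matrix over input, candidates and a
background corpus sample.

## Synthetic data: what it emulates and what it does not

No external corpus ships with the package. `make_corpus()` assembles
molecules from a fragment grammar — aromatic, heteroaromatic and saturated
ring cores, linkers, and drug-like substituents, with one to three ring
systems — which guarantees syntactic validity without a chemistry oracle in
the generation loop. A 1000-molecule corpus spans roughly 70–470 g/mol,
covering the drug-like molecular weight range. `make_labeled_set()` plants
a monotone structure–activity relationship,

```
pIC50 = 3.6 + 0.55·LogP − 0.9·TPSA/100 + 0.8·basicN + N(0, 0.4),
```

chosen once so that pIC50 rises with lipophilicity, falls with polar
surface area, rewards a basic aliphatic nitrogen (the qualitative
correlations reported for public hERG data), spans the 5.0 blocker
threshold, and yields a roughly balanced blocker rate (real channel data
are closer to 78/22; balance maximizes test power and the imbalance is
configurable). Passing tests on these fixtures demonstrates that the
machinery can learn and recover a planted monotone signal at desk scale —
not that it reaches published benchmark performance on curated
experimental data, which requires the external benchmark sets and
full-scale training.

## Desk-scale study conditions

The tests and the acceptance script train everything from scratch on one
CPU, so problem sizes are fixed at desk scale: a 300-molecule corpus with
a 36-token content limit, 2-block / 4-head / 48-dimension transformers
(featurizer 6 epochs, generator 45 epochs, batch 16), predictors with
branch width 32 / GAT width 32 / fused width 64 trained 22–30 epochs on a
few hundred labeled molecules, a 25-candidate re-engineering run, and
statistical suites (masking law, Y-randomization, conditioning shift) at
10^3–10^4 draws. The conditioning-shift check runs the fixed-property
evaluation in its in-distribution form: a desk-scale generator produces
almost no valid strings when handed property vectors far from anything it
was trained on, so the test conditions on the scaffold + property vectors
of light versus heavy corpus molecules (three probes each, tempered top-k
sampling) and requires the generated molecular-weight distributions to
order with the conditioning, by a one-sided rank test at α = 0.01. The full-scale defaults (133-token blocks, 8×8×256
transformers, 100–200 epochs, batch 512) remain the constructors'
defaults and are exercised structurally (shapes, layouts) rather than
trained.

## Numerical choices and degenerate inputs

* Gradient checks hold all operations to ~1e-6 against central
  differences; the stacks match independent plain-matrix oracles to 1e-5.
* Masked softmax uses additive −1e9 masks; every row retains at least one
  admissible position (self-loops in the GAT, the diagonal in causal
  attention).
* Batch norm with a single-row batch falls back to running statistics;
  eval mode always uses running statistics.
* MCC is reported as 0 when any confusion marginal is zero; other ratios
  with zero denominators are `NA` rather than silently 0.
* Constant descriptor columns are dropped before MI pruning with a
  warning; non-finite descriptor values become 0 with a warning.
* Acyclic molecules have an empty scaffold and condition the generator on
  an all-pad scaffold row.
* Sampling excludes `<pad>`, `[CLS]` and `<MASK>` from the proposal at
  every step; generation stops at `[EOS]` or the block limit.
* Canonical forms of sampled molecules occasionally exceed the
  featurizer's block length; such candidates are skipped rather than
  truncated.

## Known limitations

* The validity filter delegates valence/aromaticity judgment to OpenBabel,
  which is more permissive than the toolkit used in the original work;
  syntactically odd but parseable strings can survive.
* The pinned descriptor list is *a* standard 2D set of size 209, not the
  original toolkit's list; similarities are comparable within this package
  but not across toolkits.
* Desk-scale models memorize a small grammar corpus; their sample
  diversity and property-conditioning fidelity are qualitative, and the
  conditioning-shift test covers the strongest-signal property (molecular
  weight) rather than all ten.
* Published benchmark values (accuracies, AUCs, Pearson correlations on
  the external test sets) are out of reach without the external data and
  full-scale weights, and are deliberately not asserted anywhere.
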