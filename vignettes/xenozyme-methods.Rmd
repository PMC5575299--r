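---
title: "Predicting gut bacterial biotransformation enzymes: methods and design"
author: "xenozyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gut bacterial biotransformation enzymes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Orally administered drugs and other xenobiotics meet the gut microbiome
before, or alongside, host metabolism. Which bacterial enzyme carries out
the *first* biotransformation step of a given molecule determines the
metabolites formed downstream, yet for most drugs neither the enzyme nor
the species carrying it is known. xenozyme addresses this gap with a
structure-based prediction chain: from a query structure it predicts the
Enzyme Commission (EC) class and subclass able to transform it, assigns
candidate four-digit EC numbers by structural similarity to curated enzyme
substrates, and resolves those ECs to the gut bacterial proteins, genomes
and taxonomic lineages that carry them.

The chain rests on two assumptions worth keeping in view. First, that the
substructure content of a molecule carries enough signal to place it in
the EC hierarchy — true to the extent that each enzyme family's substrates
share recognisable chemotypes. Second, enzyme promiscuity: an enzyme tends
to accept molecules structurally similar to its canonical substrates, which
licenses transferring a known substrate's EC annotation to a structurally
similar query. Neither assumption is exact; both are why predictions carry
probabilities, Tanimoto coefficients and explicit "no-confident-call"
outcomes rather than bare labels.

## Databases

**Substrate database.** The training table is a set of molecules, each
tagged with one or more four-digit EC numbers of enzymes known to act on
it. Three curation filters are applied, in a fixed order:

1. *Cofactor removal.* Cofactors and supporting molecules of enzyme
   function (water, metal ions, ATP/ADP/AMP, NAD(P)(H), FAD/FMN, CoA,
   phosphate, glutathione, ...) appear as "substrates" of very many
   reactions while carrying no information about the principal substrate
   chemotype. They are removed by canonical-SMILES match against a
   packaged, editable exclusion list (`inst/extdata/cofactors.tsv`),
   making a manual curation step reproducible.
2. *Multi-class exclusion.* A molecule metabolized by enzymes of two or
   more different EC classes has no well-defined class label; such records
   are removed. (Multiple ECs within one class are retained — they are
   informative at prediction time.)
3. *Redundancy removal.* Near-duplicate structures (pairwise Tanimoto
   coefficient strictly greater than 0.95 under the path-based 1024-bit
   family) are collapsed by greedy leader clustering in stable input
   order: a record joins the first cluster whose leader it exceeds the
   threshold against, otherwise it founds a cluster; leaders are the
   representatives. Leader clustering was chosen because it is
   deterministic, order-stable and linear in the number of clusters; the
   fingerprint family and threshold are parameters. The first two filters
   are per-record predicates and commute; redundancy removal must run
   last, because the representative set depends on which records survive.

The curated records are indexed by EC class and by (class, subclass)
pairs; these subclass subsets are the search space of the similarity
stage.

**Enzyme database.** Bacterial proteins are annotated with an EC by
best-hit filtering of a standard 12-column tabular protein-alignment file
(plus a 13th column carrying the subject's EC): a hit is eligible when
identity > 40 %, query coverage > 80 % and E-value < 1e-15 — all strict
inequalities, so a hit sitting exactly on a threshold is rejected — and
the best eligible hit per query is taken by highest bitscore, with ties
broken by lowest E-value and then lexicographic subject id. Bitscore was
chosen as the primary criterion because it is the standard alignment
quality measure independent of database size; the residual tie-breaks make
the result deterministic. Running the aligner itself is out of scope: the
package consumes its tabular output, keeping the aligner pluggable.

## Fingerprints and the hybrid

Five binary fingerprint families are registered, chosen to be mutually
complementary in what they encode:

| family      | bits | encodes |
|-------------|------|---------|
| `fp2like`   | 1024 | hashed linear paths up to 7 atoms |
| `fp3like`   |   64 | small SMARTS key set |
| `fp4like`   |  512 | substructure / functional-group keys |
| `maccslike` |  256 | MACCS keys (166 meaningful) |
| `aplike`    | 1024 | hashed topological atom pairs |

Counted descriptors (atom pairs) are binarized (count > 0 → 1), since
feature selection and the Tanimoto coefficient are defined on binary
vectors. Bit indices are 0-based and columns carry the stable identifiers
`family:bitindex` everywhere.

The **hybrid fingerprint** is built per family and then concatenated in
family registration order:

1. *Remove useless*: constant bits, and bits whose majority value occurs
   in more than 99 % of records, are dropped — they cannot discriminate
   anything at the available sample sizes.
2. *Correlation-based feature selection (CFS)* with best-first search. A
   subset S of k bits is scored by the merit
   $$\mathrm{merit}(S) = \frac{k\,\overline{r}_{cf}}
   {\sqrt{k + k(k-1)\,\overline{r}_{ff}}},$$
   where $\overline{r}_{cf}$ is the mean symmetric uncertainty between
   each bit and the class label and $\overline{r}_{ff}$ the mean pairwise
   symmetric uncertainty among the bits. Symmetric uncertainty,
   $SU(X,Y) = 2\,I(X;Y)/(H(X)+H(Y))$, is the standard association measure
   inside CFS for nominal attributes; a zero-entropy variable has SU 0 by
   convention. The search starts from the empty subset, expands states by
   single-bit addition or removal, always expands the best-merit open
   state, and stops after 5 consecutive non-improving expansions — the
   common best-first default. Ties favour the earlier state, making the
   selection deterministic and invariant to row order.

One property of the merit is easy to misread: *exactly duplicating* a bit
leaves the merit unchanged (the numerator's factor k is cancelled by the
redundancy term when $\overline{r}_{ff}=1$), while adding a *partially*
redundant, weaker bit strictly lowers it. The redundancy penalty is real
but it is a penalty against near-duplicates, not a strict decrease under
exact duplication.

**Which labels drive the selection?** Both levels of the cascade share one
hybrid fingerprint, so bits selected only to separate the six classes can
leave subclasses within a class indistinguishable. The package therefore
selects against the combined class.subclass grouping by default
(`substrateLabels(db)$group`); `buildHybrid()` accepts any label vector,
so class-only selection is one argument away.

## The random-forest cascade

Seven forests are trained: one across the (up to six) EC classes, and one
per class across that class's subclasses, every model seeing only
features projected through the shared hybrid spec.

**Imbalance.** Substrate databases are strongly skewed (in realistic
conditions two classes can hold two thirds of the records and two classes
under a tenth). Minority classes are upsampled by random sampling with
replacement to the majority count (`caret::upSample`). Upsampling is
applied *inside each training partition only* — never before a
cross-validation, split or blind partition is drawn — so a held-out
record can never leak into training as its own duplicate. Both
`with_upsampling` and `without_upsampling` modes are first-class.

**Tuning.** `mtry` is tuned by out-of-bag (OOB) error using the
`tuneRF` search: starting at `round(sqrt(p))` (round-half-up, imposed
explicitly — `tuneRF`'s own default would be `floor`), the value is
multiplied/divided by a step factor of 2 while the relative OOB
improvement is at least 0.05, at 100 trees per probe. Every probe is
recorded in a trace and the returned value attains the trace minimum.
`ntree` is then chosen over the grid 100, 200, ..., 500 by OOB error,
with ties resolved to the largest (saturated) value. On cleanly separable
data the OOB error is flat at zero and the tie rule returns 500. Tuning
runs on whatever training set the sampling mode produces (i.e. on the
upsampled set in `with_upsampling` mode), since that is the set the final
forest sees.

Subclasses with fewer than 2 records are excluded from subclass training
(a 1-instance class cannot be validated); they remain in the substrate
database and are still reachable by the similarity stage. A class left
with fewer than two trainable subclasses gets no subclass model, and
prediction into it falls back to the class-level output with an explicit
`no-subclass-model` outcome.

Prediction emits the argmax class with its probability vector; a
configurable probability threshold (default 0, i.e. always emit) turns
low-confidence calls into an explicit "unclassified" outcome.

## Evaluation

Per class (one-vs-rest), from confusion counts TP/FP/FN/TN:
TPR = TP/(TP+FN), TNR = TN/(TN+FP), PPV = TP/(TP+FP),
ACC = (TP+TN)/total (all as percentages), and
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Conventions: a
zero MCC denominator yields 0 (prevents NaN propagation); a zero rate
denominator yields NA. Multi-class summaries are macro-averages of the
one-vs-rest rows; macro was chosen as the symmetric default since no
averaging scheme is canonical for single-row multi-class reports.

Three protocols: stratified 10-fold cross-validation (counts pooled over
folds); a stratified 75/25 split; and a blind protocol that withdraws 10 %
of each class (round-half-up, at least one where the class has ≥ 2
members, none from singletons) before any training, evaluates once, and
then retrains the production forest on the full data. Every protocol's
train/evaluation partitions are disjoint by construction and audited in
the tests.

A PCA diagnostic (`prcomp`, centred, unscaled) of the hybrid feature
table summarises the structural diversity of the database; variance
fractions are non-increasing and sum to one over the full rank.

## Similarity stage

Within the predicted (class, subclass) substrate subset, the query is
compared against every candidate under three families — `fp2like`,
`fp4like`, `maccslike` — by the Tanimoto coefficient
$TC = z/(x+y-z)$ (bits set in each molecule and in both). Each family
ranks its top candidate (ties broken by lexicographic substrate id); if
two or more families agree, that candidate wins even when the dissenting
family holds a higher coefficient; a three-way disagreement is resolved by
the globally highest coefficient. The coefficient is undefined for a pair
of all-zero fingerprints; such candidates are excluded per family, and an
error is raised only if no coefficient is defined anywhere.

If the winning coefficient clears the user-settable cutoff (default 0.5 —
a package choice, exposed as a parameter), all of the winning substrate's
EC tags *within the predicted subclass* are returned: a substrate acted
on by several enzymes of one subclass yields all of them, but never an EC
outside the predicted subclass. Below the cutoff the outcome is
`no-confident-EC`, carrying the best sub-threshold hit for transparency.
Assigned ECs (including partial ones like `1.14.-.-`) are resolved in the
enzyme database by hierarchical prefix matching.

## The synthetic data generator

Nothing in the package depends on downloading reference databases; the
fixture module generates study conditions with exact ground truth.

Molecules are composed from a curated scaffold grammar: each EC class is
anchored by a distinct ring system (benzene, pyridine, furan, thiophene,
N-methylpyrrole, cyclohexane), each subclass by a distinct marker group
(carboxylic acid, sulfonamide, nitrile), and individual molecules by a
tail drawn without replacement from a 24-substituent library. The tail
library was curated empirically against the path-based family so that any
two *distinct* molecules stay at Tanimoto ≤ 0.92 — safely under the 0.95
merge threshold — while same-class molecules share enough substructure to
be separable; an amusing constraint surfaced during curation: linear-path
fingerprints cannot distinguish some pairs that differ only by extending
an oxygen-terminated path (their path sets coincide), so such tails were
excluded. Planted near-duplicates re-emit an existing structure under a
different record id and writing (Tanimoto exactly 1 to the parent);
planted multi-class rows are fresh structures tagged with ECs of two
classes; cofactor rows are drawn from the packaged list. The
`separable6` preset (6 classes × 3 subclasses × 20 molecules = 360 base
records plus planted extras) is the default study condition; `skewed6`
applies an imbalance profile in which the two dominant classes hold about
two thirds of the records and the two rarest about 7 %, mirroring the
skew of real substrate databases.

The enzyme-world generator plants 1–3 proteins per substrate EC across
toy genomes with realistic lineage strings, and writes an alignment-hit
table containing, per annotated protein, a designated best hit, an
inferior eligible hit, a clearly failing hit, and a handful of boundary
rows sitting exactly on the 40/80/1e-15 thresholds (excluded by the
strict inequalities). Every downstream test assertion reads this ground
truth rather than re-deriving labels.

**What the fixtures do not emulate** — and hence what passing tests do
not show about real data: real substrate sets are not linearly separable
chemotype grammars; their class signal is diffuse across many weak
substructures, fingerprint families disagree more, and near-duplicates
occur at all similarity levels rather than exactly at 1.0. Accuracies on
`separable6` (at or near 100 %) are a correctness check of the machinery,
not an estimate of real-world performance; on real databases accuracies
in the 80–97 % range and OOB errors of a few percent to ~13 % per model
are the realistic regime.

## Numerical choices and degenerate inputs

* Threshold semantics are strict everywhere the method states an
  inequality: Tanimoto redundancy merges at TC > 0.95 (equality keeps
  both); alignment hits pass at identity > 40, coverage > 80,
  E-value < 1e-15 (equality fails).
* `round(sqrt(p))` uses round-half-up, implemented explicitly (base R
  `round` is banker's rounding).
* All randomness flows through explicit integer seeds; fixture
  generation, upsampling, fold assignment, tuning and forests reproduce
  exactly under a fixed seed. RNG state of the caller is restored.
* Degenerate inputs fail loudly and specifically: empty curation results
  report stage-wise counts; an all-constant feature table aborts PCA and
  selection; single-class upsampling, zero-column tables and corrupted
  model bundles (hybrid-spec hash mismatch) are errors, not warnings.
* Problem sizes in the shipped tests and acceptance script: the
  `separable6` conditions (394 raw records → 360 curated), a ~2,900-column
  feature table, 10-fold cross-validation and a 25-query end-to-end
  audit. These sizes exercise every code path in well under a minute
  each while keeping all-pairs audits exact.

## Limitations

Only the *first* biotransformation step is addressed: neither downstream
enzymes nor metabolite structures are predicted. The EC assignment is
only as good as the substrate database backing the similarity search, and
the enzyme listing only as good as the alignment-derived EC annotations
(transferred annotations inherit reference-database errors). Fingerprint
bit definitions follow the Open Babel / ChemmineR implementations; models
and hybrid specs are therefore tied to these providers (recorded in every
model manifest) and are not transferable across fingerprint dialects.
Probabilities from random forests are not calibrated; thresholds on them
select operating points but are not error rates.
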