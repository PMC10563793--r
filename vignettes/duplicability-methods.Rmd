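---
title: "Methods: classifying and comparing WGD and SSD gene duplicates"
author: "duplicability package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and comparing WGD and SSD gene duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplicability)
```

## The problem

Vertebrate genomes carry two broad classes of retained gene duplicates:
ohnologs, preserved from the two rounds (2R) of whole-genome duplication at
the base of the vertebrates, and paralogs created by small-scale duplication
(SSD). The two classes have strikingly different evolutionary profiles —
ohnologs tend to be long, slowly evolving, dosage-sensitive, broadly and
highly expressed genes, while SSD paralogs are shorter, faster evolving and
narrowly expressed — and genes retained after WGD are rarely duplicated
successfully by SSD. Because 2R ohnologs are by definition ancient while SSD
events span the whole vertebrate lineage, duplicate *age* confounds nearly
every comparison between the classes. This package implements the full
analysis chain needed to study that problem on synthetic or user-supplied
tables: rule-based duplicate classification, feature engineering,
age-controlled group statistics, a random-forest importance protocol, and
enrichment-overlap analysis.

## Duplicate classification

Classification starts from three tables: a gene table (chromosome, integer
order index along the chromosome, intron count, optional macrosynteny
segment), a paralog-pair table with a duplication-node label per pair
(youngest common ancestor of the two copies), and macrosynteny segment
assignments descending from the 2R duplications.

**Ohnolog pair calling.** A paralog pair linking two distinct macrosynteny
segments is called an ohnolog pair when it belongs to a block of at least
`min_block = 3` linking pairs in which consecutive anchor genes on each
segment are separated by at most `max_gap = 8` intervening genes.
`call_ohnolog_pairs()` assembles blocks by iterated one-dimensional
splitting: within one segment pair, anchors are repeatedly split at gaps
larger than `max_gap` genes on either segment until stable. A stable cluster
satisfies the gap rule on both segments by construction, and no chain can
cross a hole in the anchor set larger than the hole's own gap, so cluster
membership is equivalent to membership in some valid chain. Two
consequences of this reading, both covered by tests: anchor order may be
inverted between segments (orientation is ignored), and enlarging `max_gap`
or shrinking `min_block` can only add called pairs. The implementation is
checked against an exhaustive enumeration oracle on hundreds of random small
instances.

**Retroduplication.** Pairs not called as ohnolog pairs are screened for
retroduplication before being accepted as SSD: a pair is flagged when one
member has zero introns and the other three or more, or when one member has
zero introns, the other fewer than three, *and* there is no conserved
microsynteny around the pair (`check_microsynteny()`: another paralogous
pair with members within `window = 5` genes of each tested gene). The
zero/zero intron case falls under the microsynteny clause, since the parent
gene may simply have been intronless. Intron gain is never inferred.

**Gene labels and consensus.** Pair labels follow the precedence
pre-vertebrate (node older than the `Vertebrata` root) > WGD > retro > SSD.
A gene is WGD if all its vertebrate-lineage pairs are WGD pairs, SSD if all
are SSD, a singleton if it has none (subtyped by whether it has
pre-vertebrate pairs), and excluded when it touches a retroduplicated pair
(which wins) or mixes WGD and SSD pairs. Per-gene labels are computed under
each of three ohnolog data sets and the consensus is majority rule; genes on
which all three data sets disagree are excluded as `NO_MAJORITY` — the rule
itself only defines the two-of-three case, so the full three-way split
needed a decision, and exclusion is the conservative one (configurable in
principle by post-processing the per-data-set labels, which are returned).

## Derived features

* **Tissue specificity.** `tissue_specificity()` computes
  $\tau = \sum_i (1 - x_i) / (N - 1)$ with $x_i$ the expression of condition
  $i$ scaled by the row maximum: 0 for uniform (housekeeping) expression, 1
  for single-condition expression. Developmental stages are treated as
  additional tissues. $\tau$ is computed on raw TPM with no floor, ceiling
  or log transform; an all-zero row is reported as missing, never imputed.
* **Duplicate age.** `assign_duplicate_age()` builds vertebrate gene
  families as connected components over vertebrate-lineage pairs and gives
  every member the age of the oldest duplication node in its family, in
  units of `age_unit = 50` MY. WGD genes take ages by the same rule as SSD
  genes, deliberately, so the two classes are measured identically.
  Singletons get a missing age by default (not 0) so they can never leak
  into age regressions.
* **GC3 and transcripts.** `gc3_content()` reports percent G+C at third
  codon positions (partial trailing codons dropped with a warning, `N`
  excluded from numerator and denominator); `select_longest_transcript()`
  applies the longest-transcript convention with a deterministic
  lexicographic tie-break.

## Group statistics

Direct comparisons between classes use two-tailed Mann–Whitney U tests with
Bonferroni correction; the correction family defaults to all tests performed
in the call since a single analysis run is the natural family. Completely
tied comparisons return p = 1 rather than failing.

For duplicates, `fit_feature_age_model()` fits OLS models
`feature ~ age + type`, choosing the response transformation from none, log
and Box–Cox by the Jarque–Bera statistic of the model residuals, and keeps
an `age x type` interaction iff it improves AIC by at least 2 units. Two
numerical decisions matter here:

* Normality is assessed on *residuals* (configurable to raw values): the
  model's error term is what the statistic is meant to police.
* Transformations are compared with a parsimony margin: a more complex
  transformation must beat every simpler one by more than `jb_preference =
  2` JB units. Under normality JB is approximately $\chi^2_2$, so
  differences of a unit or two are noise; without the margin, genuinely
  log-normal data would make the choice between log and a Box–Cox fit with
  $\hat\lambda \approx 0$ essentially arbitrary. The margin mirrors the
  conventional two-unit AIC evidence threshold. The Box–Cox $\lambda$ is
  profiled on a fine grid (step 0.01) over $[-2, 2]$.
* Features with non-positive values skip the log and Box–Cox candidates
  with a warning rather than being silently shifted.

`residualize_on_age()` regresses each feature on age over the combined
WGD + SSD set and returns residuals (numerically orthogonal to age, at the
`1e-10` level or better). The age-controlled classifier consumes
untransformed-feature residuals: the residualization model is `feature ~
age` as stated, and reusing the selected transformation is left as an
explicit opt-in by transforming before calling.

## The importance protocol

`run_protocol()` repeats, `n_iterations = 100` times by default: a fresh
simple random 80/20 train/test split (simple, not stratified — imbalance is
handled by balanced class weights instead), a random-forest fit
(39 trees by default, the tuned value; `tune_hyperparameters()` reproduces
the tuning step as a randomized search over tree count, mtry, depth, node
size and bootstrap with 10-fold cross-validated macro-F1 — macro because
neither class is a privileged "positive"), held-out accuracy, and held-out
permutation importance: the drop in test-set accuracy when one feature's
test values are permuted, one permutation round per feature per iteration
(the iteration loop supplies the averaging; rounds are configurable).
Importances are aggregated as means, SDs and mean ranks; accuracy gets a
normal-approximation 95% CI over the iteration accuracies; confusion counts
are summed and normalized per column (precision) and per row (recall). The
whole protocol is a deterministic function of one master seed, from which
per-iteration seeds are derived.

`run_age_controlled_protocol()` is the identical protocol on age-residualized
features. `dependence_matrix()` quantifies feature redundancy: each feature
in turn becomes the regression target of a forest built from the others, and
the held-out $R^2$ ("dependence") plus per-predictor permutation importances
are reported, clipped to [0, 1]. `isolation_analysis()` addresses the
importance-splitting artifact of correlated features: for each member of a
declared group (defaults in the analysis drivers: length-related features;
domain counts), the protocol is rerun with the *other* group members
dropped; the feature's new rank is the insertion position of its isolated
mean importance in the baseline ranked list. Two exactly collinear features
roughly double their importance in isolation while barely moving accuracy —
the signature of shared rather than unique information.

## Enrichment overlap

`term_enrichment()` tests each term for over/under-representation of a class
against the whole-gene universe with a two-sided hypergeometric test (the
doubled smaller tail, capped at 1 — one pass covers enrichment and
depletion), followed by Benjamini–Hochberg FDR across terms within the
class at threshold 0.05. This is an in-house flat-set test: no ontology
graph, no term propagation, and no service-specific multiple-testing scheme,
so absolute term lists from external tools are not expected to reproduce.
`overlap_summary()` reports, for each ordered class pair, the fraction of
the source class's significant terms that are significant in the target with
the same or opposite direction (denominator = source class, hence
asymmetric), plus UpSet-style exclusive intersection sizes. Whether a shared
"term" should respect direction is genuinely ambiguous, so both term-level
and term-direction-level intersections are emitted.

## The synthetic-data generator

`simulate_genome()` plants a genome in which every classification rule has a
recoverable ground truth: ohnolog families on paired segments as chains of
3–5 linking pairs with anchor gaps of 0–2 genes (comfortably inside the
8-gene rule), SSD families with duplication nodes strictly younger than the
vertebrate root, retroduplicated pairs as intronless copies of parents with
at least three introns (so the microsynteny clause is never needed to
recover them), pre-vertebrate pairs, decoy segments with no linking pairs,
and singletons. Non-retro genes always have at least one intron so no
planted pair can trip the intron rule by accident. Chromosome layout is
unit-shuffled so segment placement is random while segments stay contiguous.
`simulate_ohnolog_replicates()` derives the three ohnolog data sets; noise
drops true ohnolog pairs and adds planted SSD pairs independently at the
configured rate, perturbing only WGD membership because that is the only
axis on which real published ohnolog sets differ materially.

`simulate_feature_table()` draws features from per-class normal or
log-normal specs (location = base + class shift + age coupling x
standardized age), and an expression matrix whose breadth and level differ
by class. Defaults plant the direction structure described above: ohnologs
longer, more domain-rich, slower evolving, more constrained, more broadly
and highly expressed; SSD paralogs the opposite; singletons intermediate.
One feature, `age_only_score`, is a near-pure age proxy (coupling 5 noise
SDs, no class shift of its own): it exists to exercise the age-control
machinery, ranking at the top of the raw importance protocol purely through
the age–class association and dropping into the noise floor once features
are residualized on age. Effect sizes are chosen for test power, not
realism — no published effect sizes exist for these features at this
granularity.

What the generator does *not* emulate: nucleotide evolution (no real dN/dS,
GC or codon-adaptation signal; sequence-derived features arrive as
distributional columns), heavy-tailed and zero-inflated feature
distributions, gene-family size variation beyond two-gene families,
physically scaled coordinates (all rules operate on gene-count gaps, so
order indices suffice), ontology structure in annotations, and any
correlation structure between features beyond what age coupling induces.
Passing tests therefore demonstrate that the *rules and protocols* are
implemented correctly and behave as designed under controlled structure —
not that real genomes will show effects of the planted sizes.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the pipeline at deliberately
modest scale, chosen so the full suite completes in minutes while keeping
every statistical check well-powered: genomes of 240–720 genes (up to 100
planted ohnologs and 100 SSD genes), importance protocols of 20–50
iterations, 100-seed replication for selection/ranking properties, and
1000-draw nulls for calibration checks. The discrete hypergeometric null is
calibrated with moderately large counts (universe 4000, term size 600,
class size 1200) where the doubled-tail test's achieved level is close to
nominal; with small counts the test is conservative by discreteness, which
is a property of the test, not a bug in the implementation.

Degenerate inputs are handled explicitly throughout: empty pair tables
(everything becomes a singleton), all-zero expression rows (missing tau,
logged), completely tied rank tests (p = 1), constant age vectors
(error — nothing to residualize), infeasible simulation layouts (sizing
error naming the constraint), and missing feature values in the classifier
(error listing the offending genes rather than silent dropping).

## Known limitations

* Block assembly assumes the gap rule binds consecutive anchors on both
  segments; the alternative "any two pairs in the block" reading would be
  strictly stricter. The consecutive reading is the one under oracle test.
* The consensus rule treats the three input ohnolog sets symmetrically;
  real data sets differ in quality and a weighted vote might be preferable.
* Permutation importance uses the held-out set; out-of-bag importance would
  avoid the 20% data cost but would not match the repeated-split protocol.
* The Box–Cox candidate is profiled against the same model used for
  selection; no shift is applied for non-positive values, those candidates
  are simply skipped.
* Enrichment treats annotations as flat sets; term hierarchies would induce
  dependence between tests that BH only partially accommodates.
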