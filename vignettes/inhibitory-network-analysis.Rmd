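---
title: "Rate-limiting enzymes in metabolic inhibitory networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-limiting enzymes in metabolic inhibitory networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rleinhib)
library(dplyr)
```

## The model

A metabolic inhibitory network is a directed graph on enzymes (EC numbers).
An edge — an *inhibiting pair* — exists in an organism when two independent
annotations coincide there: the provider enzyme produces a compound, and that
compound is an in-vivo inhibitor of the target enzyme. `build_pairs()`
computes exactly this compound join, organism by organism; annotations are
never transferred between organisms, so organisms with sparser inhibitor
annotation simply yield fewer pairs. Pairs are identified by
(organism, provider, target, compound) and deduplicated; coverage statistics
then count *distinct entities* (compounds, ECs), never link multiplicity, so
a target reachable through five compounds still counts once.

Rate-limiting enzymes (RLEs) carry a global curated flag: an enzyme is
rate-limiting wherever it occurs. Three summaries quantify their role:

1. **Inhibitor production** (`inhibitor_production_stats()`): of the distinct
   in-vivo inhibitor compounds of an organism, the fraction produced by at
   least one RLE. The companion test (`production_enrichment()`) asks whether
   inhibitors are over-represented among RLE products relative to all product
   compounds of the organism.
2. **Coverage** (`coverage_report()`): distinct providers and RLE providers;
   distinct targets, targets reachable from an RLE provider, RLE targets, and
   RLE targets inhibited by an RLE — overall and per pathway category. An
   enzyme with several categories counts once in each; provider statistics
   use the provider's categories, target statistics the target's.
3. **Target enrichment** (`enrichment_rle_targets()`): are inhibited targets
   enriched in RLEs? Population = all enzymes of the organism in the dataset
   (per category when stratified), successes = RLEs among them, sample =
   distinct inhibited targets.

All over-representation tests are one-sided (upper-tail) hypergeometric
probabilities computed by `hypergeometric_tail()` through the log-space
CDF — exact and stable for populations well beyond any dataset here — and
reported raw, without multiple-testing correction: each test answers its own
stratum-level question and significance judgements are left to the reader.

Cross-pathway regulation isolates pairs whose provider and target belong to
different pathway categories. For multi-category enzymes "different" is
ambiguous; the default criterion is *disjoint* category sets, the
conservative reading, with `"not_identical"` available as the permissive
alternative. The 6×6 matrix (`cross_pathway_matrix()`) reports, per
(source, target) category cell, the distinct targets inhibited from the
source category and the fraction of them reachable from rate-limiting
providers.

Self-pairs (a compound inhibiting its own producer) do occur in curated
inhibitor data; they are retained and flagged, with a switch to exclude them.

## Phylogenetic profiles and pair similarity

Each enzyme receives a 0/1 profile over an ordered reference panel of 82
genomes (23 prokaryotes, 59 eukaryotes): 1 if at least one gene encodes the
enzyme in that genome. One profile per enzyme is shared across all analysis
organisms. Profile similarity of a pair is the Jaccard coefficient

$$J = \frac{M_{11}}{M_{01} + M_{10} + M_{11}},$$

where $M_{xy}$ counts panel positions with the first profile $x$ and second
$y$. Joint absences ($M_{00}$) never enter, so the score is invariant to
appending genomes where both enzymes are missing. When both profiles are
all-zero the score is undefined; such pairs are *excluded* from class means
(scoring them 0 would assert dissimilarity the data cannot support), and the
exclusion count is reported.

Pairs are collapsed to distinct (provider, target) before averaging, so a
pair mediated by many compounds is not over-weighted. Classes are nested, as
drawn in comparative summaries of this kind: *common* is all pairs,
*rle_provider* those with a rate-limiting provider, *rle_both* those whose
two members are both rate-limiting. Mean monotonicity across classes is a
data property, not an invariant — the package only asserts it for synthetic
data with planted coupling. Class comparisons use Welch's unequal-variance
t-test, one-sided by default because the hypotheses are directional (higher
similarity); groups with fewer than two defined scores, or exactly constant
data, give an `NA` result with a warning.

## Conservation and compound initiation

A pair is *conservative* when it occurs in at least `min_organisms`
(default 3) of the analysed organisms. Pair identity is (provider, target):
the mediating compounds are carried as an attribute and unioned across
organisms, with a `per_compound` mode for the stricter identity. A pair is
"initiated by" a compound when that compound mediates it in at least one
organism (configurable to "in all"). `compound_preference_test()` compares
the rate-limiting share of two compounds' pair sets with the same
hypergeometric tail as every other test; ADP (C00008) and AMP (C00020) are
the default comparison, as configuration values rather than constants.

## The synthetic-data generator

`simulate_dataset()` draws complete datasets with planted structure so that
every statistic above has a ground truth:

- a global pool of `n_enzymes` (default 300) EC-like identifiers, a fraction
  `rle_fraction` (0.2) flagged rate-limiting, one or two of the six pathway
  categories each;
- five organisms (hsa, mmu, rno, sce, eco); each enzyme has a home organism
  and recurs elsewhere with probability `p_shared_across_organisms` (0.7),
  which also governs per-organism recurrence of product and inhibition
  links — this plants cross-organism conservation;
- products: truncated-Poisson counts (mean `products_per_enzyme` = 2) over a
  pool of `n_compounds` (600) compounds. Truncation at one keeps the tables
  free of empty records; Poisson is a simplicity choice, not a claim about
  real annotation degree distributions;
- a produced compound becomes an in-vivo inhibitor with probability
  `p_inhibitor_base` (0.15), multiplied by `inhibitor_boost` (default 3)
  when some RLE produces it — planting production enrichment. Targets are
  drawn with RLEs up-weighted by `rle_target_boost` (2) — planting target
  enrichment. Annotations are in-vivo with probability `p_in_vivo` (0.9),
  exercising the in-vivo filter;
- presence profiles start as independent Bernoulli(`p_presence_base` = 0.4)
  draws over the 82-genome panel. Each inhibited target is then coupled to
  one provider (the strongest available class): each position is copied from
  the provider's background profile with probability `rho_pair` (0.3) for
  RLE-provider pairs and `min(1, 1.5 rho_pair)` for both-RLE pairs — planting
  the class ordering of mean similarity. Copying is directional, but the
  Jaccard score is symmetric so the direction is immaterial; reading the
  *background* profile makes the construction order-independent, at the cost
  that chained couplings (a provider that is itself a coupled target) are
  exact copies only of the background, not of the final profile.

With `inhibitor_boost = 1`, `rle_target_boost = 1`, `rho_pair = 0` the model
is null: rate-limiting and common enzymes are exchangeable, and the target
set of an organism is, conditional on its size, a uniform draw from the
organism's enzymes — so the hypergeometric test is exactly calibrated, which
the test suite checks over 200 replicates against the exact binomial 99%
band around the nominal 0.05 level.

One seed drives a single pseudo-random stream; identical configurations give
byte-identical output files. What the generator does *not* emulate: real EC
semantics, KEGG pathway topology, phylogenetic tree structure among the
panel genomes, and annotation biases of curated databases. Passing tests on
synthetic data therefore validate the *pipeline arithmetic and its
statistical calibration*, not claims about any particular real snapshot of
the source databases; real-data headline percentages depend on the database
versions used to build the input tables.

## Numerical conventions and problem sizes

- Fractions with zero denominators are `NA`, never 0.
- Integer percentages round half away from zero (`12.5% → 13%`), matching
  the usual presentation of headline percentages.
- Validation is total: integrity checking enumerates every violating link
  rather than stopping at the first.
- Duplicate enzyme rows merge by union with an OR-combined flag; duplicate
  link rows are dropped, both logged.
- List-valued fields are kept sorted so that write/read round-trips are
  byte-exact; the full pipeline is deterministic given its inputs.
- Test and simulation sizes were chosen as the smallest that make the
  planted effects and the null calibration statistically unambiguous:
  300-enzyme pools for calibration (200 replicates), 500 for the
  production-power check (100 replicates), 120–150 for structural property
  sweeps.

## Known limitations

- The genome panel identities are user-supplied placeholders; analyses that
  depend on *which* genomes are in the panel (e.g. kingdom-restricted
  profiles) are out of scope.
- Partial EC numbers are treated as opaque identifiers and only flagged.
- No kinetic, flux-balance or topological (centrality) modelling: the
  network is analysed purely through set counts and the statistics above.
- Inhibitor potency is not modelled; an inhibition annotation is binary.
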