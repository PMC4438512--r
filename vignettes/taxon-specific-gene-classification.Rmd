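---
title: "Taxonomic classification from taxon-specific orthologous groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomic classification from taxon-specific orthologous groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxnog)
library(dplyr)
```

## The idea

Most gene-content approaches to bacterial taxonomy compare genomes by the
genes they *share*.  taxnog does the converse: it classifies a genome by
the genes that are *not shared* — orthologous groups (NOGs) present in
one taxon and absent from every other taxon at the same taxonomic rank.
A newly sequenced genome is then placed by walking down the hierarchy,
at each rank picking the taxon whose rank-specific gene set it matches
best.

The unit of comparison is the NOG identifier: every protein-coding gene
in a genome is mapped to an orthologous group (by best-hit transfer from
a members catalog), each NOG is counted at most once per genome, and a
genome becomes a finite set of NOG ids.  All downstream computation is
set algebra over these identifiers.

## Database construction

For each of the six ranks (phylum, class, order, family, genus,
species), the NOG sets of all member genomes of a taxon are unioned into
the *taxon-total* set.  The *taxon-specific* set is the total set minus
the union of every other taxon's total set at the same rank — a global
subtraction, not one restricted to sibling taxa.  Three invariants
follow and are checked on every build (`check_db()`):

* specific sets of distinct taxa at one rank are pairwise disjoint;
* each specific set is contained in the taxon's total set;
* a NOG specific to a class is necessarily specific to that class's
  phylum, and so on down the hierarchy (parent nesting).

Two data-hygiene rules precede the build.  Reference genomes with fewer
than 475 genes are excluded — 475 being the smallest gene repertoire
known for a bacterium (*Mycoplasma genitalium*); the boundary is
inclusive.  Lineages must be gap-free: once a rank is unknown, all
deeper ranks must be unknown, and a genome's phylum must be known.

**Partially classified genomes.** A reference genome known only to,
say, order still contributes its NOGs to totals at phylum–order.  At
deeper ranks it cannot be placed in any taxon, which creates a subtle
hazard: if such a genome were simply skipped, a NOG it carries could be
claimed as genus-specific by a taxon in a different phylum, breaking
parent nesting.  We therefore let unknown-rank genomes participate in
the subtraction at the ranks they are missing from, as an anonymous
competitor that can own nothing: no taxon may claim a NOG observed in a
genome whose membership at that rank is unverifiable.  When all lineages
are complete — the ordinary case for curated references — this rule
coincides exactly with the plain per-rank set difference.

Taxon identity is always the full lineage prefix (`"Firmicutes|Bacilli"`),
never the bare name, so homonymous taxon names under different parents
remain distinct.

## Classification

Given a query NOG set, the classifier scores every phylum by
`|query ∩ specific(phylum)|` and selects the maximum.  Within the chosen
phylum it scores the classes the same way, and so on down to species.
Descent stops at the first rank where fewer than `min_matches`
(default 1) specific NOGs match; that rank and everything below it is
reported `UNCLASSIFIED` — classification is only ever as deep as the
evidence.

**The ≥30% deferral rule.** When the runner-up taxon's match count is at
least 30% of the best taxon's (`tie_threshold`, a ratio of counts), the
decision is considered ambiguous and deferred: the children of *both*
candidates are scored at the next rank, and the winning child elects its
own parent.  If the children provide no evidence, the raw maximum
stands.  By default the rule is active from phylum through genus
(`tie_ranks`); species has no child rank and always resolves by maximum
count.  A `tie_ranks = c("phylum", "class")` setting restricts the rule
to the two ranks where close calls are most consequential.  Look-ahead
is stepwise with depth 1 by default; deeper recursion is supported
(`lookahead_depth`) but a chain starting at phylum or class is capped at
the order rank, past which a single best match is trusted.

Exact count ties are broken lexicographically by taxon key and flagged
with a warning — they are rare and usually indicate insufficient
evidence rather than a meaningful choice.

Species-rank output deserves a caveat: it names the *closest known
species* by gene content.  The method's reliable range is phylum through
genus; treat species assignments as advisory.

## Functional analysis

Each NOG may carry one or more of the 23 single-letter COG functional
categories.  `category_profile()` distributes a NOG with *k* letters
fractionally (1/*k* to each), so proportions over categorized NOGs sum
to one; a `mode = "each"` variant gives every letter a full count for
sensitivity analysis, since annotation conventions differ on this point.
NOGs without category information are tallied but excluded from
proportions.

Overabundance of a category in a taxon's specific set is the ratio of
its proportion there to its proportion in the taxon's total set;
`flag_abundant()` counts taxa exceeding a strict 1.2× threshold.
Significance is assessed by an exact two-sided hypergeometric test
(`enrichment_test()`): the specific set is modelled as a draw without
replacement from the total set, and the p-value sums the probabilities
of all outcomes no more likely than the observed count.  Whole-NOG
membership counts (not fractional weights) feed the test, because the
hypergeometric model requires integers.

## The synthetic benchmark

Real reference builds need genome-scale downloads, so the package ships
a generator (`simulate_taxonomy()`) that reproduces the statistical
structure the method assumes rather than any particular dataset: a
taxonomy tree in which every node owns a disjoint pool of node-specific
NOGs, a universal core pool shared by all genomes (the core-genome
analogue), and per-genome sampling.  A genome is the union of a sampled
fraction of each of its six ancestor pools, the core, and an
`noise_rate` fraction of NOGs drawn uniformly from *other* lineages'
pools — deliberately the adversarial contamination for a unique-set
method, since every noise NOG both pollutes a foreign specific set
during the build and fakes foreign evidence in a query.

Defaults, chosen once as this package's study conditions: a
4 × 3 × 2 × 2 × 2 × 2 tree (192 species), 3 genomes per species
(576 genomes), 20 specific NOGs per node, a 200-NOG core, full pool
coverage (`sample_frac = 1`), no noise.  The nominal
`genes_per_genome = 2000` places synthetic genomes comfortably above
the 475-gene filter while acknowledging that gene-to-NOG multiplicity
is not modelled.  Pool NOGs draw their COG letters with the "S"
(function unknown) category upweighted 1.5× relative to core NOGs,
planting the qualitative enrichment of unannotated genes in
taxon-specific sets that real annotations show, so the functional stage
is testable end to end.

What the generator does *not* emulate — and therefore what passing
benchmarks cannot show — includes: sequence-level evolution and
annotation error (NOG ids are sampled, not inferred from alignments);
realistic genome sizes and gene-family multiplicity; horizontal gene
transfer structured by ecology rather than uniform noise; and the
heavily skewed taxon sampling of real reference collections.  Accuracy
of 100% on the noise-free self-test is a *consistency* check of the
pipeline, not a claim about real genomes.

Two test protocols mirror common practice: the *self-test* (classify
every training genome against the database built from all of them) and
the *hold-out* (rebuild the database without a random 10% of genomes,
then classify those genomes after degradation — 5% cross-lineage noise
and loss of 20% of their lineage-specific NOGs).  `run_pipeline()`
chains either protocol in one call; `scripts/acceptance.R` in the
source repository re-runs both from scratch and writes the measured
accuracies as JSON.

```{r}
out <- run_pipeline(sim_config(children = c(3, 2, 2, 1, 1, 1),
                               genomes_per_species = 2, seed = 11))
out$accuracy
```

## Numerical and degenerate-input choices

* Best-hit selection over alignment tables is a pure function of the hit
  multiset: maximal bit score, ties by lower e-value, then
  lexicographically smallest subject id.  An optional e-value ceiling
  (default `1e-5`) is applied first; the reference analyses this method
  descends from did not publish their alignment thresholds, so the knob
  is explicit and configurable.
* All artifacts serialize deterministically (sorted rows, fixed column
  order); permuting input row or genome order never changes a byte of
  output.  Database metadata deliberately records no wall-clock
  timestamp for the same reason.
* An empty query NOG set classifies as `UNCLASSIFIED` at every rank,
  with a warning.  An empty reference after filtering is an error.
* Degenerate enrichment tables (empty sets, a category absent from or
  filling the total set) return p = 1.
* The simulator, query generator and hold-out splits consume explicit
  integer seeds; identical seeds give byte-identical results.

## Problem sizes

The shipped test suite and the acceptance script run entirely on
synthetic data at the default 576-genome scale (and smaller), with the
database-oracle comparison covering 100 random taxonomies of up to 50
genomes and 200 NOGs each.  These sizes exercise every code path —
including the deferral branch, partial lineages and noisy references —
while keeping a full run in the low minutes on a single core; the
algorithms are plain set operations and scale linearly in total
(genome, NOG) pairs per rank.

## Known limitations

* The method inherits its reference taxonomy's quality: mislabelled or
  chimeric reference lineages translate directly into wrong specific
  sets.  Only structural validity (gap-freeness, known phylum) is
  checked.
* A query from a taxon absent from the reference cannot be rejected as
  novel with confidence; it will match its nearest relative's specific
  set weakly or be `UNCLASSIFIED`.  No probabilistic confidence model is
  provided.
* Classification is genome-level; read-level metagenomic profiling is
  out of scope.
* Species-rank assignments are advisory (closest known species), as
  discussed above.
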