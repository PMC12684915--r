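---
title: "Analysing the mating system of free-ranging dog genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the mating system of free-ranging dog genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matesys)
```

## The scientific problem

Free-ranging dogs (FRDs) are unowned domestic dogs that move and breed
freely while depending on human-derived food. Unlike their prevailingly
monogamous wild relatives, FRD populations are typically polygamous in
both sexes. Characterising that mating system quantitatively requires a
reconstructed genealogy (who are the mother and father of whom, which
pups form litters, who lives in which social group and location) plus,
ideally, SNP genotypes and behavioural proximity observations.

`matesys` provides the full analysis chain for such data:

1. **Pedigree structure** — exact kinship, relationship-type
   classification up to the fourth degree, genealogical distance.
2. **Null models** — forward simulation of randomly mating populations,
   with and without litter structure, to ask which observed features
   (full-sibling counts, half-sibling asymmetries, repeated pairs,
   reproductive skew, close inbreeding) random mating can already
   explain.
3. **Genotype-based kinship** — method-of-moments IBD (PI-HAT) and
   KING-robust kinship, validated by Mendelian gene dropping.
4. **Mating-system statistics** — offspring/partner counts, sibling
   structure, multiple paternity, repeated parental pairs, close
   inbreeding, Crow's opportunity for selection and the Morisita skew
   index, kin structure of social groups, and dispersal signatures.
5. **Social networks** — weighted proximity graphs, five individual
   measures, greedy-modularity communities, group assignment.
6. **Observed-vs-null comparison** — replicate ensembles, empirical
   quantiles, and a permutation envelope for partner-count ECDFs.

## The pedigree model

A `pedigree()` is a table of individuals with sex, age class, litter,
social-group and location attributes, linked by mother/father edges that
must form a directed acyclic graph. Kinship is computed by the tabular
method: processing individuals parents-first,

$$f(i,j) = \tfrac12\big(f(m_i,j) + f(p_i,j)\big), \qquad
  f(i,i) = \tfrac12\big(1 + f(m_i,p_i)\big),$$

with missing parents treated as unique unrelated founders. For a
non-inbred pair the expected genome-wide IBD proportion (PI-HAT) is
$2f$. Relationship types are pattern-matched on the pedigree up to
great-grandparent depth: parent–offspring and full siblings (degree 1);
half siblings, grandparent–grandchild, avuncular (degree 2);
half-avuncular, full first cousins, great-grandparents (degree 3); half
first cousins (degree 4). When several types co-occur — common in
inbred families — the numerically lowest degree wins, with priority
parent-offspring > full-sibling and half-sibling >
grandparent-grandchild > avuncular within a degree. That convention
keeps, for example, a father–daughter mating classified as degree-1
even when the pair is also linked through weaker paths.

Genealogical distance is the shortest path in the undirected graph of
parent–offspring links. Sibling links are deliberately *not* edges
(full siblings are two steps apart through a shared parent): parent
edges are the only unambiguous unit of "steps connecting two
individuals", whereas treating sibships as single steps would make the
metric depend on which siblings happen to be sampled. This is a
genuinely open convention and the package fixes it explicitly.

## The null simulator and its design choices

`simulate_pedigree()` produces discrete cohorts under two null mating
scenarios, both starting from a founder cohort and adding
`n_generations - 1` rounds of `target_pop_size` offspring.

**Concurrent generations.** Every mating round draws its parents from
*all* previously created individuals, not just the immediately
preceding cohort. Two observations force this choice. First, the
repeated-parental-pair statistic (the same mother–father pair producing
litters in different rounds) is structurally zero under strictly
non-overlapping generations with one litter per female per round, yet
it is one of the statistics the null comparison must supply. Second,
with non-overlapping generations, maternal half-siblings can arise only
inside multi-father litters while paternal half-siblings also accrue
across litters, so the two could never occur at similar frequencies —
but that parity is precisely the behaviour a random-mating null must
show (males are only limited by the number of available females).
Concurrent cohorts restore both properties and match how real
multi-year genealogies accumulate.

**The two scenarios.**

* `random` (fully promiscuous): each pup independently draws a uniform
  mother (subject to the female physiological capacity, the litter cap
  times the maximum litter size per round) and a uniform father (no cap
  at all). A female's offspring within a round form her litter. Full
  siblings require the same pair to be drawn twice, so their expected
  count collapses toward zero as the male pool grows.
* `random_litter`: breeding females are drawn (at most
  `female_max_litters_per_gen` litters per round each) until the round's
  quota is met; litter sizes come from `litter_size_dist`
  (truncated-Poisson(5) on 1–10 by default) and each litter draws its
  number of fathers from `fathers_per_litter_dist`
  ({1: 0.7, 2: 0.2, 3: 0.1} by default), partitioning pups uniformly
  among that father set. Full siblings are then common (~3 per
  individual at the default sizes).

The litter-size and fathers-per-litter defaults are field-plausible
placeholders — roughly dog-like litters and a ~30% multiple-paternity
rate — and every entry is configurable. One known sensitivity deserves
emphasis: with the default cap of **one** litter per female per round,
a female's litter count across rounds is a sum of Bernoulli draws with
fairly large per-round probability, which under-disperses maternal
clustering relative to the Poisson-like paternal clustering. At the
package's reference sizes (200 founders, 200 offspring/round, 4
cohorts) the maternal/paternal half-sibling ratio under `random_litter`
settles ~13–18% apart rather than within 10%; raising the cap to two
litters per round restores parity to within ~7–10%. The cap default is
kept at one because it is the stated baseline constraint, and the
discrepancy is reported rather than hidden — it is a property of this
particular female-constraint choice, not of the engine.

**Structured generator.** `simulate_structured_population()` is the
package's synthetic stand-in for a real study population. On top of the
litter machinery it adds: persistent male mating weights
(log-normal with σ = `male_skew`; 0 = uniform, so the generator
degenerates exactly to `random_litter`), partner reuse with probability
`pair_fidelity`, social groups with offspring retained in the mother's
group with probability `philopatry`, maternally inherited locations and
between-location movement at `migration_rate` whose sex composition is
`female_dispersal_bias` (1 = all migrants female). It deliberately does
*not* model overlapping mortality schedules, age-structured fecundity,
spatially explicit movement or genotyping error; conclusions from
passing tests therefore concern the statistical machinery, not those
aspects of real data.

**Randomness.** One master seed; every stage derives an independent
substream via `substream_seed(seed, replicate, stage)`, so single
replicates are reproducible in isolation and byte-identical on rerun.

## Genotype-based kinship

`drop_genotypes()` implements gene dropping: founders draw two alleles
per locus from Hardy–Weinberg proportions at configurable frequencies;
descendants inherit one uniformly chosen allele from each parent,
independently per locus. Loci are unlinked by design — the estimators
validated against the drop are single-locus method-of-moments
quantities whose expectations do not involve linkage, so a
recombination map would add cost without changing any tested
expectation. This is a documented limitation: linkage-aware methods
(e.g. segment-based IBD) cannot be validated with this generator.

`mom_ibd()` re-implements the classic PLINK-style estimator: per pair,
observed IBS-state counts over pairwise-complete loci are combined with
frequency-based expected IBS-given-IBD proportions, solving Z0 from
IBS0, Z1 from IBS1, then Z2 = 1 − Z0 − Z1, clipping negatives and
renormalising; PI-HAT = Z2 + Z1/2. Allele frequencies are estimated
once from the full sample, relatives included; the resulting bias is
small at realistic cohort sizes and is *measured* by the gene-drop
recovery tests (parent–offspring mean PI-HAT lands within ±0.03 of
0.5). Loci with minor-allele frequency < 0.01 are excluded and pairs
with < 100 informative loci are reported as missing; both thresholds
are conventional defaults and configurable.

`king_robust()` computes the between-family KING estimator
$\varphi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N^{(i)}_{Aa} + N^{(j)}_{Aa})$,
which requires no allele frequencies and tolerates population
structure. `classify_degree()` bins kinship at powers of two
($2^{-(d+3/2)}, 2^{-(d+1/2)}]$ for degree $d$; below $2^{-5.5}\approx
0.0221$ a pair is called unrelated; PI-HAT inputs are halved first.

## Mating-system statistics

All statistics count relationships among *sampled* individuals only, so
simulated genotyping subsamples behave like real ones. Conventions
worth noting:

* **Crow's index** $I = \mathrm{var}(x)/\bar x^2$ uses the
  sample-variance ($n-1$) convention (the source definition does not
  specify one).
* **Morisita skew** $I_\delta = n \sum x_i(x_i-1) / (X(X-1))$ is 0 for
  even allocation and $n$ under complete monopolisation.
* **Close-inbreeding rate** uses, as its "detected mating" denominator,
  distinct (mother, father, litter) triples when litter ids exist and
  distinct parent pairs otherwise; the unit is configurable because the
  field convention is not fixed.
* **Multiple paternity** counts only litters with at least two sampled
  offspring in the denominator.
* Offspring are counted regardless of age class; the reduced offspring
  number (one pup per litter per parent pair) doubles as a
  successful-mating count.
* **Group kin structure** summarises groups with at least three sampled
  members; a member is "unrelated" when no within-group partner is of
  degree ≤ 3 (fourth degree and beyond count as unrelated, matching the
  practice of pooling uncertain distant-kin calls with unrelated ones).

## Social networks

Proximity counts aggregate into an undirected weighted graph.
Decisions the verbal definitions leave open, fixed here: betweenness
uses edge length 1/weight (stronger ties are shorter), endpoints
excluded, unnormalised; eigenvector centrality is the standard weighted
principal eigenvector computed per connected component and scaled to a
maximum of 1 (the verbal "sum of strengths of direct or indirect
contacts" does not correspond to a standard formula; the standard
centrality is used and the discrepancy documented rather than guessed
around); community detection is greedy modularity maximisation with
ties between equal-modularity dendrogram cuts broken toward the
coarsest partition, making a single connected edge one community.
Multi-season group assignment matches per-season communities into
consensus clusters by greedy Jaccard overlap, then assigns each
individual to the cluster receiving its largest summed interaction
weight, leaving exact ties unassigned.

## Null comparison

`run_ensemble()` simulates R replicates, optionally subsamples each to
the genotyped cohort size, and collects per-replicate statistics.
Observed values are placed with
`q = (\#\{sim < obs\} + 0.5\,\#\{sim = obs\} + 1)/(R+1)`, midranking
ties and clamping to $[1/(R+1), R/(R+1)]$ so no observation sits at an
exact 0 or 1 (the envelope flag uses the unclamped value so extremes
register even at small R). `permutation_ecdf()` compares partner-count
ECDFs between the sexes against a pointwise 2.5/97.5% envelope from
label permutations; the envelope is pointwise, not simultaneous, which
is conservative in the sense that any-exit flags fire in well under 10%
of null datasets at the sizes used (the calibration test measures
~6%), but it is not a formal level-α test.

## Problem sizes used in the checks

The packaged checks run at deliberately scaled sizes chosen to keep the
full suite fast while leaving Monte-Carlo error far below every
asserted tolerance: null ensembles use 200 replicates of a
200-founder/200-offspring, four-cohort population (the study-scale
setting uses 1,000 replicates — `n_replicates` is a config field);
estimator recovery uses 5,000 unlinked loci over a 130-individual
validation pedigree; skew recovery uses 50 trials per arm against the
200-replicate null; permutation calibration uses 100 runs of 300
permutations on 60 individuals. Oracle-equivalence checks run 1,000
random instances per statistic against independent brute-force
implementations (recursive-definition kinship, common-ancestor
enumeration, matrix eigendecomposition, Floyd–Warshall betweenness,
sorted-rank quantiles).

## Known limitations

* The female reproductive constraint is a single per-round litter cap;
  the half-sibling parity sensitivity above is its direct consequence.
* No mortality, age structure, or overlapping litter seasonality; the
  generation index is a coarse stand-in for birth cohorts.
* Gene dropping has no linkage, no genotyping error and no sex
  chromosomes.
* The permutation envelope is pointwise; simultaneous envelopes would
  need a sup-statistic calibration.
* GLM fitting, rank tests and chi-square tests on the exported tables
  are intentionally out of scope — the package produces their inputs.
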