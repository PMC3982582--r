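---
title: "Mining tissue-phenotype associations from gene annotation corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining tissue-phenotype associations from gene annotation corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotissue)
```

## The problem

Mutant phenotypes often manifest in the tissue where the disrupted gene is
expressed — but not always: obesity phenotypes, for instance, trace back to
genes expressed in the hypothalamus. Given (i) binary gene × tissue
expression calls from reporter staining and expression-barcode resources and
(ii) per-gene phenotype annotations from mouse knockout databases,
`phenotissue` asks, for every (tissue, phenotype) pair, whether genes
annotated with the phenotype are over-represented among genes expressed in
the tissue. The significant pairs form a tissue–phenotype association map
that can be browsed per phenotype and used to re-rank disease-gene
candidate lists by expression.

## The corpus model

Everything is counted over an **annotation corpus**: a universe of genes,
each carrying a set of panel tissues (tissues with a `present` call in any
source) and a set of phenotype identifiers. Merge semantics are a union of
`present` calls — a `present` in one source beats an `absent` in another —
because only `present` calls are ever counted; `absent`, `ambiguous` and
`no_data` are discarded at read time. Phenotype annotations are *not*
propagated up the phenotype ontology: annotations are accumulated at the
gene level exactly as provided. The tissue panel is caller-supplied, so
exclusions (e.g. gender-specific or hard-to-stain tissues) are expressed by
supplying a reduced panel rather than hard-coded.

## Scoring

### Hypergeometric upper tail

For a tissue annotating $T$ of the $PT$ corpus genes, a phenotype
annotating $P$, and $O_{tp}$ genes carrying both,

$$p_{tp} \;=\; \Pr(X \ge O_{tp}) \;=\;
  \sum_{k=O_{tp}}^{\min(T,P)}
  \frac{\binom{P}{k}\binom{PT-P}{T-k}}{\binom{PT}{T}},$$

the chance of at least the observed co-annotation when $T$ genes are drawn
without replacement. This equals a one-sided Fisher exact test (alternative
"greater") on the pair's 2×2 table. The sum is evaluated in log space via
`lchoose` so it stays finite at corpus sizes of ~10⁴ genes, and the result
is clamped into $(0, 1]$; at the lower support bound the value is exactly 1.

Two filters follow the method's design: phenotypes annotating fewer than
`min_phenotype_count = 10` genes are skipped entirely (small margins
distort the hypergeometric view), and pairs are reported iff
$p \le$ `p_cutoff` $= 0.005$. Both comparisons are **inclusive**, matching
the "at least" phrasing of the count filter. No multiple-testing correction
is applied by default — the cutoff is a raw p-value chosen by inspection in
the original design; `adjust = "BH"` exists but is off because enabling it
silently would change the method.

### Association rules

Genes are transactions; items are tag-prefixed tissues and phenotypes.
Rules are restricted to one tissue item and one phenotype item (the level-
wise apriori pruning is still applied, so behaviour matches the classical
algorithm on this restriction). Defaults: absolute support ≥ 6 co-occurring
genes and confidence ≥ 0.9, both inclusive. Both rule directions are formed;
the default report keeps the max-confidence direction per pair (ties prefer
the tissue antecedent), `both_directions = TRUE` keeps both. The rule
p-value is defined as the same hypergeometric upper tail of the pair's
2×2 table, so the two methods are commensurable and testable against one
oracle; it is identical for both directions.

## Ontology reasoning and evaluation

The anatomy vocabulary is a DAG over `is_a` and `part_of` edges only; other
OBO relationship types are skipped with a count. Both relations propagate
ancestors and **interleave freely** along paths — the alternative
(relation-homogeneous paths) would be a stricter reading, but an OWL
reasoner configured with part_of transitivity propagates mixed chains, and
the evaluation phrase "subclass or part_of (including transitivity)" treats
the relations jointly. Cyclic input is a hard error (the classification
logic assumes a partial order), and the offending cycle is reported.

Predictions are evaluated against EQ statements (phenotype → affected
anatomical entity; quality components are ignored). A phenotype's EQ is
*representable* iff some entity is identical to, below, or above a panel
tissue, transitively. Each predicted association is classified with
priority `exact` > `psp` (predicted tissue below the gold entity) > `ldsp`
(gold entity below the predicted tissue) > `no_match`; phenotypes without a
representable EQ yield `no_eq`. With multi-entity EQ statements a match
against *any* entity suffices at the stated priority. Summary percentages
use only phenotypes/associations **with** a representable EQ as
denominator; `no_eq` rows are reported separately, and percentages are NA
when the denominator is zero. A `no_match` is not necessarily wrong — it is
exactly the "spatially separated expression and manifestation" signal the
association map is meant to surface.

## Candidate re-ranking

`tissues_for_phenotypes()` unions the tissues associated with a query
phenotype set; `rerank()` keeps, among the first `top_n = 200` candidates,
those expressed in **any** associated tissue (`require_all = TRUE` gives
the conjunctive variant; with an empty tissue set the conjunction is
vacuously true, documented on the function). Filtering is stable — original
order and scores are preserved, ranks renumbered — and genes absent from
the corpus count as not expressed.

## The synthetic world

`generate_bundle()` emulates the *shape* of the real inputs, not their
biology:

* ~21 adult panel tissues; per-gene tissue membership is Bernoulli at
  `tissue_call_rate = 0.3` (~6 tissues/gene, a plausible breadth for
  binarized adult expression);
* phenotype membership at base rate `mean_phenotypes_per_gene /
  n_phenotypes` with the default density 13.4, the published corpus
  average; for a planted pair $(t, p, \text{odds})$ the per-gene log-odds
  of $p$ is shifted by $\log(\text{odds})$ when the gene truly expresses
  $t$ — membership is otherwise independent, so non-planted pairs are null;
* two overlapping sources each observing a true call with probability 0.8
  (union ≈ 96%), plus a 5% sprinkle of explicit absent/ambiguous/no_data
  calls, exercising the present-wins collapse and union merge;
* a foreign→canonical gene map missing 5% of genes (mapping losses);
* a small anatomy DAG where each panel tissue has an `is_a` parent group
  and a `part_of` child, so exact/psp/ldsp all occur; EQ statements cover
  60% of phenotypes, point at the planted tissue or a neighbour for 80% of
  planted phenotypes, elsewhere at off-target or unrepresentable anatomy,
  and 10% of EQ rows get an unmappable foreign id;
* a single master seed with fixed per-component substream offsets, so a
  seed reproduces the bundle byte-identically and changing one component's
  draws does not perturb the others.

What a green planted-recovery test establishes: the scoring path detects
odds-8 co-annotation signal at corpus scale with nominal false-positive
size. What it does **not** establish: robustness to correlated tissues,
annotation bias, hierarchical phenotype redundancy, or batch structure —
none of which the generator models.

## Numerical and degenerate-input choices

* Tail sums in log space with a max-shift before `exp`; clamped to
  $(0,1]$; exact 1 at the support floor.
* All threshold comparisons inclusive; ties in the rule-direction dedup
  prefer the tissue antecedent, deterministically.
* Empty corpora are rejected for counting ($PT \ge 1$); empty tissue
  panels are rejected; empty transactions are retained (they contribute to
  the universe but support nothing).
* Duplicate expression rows collapse with precedence `present` > `absent`
  > `ambiguous` > `no_data`; only the first matters downstream.
* `ontology_graph` precomputes the full ancestor closure at construction
  (Kahn order), making `relate()` O(1); fine for the vocabulary sizes in
  scope (10²–10⁴ terms).

## Known limitations

* No OWL reasoning beyond the is_a/part_of closure; no ontology-aware
  annotation propagation (deliberately, see above).
* Rules are single-antecedent/single-consequent; no lift/leverage metrics.
* The per-phenotype browse export is a flat-file rendering; there is no
  service component.
* Real-data headline counts from the motivating study are not reproducible
  here (their input snapshots are not redistributable), so the test suite
  validates properties, oracles and planted-signal recovery instead.
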