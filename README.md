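# phenotissue

Tissue–phenotype association mining from gene annotation corpora.

Mouse knockout databases annotate genes with phenotype ontology concepts;
reporter-staining and expression-barcode resources annotate the same genes
with binary per-tissue expression calls. `phenotissue` joins the two into a
single annotation corpus and asks, for every (tissue, phenotype) pair,
whether genes carrying the phenotype are over-represented among genes
expressed in the tissue. It is aimed at computational biologists who want
an association map between an anatomy vocabulary and a phenotype
vocabulary, and at anyone re-ranking disease-gene candidate lists by
expression context.

## Methods at a glance

* **Hypergeometric enrichment** — for a tissue annotating *T* of *PT*
  corpus genes, a phenotype annotating *P*, and *O*<sub>tp</sub> genes
  carrying both, the score is the upper tail
  *p* = P(X ≥ *O*<sub>tp</sub>) of a hypergeometric distribution
  (equivalently a one-sided Fisher exact test on the 2×2 table), computed
  in log space. Phenotypes with fewer than 10 annotated genes are skipped;
  pairs with *p* ≤ 0.005 are reported (`score_corpus()`).
* **Association rules** — apriori-style mining with genes as transactions:
  tissue↔phenotype rules with absolute support ≥ 6 and confidence ≥ 0.9,
  p-values from the same hypergeometric tail (`mine_rules()`).
* **EQ evaluation** — predictions are classified against entity–quality
  phenotype decompositions via transitive is_a/part_of reasoning as
  `exact`, `psp` (predicted tissue below the gold entity), `ldsp` (gold
  entity below the predicted tissue), `no_match` or `no_eq`
  (`classify_associations()`, `summarize_evaluation()`).
* **Candidate re-ranking** — restrict a pre-ranked candidate list to genes
  expressed in phenotype-associated tissues, preserving order
  (`tissues_for_phenotypes()`, `rerank()`).
* **Synthetic data** — seed-reproducible input bundles with planted
  enrichments of configurable odds so every stage is testable offline
  (`simulation_config()`, `generate_bundle()`).

## Worked example

```r
library(phenotissue)

cfg <- simulation_config(
  n_genes = 2000, n_phenotypes = 60, tissue_panel_size = 21,
  mean_phenotypes_per_gene = 13.4,
  planted = plant_pairs(25, 21, 60, odds = 8, seed = 1), seed = 1)
bundle <- generate_bundle(cfg)
corpus <- corpus_from_bundle(bundle)
corpus
#> annotation_corpus: 2000 genes, 21 panel tissues, 11391 gene-tissue links,
#> 33863 gene-phenotype links

assoc <- score_corpus(corpus, min_phenotype_count = 10, p_cutoff = 0.005)
truth_recovery_report(bundle$truth, assoc)[c("recall", "false_positives")]
#> $recall
#> [1] 1
#> $false_positives
#> [1] 3

gold <- load_eq(bundle$eq, bundle$xref, bundle$ontology)
recs <- classify_associations(assoc, gold, bundle$ontology, bundle$panel)
summarize_evaluation(recs)
#> Evaluation against EQ statements
#>
#> Phenotype level (denominator: phenotypes with representable EQ)
#>   hypergeom  expected 12 (86%)  not expected 2  no EQ 14  total 28
#>
#> Association level (denominator: associations with representable EQ)
#>   hypergeom  exact 3  psp 5  ldsp 4  no match 2 (14%)  no EQ 14  total 28
```

All 25 planted pairs are recovered at the default thresholds with 3 false
positives among the ~1 200 tested null pairs; of the 28 reported
associations, 14 phenotypes have an evaluable EQ statement and 12 of those
recover the expected tissue (exact, psp or ldsp). The `no_match` rows are
candidates for spatially separated expression and phenotype manifestation,
not necessarily errors.

Re-ranking: with `rerank(candidates, tissues, corpus, top_n = 200)` a gene
ranked 7th that is the only top candidate expressed in the query tissues
becomes rank 1 of the filtered list.

## Command line

An equivalent CLI is installed as `exec/phenotissue`:

```sh
phenotissue simulate --seed 42 --out-dir bundle/
phenotissue build-corpus --expression bundle/expression_lacz.tsv,bundle/expression_barcode.tsv \
  --phenotypes bundle/phenotypes.tsv --gene-map bundle/gene_map.tsv \
  --panel bundle/panel.txt --out corpus.tsv
phenotissue associate --corpus corpus.tsv --method hypergeom --out assoc.tsv
phenotissue evaluate --associations assoc.tsv --eq bundle/eq.tsv \
  --xref bundle/xref.tsv --ontology bundle/anatomy.tsv \
  --panel bundle/panel.txt --out eval.tsv --summary summary.txt
```

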