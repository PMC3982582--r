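# Seed-reproducible synthetic input bundles with planted tissue-phenotype
# enrichments.
#
# The generator emulates the shape of the real inputs: a ~21-tissue adult
# panel, thousands of genes with sparse 'present' calls observed by two
# overlapping sources, dense per-gene phenotype annotation lists
# (default mean 13.4 phenotypes per gene), a small DAG anatomy ontology
# in which panel tissues have both parents and part_of children (so the
# psp/ldsp evaluation paths are exercised), EQ statements for a subset of
# phenotypes, and a foreign->canonical gene id map with an unmappable
# fraction.  For a non-planted pair, tissue and phenotype membership are
# independent at their base rates; for a planted pair (t, p, odds) the
# per-gene log-odds of carrying p is shifted by log(odds) when the gene
# truly expresses t.  A single master seed feeds fixed per-component
# substream offsets, so the same seed gives a byte-identical bundle.

.SUBSTREAMS <- c(expression = 11L, phenotype = 23L, sources = 37L,
                 genemap = 53L, eq = 71L, candidates = 89L)

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param n_phenotypes number of phenotype concepts.
#' @param tissue_panel_size panel size (default 21 adult tissues).
#' @param mean_phenotypes_per_gene expected phenotype annotations per
#'   gene (default 13.4, the density of the real MGD-derived corpus);
#'   must not exceed `n_phenotypes`.
#' @param tissue_call_rate probability a gene truly expresses a given
#'   panel tissue (default 0.3, ~6 tissues per gene).
#' @param planted data.frame of planted enrichments with columns
#'   `tissue` (panel index), `phenotype` (phenotype index), `odds`
#'   (multiplicative odds inflation, >= 1); see [plant_pairs()].
#' @param eq_coverage fraction of phenotypes given an EQ statement.
#' @param eq_correct_fraction for planted phenotypes with an EQ, the
#'   fraction whose entity points at the planted tissue or one of its
#'   ontology neighbours (the rest point at unrelated anatomy, which
#'   surfaces no_match / no_eq rows in evaluation).
#' @param source_detect_rate probability each of the two expression
#'   sources observes a true present call (default 0.8 each; the union
#'   covers ~96%).
#' @param noise_call_rate fraction of non-present gene-tissue pairs per
#'   source that receive an explicit absent/ambiguous/no_data call.
#' @param unmappable_fraction fraction of genes whose foreign id is
#'   missing from the gene map (their expression is lost, mirroring the
#'   mapping losses of real cross-references).
#' @param n_candidates length of the generated ranked candidate list.
#' @param seed master seed (integer; substream seeds are small fixed
#'   offsets from it).
#' @return a validated `simulation_config`.
#' @export
simulation_config <- function(n_genes, n_phenotypes,
                              tissue_panel_size = 21,
                              mean_phenotypes_per_gene = 13.4,
                              tissue_call_rate = 0.3,
                              planted = NULL,
                              eq_coverage = 0.6,
                              eq_correct_fraction = 0.8,
                              source_detect_rate = 0.8,
                              noise_call_rate = 0.05,
                              unmappable_fraction = 0.05,
                              n_candidates = 200,
                              seed = 1) {
  stopifnot(n_genes >= 1, n_phenotypes >= 1, tissue_panel_size >= 1,
            n_candidates >= 1)
  if (mean_phenotypes_per_gene > n_phenotypes) {
    stop("infeasible config: expected phenotype count per gene (",
         mean_phenotypes_per_gene, ") exceeds n_phenotypes (",
         n_phenotypes, ")")
  }
  fracs <- c(tissue_call_rate, eq_coverage, eq_correct_fraction,
             source_detect_rate, noise_call_rate, unmappable_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all rate parameters must be in [0, 1]")
  if (is.null(planted)) {
    planted <- data.frame(tissue = integer(), phenotype = integer(),
                          odds = numeric())
  }
  stopifnot(all(c("tissue", "phenotype", "odds") %in% names(planted)))
  if (nrow(planted)) {
    if (any(planted$odds < 1)) stop("enrichment odds must be >= 1")
    if (any(planted$tissue < 1 | planted$tissue > tissue_panel_size) ||
        any(planted$phenotype < 1 | planted$phenotype > n_phenotypes)) {
      stop("planted indices out of range")
    }
    if (anyDuplicated(planted[c("tissue", "phenotype")])) {
      stop("duplicate planted pairs")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_phenotypes = as.integer(n_phenotypes),
                 tissue_panel_size = as.integer(tissue_panel_size),
                 mean_phenotypes_per_gene = mean_phenotypes_per_gene,
                 tissue_call_rate = tissue_call_rate,
                 planted = planted,
                 eq_coverage = eq_coverage,
                 eq_correct_fraction = eq_correct_fraction,
                 source_detect_rate = source_detect_rate,
                 noise_call_rate = noise_call_rate,
                 unmappable_fraction = unmappable_fraction,
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Sample planted tissue-phenotype pairs
#'
#' Samples `n_pairs` pairs with distinct phenotypes (so each phenotype
#' has one planted tissue) and a common enrichment odds.
#'
#' @param n_pairs number of pairs (at most `n_phenotypes`).
#' @param tissue_panel_size,n_phenotypes index ranges.
#' @param odds enrichment odds for every pair (default 8).
#' @param seed RNG seed for the sampling.
#' @return data.frame with columns `tissue`, `phenotype`, `odds`.
#' @export
plant_pairs <- function(n_pairs, tissue_panel_size, n_phenotypes,
                        odds = 8, seed = 1) {
  stopifnot(n_pairs <= n_phenotypes)
  set.seed(seed)
  data.frame(tissue = sample.int(tissue_panel_size, n_pairs,
                                 replace = TRUE),
             phenotype = sample.int(n_phenotypes, n_pairs),
             odds = odds)
}

# Small anatomy DAG: panel tissues sit between group terms (is_a parents,
# targets for ldsp gold entities ... the predicted tissue is then below
# the gold entity? no: group above tissue -> tissue below group = psp when
# group is the gold entity) and part_of sub-structures (psp/ldsp
# counterparts), plus a disconnected-from-the-panel branch for
# unrepresentable entities.
.make_anatomy <- function(panel) {
  K <- length(panel)
  root <- "MA:0000001"
  groups <- sprintf("MA:2%06d", seq_len(ceiling(K / 6)))
  subs <- sprintf("MA:3%06d", seq_len(K))
  other <- "MA:4000001"
  unrelated <- sprintf("MA:9%06d", 1:5)
  edges <- rbind(
    data.frame(child = groups, relation = "is_a", parent = root),
    data.frame(child = panel, relation = "is_a",
               parent = groups[ceiling(seq_len(K) / 6)]),
    data.frame(child = subs, relation = "part_of", parent = panel),
    data.frame(child = other, relation = "is_a", parent = root),
    data.frame(child = unrelated, relation = "is_a", parent = other))
  labels <- stats::setNames(
    c("anatomical structure", sprintf("region_%02d", seq_along(groups)),
      sprintf("tissue_%02d", seq_len(K)), sprintf("subtissue_%02d", seq_len(K)),
      "other structures", sprintf("unrelated_%02d", 1:5)),
    c(root, groups, panel, subs, other, unrelated))
  list(graph = ontology_graph(edges, labels), edges = edges,
       groups = groups, subs = subs, unrelated = unrelated)
}

#' Generate a complete synthetic input bundle
#'
#' Produces every input the pipeline consumes — two expression call
#' sources (foreign gene ids), phenotype annotations (canonical ids), a
#' gene id map, a panel file, a small anatomy DAG, EQ statements in a
#' foreign anatomy namespace plus their cross-reference table, a ranked
#' candidate list — together with the truth table of planted pairs and
#' the generator's own bookkeeping counts (used as test oracles).
#'
#' @param config a [simulation_config()].
#' @return a `sim_bundle` list; see Details in the package vignette.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  K <- config$tissue_panel_size
  P <- config$n_phenotypes
  seeds <- config$seed + .SUBSTREAMS

  canonical <- sprintf("MGI:%07d", seq_len(n))
  foreign <- sprintf("ENSMUSG%011d", seq_len(n))
  panel <- sprintf("MA:1%06d", seq_len(K))
  phenos <- sprintf("MP:%07d", seq_len(P))
  anat <- .make_anatomy(panel)

  # true tissue membership
  set.seed(seeds[["expression"]])
  Tm <- matrix(stats::runif(n * K) < config$tissue_call_rate, n, K,
               dimnames = list(canonical, panel))

  # phenotype membership: base log-odds shifted by planted tissues
  set.seed(seeds[["phenotype"]])
  base_r <- config$mean_phenotypes_per_gene / P
  lo <- stats::qlogis(min(base_r, 1 - 1e-12))
  Pm <- matrix(FALSE, n, P, dimnames = list(canonical, phenos))
  planted <- config$planted
  for (j in seq_len(P)) {
    shift <- rep(0, n)
    pl <- planted[planted$phenotype == j, , drop = FALSE]
    for (k in seq_len(nrow(pl))) {
      shift <- shift + log(pl$odds[k]) * Tm[, pl$tissue[k]]
    }
    Pm[, j] <- stats::runif(n) < stats::plogis(lo + shift)
  }

  # two overlapping expression sources, foreign ids, four-valued calls
  set.seed(seeds[["sources"]])
  make_source <- function() {
    detect <- Tm & matrix(stats::runif(n * K) < config$source_detect_rate,
                          n, K)
    idx <- which(detect, arr.ind = TRUE)
    present <- data.frame(gene_id = foreign[idx[, 1L]],
                          tissue_id = panel[idx[, 2L]],
                          call = rep("present", nrow(idx)),
                          stringsAsFactors = FALSE)
    bg <- which(!detect)
    noisy <- bg[stats::runif(length(bg)) < config$noise_call_rate]
    ri <- ((noisy - 1L) %% n) + 1L
    ci <- ((noisy - 1L) %/% n) + 1L
    noise <- data.frame(gene_id = foreign[ri], tissue_id = panel[ci],
                        call = sample(c("absent", "ambiguous", "no_data"),
                                      length(noisy), replace = TRUE,
                                      prob = c(0.7, 0.15, 0.15)),
                        stringsAsFactors = FALSE)
    out <- rbind(present, noise)
    out[order(out$gene_id, out$tissue_id), , drop = FALSE]
  }
  source_a <- make_source()
  source_b <- make_source()

  # foreign -> canonical map with an unmappable fraction
  set.seed(seeds[["genemap"]])
  unmappable <- stats::runif(n) < config$unmappable_fraction
  gene_map <- data.frame(foreign_id = foreign[!unmappable],
                         canonical_id = canonical[!unmappable],
                         stringsAsFactors = FALSE)

  annotations <- {
    idx <- which(Pm, arr.ind = TRUE)
    out <- data.frame(gene_id = canonical[idx[, 1L]],
                      phenotype_id = phenos[idx[, 2L]],
                      stringsAsFactors = FALSE)
    out[order(out$gene_id, out$phenotype_id), , drop = FALSE]
  }

  # EQ statements in a foreign (species-agnostic) namespace + xref
  set.seed(seeds[["eq"]])
  all_anat <- anat$graph$terms
  uberon <- stats::setNames(sprintf("UBERON:%06d", seq_along(all_anat)),
                            all_anat)
  planted_tissue_of <- stats::setNames(rep(NA_integer_, P), phenos)
  if (nrow(planted)) {
    first <- planted[!duplicated(planted$phenotype), ]
    planted_tissue_of[first$phenotype] <- first$tissue
  }
  eq_rows <- list()
  n_eq_unmappable <- 0L
  for (j in seq_len(P)) {
    if (stats::runif(1) >= config$eq_coverage) next
    ti <- planted_tissue_of[[j]]
    if (!is.na(ti) && stats::runif(1) < config$eq_correct_fraction) {
      # entity relates to the planted tissue: exact / parent / child
      pick <- sample(c("exact", "parent", "child"), 1,
                     prob = c(0.6, 0.2, 0.2))
      entity <- switch(pick,
                       exact = panel[ti],
                       parent = anat$groups[ceiling(ti / 6)],
                       child = anat$subs[ti])
    } else if (stats::runif(1) < 0.7) {
      # representable but off-target: a different panel tissue
      pool <- if (is.na(ti)) panel else panel[-ti]
      if (!length(pool)) pool <- panel
      entity <- sample(pool, 1)
    } else {
      # not representable: disconnected branch -> no_eq in evaluation
      entity <- sample(anat$unrelated, 1)
    }
    fid <- uberon[[entity]]
    if (stats::runif(1) < 0.1) {
      # plant an unmappable row: fresh foreign id, absent from xref
      fid <- sprintf("UBERON:9%05d", j)
      n_eq_unmappable <- n_eq_unmappable + 1L
    }
    eq_rows[[length(eq_rows) + 1L]] <-
      data.frame(phenotype_id = phenos[j], anatomy_id = fid,
                 stringsAsFactors = FALSE)
  }
  eq <- if (length(eq_rows)) do.call(rbind, eq_rows) else
    data.frame(phenotype_id = character(), anatomy_id = character())
  xref <- data.frame(foreign_id = unname(uberon),
                     working_id = names(uberon), stringsAsFactors = FALSE)

  # ranked candidate list over a random gene subset
  set.seed(seeds[["candidates"]])
  n_cand <- min(config$n_candidates, n)
  cand_genes <- sample(canonical, n_cand)
  candidates <- data.frame(rank = seq_len(n_cand), gene_id = cand_genes,
                           score = round(sort(stats::runif(n_cand),
                                              decreasing = TRUE), 6),
                           stringsAsFactors = FALSE)

  truth <- data.frame(tissue = panel[planted$tissue],
                      phenotype = phenos[planted$phenotype],
                      odds = planted$odds, stringsAsFactors = FALSE)
  truth_counts <- if (nrow(planted)) {
    data.frame(tissue = truth$tissue, phenotype = truth$phenotype,
               t_true = colSums(Tm)[planted$tissue],
               p_true = colSums(Pm)[planted$phenotype],
               o_true = vapply(seq_len(nrow(planted)), function(k) {
                 sum(Tm[, planted$tissue[k]] & Pm[, planted$phenotype[k]])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tissue = character(), phenotype = character(),
               t_true = numeric(), p_true = numeric(), o_true = numeric())
  }

  bookkeeping <- list(
    n_true_gene_tissue = sum(Tm),
    n_gene_phenotype = sum(Pm),
    n_distinct_pairs_a = sum(!duplicated(source_a[c("gene_id", "tissue_id")])),
    n_distinct_pairs_b = sum(!duplicated(source_b[c("gene_id", "tissue_id")])),
    n_unmappable_genes = sum(unmappable),
    n_eq_unmappable_rows = n_eq_unmappable,
    truth_counts = truth_counts)

  structure(list(config = config, panel = panel, phenotypes = phenos,
                 genes_canonical = canonical, genes_foreign = foreign,
                 ontology = anat$graph, anatomy_edges = anat$edges,
                 expression_sources = list(lacz = source_a,
                                           barcode = source_b),
                 phenotype_annotations = annotations,
                 gene_map = gene_map, eq = eq, xref = xref,
                 candidates = candidates, truth = truth,
                 bookkeeping = bookkeeping),
            class = "sim_bundle")
}

#' Build the annotation corpus from a bundle
#'
#' Runs the corpus_io path on the bundle's raw tables: parse each
#' expression source, translate foreign gene ids through the gene map,
#' and union-merge with the phenotype annotations over the panel.
#'
#' @param bundle a `sim_bundle` from [generate_bundle()].
#' @return an [annotation_corpus()].
#' @export
corpus_from_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "sim_bundle"))
  map <- stats::setNames(bundle$gene_map$canonical_id,
                         bundle$gene_map$foreign_id)
  sources <- lapply(names(bundle$expression_sources), function(s) {
    apply_gene_map(
      read_expression_calls(bundle$expression_sources[[s]], source = s),
      map)
  })
  build_corpus(sources, bundle$phenotype_annotations, bundle$panel)
}

#' Write a bundle's tables to a directory
#'
#' Emits `expression_<source>.tsv`, `phenotypes.tsv`, `gene_map.tsv`,
#' `panel.txt`, `anatomy.tsv`, `eq.tsv`, `xref.tsv`, `candidates.tsv`
#' and `truth.tsv` in the formats the loaders expect.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (s in names(bundle$expression_sources)) {
    tsv(bundle$expression_sources[[s]], paste0("expression_", s, ".tsv"))
  }
  tsv(bundle$phenotype_annotations, "phenotypes.tsv")
  tsv(bundle$gene_map, "gene_map.tsv")
  writeLines(bundle$panel, file.path(dir, "panel.txt"))
  write_ontology(bundle$ontology, file.path(dir, "anatomy.tsv"))
  tsv(bundle$eq, "eq.tsv")
  tsv(bundle$xref, "xref.tsv")
  tsv(bundle$candidates, "candidates.tsv")
  tsv(bundle$truth, "truth.tsv")
  invisible(dir)
}

#' Recovery of planted pairs by an association set
#'
#' @param truth truth data.frame with columns `tissue`, `phenotype`
#'   (the planted pairs), e.g. `bundle$truth`.
#' @param associations association data.frame with columns `tissue`,
#'   `phenotype`.
#' @return list with `recall` (fraction of planted pairs present in the
#'   associations; NaN when nothing is planted), `n_planted`,
#'   `n_recovered`, `false_positives` (association rows whose pair is
#'   not planted) and `fp_pairs` (that subset of the associations).
#' @export
truth_recovery_report <- function(truth, associations) {
  tk <- paste(truth$tissue, truth$phenotype, sep = "\r")
  ak <- unique(paste(associations$tissue, associations$phenotype,
                     sep = "\r"))
  n_rec <- sum(tk %in% ak)
  fp <- !paste(associations$tissue, associations$phenotype,
               sep = "\r") %in% tk
  list(recall = n_rec / length(tk), n_planted = length(tk),
       n_recovered = n_rec, false_positives = sum(fp),
       fp_pairs = associations[fp, c("tissue", "phenotype"), drop = FALSE])
}
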