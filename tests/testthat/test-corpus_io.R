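test_that("read_expression_calls parses, validates and collapses", {
  empty <- read_expression_calls(data.frame(gene_id = character(),
                                            tissue_id = character(),
                                            call = character()))
  expect_equal(nrow(empty), 0)

  dup <- data.frame(gene_id = c("g1", "g1"), tissue_id = c("t1", "t1"),
                    call = c("ambiguous", "present"))
  out <- read_expression_calls(dup, source = "lacz")
  expect_equal(nrow(out), 1)
  expect_identical(out$call, "present")
  expect_identical(out$source, "lacz")

  expect_error(read_expression_calls(
    data.frame(gene_id = "g", tissue_id = "t", call = "maybe")),
    "invalid call token")
  expect_error(read_expression_calls(
    data.frame(gene_id = "g", call = "present")),
    "missing column")
})

test_that("duplicate collapse matches generator bookkeeping at scale", {
  set.seed(11)
  n <- 1000
  genes <- sprintf("g%02d", sample.int(40, n, replace = TRUE))
  tissues <- sprintf("t%02d", sample.int(10, n, replace = TRUE))
  tab <- data.frame(gene_id = genes, tissue_id = tissues,
                    call = sample(c("present", "absent", "ambiguous",
                                    "no_data"), n, replace = TRUE))
  n_distinct <- sum(!duplicated(tab[c("gene_id", "tissue_id")]))
  out <- read_expression_calls(tab)
  expect_equal(nrow(out), n_distinct)
  # present wins over any other call for the same pair
  key <- paste(tab$gene_id, tab$tissue_id)
  had_present <- tapply(tab$call == "present", key, any)
  got <- setNames(out$call == "present", paste(out$gene, out$tissue))
  expect_identical(as.vector(got[names(had_present)]),
                   as.vector(had_present))
})

test_that("apply_gene_map drops unmappables and merges by union", {
  x <- data.frame(gene = c("a", "b"), phenotype = c("p1", "p2"),
                  stringsAsFactors = FALSE)
  idmap <- setNames(c("a", "b"), c("a", "b"))
  expect_equal(apply_gene_map(x, idmap)[1:2], x, ignore_attr = TRUE)
  expect_equal(attr(apply_gene_map(x, idmap), "n_dropped"), 0)

  # two foreign ids -> one canonical id: union of annotations
  calls <- data.frame(gene = c("f1", "f2"), tissue = c("t1", "t2"),
                      source = "s", call = "present",
                      stringsAsFactors = FALSE)
  m <- setNames(c("G", "G"), c("f1", "f2"))
  mapped <- apply_gene_map(calls, m)
  expect_setequal(mapped$tissue[mapped$gene == "G"], c("t1", "t2"))

  # planted unmappable fraction is reported
  set.seed(5)
  genes <- sprintf("f%03d", 1:200)
  mappable <- runif(200) >= 0.1
  m2 <- setNames(toupper(genes[mappable]), genes[mappable])
  ann <- data.frame(gene = genes, phenotype = "p",
                    stringsAsFactors = FALSE)
  out <- apply_gene_map(ann, m2)
  expect_equal(attr(out, "n_dropped"), sum(!mappable))
  expect_equal(nrow(out), sum(mappable))
})

test_that("build_corpus unions present calls across sources over the panel", {
  s1 <- read_expression_calls(data.frame(
    gene_id = c("g1", "g1", "g2"), tissue_id = c("t1", "t9", "t1"),
    call = c("present", "present", "absent")), "a")
  s2 <- read_expression_calls(data.frame(
    gene_id = "g1", tissue_id = "t2", call = "present"), "b")
  ph <- data.frame(gene_id = "g1", phenotype_id = "p1")
  corp <- build_corpus(list(s1, s2), ph, panel = c("t1", "t2", "t3"))
  expect_identical(corp$tissues_of$g1, c("t1", "t2"))
  expect_null(corp$tissues_of$g2)          # absent never counts
  expect_identical(corp$genes, "g1")       # g2 has no annotations at all
  expect_equal(attr(corp, "n_off_panel"), 1)  # t9 discarded, counted
  expect_error(build_corpus(list(s1), ph, panel = character()),
               "non-empty")
})

test_that("merging is idempotent and order-independent", {
  cfg <- simulation_config(n_genes = 120, n_phenotypes = 12,
                           mean_phenotypes_per_gene = 5, seed = 3)
  b <- generate_bundle(cfg)
  idmap <- setNames(b$gene_map$canonical_id, b$gene_map$foreign_id)
  srcs <- lapply(names(b$expression_sources), function(s) {
    apply_gene_map(read_expression_calls(b$expression_sources[[s]], s),
                   idmap)
  })
  ph <- b$phenotype_annotations
  c1 <- build_corpus(srcs, ph, b$panel)
  c2 <- build_corpus(rev(srcs), ph, b$panel)
  c3 <- build_corpus(c(srcs, srcs[1]), ph, b$panel)  # self-merge
  strip <- function(x) { attr(x, "n_off_panel") <- NULL; x }
  expect_identical(strip(c1), strip(c2))
  expect_identical(strip(c1), strip(c3))
})

test_that("per-gene tissue sets match an independent recount of raw calls", {
  cfg <- simulation_config(n_genes = 150, n_phenotypes = 10,
                           mean_phenotypes_per_gene = 5, seed = 9)
  b <- generate_bundle(cfg)
  corp <- corpus_from_bundle(b)
  idmap <- setNames(b$gene_map$canonical_id, b$gene_map$foreign_id)
  raw <- do.call(rbind, b$expression_sources)
  raw <- raw[raw$call == "present" & raw$gene_id %in% names(idmap), ]
  raw$gene <- unname(idmap[raw$gene_id])
  recount <- lapply(split(raw$tissue_id, raw$gene),
                    function(v) sort(unique(v)))
  for (g in names(recount)) {
    expect_identical(corp$tissues_of[[g]], recount[[g]])
  }
  n_with_tissue <- sum(lengths(corp$tissues_of) > 0)
  expect_equal(n_with_tissue, length(recount))
  # corpus genes never exceed distinct canonical ids in the inputs
  expect_lte(length(corp$genes),
             length(unique(c(idmap, b$phenotype_annotations$gene_id))))
})

test_that("corpus TSV round trip reproduces the corpus", {
  cfg <- simulation_config(n_genes = 60, n_phenotypes = 8,
                           mean_phenotypes_per_gene = 4, seed = 21)
  corp <- corpus_from_bundle(generate_bundle(cfg))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, f)
  corp2 <- read_corpus(f)
  expect_identical(corp$tissue_panel, corp2$tissue_panel)
  expect_identical(corp$genes, corp2$genes)
  expect_identical(corp$tissues_of, corp2$tissues_of)
  expect_identical(corp$phenotypes_of, corp2$phenotypes_of)
})
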