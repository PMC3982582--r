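test_that("contingency counts a tiny corpus by hand", {
  cc <- contingency(tiny_corpus(), "t", "p")
  expect_equal(cc$o_tp, 1)
  expect_equal(cc$t, 2)
  expect_equal(cc$p, 2)
  expect_equal(cc$pt, 3)
  expect_error(contingency(tiny_corpus(), "nope", "p"), "not in panel")
})

test_that("degenerate and invalid counts are rejected", {
  expect_error(contingency_counts(0, 0, 0, 0), "pt must be >= 1")
  expect_error(contingency_counts(3, 2, 5, 10), "o_tp cannot exceed")
  expect_error(contingency_counts(0, 5, 7, 10), "t \\+ p - pt")
  expect_error(contingency_counts(1, 11, 2, 10), "exceed pt")
  expect_error(hypergeom_upper_tail(3, 2, 5, 10))
})

test_that("analytic edge cases hold exactly", {
  expect_identical(hypergeom_upper_tail(0, 6, 5, 20), 1)
  # tissue annotates every gene: o_tp is forced to equal p
  expect_identical(hypergeom_upper_tail(5, 20, 5, 20), 1)
  expect_identical(hypergeom_upper_tail(contingency_counts(0, 3, 3, 9)), 1)
})

test_that("the pt=20 example matches exhaustive enumeration and is frozen", {
  got <- hypergeom_upper_tail(3, 6, 5, 20)
  expect_equal(got, oracle_tail_subsets(3, 6, 5, 20), tolerance = 1e-14)
  # frozen regression baseline: 5090 / 38760 draws with overlap >= 3
  expect_equal(got, 5090 / 38760, tolerance = 1e-14)
})

test_that("tail is symmetric in (t, p) and non-increasing in o_tp", {
  set.seed(2)
  for (i in 1:100) {
    q <- random_quadruple(150)
    expect_equal(hypergeom_upper_tail(q["o"], q["t"], q["p"], q["pt"]),
                 hypergeom_upper_tail(q["o"], q["p"], q["t"], q["pt"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  for (t in 0:12) for (p in 0:12) {
    pt <- 12
    os <- max(0, t + p - pt):min(t, p)
    vals <- hypergeom_upper_tail(os, rep(t, length(os)),
                                 rep(p, length(os)), rep(pt, length(os)))
    expect_true(all(diff(vals) <= 1e-15))
    expect_true(all(vals > 0 & vals <= 1))
  }
})

test_that("score_corpus applies the occurrence and p filters", {
  # phenotype annotating 9 genes is skipped regardless of p
  tis <- setNames(rep(list("t1"), 9), paste0("g", 1:9))
  ph <- setNames(rep(list("p1"), 9), paste0("g", 1:9))
  extra <- setNames(rep(list(character()), 6), paste0("h", 1:6))
  corp <- annotation_corpus(c("t1", "t2"), tis, c(ph, extra))
  expect_equal(nrow(score_corpus(corp, min_phenotype_count = 10)), 0)
  a <- score_corpus(corp, min_phenotype_count = 9)
  expect_equal(nrow(a), 1)
  expect_identical(a$supporting_genes, paste(paste0("g", 1:9),
                                             collapse = ","))

  # inclusive p cutoff: a pair at exactly the cutoff is kept
  p_at <- a$p_value
  expect_equal(nrow(score_corpus(corp, 9, p_cutoff = p_at)), 1)
  expect_equal(nrow(score_corpus(corp, 9, p_cutoff = p_at * 0.999)), 0)
})

test_that("emitted associations equal a full brute-force rescoring", {
  cfg <- simulation_config(n_genes = 250, n_phenotypes = 15,
                           mean_phenotypes_per_gene = 5,
                           planted = plant_pairs(3, 21, 15, odds = 8,
                                                 seed = 13),
                           seed = 13)
  corp <- corpus_from_bundle(generate_bundle(cfg))
  a <- score_corpus(corp, min_phenotype_count = 10, p_cutoff = 0.005)

  genes <- corp$genes
  pt <- length(genes)
  phenos <- sort(unique(unlist(corp$phenotypes_of)))
  rows <- list()
  for (ph in phenos) {
    hp <- vapply(genes, function(g) ph %in% corp$phenotypes_of[[g]],
                 logical(1))
    if (sum(hp) < 10) next
    for (ti in corp$tissue_panel) {
      ht <- vapply(genes, function(g) ti %in% corp$tissues_of[[g]],
                   logical(1))
      pv <- oracle_tail_count(sum(ht & hp), sum(ht), sum(hp), pt)
      if (pv <= 0.005) {
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = ph, tissue = ti, p_value = pv,
          o_tp = sum(ht & hp),
          supporting_genes = paste(sort(genes[ht & hp]), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  oracle <- do.call(rbind, rows)
  oracle <- oracle[order(oracle$phenotype, oracle$p_value,
                         oracle$tissue), ]
  expect_equal(nrow(a), nrow(oracle))
  expect_identical(a$phenotype, oracle$phenotype)
  expect_identical(a$tissue, oracle$tissue)
  expect_identical(a$supporting_genes, oracle$supporting_genes)
  expect_equal(a$p_value, oracle$p_value, tolerance = 1e-12)
  expect_equal(a$o_tp, oracle$o_tp)
})

test_that("association TSV round trip keeps schema and order", {
  cfg <- simulation_config(n_genes = 200, n_phenotypes = 12,
                           mean_phenotypes_per_gene = 5,
                           planted = plant_pairs(2, 21, 12, odds = 8,
                                                 seed = 4),
                           seed = 4)
  corp <- corpus_from_bundle(generate_bundle(cfg))
  a <- score_corpus(corp)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_associations(a, f)
  a2 <- read_associations(f)
  expect_identical(a2$phenotype, a$phenotype)
  expect_identical(a2$tissue, a$tissue)
  expect_identical(a2$supporting_genes, a$supporting_genes)
  expect_equal(a2$p_value, a$p_value, tolerance = 1e-5)
})
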