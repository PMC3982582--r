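test_that("load_eq cross-references entities and reports drops", {
  fx <- eval_fixture()
  eq <- data.frame(phenotype_id = c("p1", "p1", "p2", "p9"),
                   anatomy_id = c("UB:1", "retina", "UB:2", "UB:404"))
  xref <- data.frame(foreign_id = c("UB:1", "UB:2"),
                     working_id = c("eye", "cornea"))
  gold <- load_eq(eq, xref, fx$anatomy)
  # UB:1 -> eye via xref; 'retina' passes through as a working id;
  # UB:404 has no xref and is unknown -> row and phenotype dropped
  expect_setequal(gold$p1, c("eye", "retina"))
  expect_identical(gold$p2, "cornea")
  expect_null(gold$p9)
  expect_equal(attr(gold, "n_dropped_rows"), 1)
  expect_equal(attr(gold, "n_dropped_phenotypes"), 1)
})

test_that("planted unmappable EQ rows are dropped with matching counts", {
  cfg <- simulation_config(n_genes = 80, n_phenotypes = 40,
                           planted = plant_pairs(10, 21, 40, seed = 31),
                           seed = 31)
  b <- generate_bundle(cfg)
  gold <- load_eq(b$eq, b$xref, b$ontology)
  expect_equal(attr(gold, "n_dropped_rows"),
               b$bookkeeping$n_eq_unmappable_rows)
  expect_true(all(unlist(gold) %in% b$ontology$terms))
})

test_that("representable follows transitive relations in both directions", {
  fx <- eval_fixture()
  expect_true(representable("eye", fx$panel, fx$anatomy))      # identical
  expect_true(representable("retina", fx$panel, fx$anatomy))   # below eye
  expect_true(representable("organ", fx$panel, fx$anatomy))    # above panel
  expect_false(representable("island", fx$panel, fx$anatomy))  # disconnected
  # exhaustive relate oracle over the panel
  for (e in fx$anatomy$terms) {
    want <- any(vapply(fx$panel,
                       function(t) relate(e, t, fx$anatomy) != "unrelated",
                       logical(1)))
    expect_identical(representable(e, fx$panel, fx$anatomy), want)
  }
})

test_that("classification reproduces the hand-derived categories", {
  fx <- eval_fixture()
  recs <- classify_associations(fx$assoc, fx$gold, fx$anatomy, fx$panel)
  expect_identical(recs$category, fx$expected)
  # matched_entity present iff a positive category
  pos <- recs$category %in% c("exact", "psp", "ldsp")
  expect_identical(!is.na(recs$matched_entity), pos)
  expect_identical(recs$matched_entity[1], "eye")
  expect_identical(recs$matched_entity[3], "retina")
  expect_error(classify_association("nowhere", "p1", fx$gold,
                                    fx$anatomy, fx$panel), "nowhere")
})

test_that("classification priority is order-independent", {
  fx <- eval_fixture()
  # gold with entities at several levels: exact must win
  gold <- list(p1 = c("organ", "eye", "retina"))
  a <- classify_association("eye", "p1", gold, fx$anatomy, fx$panel)
  expect_identical(a$category, "exact")
  gold_rev <- list(p1 = rev(gold$p1))
  b <- classify_association("eye", "p1", gold_rev, fx$anatomy, fx$panel)
  expect_identical(a, b)
  # with exact removed, psp (eye below organ) outranks ldsp (retina)
  c1 <- classify_association("eye", "p1",
                             list(p1 = c("retina", "organ")),
                             fx$anatomy, fx$panel)
  expect_identical(c1$category, "psp")
  expect_identical(c1$matched_entity, "organ")
})

test_that("an edgeless anatomy yields only exact or no_match", {
  panel <- c("a", "b")
  flat <- ontology_graph(labels = c(a = "a", b = "b", c = "c"))
  gold <- list(p1 = "a", p2 = "c")
  assoc <- data.frame(phenotype = c("p1", "p1", "p2"),
                      tissue = c("a", "b", "a"), method = "hypergeom")
  recs <- classify_associations(assoc, gold, flat, panel)
  expect_identical(recs$category, c("exact", "no_match", "no_eq"))
})

test_that("summaries tally the fixture exactly, with the right denominators", {
  fx <- eval_fixture()
  recs <- classify_associations(fx$assoc, fx$gold, fx$anatomy, fx$panel)
  s <- summarize_evaluation(recs)
  h <- s$association[s$association$method == "hypergeom", ]
  expect_equal(unlist(h[c("exact", "psp", "ldsp", "no_match",
                          "no_eq", "total")]),
               c(exact = 2, psp = 1, ldsp = 2, no_match = 1,
                 no_eq = 2, total = 8))
  expect_equal(h$pct_expected, 100 * 5 / 6)
  expect_equal(h$pct_no_match, 100 * 1 / 6)
  r <- s$association[s$association$method == "rules", ]
  expect_equal(unlist(r[c("exact", "psp", "ldsp", "no_match",
                          "no_eq", "total")]),
               c(exact = 0, psp = 1, ldsp = 0, no_match = 2,
                 no_eq = 1, total = 4))
  hp <- s$phenotype[s$phenotype$method == "hypergeom", ]
  expect_equal(unlist(hp[c("expected", "not_expected", "no_eq", "total")]),
               c(expected = 5, not_expected = 0, no_eq = 2, total = 7))
  expect_equal(hp$pct_expected, 100)
  rp <- s$phenotype[s$phenotype$method == "rules", ]
  expect_equal(unlist(rp[c("expected", "not_expected", "no_eq", "total")]),
               c(expected = 1, not_expected = 2, no_eq = 1, total = 4))
  # association-level categories are exhaustive
  expect_equal(sum(s$association$total), nrow(fx$assoc))
  # all-no_eq input: denominators 0, percentages undefined
  none <- recs[recs$category == "no_eq", ]
  s0 <- summarize_evaluation(none)
  expect_true(all(is.na(s0$association$pct_expected)))
  expect_true(all(is.na(s0$phenotype$pct_expected)))
})
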