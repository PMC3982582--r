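# Small hand-built fixtures shared across test files.

# retina part_of eye, eye is_a organ
chain_graph <- function() {
  ontology_graph(data.frame(
    child = c("retina", "eye"),
    relation = c("part_of", "is_a"),
    parent = c("eye", "organ"), stringsAsFactors = FALSE))
}

# diamond: d below b and c, both below a
diamond_graph <- function() {
  ontology_graph(data.frame(
    child = c("d", "d", "b", "c"),
    relation = c("is_a", "part_of", "is_a", "part_of"),
    parent = c("b", "c", "a", "a"), stringsAsFactors = FALSE))
}

# 3-gene hand-count corpus: g1:{t,p}, g2:{t}, g3:{p}
tiny_corpus <- function() {
  annotation_corpus(
    tissue_panel = c("t", "t2"),
    tissues_of = list(g1 = "t", g2 = "t"),
    phenotypes_of = list(g1 = "p", g3 = "p"))
}

# 10-term anatomy DAG for the evaluation fixture:
#   organ; eye is_a organ; retina/cornea part_of eye; liver is_a organ;
#   lobe part_of liver; brain/skin/heart is_a organ; island (isolated).
# Panel: eye, liver, brain, skin, heart.
eval_fixture <- function() {
  anatomy <- ontology_graph(
    data.frame(
      child = c("eye", "retina", "cornea", "liver", "lobe",
                "brain", "skin", "heart"),
      relation = c("is_a", "part_of", "part_of", "is_a", "part_of",
                   "is_a", "is_a", "is_a"),
      parent = c("organ", "eye", "eye", "organ", "liver",
                 "organ", "organ", "organ"), stringsAsFactors = FALSE),
    labels = c(island = "disconnected structure"))
  panel <- c("eye", "liver", "brain", "skin", "heart")
  gold <- list(p1 = "eye", p2 = "retina", p3 = "cornea", p4 = "organ",
               p5 = "island", p7 = "brain")
  assoc <- data.frame(
    phenotype = c("p1", "p1", "p2", "p3", "p4", "p5", "p6", "p7",
                  "p2", "p4", "p7", "p6"),
    tissue = c("eye", "liver", "eye", "eye", "eye", "eye", "brain",
               "brain", "brain", "liver", "skin", "skin"),
    method = c(rep("hypergeom", 8), rep("rules", 4)),
    stringsAsFactors = FALSE)
  # hand-derived expected categories, row by row
  expected <- c("exact", "no_match", "ldsp", "ldsp", "psp", "no_eq",
                "no_eq", "exact", "no_match", "psp", "no_match", "no_eq")
  list(anatomy = anatomy, panel = panel, gold = gold, assoc = assoc,
       expected = expected)
}

# acceptance-scale simulation scenario (the "stated world")
acceptance_config <- function(seed) {
  simulation_config(
    n_genes = 2000, n_phenotypes = 60, tissue_panel_size = 21,
    mean_phenotypes_per_gene = 13.4,
    planted = plant_pairs(25, 21, 60, odds = 8, seed = seed),
    seed = seed)
}
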