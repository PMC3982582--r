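# Evaluation of predicted associations against EQ-decomposed phenotype
# definitions (phenotype -> affected anatomical entity), reproducing the
# exact / psp / ldsp classification:
#
#   exact — the predicted tissue is the gold entity;
#   psp   — the predicted tissue is a subclass or part_of the gold entity;
#   ldsp  — the gold entity is a subclass or part_of the predicted tissue;
#   no_match — related by neither direction;
#   no_eq — the phenotype has no EQ statement representable with the panel.
#
# Quality components of EQ statements are ignored; only the anatomical
# entity is evaluated.

.EVAL_CATEGORIES <- c("exact", "psp", "ldsp", "no_match", "no_eq")

#' Load EQ statements and cross-reference their entities
#'
#' Each row links a phenotype to one anatomical entity in a foreign
#' anatomy namespace (e.g. species-agnostic ids); entities are translated
#' into the working anatomy vocabulary through the cross-reference table.
#' An entity with no cross-reference that is also absent from the
#' ontology is dropped (counted in attribute `"n_dropped_rows"`); a
#' phenotype keeps the union of its surviving rows' entities and is
#' dropped from the gold map when none survive (attribute
#' `"n_dropped_phenotypes"`).
#'
#' @param eq_table data.frame or TSV path with columns `phenotype_id`,
#'   `anatomy_id` (one entity per row).
#' @param xref data.frame or TSV path with columns `foreign_id`,
#'   `working_id`, or a named character vector.
#' @param anatomy the working-anatomy [ontology_graph()].
#' @return named list: phenotype id -> character vector of working
#'   anatomy entity ids (non-empty).
#' @export
load_eq <- function(eq_table, xref, anatomy) {
  stopifnot(inherits(anatomy, "ontology_graph"))
  eq <- .read_table_arg(eq_table)
  if (!all(c("phenotype_id", "anatomy_id") %in% names(eq))) {
    bad <- setdiff(c("phenotype_id", "anatomy_id"), names(eq))
    stop("EQ table is missing column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(eq$phenotype_id) || anyNA(eq$anatomy_id)) {
    stop("malformed EQ rows (NA fields) at line(s): ",
         paste(which(is.na(eq$phenotype_id) | is.na(eq$anatomy_id)),
               collapse = ", "))
  }
  if (!is.character(xref) || !is.null(dim(xref))) {
    # data.frame or path
    xr <- .read_table_arg(xref)
    if (!all(c("foreign_id", "working_id") %in% names(xr))) {
      stop("xref table must have columns foreign_id and working_id")
    }
    xref <- stats::setNames(as.character(xr$working_id),
                            as.character(xr$foreign_id))
  }
  raw <- as.character(eq$anatomy_id)
  working <- unname(xref[raw])
  # ids already in the working vocabulary pass through
  direct <- is.na(working) & raw %in% anatomy$terms
  working[direct] <- raw[direct]
  known <- !is.na(working) & working %in% anatomy$terms
  n_dropped <- sum(!known)
  phen <- as.character(eq$phenotype_id)[known]
  gold <- lapply(split(working[known], phen), function(v) sort(unique(v)))
  n_dropped_phen <- length(setdiff(unique(as.character(eq$phenotype_id)),
                                   names(gold)))
  attr(gold, "n_dropped_rows") <- n_dropped
  attr(gold, "n_dropped_phenotypes") <- n_dropped_phen
  gold
}

#' Is an EQ statement representable with the tissue panel?
#'
#' TRUE iff at least one gold entity is identical to, transitively below,
#' or transitively above some panel tissue.
#'
#' @param entities character vector of working anatomy entity ids.
#' @param panel character vector of panel tissue ids (must be ontology
#'   terms).
#' @param anatomy the anatomy [ontology_graph()].
#' @return logical scalar.
#' @export
representable <- function(entities, panel, anatomy) {
  for (e in entities) {
    for (tis in panel) {
      if (relate(e, tis, anatomy) != "unrelated") return(TRUE)
    }
  }
  FALSE
}

# Category of one (predicted tissue, gold entity) comparison.
.entity_category <- function(tissue, entity, anatomy) {
  switch(relate(tissue, entity, anatomy),
         identical = "exact",
         first_below_second = "psp",
         second_below_first = "ldsp",
         unrelated = "no_match")
}

#' Classify one predicted association against the gold EQ map
#'
#' Returns `no_eq` when the phenotype has no gold entry or none of its
#' entities is representable with the panel; otherwise the best category
#' over all gold entities with priority exact > psp > ldsp > no_match
#' (deterministic, independent of entity order).  `matched_entity` is
#' the first entity (in sorted id order) achieving the best category,
#' or NA for no_match/no_eq.
#'
#' @param tissue predicted panel tissue id (must be an ontology term).
#' @param phenotype phenotype id.
#' @param gold named list from [load_eq()].
#' @param anatomy the anatomy [ontology_graph()].
#' @param panel character vector of panel tissue ids.
#' @return list with elements `category` and `matched_entity`.
#' @export
classify_association <- function(tissue, phenotype, gold, anatomy, panel) {
  .check_term(tissue, anatomy)
  entities <- gold[[phenotype]]
  if (is.null(entities) || !representable(entities, panel, anatomy)) {
    return(list(category = "no_eq", matched_entity = NA_character_))
  }
  cats <- vapply(entities, .entity_category, character(1),
                 tissue = tissue, anatomy = anatomy)
  best <- .EVAL_CATEGORIES[min(match(cats, .EVAL_CATEGORIES))]
  matched <- if (best %in% c("exact", "psp", "ldsp")) {
    sort(entities[cats == best])[[1L]]
  } else {
    NA_character_
  }
  list(category = best, matched_entity = matched)
}

#' Classify an association table
#'
#' Vectorized [classify_association()] over the rows of an association
#' data.frame.
#'
#' @param assoc association data.frame with columns `phenotype`,
#'   `tissue`, `method`.
#' @inheritParams classify_association
#' @return `assoc` with added columns `category` and `matched_entity`.
#' @export
classify_associations <- function(assoc, gold, anatomy, panel) {
  stopifnot(all(c("phenotype", "tissue", "method") %in% names(assoc)))
  recs <- lapply(seq_len(nrow(assoc)), function(i) {
    classify_association(assoc$tissue[i], assoc$phenotype[i],
                         gold, anatomy, panel)
  })
  assoc$category <- vapply(recs, `[[`, "", "category")
  assoc$matched_entity <- vapply(recs, `[[`, "", "matched_entity")
  assoc
}

#' Summarize evaluation records
#'
#' Tallies classified associations per method, at the association level
#' (exact / psp / ldsp / no_match / no_eq) and at the phenotype level: a
#' phenotype with a representable EQ counts as `expected` iff any of its
#' associations is exact, psp or ldsp.  Percentages use only the
#' phenotypes / associations WITH a representable EQ as denominator
#' (no_eq rows are reported separately) and are NA when that denominator
#' is 0.
#'
#' @param records classified association data.frame from
#'   [classify_associations()].
#' @return an `evaluation_summary`: list of data.frames `association`
#'   (method, exact, psp, ldsp, no_match, no_eq, total, pct_expected,
#'   pct_no_match) and `phenotype` (method, expected, not_expected,
#'   no_eq, total, pct_expected).
#' @export
summarize_evaluation <- function(records) {
  stopifnot(all(c("phenotype", "tissue", "method", "category")
                %in% names(records)))
  stopifnot(all(records$category %in% .EVAL_CATEGORIES))
  methods <- sort(unique(records$method))
  assoc_rows <- list(); phen_rows <- list()
  for (m in methods) {
    r <- records[records$method == m, , drop = FALSE]
    counts <- vapply(.EVAL_CATEGORIES,
                     function(cc) sum(r$category == cc), integer(1))
    with_eq <- sum(counts[c("exact", "psp", "ldsp", "no_match")])
    assoc_rows[[m]] <- data.frame(
      method = m, exact = counts[["exact"]], psp = counts[["psp"]],
      ldsp = counts[["ldsp"]], no_match = counts[["no_match"]],
      no_eq = counts[["no_eq"]], total = nrow(r),
      pct_expected = if (with_eq)
        100 * sum(counts[c("exact", "psp", "ldsp")]) / with_eq else NA_real_,
      pct_no_match = if (with_eq)
        100 * counts[["no_match"]] / with_eq else NA_real_,
      stringsAsFactors = FALSE)
    by_phen <- split(r$category, r$phenotype)
    status <- vapply(by_phen, function(cats) {
      if (all(cats == "no_eq")) "no_eq"
      else if (any(cats %in% c("exact", "psp", "ldsp"))) "expected"
      else "not_expected"
    }, character(1))
    n_exp <- sum(status == "expected")
    n_not <- sum(status == "not_expected")
    phen_rows[[m]] <- data.frame(
      method = m, expected = n_exp, not_expected = n_not,
      no_eq = sum(status == "no_eq"), total = length(status),
      pct_expected = if (n_exp + n_not)
        100 * n_exp / (n_exp + n_not) else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(association = do.call(rbind, c(assoc_rows,
                                                make.row.names = FALSE)),
                 phenotype = do.call(rbind, c(phen_rows,
                                              make.row.names = FALSE))),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  fmt_pct <- function(v) ifelse(is.na(v), "-", sprintf("%.0f%%", v))
  cat("Evaluation against EQ statements\n")
  cat("\nPhenotype level (denominator: phenotypes with representable EQ)\n")
  p <- x$phenotype
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-10s expected %d (%s)  not expected %d  no EQ %d  total %d\n",
                p$method[i], p$expected[i], fmt_pct(p$pct_expected[i]),
                p$not_expected[i], p$no_eq[i], p$total[i]))
  }
  cat("\nAssociation level (denominator: associations with representable EQ)\n")
  a <- x$association
  for (i in seq_len(nrow(a))) {
    cat(sprintf(paste0("  %-10s exact %d  psp %d  ldsp %d  ",
                       "no match %d (%s)  no EQ %d  total %d\n"),
                a$method[i], a$exact[i], a$psp[i], a$ldsp[i],
                a$no_match[i], fmt_pct(a$pct_no_match[i]),
                a$no_eq[i], a$total[i]))
  }
  invisible(x)
}

#' Write evaluation records / summary
#'
#' Records go to a TSV `phenotype_id  tissue_id  method  category
#' matched_entity` (NA entities as `-`); the summary to a plain-text
#' rendering of [print.evaluation_summary()].
#'
#' @param records classified association data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(records, path) {
  out <- data.frame(phenotype_id = records$phenotype,
                    tissue_id = records$tissue,
                    method = records$method,
                    category = records$category,
                    matched_entity = ifelse(is.na(records$matched_entity),
                                            "-", records$matched_entity),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_evaluation
#' @param summary an `evaluation_summary`.
#' @export
write_evaluation_summary <- function(summary, path) {
  txt <- utils::capture.output(print(summary))
  writeLines(txt, path)
  invisible(path)
}
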