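# Combining the two scoring methods into one deduplicated association
# view and serializing the per-phenotype browse report (flat-file
# analogue of a results web page).

#' Combine hypergeometric and rule associations
#'
#' Outer join on the `(phenotype, tissue)` key.  Each key appears once;
#' a method that did not score the pair contributes an NA p-value
#' (rendered as `-` on disk).  Duplicate keys within the rules input
#' (both rule directions) collapse first — they share support and
#' p-value by construction.  Conflicting supporting-gene lists for the
#' same key across methods indicate the two inputs were scored on
#' different corpora and are an error.
#'
#' @param hyper association data.frame from [score_corpus()] (may be
#'   empty or NULL).
#' @param rules association data.frame from [mine_rules()] (may be
#'   empty or NULL).
#' @return data.frame with columns `phenotype`, `tissue`,
#'   `p_hypergeom`, `p_rules`, `n_support`, `supporting_genes`, sorted
#'   by (phenotype, tissue); attributes `"n_phenotypes"` and
#'   `"n_associations"`.
#' @export
combine_associations <- function(hyper, rules) {
  take <- function(x, method) {
    if (is.null(x) || !nrow(x)) {
      return(data.frame(phenotype = character(), tissue = character(),
                        p_value = numeric(), o_tp = integer(),
                        supporting_genes = character(),
                        stringsAsFactors = FALSE))
    }
    x <- x[order(x$phenotype, x$tissue, x$p_value), , drop = FALSE]
    x <- x[!duplicated(x[c("phenotype", "tissue")]), , drop = FALSE]
    x[c("phenotype", "tissue", "p_value", "o_tp", "supporting_genes")]
  }
  h <- take(hyper); r <- take(rules)
  m <- merge(h, r, by = c("phenotype", "tissue"), all = TRUE,
             suffixes = c("_h", "_r"))
  both <- !is.na(m$supporting_genes_h) & !is.na(m$supporting_genes_r)
  if (any(both & m$supporting_genes_h != m$supporting_genes_r)) {
    stop("conflicting supporting-gene lists for the same ",
         "(phenotype, tissue) key; were the methods run on the ",
         "same corpus?")
  }
  out <- data.frame(
    phenotype = m$phenotype, tissue = m$tissue,
    p_hypergeom = m$p_value_h, p_rules = m$p_value_r,
    n_support = ifelse(is.na(m$o_tp_h), m$o_tp_r, m$o_tp_h),
    supporting_genes = ifelse(is.na(m$supporting_genes_h),
                              m$supporting_genes_r, m$supporting_genes_h),
    stringsAsFactors = FALSE)
  out <- out[order(out$phenotype, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_phenotypes") <- length(unique(out$phenotype))
  attr(out, "n_associations") <- nrow(out)
  out
}

#' Write / read the combined association table
#'
#' TSV `phenotype_id  tissue_id  p_hypergeom  p_rules  n_support
#' supporting_genes` with a literal `-` for a missing method p-value.
#' P-values are printed with 17 significant digits so the
#' write-then-read round trip reproduces the table exactly.
#'
#' @param combined data.frame from [combine_associations()].
#' @param path file path.
#' @return `write_combined` returns `path` invisibly; `read_combined`
#'   the reconstructed data.frame.
#' @export
write_combined <- function(combined, path) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.17g", v))
  out <- data.frame(phenotype_id = combined$phenotype,
                    tissue_id = combined$tissue,
                    p_hypergeom = fmt(combined$p_hypergeom),
                    p_rules = fmt(combined$p_rules),
                    n_support = combined$n_support,
                    supporting_genes = combined$supporting_genes,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_combined
#' @export
read_combined <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = "character")
  out <- data.frame(
    phenotype = tab$phenotype_id, tissue = tab$tissue_id,
    p_hypergeom = suppressWarnings(
      as.numeric(ifelse(tab$p_hypergeom == "-", NA, tab$p_hypergeom))),
    p_rules = suppressWarnings(
      as.numeric(ifelse(tab$p_rules == "-", NA, tab$p_rules))),
    n_support = as.integer(tab$n_support),
    supporting_genes = tab$supporting_genes,
    stringsAsFactors = FALSE)
  attr(out, "n_phenotypes") <- length(unique(out$phenotype))
  attr(out, "n_associations") <- nrow(out)
  out
}

#' Export per-phenotype browse reports
#'
#' One markdown file per phenotype with an association, listing each
#' significant tissue with its per-method p-values (`-` when the method
#' found nothing), the phenotype's EQ entities when known, and the
#' supporting genes.  Phenotypes without associations emit no file.
#'
#' @param combined data.frame from [combine_associations()].
#' @param dir output directory (created if needed); files are named
#'   `<phenotype_id>.md` with `:` replaced by `_`.
#' @param eq optional gold map from [load_eq()].
#' @param labels optional named character vector of term labels.
#' @return character vector of written file paths, invisibly.
#' @export
browse_export <- function(combined, dir, eq = NULL, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_p <- function(v) ifelse(is.na(v), "-", sprintf("%.5e", v))
  lab <- function(id) {
    if (!is.null(labels) && !is.na(labels[id])) {
      sprintf("%s (%s)", id, labels[[id]])
    } else id
  }
  paths <- character()
  for (ph in unique(combined$phenotype)) {
    rows <- combined[combined$phenotype == ph, , drop = FALSE]
    f <- file.path(dir, paste0(gsub(":", "_", ph), ".md"))
    con <- file(f, "w", encoding = "UTF-8")
    writeLines(sprintf("# %s", lab(ph)), con)
    if (!is.null(eq) && !is.null(eq[[ph]])) {
      writeLines(sprintf("\nEQ entities: %s",
                         paste(vapply(eq[[ph]], lab, ""), collapse = ", ")),
                 con)
    }
    writeLines("\n| tissue | p (hypergeom) | p (rules) | supporting genes |",
               con)
    writeLines("|---|---|---|---|", con)
    for (i in seq_len(nrow(rows))) {
      writeLines(sprintf("| %s | %s | %s | %s |",
                         lab(rows$tissue[i]),
                         fmt_p(rows$p_hypergeom[i]),
                         fmt_p(rows$p_rules[i]),
                         rows$supporting_genes[i]), con)
    }
    close(con)
    paths <- c(paths, f)
  }
  invisible(paths)
}
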