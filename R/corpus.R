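# Reading, mapping and merging the expression / phenotype inputs into a
# single annotation corpus, the universe for all downstream counting.

.CALL_TOKENS <- c("present", "absent", "ambiguous", "no_data")

.read_table_arg <- function(x) {
  if (is.data.frame(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) stop("no such file: ", x)
  utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read binary expression calls for one source
#'
#' Parses a table of per-gene, per-tissue staining / barcode calls.  Calls
#' use the four-valued vocabulary `present`, `absent`, `ambiguous`,
#' `no_data`.  Duplicate `(gene, tissue)` rows within the source collapse
#' to a single row, with `present` winning over any other call (the
#' remaining precedence is `absent` > `ambiguous` > `no_data`, which is
#' irrelevant downstream since only `present` calls are ever counted).
#'
#' @param table a data.frame or path to a TSV with columns `gene_id`,
#'   `tissue_id`, `call` (`#` comments allowed).
#' @param source a label identifying the data source.
#' @return data.frame with columns `gene`, `tissue`, `source`, `call`;
#'   `(gene, tissue)` pairs are unique.
#' @export
read_expression_calls <- function(table, source = "source1") {
  tab <- .read_table_arg(table)
  need <- c("gene_id", "tissue_id", "call")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("expression table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  calls <- data.frame(gene = as.character(tab$gene_id),
                      tissue = as.character(tab$tissue_id),
                      source = rep(source, nrow(tab)),
                      call = as.character(tab$call),
                      stringsAsFactors = FALSE)
  bad <- which(!calls$call %in% .CALL_TOKENS)
  if (length(bad)) {
    stop("invalid call token(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": ", paste(unique(calls$call[bad]), collapse = ", "))
  }
  .collapse_calls(calls)
}

# present > absent > ambiguous > no_data within each (gene, tissue, source)
.collapse_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  prec <- match(calls$call, .CALL_TOKENS)
  o <- order(calls$gene, calls$tissue, calls$source, prec)
  calls <- calls[o, , drop = FALSE]
  keep <- !duplicated(calls[c("gene", "tissue", "source")])
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene identifier cross-reference map
#'
#' @param table data.frame or TSV path with columns `foreign_id`,
#'   `canonical_id`.
#' @return named character vector: `foreign_id -> canonical_id`.
#' @export
read_gene_map <- function(table) {
  tab <- .read_table_arg(table)
  need <- c("foreign_id", "canonical_id")
  if (!all(need %in% names(tab))) {
    stop("gene map must have columns foreign_id and canonical_id")
  }
  f <- as.character(tab$foreign_id)
  k <- as.character(tab$canonical_id)
  if (any(!nzchar(k)) || anyNA(k)) stop("canonical ids must be non-empty")
  if (anyDuplicated(f)) {
    dups <- unique(f[duplicated(f)])
    stop("foreign id(s) map to more than one row: ",
         paste(utils::head(dups, 5L), collapse = ", "))
  }
  stats::setNames(k, f)
}

#' Translate gene identifiers to the canonical namespace
#'
#' Records whose gene id has no entry in the map are dropped (a reported,
#' non-fatal outcome: the number is attached as attribute `"n_dropped"`).
#' Records sharing a canonical id after mapping merge by annotation union;
#' for expression calls the present-wins collapse is re-applied per
#' `(gene, tissue, source)`.
#'
#' @param x a data.frame with a `gene` column (expression calls or
#'   `gene`/`phenotype` annotation pairs).
#' @param map named character vector from [read_gene_map()], or a
#'   data.frame acceptable to it.
#' @return `x` with canonical gene ids, deduplicated; attribute
#'   `"n_dropped"` counts dropped input records.
#' @export
apply_gene_map <- function(x, map) {
  stopifnot(is.data.frame(x), "gene" %in% names(x))
  if (is.data.frame(map)) map <- read_gene_map(map)
  mapped <- unname(map[x$gene])
  keep <- !is.na(mapped)
  n_dropped <- sum(!keep)
  out <- x[keep, , drop = FALSE]
  out$gene <- mapped[keep]
  out <- if ("call" %in% names(out)) .collapse_calls(out) else unique(out)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Assemble the annotation corpus
#'
#' Merges expression call sets from multiple sources with per-gene
#' phenotype annotations into one `annotation_corpus`: for each gene the
#' set of panel tissues carrying a `present` call in any source
#' (union-merge across sources, so `present` in one source beats `absent`
#' in another), and the set of phenotype identifiers.  Calls on tissues
#' outside the panel are discarded and counted (attribute
#' `"n_off_panel"`).  Genes with neither expression nor phenotype
#' annotations do not appear.
#'
#' @param sources a list of call data.frames from
#'   [read_expression_calls()] (or a single data.frame).
#' @param phenotype_annotations data.frame or TSV path with columns
#'   `gene_id`/`gene` and `phenotype_id`/`phenotype`.
#' @param panel character vector of anatomy term ids (the tissue panel),
#'   non-empty and duplicate-free.
#' @return an object of class `annotation_corpus` with fields
#'   `tissue_panel`, `genes`, `tissues_of`, `phenotypes_of`.
#' @export
build_corpus <- function(sources, phenotype_annotations, panel) {
  if (is.data.frame(sources)) sources <- list(sources)
  if (!length(panel)) stop("tissue panel must be non-empty")
  panel <- as.character(panel)
  if (anyDuplicated(panel)) stop("tissue panel contains duplicates")

  calls <- do.call(rbind, lapply(sources, function(s) {
    stopifnot(is.data.frame(s))
    s[c("gene", "tissue", "call")]
  }))
  if (is.null(calls)) {
    calls <- data.frame(gene = character(), tissue = character(),
                        call = character(), stringsAsFactors = FALSE)
  }
  present <- calls[calls$call == "present", , drop = FALSE]
  on_panel <- present$tissue %in% panel
  n_off_panel <- sum(!on_panel)
  present <- unique(present[on_panel, c("gene", "tissue")])
  tissues_of <- lapply(split(present$tissue, present$gene),
                       function(v) sort(unique(v)))

  ph <- .read_table_arg(phenotype_annotations)
  nm <- names(ph)
  nm[nm == "gene_id"] <- "gene"
  nm[nm == "phenotype_id"] <- "phenotype"
  names(ph) <- nm
  if (!all(c("gene", "phenotype") %in% names(ph))) {
    stop("phenotype annotations need columns gene_id and phenotype_id")
  }
  ph <- unique(data.frame(gene = as.character(ph$gene),
                          phenotype = as.character(ph$phenotype),
                          stringsAsFactors = FALSE))
  phenotypes_of <- lapply(split(ph$phenotype, ph$gene),
                          function(v) sort(unique(v)))

  corpus <- annotation_corpus(panel, tissues_of, phenotypes_of)
  attr(corpus, "n_off_panel") <- n_off_panel
  corpus
}

#' Low-level annotation corpus constructor
#'
#' @param tissue_panel ordered character vector of panel tissue ids.
#' @param tissues_of named list: gene -> character vector of panel
#'   tissues with a present call.
#' @param phenotypes_of named list: gene -> character vector of
#'   phenotype ids.
#' @return a validated `annotation_corpus`.
#' @export
annotation_corpus <- function(tissue_panel, tissues_of = list(),
                              phenotypes_of = list()) {
  tissue_panel <- as.character(tissue_panel)
  if (!length(tissue_panel)) stop("tissue panel must be non-empty")
  if (anyDuplicated(tissue_panel)) stop("tissue panel contains duplicates")
  tissues_of <- lapply(tissues_of, function(v) sort(unique(as.character(v))))
  phenotypes_of <- lapply(phenotypes_of,
                          function(v) sort(unique(as.character(v))))
  off <- setdiff(unique(unlist(tissues_of, use.names = FALSE)), tissue_panel)
  if (length(off)) {
    stop("tissues_of refers to tissue(s) outside the panel: ",
         paste(utils::head(off, 5L), collapse = ", "))
  }
  genes <- sort(unique(c(names(tissues_of), names(phenotypes_of))))
  structure(list(tissue_panel = tissue_panel,
                 genes = genes,
                 tissues_of = tissues_of,
                 phenotypes_of = phenotypes_of),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  n_t <- sum(lengths(x$tissues_of))
  n_p <- sum(lengths(x$phenotypes_of))
  cat(sprintf(paste0("annotation_corpus: %d genes, %d panel tissues, ",
                     "%d gene-tissue links, %d gene-phenotype links\n"),
              length(x$genes), length(x$tissue_panel), n_t, n_p))
  invisible(x)
}

#' Serialize / deserialize an annotation corpus as TSV
#'
#' The on-disk format is a long table `gene_id  kind  term_id` with
#' `kind` in `{tissue, phenotype}`, preceded by a `#panel:` comment line
#' holding the ordered, comma-separated tissue panel.
#'
#' @param corpus an `annotation_corpus`.
#' @param path file path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` the
#'   reconstructed corpus.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#panel: ", paste(corpus$tissue_panel, collapse = ",")),
             con)
  writeLines("gene_id\tkind\tterm_id", con)
  for (g in corpus$genes) {
    for (t in corpus$tissues_of[[g]]) {
      writeLines(paste(g, "tissue", t, sep = "\t"), con)
    }
    for (p in corpus$phenotypes_of[[g]]) {
      writeLines(paste(g, "phenotype", p, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  panel_line <- grep("^#panel:", lines, value = TRUE)
  if (length(panel_line) != 1L) {
    stop("corpus file must contain exactly one '#panel:' line")
  }
  panel <- strsplit(trimws(sub("^#panel:", "", panel_line)), ",")[[1L]]
  tab <- utils::read.delim(text = lines, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "kind", "term_id") %in% names(tab)))
  ti <- tab[tab$kind == "tissue", , drop = FALSE]
  ph <- tab[tab$kind == "phenotype", , drop = FALSE]
  annotation_corpus(panel,
                    split(ti$term_id, ti$gene_id),
                    split(ph$term_id, ph$gene_id))
}
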