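# Expression-constrained candidate gene prioritization: restrict a
# pre-ranked disease-gene candidate list to genes expressed in the
# tissues associated with the disease's phenotypes.

#' Read / validate a ranked candidate list
#'
#' @param table data.frame or TSV path with columns `rank`, `gene_id`,
#'   `score`.  Ranks must be consecutive from 1 and scores
#'   non-increasing with rank.
#' @return data.frame with columns `rank`, `gene`, `score`.
#' @export
read_candidates <- function(table) {
  tab <- .read_table_arg(table)
  nm <- names(tab)
  nm[nm == "gene_id"] <- "gene"
  names(tab) <- nm
  if (!all(c("rank", "gene", "score") %in% names(tab))) {
    stop("candidate table needs columns rank, gene_id, score")
  }
  tab <- tab[order(tab$rank), c("rank", "gene", "score")]
  if (!identical(as.integer(tab$rank), seq_len(nrow(tab)))) {
    stop("ranks must be consecutive integers starting at 1")
  }
  if (nrow(tab) > 1 && any(diff(tab$score) > 0)) {
    stop("scores must be non-increasing with rank")
  }
  tab$gene <- as.character(tab$gene)
  rownames(tab) <- NULL
  tab
}

#' Tissues associated with a set of phenotypes
#'
#' Union of the tissues over all associations whose phenotype is in the
#' query set.
#'
#' @param phenotypes character vector of phenotype ids.
#' @param associations association data.frame (any method) with columns
#'   `phenotype` and `tissue`.
#' @return sorted character vector of tissue ids (possibly empty).
#' @export
tissues_for_phenotypes <- function(phenotypes, associations) {
  stopifnot(all(c("phenotype", "tissue") %in% names(associations)))
  sort(unique(associations$tissue[associations$phenotype %in% phenotypes]))
}

#' Re-rank candidates by expression in associated tissues
#'
#' Takes the first `top_n` candidates and keeps those with at least one
#' `present` call in any query tissue (`require_all = TRUE` demands
#' expression in every query tissue instead).  Survivors keep their
#' original relative order and scores and are renumbered 1..k; genes
#' absent from the corpus are treated as not expressed and dropped.
#'
#' @param candidates data.frame from [read_candidates()].
#' @param tissues character vector of query tissue ids.
#' @param corpus an [annotation_corpus()].
#' @param top_n number of leading candidates to consider (default 200).
#' @param require_all require expression in all query tissues rather
#'   than any.  With an empty tissue set the conjunction is vacuously
#'   true, so all corpus genes pass; the default any-mode keeps none.
#' @return data.frame with columns `rank` (new, 1..k),
#'   `original_rank`, `gene`, `score`.
#' @export
rerank <- function(candidates, tissues, corpus, top_n = 200,
                   require_all = FALSE) {
  stopifnot(inherits(corpus, "annotation_corpus"), top_n >= 1)
  stopifnot(all(c("rank", "gene", "score") %in% names(candidates)))
  top <- utils::head(candidates[order(candidates$rank), , drop = FALSE],
                     top_n)
  expressed <- vapply(top$gene, function(g) {
    tg <- corpus$tissues_of[[g]]
    if (is.null(tg) && !g %in% corpus$genes) return(FALSE)
    if (require_all) all(tissues %in% tg) else any(tissues %in% tg)
  }, logical(1))
  out <- data.frame(rank = seq_len(sum(expressed)),
                    original_rank = top$rank[expressed],
                    gene = top$gene[expressed],
                    score = top$score[expressed],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a re-ranked candidate list
#'
#' @param reranked data.frame from [rerank()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(reranked, path) {
  out <- reranked
  nm <- names(out)
  nm[nm == "gene"] <- "gene_id"
  names(out) <- nm
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
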