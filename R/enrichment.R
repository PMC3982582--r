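# Hypergeometric tissue-phenotype enrichment scoring.
#
# For a tissue annotating T of the PT corpus genes and a phenotype
# annotating P of them, the observed co-annotation count O_tp is scored
# with the hypergeometric upper tail
#
#   p_tp = P(X >= O_tp) = sum_{k = O_tp}^{min(T, P)}
#            C(P, k) C(PT - P, T - k) / C(PT, T),
#
# the probability of drawing at least O_tp phenotype-annotated genes when
# T genes are drawn without replacement from the corpus.  The sum is
# evaluated in log space via log-gamma so it stays finite at realistic
# corpus sizes (~10^4 genes); this is equivalent to a one-sided Fisher
# exact test (alternative "greater") on the pair's 2x2 table.

#' Contingency counts for a tissue-phenotype pair
#'
#' The quadruple behind every p-value: `o_tp` genes annotated with both
#' terms, `t` with the tissue, `p` with the phenotype, `pt` genes in the
#' corpus.  A gene contributes at most 1 to each count.
#'
#' @param o_tp,t,p,pt non-negative integer counts.
#' @return an object of class `contingency_counts`.
#' @export
contingency_counts <- function(o_tp, t, p, pt) {
  v <- c(o_tp = o_tp, t = t, p = p, pt = pt)
  if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
    stop("counts must be non-negative integers")
  }
  if (pt < 1) stop("corpus gene count pt must be >= 1")
  if (t > pt || p > pt) stop("t and p cannot exceed pt")
  if (o_tp > min(t, p)) stop("o_tp cannot exceed min(t, p)")
  if (o_tp < t + p - pt) stop("o_tp must be >= t + p - pt")
  structure(as.list(v), class = "contingency_counts")
}

#' Contingency counts of a pair in a corpus
#'
#' @param corpus an [annotation_corpus()]; must contain at least one gene.
#' @param tissue a panel tissue id.
#' @param phenotype a phenotype id.
#' @return a [contingency_counts()] object.
#' @export
contingency <- function(corpus, tissue, phenotype) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!tissue %in% corpus$tissue_panel) {
    stop("tissue not in panel: ", tissue)
  }
  pt <- length(corpus$genes)
  if (pt < 1L) stop("corpus is empty (pt must be >= 1)")
  has_t <- vapply(corpus$genes,
                  function(g) tissue %in% corpus$tissues_of[[g]],
                  logical(1))
  has_p <- vapply(corpus$genes,
                  function(g) phenotype %in% corpus$phenotypes_of[[g]],
                  logical(1))
  contingency_counts(sum(has_t & has_p), sum(has_t), sum(has_p), pt)
}

# Vectorized log-space tail sum; the exported wrapper validates.
.hg_upper_tail <- function(o_tp, t, p, pt) {
  mapply(function(o, t1, p1, n) {
    if (o <= max(0, t1 + p1 - n)) return(1)
    k <- o:min(t1, p1)
    lt <- lchoose(p1, k) + lchoose(n - p1, t1 - k) - lchoose(n, t1)
    m <- max(lt)
    val <- exp(m + log(sum(exp(lt - m))))
    min(max(val, .Machine$double.xmin), 1)
  }, o_tp, t, p, pt)
}

#' Hypergeometric upper-tail p-value
#'
#' Returns `P(X >= o_tp)` for `X` hypergeometric with population `pt`,
#' `p` successes and `t` draws.  Accepts either a single
#' [contingency_counts()] object or the four counts (vectorized).  The
#' value is exactly 1 when `o_tp` is at the lower support bound, lies in
#' `(0, 1]`, and is symmetric in `(t, p)`.
#'
#' @param o_tp a `contingency_counts` object, or the co-annotation count.
#' @param t,p,pt the remaining counts when `o_tp` is numeric.
#' @return numeric p-value(s) in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(o_tp, t = NULL, p = NULL, pt = NULL) {
  if (inherits(o_tp, "contingency_counts")) {
    c0 <- o_tp
    return(.hg_upper_tail(c0$o_tp, c0$t, c0$p, c0$pt))
  }
  # validate elementwise via the constructor
  invisible(mapply(contingency_counts, o_tp, t, p, pt))
  .hg_upper_tail(o_tp, t, p, pt)
}

# Logical incidence matrices genes x terms for vectorized counting.
.incidence <- function(genes, sets, terms) {
  m <- matrix(FALSE, length(genes), length(terms),
              dimnames = list(genes, terms))
  for (g in names(sets)) {
    hit <- intersect(sets[[g]], terms)
    if (length(hit)) m[g, hit] <- TRUE
  }
  m
}

#' Score all tissue-phenotype pairs of a corpus
#'
#' Applies the hypergeometric upper-tail test to every (panel tissue,
#' phenotype) pair.  Phenotypes annotating fewer than
#' `min_phenotype_count` genes are skipped entirely (low-occurrence
#' concepts distort the hypergeometric view); pairs with
#' `p_value <= p_cutoff` (inclusive) are emitted.  No multiple-testing
#' correction is applied by default, matching the raw-cutoff design;
#' `adjust = "BH"` optionally applies Benjamini-Hochberg across the
#' tested pairs before the cutoff.
#'
#' @param corpus an [annotation_corpus()] with at least one gene.
#' @param min_phenotype_count minimum number of genes a phenotype must
#'   annotate to be tested (default 10, inclusive).
#' @param p_cutoff significance cutoff on the p-value (default 0.005,
#'   inclusive).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of associations sorted by (phenotype, p_value,
#'   tissue) with columns `phenotype`, `tissue`, `method` (=
#'   `"hypergeom"`), `p_value`, `o_tp`, `t`, `p`, `pt`,
#'   `supporting_genes` (comma-joined, sorted).  Attributes
#'   `"n_pairs_tested"` and `"phenotypes_tested"` record the tested
#'   universe (used for nominal-size checks).
#' @export
score_corpus <- function(corpus, min_phenotype_count = 10, p_cutoff = 0.005,
                         adjust = c("none", "BH")) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  adjust <- match.arg(adjust)
  genes <- corpus$genes
  pt <- length(genes)
  if (pt < 1L) stop("corpus is empty")
  phenos <- sort(unique(unlist(corpus$phenotypes_of, use.names = FALSE)))
  p_counts <- vapply(phenos, function(ph) {
    sum(vapply(corpus$phenotypes_of,
               function(v) ph %in% v, logical(1)))
  }, integer(1))
  phenos <- phenos[p_counts >= min_phenotype_count]

  empty <- data.frame(phenotype = character(), tissue = character(),
                      method = character(), p_value = numeric(),
                      o_tp = integer(), t = integer(), p = integer(),
                      pt = integer(), supporting_genes = character(),
                      stringsAsFactors = FALSE)
  if (!length(phenos)) {
    attr(empty, "n_pairs_tested") <- 0L
    attr(empty, "phenotypes_tested") <- character()
    return(empty)
  }

  Tm <- .incidence(genes, corpus$tissues_of, corpus$tissue_panel)
  Pm <- .incidence(genes, corpus$phenotypes_of, phenos)
  O <- crossprod(Tm, Pm)                       # tissues x phenotypes
  t_counts <- colSums(Tm)
  p_counts <- colSums(Pm)

  res <- expand.grid(tissue = corpus$tissue_panel, phenotype = phenos,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$o_tp <- as.integer(O[cbind(res$tissue, res$phenotype)])
  res$t <- as.integer(t_counts[res$tissue])
  res$p <- as.integer(p_counts[res$phenotype])
  res$pt <- pt
  res$p_value <- .hg_upper_tail(res$o_tp, res$t, res$p, res$pt)
  n_tested <- nrow(res)
  if (adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  }
  res <- res[res$p_value <= p_cutoff, , drop = FALSE]

  if (nrow(res)) {
    res$supporting_genes <- vapply(seq_len(nrow(res)), function(i) {
      paste(genes[Tm[, res$tissue[i]] & Pm[, res$phenotype[i]]],
            collapse = ",")
    }, character(1))
  } else {
    res$supporting_genes <- character(0)
  }
  res$method <- rep("hypergeom", nrow(res))
  res <- res[order(res$phenotype, res$p_value, res$tissue),
             c("phenotype", "tissue", "method", "p_value",
               "o_tp", "t", "p", "pt", "supporting_genes")]
  rownames(res) <- NULL
  attr(res, "n_pairs_tested") <- n_tested
  attr(res, "phenotypes_tested") <- phenos
  res
}

#' Write / read an association table
#'
#' TSV with columns `phenotype_id`, `tissue_id`, `method`, `p_value`
#' (6 significant digits, scientific notation), `o_tp`, `t`, `p`, `pt`,
#' `supporting_genes` (comma-separated, sorted) and, for rule
#' associations, `antecedent` and `confidence`.
#'
#' @param assoc association data.frame from [score_corpus()] or
#'   [mine_rules()].
#' @param path file path.
#' @return `write_associations` returns `path` invisibly;
#'   `read_associations` the parsed data.frame with internal column
#'   names.
#' @export
write_associations <- function(assoc, path) {
  out <- assoc
  out$p_value <- sprintf("%.5e", out$p_value)
  if ("confidence" %in% names(out)) {
    out$confidence <- sprintf("%.6f", out$confidence)
  }
  nm <- names(out)
  nm[nm == "phenotype"] <- "phenotype_id"
  nm[nm == "tissue"] <- "tissue_id"
  names(out) <- nm
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(supporting_genes = "character"))
  nm <- names(tab)
  nm[nm == "phenotype_id"] <- "phenotype"
  nm[nm == "tissue_id"] <- "tissue"
  names(tab) <- nm
  tab
}
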