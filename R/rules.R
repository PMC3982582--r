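# Apriori-style association-rule mining between tissue items and
# phenotype items, with genes as the transactions.
#
# Rule shape is restricted to one antecedent and one consequent item of
# different tags (one tissue, one phenotype); the classical apriori
# pruning (only individually frequent items can form a frequent pair) is
# kept so behavior matches the level-wise algorithm on this restriction.
# Support is an absolute gene count; confidence is support / antecedent
# count.  The rule p-value is the one-sided Fisher / hypergeometric
# upper-tail p of the pair's 2x2 table over all transactions, so both
# scoring methods are commensurable and share one oracle.

.TISSUE_TAG <- "tissue:"
.PHENO_TAG <- "phenotype:"

#' Convert a corpus to tagged transactions
#'
#' One transaction per corpus gene; its items are the gene's panel
#' tissues and phenotypes, tag-prefixed (`tissue:`/`phenotype:`) so the
#' two namespaces cannot collide.  Genes without annotations yield empty
#' transactions, which are retained (they count towards the transaction
#' total but support nothing).
#'
#' @param corpus an [annotation_corpus()].
#' @return named list (by gene) of character item vectors.
#' @export
corpus_to_transactions <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  out <- lapply(corpus$genes, function(g) {
    tis <- corpus$tissues_of[[g]]
    phe <- corpus$phenotypes_of[[g]]
    as.character(c(if (length(tis)) paste0(.TISSUE_TAG, tis),
                   if (length(phe)) paste0(.PHENO_TAG, phe)))
  })
  names(out) <- corpus$genes
  out
}

.item_tag <- function(items) {
  ifelse(startsWith(items, .TISSUE_TAG), "tissue",
         ifelse(startsWith(items, .PHENO_TAG), "phenotype", NA_character_))
}

.item_name <- function(items) {
  sub(paste0("^(", .TISSUE_TAG, "|", .PHENO_TAG, ")"), "", items)
}

#' Frequent mixed-tag item pairs
#'
#' Level-wise search: item supports are counted first and only items
#' individually reaching `min_support_abs` can enter a candidate pair
#' (support anti-monotonicity); candidate (tissue-item, phenotype-item)
#' pairs are then recounted over the transactions and kept iff their
#' co-occurrence count reaches `min_support_abs`.
#'
#' @param transactions list of tagged item vectors from
#'   [corpus_to_transactions()].
#' @param min_support_abs minimum absolute co-occurrence count
#'   (default 6, inclusive).
#' @return data.frame with columns `tissue`, `phenotype`,
#'   `support_abs`, sorted by (tissue, phenotype).
#' @export
frequent_pairs <- function(transactions, min_support_abs = 6) {
  stopifnot(min_support_abs >= 1)
  items <- lapply(transactions, unique)
  supp <- table(unlist(items, use.names = FALSE))
  frequent <- names(supp)[supp >= min_support_abs]
  f_tis <- frequent[.item_tag(frequent) == "tissue"]
  f_phe <- frequent[.item_tag(frequent) == "phenotype"]
  empty <- data.frame(tissue = character(), phenotype = character(),
                      support_abs = integer(), stringsAsFactors = FALSE)
  if (!length(f_tis) || !length(f_phe)) return(empty)

  pair_rows <- lapply(items, function(it) {
    ti <- intersect(it, f_tis)
    ph <- intersect(it, f_phe)
    if (!length(ti) || !length(ph)) return(NULL)
    expand.grid(tissue = ti, phenotype = ph,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  pair_rows <- do.call(rbind, pair_rows)
  if (is.null(pair_rows)) return(empty)
  key <- paste(pair_rows$tissue, pair_rows$phenotype, sep = "\r")
  counts <- table(key)
  keep <- counts[counts >= min_support_abs]
  if (!length(keep)) return(empty)
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  out <- data.frame(tissue = .item_name(vapply(parts, `[`, "", 1L)),
                    phenotype = .item_name(vapply(parts, `[`, "", 2L)),
                    support_abs = as.integer(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tissue, out$phenotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rule p-value for a tissue-phenotype pair
#'
#' The one-sided Fisher exact (hypergeometric upper-tail) p-value of the
#' pair's 2x2 table over the transaction universe, delegating to
#' [hypergeom_upper_tail()].  Identical for both rule directions over
#' the same pair.
#'
#' @param support_abs co-occurrence count of the pair.
#' @param tissue_count,phenotype_count item supports.
#' @param n_transactions number of transactions (corpus genes).
#' @return p-value in `(0, 1]`.
#' @export
rule_pvalue <- function(support_abs, tissue_count, phenotype_count,
                        n_transactions) {
  hypergeom_upper_tail(support_abs, tissue_count, phenotype_count,
                       n_transactions)
}

#' Directed rules from frequent pairs
#'
#' For each frequent mixed pair both directed rules (tissue -> phenotype
#' and phenotype -> tissue) are formed; a rule is kept iff its confidence
#' `support / |antecedent|` reaches `min_confidence` (inclusive).  The
#' two directions share `support_abs` and `p_value` and may differ only
#' in confidence.
#'
#' @param pairs data.frame from [frequent_pairs()].
#' @param transactions the transaction list the pairs were mined from.
#' @param min_confidence minimum confidence in `(0, 1]` (default 0.9).
#' @return data.frame sorted by (antecedent, consequent) with columns
#'   `antecedent`, `consequent`, `antecedent_tag`, `tissue`,
#'   `phenotype`, `support_abs`, `confidence`, `p_value`.
#' @export
extract_rules <- function(pairs, transactions, min_confidence = 0.9) {
  stopifnot(min_confidence > 0, min_confidence <= 1)
  items <- lapply(transactions, unique)
  supp <- table(unlist(items, use.names = FALSE))
  n <- length(transactions)
  empty <- data.frame(antecedent = character(), consequent = character(),
                      antecedent_tag = character(), tissue = character(),
                      phenotype = character(), support_abs = integer(),
                      confidence = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ti <- pairs$tissue[i]; ph <- pairs$phenotype[i]
    s <- pairs$support_abs[i]
    t_cnt <- as.integer(supp[[paste0(.TISSUE_TAG, ti)]])
    p_cnt <- as.integer(supp[[paste0(.PHENO_TAG, ph)]])
    pv <- rule_pvalue(s, t_cnt, p_cnt, n)
    rbind(
      data.frame(antecedent = ti, consequent = ph,
                 antecedent_tag = "tissue", tissue = ti, phenotype = ph,
                 support_abs = s, confidence = s / t_cnt, p_value = pv,
                 stringsAsFactors = FALSE),
      data.frame(antecedent = ph, consequent = ti,
                 antecedent_tag = "phenotype", tissue = ti, phenotype = ph,
                 support_abs = s, confidence = s / p_cnt, p_value = pv,
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[out$confidence >= min_confidence, , drop = FALSE]
  out <- out[order(out$antecedent, out$consequent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine rule associations from a corpus
#'
#' Runs [corpus_to_transactions()], [frequent_pairs()] and
#' [extract_rules()] and reshapes the kept rules into the association
#' table schema shared with [score_corpus()].  By default the two
#' directions of a pair are deduplicated to one row keeping the
#' max-confidence direction (ties prefer the tissue-antecedent rule);
#' `both_directions = TRUE` keeps both.
#'
#' @param corpus an [annotation_corpus()].
#' @param min_support_abs absolute support threshold (default 6).
#' @param min_confidence confidence threshold (default 0.9).
#' @param both_directions keep both directed rules per pair?
#' @return association data.frame with columns `phenotype`, `tissue`,
#'   `method` (= `"rules"`), `p_value`, `o_tp`, `t`, `p`, `pt`,
#'   `supporting_genes`, `antecedent`, `confidence`, sorted by
#'   (phenotype, p_value, tissue).
#' @export
mine_rules <- function(corpus, min_support_abs = 6, min_confidence = 0.9,
                       both_directions = FALSE) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  tr <- corpus_to_transactions(corpus)
  rules <- extract_rules(frequent_pairs(tr, min_support_abs), tr,
                         min_confidence)
  if (!both_directions && nrow(rules)) {
    key <- paste(rules$tissue, rules$phenotype, sep = "\r")
    pref <- order(key, -rules$confidence,
                  rules$antecedent_tag != "tissue")
    rules <- rules[pref, , drop = FALSE]
    rules <- rules[!duplicated(paste(rules$tissue, rules$phenotype,
                                     sep = "\r")), , drop = FALSE]
  }
  if (!nrow(rules)) {
    return(data.frame(phenotype = character(), tissue = character(),
                      method = character(), p_value = numeric(),
                      o_tp = integer(), t = integer(), p = integer(),
                      pt = integer(), supporting_genes = character(),
                      antecedent = character(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  }
  items <- lapply(tr, unique)
  support_genes <- vapply(seq_len(nrow(rules)), function(i) {
    key_t <- paste0(.TISSUE_TAG, rules$tissue[i])
    key_p <- paste0(.PHENO_TAG, rules$phenotype[i])
    hit <- vapply(items, function(it) key_t %in% it && key_p %in% it,
                  logical(1))
    paste(sort(names(tr)[hit]), collapse = ",")
  }, character(1))
  supp <- table(unlist(items, use.names = FALSE))
  out <- data.frame(
    phenotype = rules$phenotype,
    tissue = rules$tissue,
    method = rep("rules", nrow(rules)),
    p_value = rules$p_value,
    o_tp = rules$support_abs,
    t = as.integer(supp[paste0(.TISSUE_TAG, rules$tissue)]),
    p = as.integer(supp[paste0(.PHENO_TAG, rules$phenotype)]),
    pt = rep(length(tr), nrow(rules)),
    supporting_genes = support_genes,
    antecedent = rules$antecedent,
    confidence = rules$confidence,
    stringsAsFactors = FALSE)
  out <- out[order(out$phenotype, out$p_value, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
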