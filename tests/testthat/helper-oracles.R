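# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (counting, fixpoint iteration, brute-force
# enumeration) and share no code with the package internals.

# Upper-tail probability by combinatorial counting: number of t-subsets
# of a pt universe whose overlap with a fixed p-subset is >= o, divided
# by the total number of t-subsets.  Exact in double precision for the
# small pt used in tests.
oracle_tail_count <- function(o, t, p, pt) {
  ks <- max(0, t + p - pt):min(t, p)
  ks <- ks[ks >= o]
  if (!length(ks)) ks <- integer(0)
  num <- sum(choose(p, ks) * choose(pt - p, t - ks))
  tot <- choose(pt, t)
  if (o <= max(0, t + p - pt)) 1 else num / tot
}

# Literal draw enumeration: generate every t-subset of 1..pt and count
# those overlapping 1..p in at least o elements.  Only for small pt.
oracle_tail_subsets <- function(o, t, p, pt) {
  if (t == 0) return(if (o <= 0) 1 else 0)
  subsets <- utils::combn(pt, t)
  overlaps <- colSums(subsets <= p)
  mean(overlaps >= o)
}

# One-sided Fisher exact test on the 2x2 table implied by the counts.
oracle_fisher <- function(o, t, p, pt) {
  m <- matrix(c(o, t - o, p - o, pt - t - p + o), 2)
  stats::fisher.test(m, alternative = "greater")$p.value
}

# Ancestors by iterated single-step parent expansion until fixpoint.
oracle_ancestors <- function(term, edges) {
  frontier <- term
  anc <- character()
  repeat {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(nxt, anc)
    if (!length(new)) break
    anc <- c(anc, new)
    frontier <- new
  }
  sort(setdiff(anc, term))
}

# Exhaustive path search: is there a directed child->parent path a -> b?
oracle_reachable <- function(a, b, edges) {
  b %in% oracle_ancestors(a, edges)
}

# Random DAG on n terms: edges always point from a higher-index child to
# a lower-index parent, so acyclicity holds by construction.
random_dag <- function(n_terms, n_edges, seed) {
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n_terms))
  child_i <- sample(2:n_terms, n_edges, replace = TRUE)
  parent_i <- vapply(child_i, function(ci) sample.int(ci - 1L, 1L),
                     integer(1))
  edges <- unique(data.frame(
    child = terms[child_i],
    relation = sample(c("is_a", "part_of"), n_edges, replace = TRUE),
    parent = terms[parent_i], stringsAsFactors = FALSE))
  list(terms = terms, edges = edges,
       n_terms = length(unique(c(edges$child, edges$parent))),
       n_edges = nrow(edges))
}

# Brute-force directed rule search over ALL mixed-tag item pairs (no
# apriori pruning): support and confidence computed by direct counting.
oracle_rules <- function(transactions, min_support, min_confidence) {
  items <- lapply(transactions, unique)
  all_items <- sort(unique(unlist(items, use.names = FALSE)))
  tis <- all_items[startsWith(all_items, "tissue:")]
  phe <- all_items[startsWith(all_items, "phenotype:")]
  supp_of <- function(set) {
    sum(vapply(items, function(it) all(set %in% it), logical(1)))
  }
  rows <- list()
  for (a in tis) for (b in phe) {
    s <- supp_of(c(a, b))
    if (s < min_support) next
    for (dir in 1:2) {
      ante <- if (dir == 1) a else b
      cons <- if (dir == 1) b else a
      conf <- s / supp_of(ante)
      if (conf >= min_confidence) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = sub("^(tissue:|phenotype:)", "", ante),
          consequent = sub("^(tissue:|phenotype:)", "", cons),
          support_abs = s, confidence = conf, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support_abs = integer(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$antecedent, out$consequent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random tagged transaction sets for rule-mining property tests.
random_transactions <- function(n_items, n_trans, seed) {
  set.seed(seed)
  n_tis <- max(1L, n_items %/% 2L)
  items <- c(paste0("tissue:t", seq_len(n_tis)),
             paste0("phenotype:p", seq_len(n_items - n_tis)))
  rate <- stats::runif(length(items), 0.02, 0.35)
  out <- lapply(seq_len(n_trans), function(i) {
    items[stats::runif(length(items)) < rate]
  })
  names(out) <- sprintf("g%03d", seq_len(n_trans))
  out
}

# Random valid contingency quadruple with pt <= max_pt.
random_quadruple <- function(max_pt) {
  pt <- sample(1:max_pt, 1)
  t <- sample(0:pt, 1)
  p <- sample(0:pt, 1)
  lo <- max(0, t + p - pt)
  hi <- min(t, p)
  o <- if (lo == hi) lo else sample(lo:hi, 1)
  c(o = o, t = t, p = p, pt = pt)
}
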