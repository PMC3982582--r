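# Term graphs for the anatomy / phenotype vocabularies.
#
# Only is_a and part_of edges are represented; both are treated as
# ancestor-propagating and may interleave freely along a path.  All
# downstream classification assumes a partial order, so cyclic input is a
# hard error.

.ONTOLOGY_RELATIONS <- c("is_a", "part_of")

#' Construct an ontology graph from an edge table
#'
#' An `ontology_graph` is a directed acyclic term graph whose edges point
#' from a child term to a parent term via `is_a` or `part_of`.  The
#' transitive ancestor closure is precomputed at construction time, so
#' [ancestors()] and [relate()] are O(1) lookups.
#'
#' @param edges data.frame with columns `child`, `relation`, `parent`.
#'   Relations must be `"is_a"` or `"part_of"`.  Duplicate edges collapse.
#' @param labels optional named character vector mapping term ids to
#'   human-readable names.  Terms appearing only in `labels` become
#'   isolated nodes.
#' @return an object of class `ontology_graph` with fields `terms`
#'   (character vector), `edges` (data.frame), `labels`, and the
#'   precomputed `ancestors` list.
#' @seealso [load_ontology()] to read the TSV/OBO serializations.
#' @export
ontology_graph <- function(edges = NULL, labels = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(child = character(), relation = character(),
                        parent = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges))
  need <- c("child", "relation", "parent")
  if (!all(need %in% names(edges))) {
    stop("edge table must have columns child, relation, parent")
  }
  edges <- unique(edges[need])
  edges[] <- lapply(edges, as.character)
  if (nrow(edges)) {
    bad <- setdiff(unique(edges$relation), .ONTOLOGY_RELATIONS)
    if (length(bad)) {
      stop("unknown relation token(s): ", paste(bad, collapse = ", "),
           " (expected is_a or part_of)")
    }
    if (anyNA(edges$child) || anyNA(edges$parent) ||
        any(!nzchar(edges$child)) || any(!nzchar(edges$parent))) {
      stop("edge endpoints must be non-empty term identifiers")
    }
  }
  if (!is.null(labels)) {
    labels <- stats::setNames(as.character(labels), names(labels))
    if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
      stop("labels must be a named character vector")
    }
  }
  terms <- sort(unique(c(edges$child, edges$parent, names(labels))))
  anc <- .transitive_ancestors(terms, edges)
  structure(list(terms = terms, edges = edges, labels = labels,
                 ancestors = anc),
            class = "ontology_graph")
}

# Kahn topological processing: a node's ancestor set is the union of its
# parents and their ancestor sets, so parents are resolved first.  Nodes
# left unprocessed witness a cycle, which is extracted and reported.
.transitive_ancestors <- function(terms, edges) {
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) anc[[t]] <- character()
  if (!nrow(edges)) return(anc)
  parents_of <- split(edges$parent, edges$child)
  children_of <- split(edges$child, edges$parent)
  n_parents <- stats::setNames(integer(length(terms)), terms)
  np <- vapply(parents_of, function(p) length(unique(p)), integer(1))
  n_parents[names(np)] <- np
  queue <- terms[n_parents == 0L]
  done <- character()
  while (length(queue)) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    done <- c(done, node)
    ps <- unique(parents_of[[node]])
    if (length(ps)) {
      anc[[node]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
    }
    for (ch in unique(children_of[[node]])) {
      n_parents[[ch]] <- n_parents[[ch]] - 1L
      if (n_parents[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(done) < length(terms)) {
    remaining <- setdiff(terms, done)
    stop("cycle detected in ontology: ",
         paste(.find_cycle(remaining, parents_of), collapse = " -> "))
  }
  anc
}

# Walk parent links within the cyclic subgraph until a term repeats.
.find_cycle <- function(remaining, parents_of) {
  node <- remaining[[1L]]
  path <- character()
  while (!(node %in% path)) {
    path <- c(path, node)
    nxt <- intersect(parents_of[[node]], remaining)
    node <- nxt[[1L]]
  }
  c(path[which(path == node)[1L]:length(path)], node)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d edges (%d is_a, %d part_of)\n",
              length(x$terms), nrow(x$edges),
              sum(x$edges$relation == "is_a"),
              sum(x$edges$relation == "part_of")))
  invisible(x)
}

#' Load an ontology from a TSV edge list or an OBO 1.2 file
#'
#' The canonical serialization is a 3-column TSV with header
#' `child_id  relation  parent_id` (tab-separated, `#` comments, UTF-8)
#' whose relation tokens are exactly `is_a` or `part_of`; unknown tokens
#' are an error.  As a convenience an OBO 1.2 file (recognized by its
#' `format-version:` header or a `.obo` extension) is normalized into the
#' same edge list: only `[Term]` stanzas are read, `is_a:` and
#' `relationship: part_of` edges are kept, obsolete terms are skipped and
#' other relationship types are ignored with a count stored in the
#' `"skipped_relations"` attribute.
#'
#' @param x path to a TSV or OBO file, or a data.frame with columns
#'   `child_id`/`child`, `relation`, `parent_id`/`parent`.
#' @return an [ontology_graph()].
#' @export
load_ontology <- function(x) {
  if (is.data.frame(x)) {
    nm <- names(x)
    nm[nm == "child_id"] <- "child"
    nm[nm == "parent_id"] <- "parent"
    names(x) <- nm
    return(ontology_graph(x))
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) stop("no such file: ", x)
  lines <- readLines(x, encoding = "UTF-8", warn = FALSE)
  is_obo <- grepl("\\.obo$", x, ignore.case = TRUE) ||
    any(startsWith(lines, "format-version:")) ||
    any(startsWith(lines, "[Term]"))
  if (is_obo) return(.parse_obo(lines))
  tab <- utils::read.delim(text = lines, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("child_id", "relation", "parent_id")
  if (!all(need %in% names(tab))) {
    stop("ontology TSV must have columns: ", paste(need, collapse = ", "))
  }
  load_ontology(tab)
}

.parse_obo <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  in_term <- FALSE
  cur_id <- NA_character_
  obsolete <- FALSE
  child <- character(); relation <- character(); parent <- character()
  labels <- character()
  skipped <- 0L
  flushable <- function(line) startsWith(line, "[")
  strip_comment <- function(v) sub("\\s*!.*$", "", v)
  for (line in lines) {
    if (flushable(line)) {
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_
      obsolete <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (startsWith(line, "id:")) {
      cur_id <- trimws(sub("^id:", "", line))
    } else if (startsWith(line, "is_obsolete:")) {
      obsolete <- grepl("true", line)
    } else if (is.na(cur_id) || obsolete) {
      next
    } else if (startsWith(line, "name:")) {
      labels[cur_id] <- trimws(sub("^name:", "", line))
    } else if (startsWith(line, "is_a:")) {
      tgt <- trimws(strip_comment(sub("^is_a:", "", line)))
      child <- c(child, cur_id); relation <- c(relation, "is_a")
      parent <- c(parent, tgt)
    } else if (startsWith(line, "relationship:")) {
      body <- trimws(strip_comment(sub("^relationship:", "", line)))
      toks <- strsplit(body, "\\s+")[[1L]]
      if (length(toks) >= 2L && toks[[1L]] == "part_of") {
        child <- c(child, cur_id); relation <- c(relation, "part_of")
        parent <- c(parent, toks[[2L]])
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  g <- ontology_graph(
    data.frame(child = child, relation = relation, parent = parent,
               stringsAsFactors = FALSE),
    labels = if (length(labels)) labels else NULL)
  attr(g, "skipped_relations") <- skipped
  g
}

.check_term <- function(term, graph) {
  if (!term %in% graph$terms) stop("unknown ontology term: ", term)
}

#' Transitive ancestors of a term
#'
#' All terms reachable from `term` by following any interleaving of
#' `is_a`/`part_of` edges towards parents.  The term itself is excluded;
#' "identical" is a separate [relate()] category.
#'
#' @param term a term identifier present in the graph.
#' @param graph an [ontology_graph()].
#' @return character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(term, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  .check_term(term, graph)
  graph$ancestors[[term]]
}

#' Relation category of an ordered term pair
#'
#' Classifies `(a, b)` as exactly one of `identical` (equal ids),
#' `first_below_second` (`b` is a transitive ancestor of `a`),
#' `second_below_first` (`a` is a transitive ancestor of `b`), or
#' `unrelated`.  Acyclicity guarantees the two "below" cases are mutually
#' exclusive for distinct terms.
#'
#' @inheritParams ancestors
#' @param a,b term identifiers present in the graph.
#' @return one of `"identical"`, `"first_below_second"`,
#'   `"second_below_first"`, `"unrelated"`.
#' @export
relate <- function(a, b, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  .check_term(a, graph)
  .check_term(b, graph)
  if (a == b) return("identical")
  if (b %in% graph$ancestors[[a]]) return("first_below_second")
  if (a %in% graph$ancestors[[b]]) return("second_below_first")
  "unrelated"
}

#' Write an ontology graph as a TSV edge list
#'
#' @param graph an [ontology_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  out <- graph$edges
  names(out) <- c("child_id", "relation", "parent_id")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
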