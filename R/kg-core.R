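#' Construct a KnowledgeGraph
#'
#' Builds a validated [KnowledgeGraph-class] from a node table and a triple
#' table. Duplicate (head, relation, tail) rows are merged, taking the union
#' of their supporting-article identifiers, so the resulting triple multiset
#' is independent of input row order.
#'
#' @param nodes data.frame with character columns \code{cui}, \code{name},
#'   \code{node_type}.
#' @param triples data.frame with character columns \code{head},
#'   \code{relation}, \code{tail} and optionally \code{pmids} (comma-joined
#'   article identifiers; empty string for none).
#' @param typeVocabulary semantic-type codes the graph admits; defaults to
#'   the types present in \code{nodes}.
#' @param relationVocabulary relation labels the graph admits; defaults to
#'   the relations present in \code{triples}.
#' @return a [KnowledgeGraph-class] object.
#' @examples
#' nodes <- data.frame(cui = c("C1", "C2"), name = c("a", "b"),
#'                     node_type = c("aapp", "dsyn"))
#' trips <- data.frame(head = "C1", relation = "affects", tail = "C2",
#'                     pmids = "123")
#' KnowledgeGraph(nodes, trips)
#' @export
KnowledgeGraph <- function(nodes, triples,
                           typeVocabulary = NULL, relationVocabulary = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  for (cl in intersect(c("cui", "name", "node_type"), names(nodes))) {
    nodes[[cl]] <- as.character(nodes[[cl]])
  }
  if (!nrow(triples)) {
    triples <- data.frame(head = character(0), relation = character(0),
                          tail = character(0), pmids = character(0),
                          stringsAsFactors = FALSE)
  }
  if (is.null(triples$pmids)) triples$pmids <- ""
  triples$pmids[is.na(triples$pmids)] <- ""
  for (cl in c("head", "relation", "tail", "pmids")) {
    triples[[cl]] <- as.character(triples[[cl]])
  }
  triples <- mergeDuplicateTriples(triples)
  if (is.null(typeVocabulary)) typeVocabulary <- sort(unique(nodes$node_type))
  if (is.null(relationVocabulary)) {
    relationVocabulary <- sort(unique(triples$relation))
  }
  new("KnowledgeGraph",
      nodes = nodes[, c("cui", "name", "node_type")],
      triples = triples[, c("head", "relation", "tail", "pmids")],
      typeVocabulary = typeVocabulary,
      relationVocabulary = relationVocabulary)
}

# Merge duplicate (head, relation, tail) rows, pmid union, deterministic
# order (head, relation, tail).
mergeDuplicateTriples <- function(triples) {
  if (!nrow(triples)) return(triples)
  key <- paste(triples$head, triples$relation, triples$tail, sep = "\r")
  if (anyDuplicated(key)) {
    pm <- lapply(split(triples$pmids, key), function(v) {
      joinPmids(unlist(lapply(v, splitPmids)))
    })
    first <- !duplicated(key)
    triples <- triples[first, , drop = FALSE]
    triples$pmids <- unlist(pm[key[first]], use.names = FALSE)
  } else {
    triples$pmids <- vapply(triples$pmids,
                            function(p) joinPmids(splitPmids(p)), "")
  }
  o <- order(triples$head, triples$relation, triples$tail, method = "radix")
  triples <- triples[o, , drop = FALSE]
  rownames(triples) <- NULL
  triples
}

#' @rdname kgAccessors
#' @param x a \linkS4class{KnowledgeGraph}.
#' @name kgAccessors
#' @title Accessors for KnowledgeGraph slots
#' @return \code{kgNodes}/\code{kgTriples} return data.frames;
#'   the vocabulary accessors return character vectors.
#' @aliases kgNodes kgTriples typeVocabulary relationVocabulary
#' @export
setMethod("kgNodes", "KnowledgeGraph", function(x) x@nodes)

#' @rdname kgAccessors
#' @export
setMethod("kgTriples", "KnowledgeGraph", function(x) x@triples)

#' @rdname kgAccessors
#' @export
setMethod("typeVocabulary", "KnowledgeGraph", function(x) x@typeVocabulary)

#' @rdname kgAccessors
#' @export
setMethod("relationVocabulary", "KnowledgeGraph", function(x) x@relationVocabulary)

#' Load a knowledge graph from node and edge tables
#'
#' Reads the package's TSV dialect: the node table has header
#' \code{cui name node_type}; the edge table has header
#' \code{head relation tail pmids}, with \code{pmids} a comma-joined
#' (possibly empty) list. UTF-8, no quoting; literal tabs are forbidden
#' inside fields, so every data row must have exactly as many fields as the
#' header. Duplicate triples are merged with pmid union, so the loaded
#' graph does not depend on row order.
#'
#' @param nodeFile,edgeFile paths to the two TSV tables.
#' @return a [KnowledgeGraph-class].
#' @seealso [writeKnowledgeGraph()]
#' @export
loadKnowledgeGraph <- function(nodeFile, edgeFile) {
  nodes <- readStrictTSV(nodeFile, c("cui", "name", "node_type"))
  triples <- readStrictTSV(edgeFile, c("head", "relation", "tail", "pmids"))
  dangling <- setdiff(unique(c(triples$head, triples$tail)), nodes$cui)
  if (length(dangling)) {
    rows <- which(triples$head %in% dangling | triples$tail %in% dangling)
    kgStop("kgIntegrityError",
           "edge table references unknown cui(s) %s (first offending row %d)",
           paste(utils::head(dangling, 5L), collapse = ", "), rows[1L])
  }
  KnowledgeGraph(nodes, triples)
}

# Strict TSV reader: exact header, exact field count, line numbers in errors.
readStrictTSV <- function(path, columns) {
  if (!file.exists(path)) kgStop("kgIOError", "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) kgStop("kgParseError", "%s: empty file, header expected", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1L]]
  if (!identical(hdr, columns)) {
    kgStop("kgParseError", "%s: header must be '%s', found '%s'",
           path, paste(columns, collapse = "\t"), paste(hdr, collapse = "\t"))
  }
  body <- fields[-1L]
  # a trailing empty pmids field is dropped by strsplit; restore it
  n <- length(columns)
  if (columns[n] == "pmids") {
    short <- lengths(body) == n - 1L
    body[short] <- lapply(body[short], function(f) c(f, ""))
  }
  lens <- lengths(body)
  bad <- which(lens != n)
  if (length(bad)) {
    kgStop("kgParseError", "%s: line %d has %d fields, expected %d",
           path, bad[1L] + 1L, lens[bad[1L]], n)
  }
  out <- as.data.frame(do.call(rbind, c(body, list(deparse.level = 0))),
                       stringsAsFactors = FALSE)
  if (!length(body)) {
    out <- as.data.frame(matrix(character(0), ncol = n),
                         stringsAsFactors = FALSE)
  }
  names(out) <- columns
  out
}

#' Write a knowledge graph to node and edge TSV tables
#'
#' Inverse of [loadKnowledgeGraph()]: emits the same TSV dialect, rows in
#' the graph's canonical order, so write/load round-trips exactly.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param nodeFile,edgeFile output paths.
#' @return invisibly, the two paths.
#' @export
writeKnowledgeGraph <- function(graph, nodeFile, edgeFile) {
  writeTSV(kgNodes(graph), nodeFile)
  writeTSV(kgTriples(graph), edgeFile)
  invisible(c(nodeFile, edgeFile))
}

writeTSV <- function(df, path) {
  bad <- vapply(df, function(col) any(grepl("\t", col, fixed = TRUE)), logical(1L))
  if (any(bad)) {
    kgStop("kgIOError", "literal tab inside field(s): %s",
           paste(names(df)[bad], collapse = ", "))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(unname(as.list(df)), sep = "\t"))),
             con, useBytes = TRUE)
}

#' Nodes reachable within a hop limit
#'
#' All concept nodes reachable from \code{cui} in at most \code{depth}
#' hops, treating every triple as traversable in both directions (search
#' depth counts connections, not edge directions). The start node itself is
#' excluded.
#'
#' @param x a [KnowledgeGraph-class].
#' @param cui start concept identifier.
#' @param depth maximum number of hops (\eqn{\ge 1}).
#' @return character vector of reachable cuis (sorted).
#' @examples
#' g <- KnowledgeGraph(
#'   data.frame(cui = c("a", "b", "c"), name = c("a", "b", "c"),
#'              node_type = "aapp"),
#'   data.frame(head = c("a", "b"), relation = "affects",
#'              tail = c("b", "c"), pmids = ""))
#' neighborhood(g, "a", 1)  # "b"
#' neighborhood(g, "a", 2)  # "b" "c"
#' @rdname neighborhood
#' @export
setMethod("neighborhood", "KnowledgeGraph", function(x, cui, depth = 1L) {
  if (!cui %in% x@nodes$cui) {
    kgStop("kgLookupError", "unknown cui: %s", cui)
  }
  stopifnot(depth >= 1L)
  ig <- asIgraph(x)
  nb <- igraph::ego(ig, order = depth, nodes = cui, mode = "all", mindist = 1L)
  sort(names(nb[[1L]]))
})

# Undirected igraph view used for hop-count reachability.
asIgraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph@triples[, c("head", "tail")],
    directed = FALSE,
    vertices = graph@nodes$cui
  )
}

#' Nodes of a given semantic type
#'
#' @param x a [KnowledgeGraph-class].
#' @param nodeType a semantic-type code declared in the graph's vocabulary.
#' @return character vector of cuis of that type (sorted; possibly empty).
#' @rdname nodesOfType
#' @export
setMethod("nodesOfType", "KnowledgeGraph", function(x, nodeType) {
  if (!nodeType %in% x@typeVocabulary) {
    kgStop("kgLookupError", "unknown node type: %s", nodeType)
  }
  sort(x@nodes$cui[x@nodes$node_type == nodeType])
})
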