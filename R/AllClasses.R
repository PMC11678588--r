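#' KnowledgeGraph class
#'
#' A heterogeneous biomedical knowledge graph of semantic triples. Nodes are
#' UMLS-style concepts (a concept unique identifier, a human-readable name,
#' and a semantic-type code such as \code{"aapp"} or \code{"dsyn"}); edges
#' are directed head--relation--tail assertions extracted from literature,
#' each carrying the identifiers of its supporting articles.
#'
#' Duplicate (head, relation, tail) assertions are merged on construction,
#' taking the union of their supporting-article identifiers: a triple is a
#' literature claim and multiplicity is provenance, not weight.
#'
#' @slot nodes data.frame with columns \code{cui}, \code{name},
#'   \code{node_type} (all character).
#' @slot triples data.frame with columns \code{head}, \code{relation},
#'   \code{tail}, \code{pmids}; \code{pmids} is a comma-joined (possibly
#'   empty) list of article identifiers.
#' @slot typeVocabulary declared semantic-type codes.
#' @slot relationVocabulary declared relation labels.
#'
#' @seealso [KnowledgeGraph()], [loadKnowledgeGraph()], [neighborhood()],
#'   [nodesOfType()]
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph",
  representation(
    nodes = "data.frame",
    triples = "data.frame",
    typeVocabulary = "character",
    relationVocabulary = "character"
  )
)

setValidity("KnowledgeGraph", function(object) {
  nd <- object@nodes
  tr <- object@triples
  msgs <- character(0)
  need_n <- c("cui", "name", "node_type")
  need_t <- c("head", "relation", "tail", "pmids")
  if (!all(need_n %in% names(nd))) {
    return(sprintf("nodes must have columns %s", paste(need_n, collapse = ", ")))
  }
  if (!all(need_t %in% names(tr))) {
    return(sprintf("triples must have columns %s", paste(need_t, collapse = ", ")))
  }
  if (anyNA(nd$cui) || any(!nzchar(nd$cui))) {
    msgs <- c(msgs, "node cui values must be non-empty")
  }
  if (anyDuplicated(nd$cui)) {
    msgs <- c(msgs, sprintf(
      "duplicate node cui: %s",
      paste(unique(nd$cui[duplicated(nd$cui)]), collapse = ", ")
    ))
  }
  bad_type <- setdiff(unique(nd$node_type), object@typeVocabulary)
  if (length(bad_type)) {
    msgs <- c(msgs, sprintf(
      "node_type not in type vocabulary: %s", paste(bad_type, collapse = ", ")
    ))
  }
  if (nrow(tr)) {
    dangling <- setdiff(unique(c(tr$head, tr$tail)), nd$cui)
    if (length(dangling)) {
      msgs <- c(msgs, sprintf(
        "triple endpoint not in node table: %s", paste(dangling, collapse = ", ")
      ))
    }
    bad_rel <- setdiff(unique(tr$relation), object@relationVocabulary)
    if (length(bad_rel)) {
      msgs <- c(msgs, sprintf(
        "relation not in relation vocabulary: %s", paste(bad_rel, collapse = ", ")
      ))
    }
    key <- paste(tr$head, tr$relation, tr$tail, sep = "\r")
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "duplicate (head, relation, tail) triples present")
    }
    if (anyNA(tr$pmids)) msgs <- c(msgs, "pmids may be empty but never NA")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' VennSummary class
#'
#' Exact three-set overlap bookkeeping for per-disease node sets: the three
#' totals, the three pairwise intersection sizes, the triple intersection,
#' and the seven exclusive Venn region counts derived from them by
#' inclusion--exclusion.
#'
#' @slot labels the three set labels, in order.
#' @slot totals named sizes of the three sets.
#' @slot pairwise named sizes of the three pairwise intersections
#'   (names like \code{"AD:ALS"}).
#' @slot triple size of the three-way intersection.
#' @slot regions the seven exclusive region counts (names like
#'   \code{"AD_only"}, \code{"AD_ALS"}, \code{"all_three"}).
#'
#' @seealso [intersectSets()], [vennFromCounts()], [vennPercentages()]
#' @exportClass VennSummary
setClass("VennSummary",
  representation(
    labels = "character",
    totals = "numeric",
    pairwise = "numeric",
    triple = "numeric",
    regions = "numeric"
  )
)

setValidity("VennSummary", function(object) {
  msgs <- character(0)
  if (length(object@labels) != 3L || anyDuplicated(object@labels)) {
    return("exactly three distinct set labels required")
  }
  if (length(object@totals) != 3L || length(object@pairwise) != 3L ||
      length(object@triple) != 1L || length(object@regions) != 7L) {
    return("totals/pairwise/triple/regions have lengths 3/3/1/7")
  }
  if (any(object@regions < 0)) {
    neg <- names(object@regions)[object@regions < 0]
    msgs <- c(msgs, sprintf("negative region count: %s", paste(neg, collapse = ", ")))
  }
  if (any(object@triple > object@pairwise)) {
    msgs <- c(msgs, "triple intersection exceeds a pairwise intersection")
  }
  # each total must be reconstructed by its four constituent regions
  l <- object@labels
  for (i in seq_len(3L)) {
    others <- l[-i]
    parts <- c(
      paste0(l[i], "_only"),
      pairKey(l[i], others[1L], l), pairKey(l[i], others[2L], l),
      "all_three"
    )
    if (all(parts %in% names(object@regions))) {
      s <- sum(object@regions[parts])
      if (abs(s - object@totals[i]) > 1e-9) {
        msgs <- c(msgs, sprintf("regions for %s sum to %g, total is %g",
                                l[i], s, object@totals[i]))
      }
    } else {
      msgs <- c(msgs, "region names inconsistent with labels")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ProcessProfile class
#'
#' Biological-process profile of disease-pair intersections: raw
#' (node, category) assignment counts per intersection, the per-intersection
#' normalized percentages, and per-category z-scores of those percentages
#' across intersections.
#'
#' @slot counts category x intersection matrix of assignment counts.
#' @slot normalized per-intersection column percentages of \code{counts}.
#' @slot zscores per-category standardized values across intersections
#'   (population standard deviation).
#' @slot overall data.frame of per-category shares across all
#'   intersections, unrounded and rounded to the nearest integer.
#'
#' @seealso [intersectionProfile()], [normalizeProfile()],
#'   [processZscores()], [overallPercentages()]
#' @exportClass ProcessProfile
setClass("ProcessProfile",
  representation(
    counts = "matrix",
    normalized = "matrix",
    zscores = "matrix",
    overall = "data.frame"
  )
)

setValidity("ProcessProfile", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!identical(dim(object@counts), dim(object@normalized))) {
    return("counts and normalized must share dimensions")
  }
  ok <- vapply(seq_len(ncol(object@normalized)), function(j) {
    s <- sum(object@normalized[, j])
    s == 0 || abs(s - 100) < 0.5
  }, logical(1L))
  if (!all(ok)) return("normalized columns must sum to 100 (or be all zero)")
  TRUE
})

setMethod("show", "KnowledgeGraph", function(object) {
  cat(sprintf(
    "KnowledgeGraph: %d nodes (%d types), %d triples (%d relations)\n",
    nrow(object@nodes), length(object@typeVocabulary),
    nrow(object@triples), length(object@relationVocabulary)
  ))
  tab <- sort(table(object@nodes$node_type), decreasing = TRUE)
  cat("  node types:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "VennSummary", function(object) {
  cat(sprintf("VennSummary of {%s}\n", paste(object@labels, collapse = ", ")))
  cat("  totals:  ",
      paste(sprintf("%s=%g", names(object@totals), object@totals), collapse = "  "), "\n")
  cat("  regions: ",
      paste(sprintf("%s=%g", names(object@regions), object@regions), collapse = "  "), "\n")
})

setMethod("show", "ProcessProfile", function(object) {
  cat(sprintf("ProcessProfile: %d categories x %d intersections\n",
              nrow(object@counts), ncol(object@counts)))
  cat("  intersections:", paste(colnames(object@counts), collapse = ", "), "\n")
  cat("  total assignments:", sum(object@counts), "\n")
})
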