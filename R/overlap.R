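# Three-set overlap quantification by inclusion-exclusion.

vennRegionNames <- function(labels) {
  c(paste0(labels, "_only"),
    pairKey(labels[1L], labels[2L], labels),
    pairKey(labels[1L], labels[3L], labels),
    pairKey(labels[2L], labels[3L], labels),
    "all_three")
}

#' Three-way overlap of node sets
#'
#' Classifies every element of three identifier sets into one of the seven
#' exclusive Venn regions and records totals, pairwise intersections and
#' the triple intersection.
#'
#' @param A,B,C character vectors of identifiers (duplicates ignored).
#' @param labels the three set labels (default \code{AD}, \code{ALS},
#'   \code{FTD}).
#' @return a [VennSummary-class].
#' @examples
#' intersectSets(c("x", "y"), c("y", "z"), c("y"))
#' @export
intersectSets <- function(A, B, C, labels = c("AD", "ALS", "FTD")) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  C <- unique(as.character(C))
  totals <- stats::setNames(c(length(A), length(B), length(C)), labels)
  pw <- stats::setNames(
    c(length(intersect(A, B)), length(intersect(A, C)),
      length(intersect(B, C))),
    c(pairKey(labels[1L], labels[2L], labels),
      pairKey(labels[1L], labels[3L], labels),
      pairKey(labels[2L], labels[3L], labels)))
  tri <- length(intersect(intersect(A, B), C))
  vennFromCounts(totals, pw, tri, labels = labels)
}

#' Venn summary from printed summary counts
#'
#' Derives the seven exclusive region counts from three set totals, three
#' pairwise intersection counts and the triple intersection via
#' inclusion--exclusion, e.g.
#' \eqn{|A only| = |A| - |A \cap B| - |A \cap C| + |A \cap B \cap C|}.
#' This is how published overlap tables (totals + intersections) are turned
#' back into a full Venn diagram.
#'
#' @param totals named (or ordered) sizes of the three sets.
#' @param pairwise sizes of the three pairwise intersections, in the order
#'   (1,2), (1,3), (2,3).
#' @param triple size of the three-way intersection.
#' @param labels the three set labels.
#' @return a [VennSummary-class].
#' @examples
#' vennFromCounts(c(AD = 67213, ALS = 63179, FTD = 43643),
#'                c(62335, 43418, 43368), 43176)
#' @export
vennFromCounts <- function(totals, pairwise, triple,
                           labels = NULL) {
  if (is.null(labels)) {
    labels <- if (!is.null(names(totals))) names(totals) else c("A", "B", "C")
  }
  totals <- stats::setNames(as.numeric(totals), labels)
  pwNames <- c(pairKey(labels[1L], labels[2L], labels),
               pairKey(labels[1L], labels[3L], labels),
               pairKey(labels[2L], labels[3L], labels))
  pairwise <- stats::setNames(as.numeric(pairwise), pwNames)
  triple <- as.numeric(triple)
  if (any(triple > pairwise)) {
    kgStop("kgConsistencyError",
           "triple intersection (%g) exceeds pairwise intersection %s",
           triple, names(pairwise)[which(triple > pairwise)[1L]])
  }
  regions <- c(
    totals[1L] - pairwise[1L] - pairwise[2L] + triple,
    totals[2L] - pairwise[1L] - pairwise[3L] + triple,
    totals[3L] - pairwise[2L] - pairwise[3L] + triple,
    pairwise[1L] - triple,
    pairwise[2L] - triple,
    pairwise[3L] - triple,
    triple)
  names(regions) <- vennRegionNames(labels)
  neg <- names(regions)[regions < 0]
  if (length(neg)) {
    kgStop("kgConsistencyError",
           "inconsistent counts: region %s would be negative",
           paste(neg, collapse = ", "))
  }
  new("VennSummary", labels = labels, totals = totals, pairwise = pairwise,
      triple = triple, regions = regions)
}

#' @rdname vennAccessors
#' @name vennAccessors
#' @title Accessors for VennSummary slots
#' @param x a \linkS4class{VennSummary}.
#' @return \code{vennRegions}: named numeric of the seven exclusive region
#'   counts; \code{vennTotals}: named numeric of the three set sizes.
#' @aliases vennRegions vennTotals
#' @export
setMethod("vennRegions", "VennSummary", function(x) x@regions)

#' @rdname vennAccessors
#' @export
setMethod("vennTotals", "VennSummary", function(x) x@totals)

#' Per-disease Venn percentages
#'
#' For one disease, the share of its nodes in the triple intersection, the
#' shares shared exclusively with each of the other two diseases, and the
#' exclusive share -- each as \eqn{100 \cdot region / total}, rounded half
#' away from zero to one decimal. The base is always the named disease's
#' own total.
#'
#' @param summary a [VennSummary-class].
#' @param disease one of the summary's labels.
#' @return named numeric of length four: \code{all_three}, one entry per
#'   other disease (\code{shared_<other>}), and \code{exclusive}.
#' @examples
#' v <- vennFromCounts(c(AD = 67213, ALS = 63179, FTD = 43643),
#'                     c(62335, 43418, 43368), 43176)
#' vennPercentages(v, "FTD")   # all_three = 98.9
#' @export
vennPercentages <- function(summary, disease) {
  stopifnot(is(summary, "VennSummary"))
  labels <- summary@labels
  if (!disease %in% labels) {
    kgStop("kgLookupError", "unknown disease label: %s", disease)
  }
  total <- summary@totals[[disease]]
  if (total <= 0) {
    kgStop("kgUndefinedError",
           "percentages undefined: %s has zero total", disease)
  }
  others <- setdiff(labels, disease)
  regs <- summary@regions
  vals <- c(
    all_three = regs[["all_three"]],
    stats::setNames(c(regs[[pairKey(disease, others[1L], labels)]],
                      regs[[pairKey(disease, others[2L], labels)]]),
                    paste0("shared_", others)),
    exclusive = regs[[paste0(disease, "_only")]])
  roundHalfAway(100 * vals / total, 1)
}
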