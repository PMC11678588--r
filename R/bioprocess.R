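# Mapping top-ranked concept nodes to eight biological processes and
# profiling the disease-pair intersections.

processCategories <- function() names(categoryWeights())

defaultLexicon <- function() {
  list(
    "cell cycle regulation" = c(
      "cell cycle", "mitosis", "mitotic", "apoptosis", "apoptotic",
      "cyclin", "tumor", "neoplasm"),
    "energy and metabolism" = c(
      "metabolism", "metabolic", "respiration", "glucose", "lipid",
      "mitochondria", "mitochondrial", "redox", "oxidative", "energy"),
    "gene regulation and expression" = c(
      "transcription", "transcriptional", "gene expression", "dna repair",
      "dna replication", "gene regulation"),
    "inflammation and immune response" = c(
      "inflammation", "inflammatory", "immune", "cytokine", "microglia",
      "astrocyte", "autoimmune", "interleukin"),
    "membrane regulation" = c(
      "membrane", "transport", "transporter", "vesicle docking"),
    "protein aggregation" = c(
      "aggregation", "aggregate", "misfolded", "plaque", "tangle",
      "proteasome", "ubiquitin"),
    "stress response regulation" = c(
      "stress", "thyroid", "hormone", "cortisol", "hypothalamic",
      "adrenal", "pituitary"),
    "synapse and neurotransmission" = c(
      "synapse", "synaptic", "neurotransmission", "neurotransmitter",
      "ion channel", "potassium channel", "calcium channel", "plasticity")
  )
}

#' Biological-process taxonomy
#'
#' The eight fixed biological-process categories with a per-category
#' keyword lexicon used for name-based multi-label mapping. The default
#' lexicon is a deterministic, auditable keyword list distilled from the
#' category definitions (mitosis/apoptosis for cell cycle, cytokine for
#' inflammation, ion channel for synapse, ...); it is replaceable
#' configuration, the eight category labels are not.
#'
#' @param lexicon optional named list (category -> character keywords)
#'   overriding the default; must cover exactly the eight categories.
#' @param file optional path to a YAML lexicon (category -> keyword list),
#'   used instead of \code{lexicon}.
#' @return list of class \code{ProcessTaxonomy} with elements
#'   \code{categories} and \code{lexicon} (keywords lower-cased, unique
#'   within a category).
#' @export
processTaxonomy <- function(lexicon = NULL, file = NULL) {
  if (!is.null(file)) lexicon <- yaml::read_yaml(file)
  if (is.null(lexicon)) lexicon <- defaultLexicon()
  lexicon <- lapply(lexicon, function(k) unique(tolower(as.character(k))))
  cats <- processCategories()
  if (!setequal(names(lexicon), cats)) {
    kgStop("kgConfigError",
           "lexicon must cover exactly the eight process categories")
  }
  if (any(lengths(lexicon) == 0L)) {
    kgStop("kgConfigError", "every category needs at least one keyword")
  }
  structure(list(categories = cats, lexicon = lexicon[cats]),
            class = "ProcessTaxonomy")
}

#' Map concept nodes to biological processes by name
#'
#' A node is assigned a category if and only if any of the category's
#' lexicon keywords matches the node's lower-cased name on word
#' boundaries. Multi-label assignments are permitted; nodes matching no
#' keyword get the empty set and their count is reported.
#'
#' @param nodes data.frame with columns \code{cui} and \code{name}, or a
#'   [KnowledgeGraph-class] (all its nodes are mapped).
#' @param taxonomy a \code{ProcessTaxonomy} (default [processTaxonomy()]).
#' @return named list (cui -> character vector of categories, possibly
#'   empty), one entry per input node.
#' @examples
#' mapNodes(data.frame(cui = "P1", name = "synaptic vesicle protein X"))
#' @export
mapNodes <- function(nodes, taxonomy = processTaxonomy()) {
  stopifnot(inherits(taxonomy, "ProcessTaxonomy"))
  if (is(nodes, "KnowledgeGraph")) nodes <- kgNodes(nodes)
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("cui", "name") %in% names(nodes)))
  nm <- tolower(as.character(nodes$name))
  hit <- matrix(FALSE, nrow = nrow(nodes), ncol = length(taxonomy$categories),
                dimnames = list(NULL, taxonomy$categories))
  for (cg in taxonomy$categories) {
    for (kw in taxonomy$lexicon[[cg]]) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw), "\\b")
      hit[, cg] <- hit[, cg] | grepl(pat, nm, perl = TRUE)
    }
  }
  out <- lapply(seq_len(nrow(nodes)), function(i) {
    taxonomy$categories[hit[i, ]]
  })
  names(out) <- as.character(nodes$cui)
  nUnmatched <- sum(vapply(out, length, 0L) == 0L)
  if (nUnmatched > 0L) {
    message(nUnmatched, " node(s) matched no biological-process keyword")
  }
  out
}

pairColumns <- function(diseases) {
  cmb <- utils::combn(diseases, 2L)
  apply(cmb, 2L, paste, collapse = ":")
}

#' Biological-process counts per disease-pair intersection
#'
#' For each unordered disease pair (X, Y), counts per category the
#' (node, category) assignments among the nodes in
#' \eqn{top(X) \cap top(Y)}. A multi-label node increments each of its
#' categories once; the counting unit is the assignment, not the node.
#'
#' @param topSets named list (disease -> character vector of top node
#'   cuis); at least two diseases.
#' @param mapping a mapping table from [mapNodes()].
#' @param pairSets optional named list (\code{"X:Y"} -> cuis) overriding
#'   the pairwise intersections, for the alternative where each pair's
#'   shared set is ranked and thresholded directly rather than built from
#'   per-disease top slices.
#' @return integer matrix, categories x disease pairs (columns named
#'   \code{"X:Y"}).
#' @export
intersectionProfile <- function(topSets, mapping, pairSets = NULL) {
  stopifnot(is.list(topSets), length(topSets) >= 2L, !is.null(names(topSets)))
  diseases <- names(topSets)
  cols <- pairColumns(diseases)
  cats <- processCategories()
  counts <- matrix(0L, nrow = length(cats), ncol = length(cols),
                   dimnames = list(cats, cols))
  cmb <- utils::combn(diseases, 2L)
  for (j in seq_len(ncol(cmb))) {
    shared <- if (!is.null(pairSets)) {
      pairSets[[cols[j]]]
    } else {
      intersect(topSets[[cmb[1L, j]]], topSets[[cmb[2L, j]]])
    }
    if (is.null(shared)) shared <- character(0)
    if (!length(shared)) {
      warning("empty intersection for ", cols[j])
      next
    }
    labs <- unlist(mapping[shared], use.names = FALSE)
    if (length(labs)) {
      tab <- table(factor(labs, levels = cats))
      counts[, j] <- as.integer(tab)
    }
  }
  counts
}

#' Normalize an intersection profile to column percentages
#'
#' \code{normalized[p, i] = 100 counts[p, i] / sum_p counts[p, i]},
#' adjusting for the different node counts of the intersections; an
#' all-zero column stays zero with a warning.
#'
#' @param counts category x intersection count matrix.
#' @return matrix of percentages with the same dimensions.
#' @export
normalizeProfile <- function(counts) {
  counts <- as.matrix(counts)
  out <- counts * 0
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero intersection column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
  }
  nz <- which(!zero)
  out[, nz] <- sweep(counts[, nz, drop = FALSE], 2L, cs[nz], "/") * 100
  out
}

#' Z-scores of a profile across intersections
#'
#' Per category, standardized deviation of each intersection from the
#' category's cross-intersection mean, using the population standard
#' deviation (with three intersections this choice is material).
#' Zero-variance categories get all-zero rows with a warning.
#'
#' @param x category x intersection matrix (normalized percentages by
#'   default in the pipeline; raw counts may be passed instead).
#' @return matrix of z-scores with the same dimensions.
#' @export
processZscores <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    kgStop("kgInputError",
           "z-scores need at least two intersections (got %d)", ncol(x))
  }
  out <- x * 0
  flat <- character(0)
  for (i in seq_len(nrow(x))) {
    s <- popSD(x[i, ])
    if (s == 0) {
      flat <- c(flat, rownames(x)[i])
    } else {
      out[i, ] <- (x[i, ] - mean(x[i, ])) / s
    }
  }
  if (length(flat)) {
    warning("zero-variance categor(ies): ", paste(flat, collapse = ", "))
  }
  out
}

#' Overall per-category shares across all intersections
#'
#' \code{share[p] = 100 sum_i counts[p, i] / sum_{p,i} counts[p, i]}.
#'
#' @param counts category x intersection count matrix with at least one
#'   non-zero entry.
#' @return data.frame with columns \code{category}, \code{share_pct}
#'   (unrounded) and \code{share_rounded} (nearest integer, half away from
#'   zero).
#' @export
overallPercentages <- function(counts) {
  counts <- as.matrix(counts)
  tot <- sum(counts)
  if (tot == 0) kgStop("kgInputError", "all-zero count matrix")
  share <- 100 * rowSums(counts) / tot
  data.frame(category = rownames(counts),
             share_pct = unname(share),
             share_rounded = unname(roundHalfAway(share, 0)))
}

#' Assemble a full ProcessProfile
#'
#' Convenience wrapper running [intersectionProfile()],
#' [normalizeProfile()], [processZscores()] and [overallPercentages()] into
#' one [ProcessProfile-class] object. Z-scores are computed on the
#' normalized percentages (set \code{zscoresOn = "counts"} to standardize
#' raw counts instead).
#'
#' @param topSets named list (disease -> top node cuis).
#' @param mapping mapping table from [mapNodes()].
#' @param zscoresOn \code{"normalized"} (default) or \code{"counts"}.
#' @param pairSets optional pairwise shared sets, see
#'   [intersectionProfile()].
#' @return a [ProcessProfile-class].
#' @export
buildProcessProfile <- function(topSets, mapping,
                                zscoresOn = c("normalized", "counts"),
                                pairSets = NULL) {
  zscoresOn <- match.arg(zscoresOn)
  counts <- intersectionProfile(topSets, mapping, pairSets = pairSets)
  normalized <- normalizeProfile(counts)
  z <- processZscores(if (zscoresOn == "normalized") normalized else counts)
  overall <- overallPercentages(counts)
  new("ProcessProfile", counts = counts, normalized = normalized,
      zscores = z, overall = overall)
}

#' @rdname profileAccessors
#' @name profileAccessors
#' @title Accessors for ProcessProfile slots
#' @param x a \linkS4class{ProcessProfile}.
#' @return matrices (\code{profileCounts}, \code{profileNormalized},
#'   \code{profileZscores}) or a data.frame (\code{profileOverall}).
#' @aliases profileCounts profileNormalized profileZscores profileOverall
#' @export
setMethod("profileCounts", "ProcessProfile", function(x) x@counts)

#' @rdname profileAccessors
#' @export
setMethod("profileNormalized", "ProcessProfile", function(x) x@normalized)

#' @rdname profileAccessors
#' @export
setMethod("profileZscores", "ProcessProfile", function(x) x@zscores)

#' @rdname profileAccessors
#' @export
setMethod("profileOverall", "ProcessProfile", function(x) x@overall)
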