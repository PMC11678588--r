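#' Metapath signatures
#'
#' A metapath signature is the type-level shape of a set of instance paths:
#' the ordered node types visited, the relation used at each step, and the
#' direction in which each triple is traversed (\code{"forward"} means the
#' path follows head-to-tail, \code{"reverse"} tail-to-head). All instance
#' paths with the same shape are condensed into one signature; relevance is
#' then computed per signature rather than per path.
#'
#' @param nodeTypes character vector of length \code{L + 1}: the semantic
#'   types along the path, source type first, target type last.
#' @param relations character vector of length \code{L}.
#' @param directions character vector of length \code{L}, each
#'   \code{"forward"} or \code{"reverse"}.
#' @return an object of class \code{MetapathSignature}.
#' @examples
#' metapathSignature(c("aapp", "gngm", "dsyn"),
#'                   c("interacts_with", "associated_with"),
#'                   c("forward", "forward"))
#' @export
metapathSignature <- function(nodeTypes, relations, directions) {
  L <- length(relations)
  if (L < 1L) kgStop("kgSignatureError", "signature must have length >= 1")
  if (length(nodeTypes) != L + 1L || length(directions) != L) {
    kgStop("kgSignatureError",
           "need %d node types and %d directions for %d relations",
           L + 1L, L, L)
  }
  if (!all(directions %in% c("forward", "reverse"))) {
    kgStop("kgSignatureError", "directions must be 'forward' or 'reverse'")
  }
  structure(
    list(nodeTypes = as.character(nodeTypes),
         relations = as.character(relations),
         directions = as.character(directions)),
    class = "MetapathSignature"
  )
}

#' @export
length.MetapathSignature <- function(x) length(x$relations)

#' @export
format.MetapathSignature <- function(x, ...) {
  arrows <- ifelse(x$directions == "forward", "-[%s]->", "<-[%s]-")
  steps <- sprintf(arrows, x$relations)
  paste0(x$nodeTypes[1L],
         paste0(steps, x$nodeTypes[-1L], collapse = ""))
}

#' @export
print.MetapathSignature <- function(x, ...) {
  cat("MetapathSignature:", format(x), "\n")
  invisible(x)
}

# Canonical key used for deduplication and caching.
signatureKey <- function(sig) {
  paste(c(sig$nodeTypes, sig$relations, sig$directions), collapse = "\r")
}

# ---------------------------------------------------------------------------
# Instance-path enumeration (simple paths, undirected traversal)

# Directed-expansion edge table: every triple in both traversal directions,
# self-loops dropped (a simple path cannot use them).
expansionTable <- function(graph) {
  tr <- graph@triples
  nt <- stats::setNames(graph@nodes$node_type, graph@nodes$cui)
  tr <- tr[tr$head != tr$tail, , drop = FALSE]
  fwd <- data.table::data.table(
    from = tr$head, to = tr$tail, rel = tr$relation, dir = "forward",
    ft = unname(nt[tr$head]), tt = unname(nt[tr$tail]))
  rev <- data.table::data.table(
    from = tr$tail, to = tr$head, rel = tr$relation, dir = "reverse",
    ft = unname(nt[tr$tail]), tt = unname(nt[tr$head]))
  data.table::rbindlist(list(fwd, rev))
}

# All simple instance paths from any of `sources` to `target` with
# 1..maxLength steps. Returns a data.table with columns source, length,
# and per-step signature columns (t0, r1, d1, t1, r2, d2, t2, r3, d3, t3;
# unused steps NA). maxLength up to 3 is supported (the study setting).
enumeratePaths <- function(graph, sources, target, maxLength = 3L) {
  stopifnot(maxLength >= 1L)
  if (maxLength > 3L) {
    kgStop("kgSignatureError",
           "metapath lengths above 3 are not supported (study setting is 3)")
  }
  E <- expansionTable(graph)
  sources <- setdiff(sources, target)
  empty <- data.table::data.table(
    source = character(0), length = integer(0),
    t0 = character(0), r1 = character(0), d1 = character(0), t1 = character(0),
    r2 = character(0), d2 = character(0), t2 = character(0),
    r3 = character(0), d3 = character(0), t3 = character(0))
  if (!nrow(E) || !length(sources)) return(empty)

  A <- E[E$from %in% sources]                      # first step
  B <- E[E$to == target]                           # last step
  out <- list()

  if (nrow(A)) {
    L1 <- A[A$to == target]
    if (nrow(L1)) {
      out$L1 <- data.table::data.table(
        source = L1$from, length = 1L,
        t0 = L1$ft, r1 = L1$rel, d1 = L1$dir, t1 = L1$tt,
        r2 = NA_character_, d2 = NA_character_, t2 = NA_character_,
        r3 = NA_character_, d3 = NA_character_, t3 = NA_character_)
    }
  }

  if (maxLength >= 2L && nrow(A) && nrow(B)) {
    A2 <- A[A$to != target]
    B2 <- data.table::copy(B)
    data.table::setnames(B2, c("mid", "tgt", "rl", "dl", "mt", "lt"))
    M <- merge(A2, B2, by.x = "to", by.y = "mid",
               allow.cartesian = TRUE)
    M <- M[M$from != M$tgt]                        # source != target (defensive)
    if (nrow(M)) {
      out$L2 <- data.table::data.table(
        source = M$from, length = 2L,
        t0 = M$ft, r1 = M$rel, d1 = M$dir, t1 = M$tt,
        r2 = M$rl, d2 = M$dl, t2 = M$lt,
        r3 = NA_character_, d3 = NA_character_, t3 = NA_character_)
    }
  }

  if (maxLength >= 3L && nrow(A) && nrow(B)) {
    A3 <- A[A$to != target]
    data.table::setnames(A3, c("s", "m1", "r1", "d1", "t0", "t1"))
    E2 <- data.table::copy(E)
    data.table::setnames(E2, c("m1b", "m2", "r2", "d2", "x1", "t2"))
    P <- merge(A3, E2, by.x = "m1", by.y = "m1b", allow.cartesian = TRUE)
    P <- P[P$m2 != P$s & P$m2 != target]
    if (nrow(P)) {
      B3 <- data.table::copy(B)
      data.table::setnames(B3, c("m2b", "tgt", "r3", "d3", "x2", "t3"))
      Q <- merge(P, B3, by.x = "m2", by.y = "m2b", allow.cartesian = TRUE)
      Q <- Q[Q$m1 != Q$tgt]                        # defensive; A3 excluded it
      if (nrow(Q)) {
        out$L3 <- data.table::data.table(
          source = Q$s, length = 3L,
          t0 = Q$t0, r1 = Q$r1, d1 = Q$d1, t1 = Q$t1,
          r2 = Q$r2, d2 = Q$d2, t2 = Q$t2,
          r3 = Q$r3, d3 = Q$d3, t3 = Q$t3)
      }
    }
  }
  if (!length(out)) return(empty)
  data.table::rbindlist(out)
}

# Convert one row of the enumeratePaths signature columns to a signature.
rowToSignature <- function(row) {
  L <- row$length
  types <- c(row$t0, row$t1, if (L >= 2L) row$t2, if (L >= 3L) row$t3)
  rels <- c(row$r1, if (L >= 2L) row$r2, if (L >= 3L) row$r3)
  dirs <- c(row$d1, if (L >= 2L) row$d2, if (L >= 3L) row$d3)
  metapathSignature(types, rels, dirs)
}

#' Enumerate metapath signatures between two nodes
#'
#' Finds every distinct type-level signature realized by at least one simple
#' instance path (no repeated node) of length at most \code{maxLength}
#' between \code{source} and \code{target}, traversing triples in either
#' direction.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param source,target concept identifiers present in the graph.
#' @param maxLength maximum number of relation steps (default 3, the study
#'   setting).
#' @return list of \code{MetapathSignature} objects (possibly empty),
#'   ordered by their canonical string form.
#' @seealso [heteSim()], [rankSources()]
#' @export
enumerateSignatures <- function(graph, source, target, maxLength = 3L) {
  for (id in c(source, target)) {
    if (!id %in% graph@nodes$cui) kgStop("kgLookupError", "unknown cui: %s", id)
  }
  paths <- enumeratePaths(graph, source, target, maxLength)
  if (!nrow(paths)) return(list())
  sigcols <- c("length", "t0", "r1", "d1", "t1", "r2", "d2", "t2",
               "r3", "d3", "t3")
  u <- unique(paths[, sigcols, with = FALSE])
  sigs <- lapply(seq_len(nrow(u)), function(i) rowToSignature(u[i]))
  sigs[order(vapply(sigs, format, ""))]
}

# ---------------------------------------------------------------------------
# HeteSim proper

# Node index per type: list(cuis = character, pos = named integer).
typeIndex <- function(graph, type) {
  cuis <- sort(graph@nodes$cui[graph@nodes$node_type == type])
  list(cuis = cuis, pos = stats::setNames(seq_along(cuis), cuis))
}

# Unnormalized typed incidence for one step: rows = nodes of fromType,
# cols = nodes of toType, 1 where a triple with `rel` connects them in the
# given traversal direction.
stepIncidence <- function(graph, fromType, rel, dir, toType, cache = NULL) {
  key <- paste("inc", fromType, rel, dir, toType, sep = "\r")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  fi <- typeIndex(graph, fromType)
  ti <- typeIndex(graph, toType)
  tr <- graph@triples
  if (dir == "forward") {
    sel <- tr$relation == rel & tr$head %in% fi$cuis & tr$tail %in% ti$cuis
    ii <- fi$pos[tr$head[sel]]
    jj <- ti$pos[tr$tail[sel]]
  } else {
    sel <- tr$relation == rel & tr$tail %in% fi$cuis & tr$head %in% ti$cuis
    ii <- fi$pos[tr$tail[sel]]
    jj <- ti$pos[tr$head[sel]]
  }
  M <- Matrix::sparseMatrix(i = as.integer(ii), j = as.integer(jj), x = 1,
                            dims = c(length(fi$cuis), length(ti$cuis)),
                            dimnames = list(fi$cuis, ti$cuis))
  if (!is.null(cache)) cache[[key]] <- M
  M
}

# Row-normalize a sparse matrix; all-zero rows stay zero (mass is lost, as
# for a walk with nowhere to go).
rowNormalize <- function(M) {
  rs <- Matrix::rowSums(M)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  Matrix::Diagonal(x = inv) %*% M
}

flipDir <- function(d) ifelse(d == "forward", "reverse", "forward")

#' Reverse a metapath signature
#'
#' The signature read from target to source: node types reversed, relations
#' reversed, each step's traversal direction flipped.
#'
#' @param sig a \code{MetapathSignature}.
#' @return the reversed \code{MetapathSignature}.
#' @export
reverseSignature <- function(sig) {
  metapathSignature(rev(sig$nodeTypes), rev(sig$relations),
                    flipDir(rev(sig$directions)))
}

checkSignature <- function(graph, sig) {
  badt <- setdiff(sig$nodeTypes, graph@typeVocabulary)
  if (length(badt)) {
    kgStop("kgSignatureError", "signature uses unknown node type(s): %s",
           paste(badt, collapse = ", "))
  }
  badr <- setdiff(sig$relations, graph@relationVocabulary)
  if (length(badr)) {
    kgStop("kgSignatureError", "signature uses unknown relation(s): %s",
           paste(badr, collapse = ", "))
  }
}

# Meeting distributions of several sources (forward) and one target
# (backward) over the midpoint domain of a signature. Odd-length paths are
# made even by splitting the middle relation: every middle-edge instance
# becomes an artificial midpoint, so the meeting domain is the set of
# middle-edge instances.
#
# Returns list(F = |sources| x midpoint dgCMatrix, b = numeric midpoint
# vector).
meetingDistributions <- function(graph, sources, target, sig, cache = NULL) {
  L <- length(sig)
  types <- sig$nodeTypes
  si <- typeIndex(graph, types[1L])
  ti <- typeIndex(graph, types[L + 1L])
  if (!all(sources %in% si$cuis)) {
    kgStop("kgSignatureError",
           "source node(s) not of signature source type '%s'", types[1L])
  }
  if (!target %in% ti$cuis) {
    kgStop("kgSignatureError",
           "target node not of signature target type '%s'", types[L + 1L])
  }
  Fm <- Matrix::sparseMatrix(
    i = seq_along(sources), j = as.integer(si$pos[sources]), x = 1,
    dims = c(length(sources), length(si$cuis)),
    dimnames = list(sources, si$cuis))
  Bm <- Matrix::sparseMatrix(
    i = 1L, j = as.integer(ti$pos[target]), x = 1,
    dims = c(1L, length(ti$cuis)), dimnames = list(target, ti$cuis))

  fwdStep <- function(i) rowNormalize(
    stepIncidence(graph, types[i], sig$relations[i], sig$directions[i],
                  types[i + 1L], cache))
  bwdStep <- function(i) rowNormalize(
    stepIncidence(graph, types[i + 1L], sig$relations[i],
                  flipDir(sig$directions[i]), types[i], cache))

  if (L %% 2L == 0L) {
    m <- L %/% 2L
    for (i in seq_len(m)) Fm <- Fm %*% fwdStep(i)
    for (i in rev(seq.int(m + 1L, L))) Bm <- Bm %*% bwdStep(i)
  } else {
    m <- (L + 1L) %/% 2L                 # middle step index
    A <- stepIncidence(graph, types[m], sig$relations[m], sig$directions[m],
                       types[m + 1L], cache)
    idx <- Matrix::which(A != 0, arr.ind = TRUE)
    nE <- nrow(idx)
    Aout <- Matrix::sparseMatrix(i = idx[, 1L], j = seq_len(nE), x = 1,
                                 dims = c(nrow(A), max(nE, 0L)))
    Ain <- Matrix::sparseMatrix(i = seq_len(nE), j = idx[, 2L], x = 1,
                                dims = c(max(nE, 0L), ncol(A)))
    for (i in seq_len(m - 1L)) Fm <- Fm %*% fwdStep(i)
    Fm <- Fm %*% rowNormalize(Aout)
    if (L > m) for (i in rev(seq.int(m + 1L, L))) Bm <- Bm %*% bwdStep(i)
    Bm <- Bm %*% rowNormalize(Matrix::t(Ain))
  }
  list(F = Fm, b = as.numeric(Bm))
}

cosineRows <- function(Fm, b) {
  num <- as.numeric(Fm %*% b)
  fn <- sqrt(Matrix::rowSums(Fm^2))
  bn <- sqrt(sum(b^2))
  den <- fn * bn
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, 0), 1)
}

# Vectorized HeteSim for many sources against one target and one signature.
heteSimMany <- function(graph, sources, target, sig, cache = NULL) {
  checkSignature(graph, sig)
  md <- meetingDistributions(graph, sources, target, sig, cache)
  stats::setNames(cosineRows(md$F, md$b), sources)
}

#' Deterministic HeteSim relevance along a metapath signature
#'
#' Computes the HeteSim relatedness of \code{source} and \code{target}
#' along one metapath signature. Per-step reachability operators are the
#' row-normalized typed adjacency matrices restricted to the step's
#' (type, relation, direction); for even path lengths the score is the
#' cosine of the source's forward and the target's backward meeting
#' distributions over the midpoint type; odd lengths are first made even by
#' splitting the middle relation, one artificial midpoint per middle-edge
#' instance. The value is deterministic and lies in \eqn{[0, 1]}; it is 0
#' when either meeting distribution is all-zero.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param source,target concept identifiers.
#' @param signature a \code{MetapathSignature} whose endpoint types match
#'   the two nodes.
#' @return a single numeric HeteSim value in \eqn{[0, 1]}.
#' @seealso [enumerateSignatures()], [rankSources()]
#' @export
heteSim <- function(graph, source, target, signature) {
  for (id in c(source, target)) {
    if (!id %in% graph@nodes$cui) kgStop("kgLookupError", "unknown cui: %s", id)
  }
  unname(heteSimMany(graph, source, target, signature))
}

#' Rank source nodes by HeteSim relevance to disease targets
#'
#' For every node of \code{sourceType} within \code{depth} undirected hops
#' of at least one target: enumerates the distinct metapath signatures of
#' simple instance paths of length at most \code{maxLength} to each target,
#' scores each signature with [heteSim()], averages the signature scores
#' per (source, target), and aggregates across targets with the exact
#' arithmetic mean over the targets for which the source has at least one
#' signature.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param targets character vector of target cuis (non-empty, all present).
#' @param sourceType semantic type of the candidate source nodes
#'   (default \code{"aapp"}).
#' @param depth candidate-discovery hop limit (default 2, the study
#'   setting).
#' @param maxLength maximum metapath length (default 3, the study setting).
#' @return data.frame with one row per (source, target) that has at least
#'   one signature: \code{source_cui}, \code{target_cui}, \code{hetesim}
#'   (per-target mean over signatures), \code{n_signatures}, and
#'   \code{aggregate} (the source's cross-target exact mean). Sorted by
#'   \code{aggregate} descending, ties broken by ascending
#'   \code{source_cui}, then \code{target_cui}.
#' @export
rankSources <- function(graph, targets, sourceType = "aapp",
                        depth = 2L, maxLength = 3L) {
  stopifnot(length(targets) >= 1L)
  for (t in targets) {
    if (!t %in% graph@nodes$cui) kgStop("kgLookupError", "unknown target cui: %s", t)
  }
  candidates <- character(0)
  for (t in targets) {
    candidates <- union(candidates, neighborhood(graph, t, depth))
  }
  candidates <- sort(intersect(candidates, nodesOfType(graph, sourceType)))
  candidates <- setdiff(candidates, targets)
  emptyOut <- data.frame(source_cui = character(0), target_cui = character(0),
                         hetesim = numeric(0), n_signatures = integer(0),
                         aggregate = numeric(0))
  if (!length(candidates)) {
    warning("no source nodes of type '", sourceType,
            "' within depth ", depth, " of any target")
    return(emptyOut)
  }
  cache <- new.env(parent = emptyenv())
  sigcols <- c("length", "t0", "r1", "d1", "t1", "r2", "d2", "t2",
               "r3", "d3", "t3")
  rows <- list()
  for (t in targets) {
    paths <- enumeratePaths(graph, candidates, t, maxLength)
    if (!nrow(paths)) next
    pairs <- unique(paths[, c("source", sigcols), with = FALSE])
    usig <- unique(pairs[, sigcols, with = FALSE])
    skey <- do.call(paste, c(usig, sep = "\r"))
    pairkey <- do.call(paste, c(pairs[, sigcols, with = FALSE], sep = "\r"))
    scores <- vector("list", nrow(usig))
    for (k in seq_len(nrow(usig))) {
      sig <- rowToSignature(usig[k])
      srcs <- sort(unique(pairs$source[pairkey == skey[k]]))
      scores[[k]] <- data.table::data.table(
        source = srcs,
        value = unname(heteSimMany(graph, srcs, t, sig, cache)))
    }
    sc <- data.table::rbindlist(scores)
    agg <- sc[, list(hetesim = mean(value), n_signatures = .N),
              by = "source"]
    rows[[t]] <- data.table::data.table(
      source_cui = agg$source, target_cui = t,
      hetesim = agg$hetesim, n_signatures = agg$n_signatures)
  }
  if (!length(rows)) {
    warning("no source nodes with a metapath to any target")
    return(emptyOut)
  }
  res <- data.table::rbindlist(rows)
  aggr <- res[, list(aggregate = mean(hetesim)), by = "source_cui"]
  res <- merge(res, aggr, by = "source_cui")
  res <- res[order(-res$aggregate, res$source_cui, res$target_cui)]
  out <- as.data.frame(res[, c("source_cui", "target_cui", "hetesim",
                               "n_signatures", "aggregate"), with = FALSE])
  rownames(out) <- NULL
  out
}
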