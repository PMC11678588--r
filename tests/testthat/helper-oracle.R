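# Independent brute-force oracles used to cross-check the matrix
# implementation. Everything here works by exhaustive enumeration over the
# triple table, never through the package's sparse-operator path.

# Matching next nodes from `node` for one signature step, by scanning the
# triple table directly.
.stepNeighbors <- function(graph, node, rel, dir, nextType) {
  tr <- kgTriples(graph)
  nd <- kgNodes(graph)
  typ <- setNames(nd$node_type, nd$cui)
  if (dir == "forward") {
    out <- tr$tail[tr$head == node & tr$relation == rel]
  } else {
    out <- tr$head[tr$tail == node & tr$relation == rel]
  }
  out[typ[out] == nextType]
}

# Walk distribution after consuming steps `idx` of the signature starting
# from `start`: at every step the walk moves uniformly over the matching
# next nodes (mass dies where there is none).
.walkDist <- function(graph, start, sig, idx, flip = FALSE) {
  dist <- setNames(1, start)
  for (i in idx) {
    rel <- sig$relations[i]
    dir <- if (flip) {
      if (sig$directions[i] == "forward") "reverse" else "forward"
    } else {
      sig$directions[i]
    }
    nextType <- if (flip) sig$nodeTypes[i] else sig$nodeTypes[i + 1L]
    acc <- numeric(0)
    for (u in names(dist)) {
      nb <- .stepNeighbors(graph, u, rel, dir, nextType)
      if (!length(nb)) next
      w <- dist[[u]] / length(nb)
      for (v in nb) acc[v] <- (if (v %in% names(acc)) acc[[v]] else 0) + w
    }
    dist <- acc
    if (!length(dist)) return(numeric(0))
  }
  dist
}

# All middle-edge instances (as "head\rtail" keys in path direction) of the
# odd middle step reachable from `node`.
.middleEdgesFrom <- function(graph, node, sig, m, fromSide) {
  rel <- sig$relations[m]
  if (fromSide) {
    nb <- .stepNeighbors(graph, node, rel, sig$directions[m],
                         sig$nodeTypes[m + 1L])
    if (!length(nb)) return(character(0))
    paste(node, nb, sep = "\r")
  } else {
    dirFlip <- if (sig$directions[m] == "forward") "reverse" else "forward"
    nb <- .stepNeighbors(graph, node, rel, dirFlip, sig$nodeTypes[m])
    if (!length(nb)) return(character(0))
    paste(nb, node, sep = "\r")
  }
}

.spreadOverEdges <- function(graph, dist, sig, m, fromSide) {
  acc <- numeric(0)
  for (u in names(dist)) {
    ed <- .middleEdgesFrom(graph, u, sig, m, fromSide)
    if (!length(ed)) next
    w <- dist[[u]] / length(ed)
    for (e in ed) acc[e] <- (if (e %in% names(acc)) acc[[e]] else 0) + w
  }
  acc
}

.cosineNamed <- function(f, b) {
  if (!length(f) || !length(b)) return(0)
  keys <- union(names(f), names(b))
  fv <- setNames(numeric(length(keys)), keys); fv[names(f)] <- f
  bv <- setNames(numeric(length(keys)), keys); bv[names(b)] <- b
  den <- sqrt(sum(fv^2)) * sqrt(sum(bv^2))
  if (den == 0) return(0)
  sum(fv * bv) / den
}

# Brute-force HeteSim: enumerate walk instances for the source's forward
# and the target's backward meeting distributions, then take the cosine.
oracleHeteSim <- function(graph, source, target, sig) {
  L <- length(sig)
  if (L %% 2L == 0L) {
    m <- L %/% 2L
    f <- .walkDist(graph, source, sig, seq_len(m))
    b <- .walkDist(graph, target, sig, rev(seq.int(m + 1L, L)), flip = TRUE)
  } else {
    m <- (L + 1L) %/% 2L
    f0 <- .walkDist(graph, source, sig,
                    if (m > 1L) seq_len(m - 1L) else integer(0))
    f <- .spreadOverEdges(graph, f0, sig, m, fromSide = TRUE)
    b0 <- .walkDist(graph, target, sig,
                    if (L > m) rev(seq.int(m + 1L, L)) else integer(0),
                    flip = TRUE)
    b <- .spreadOverEdges(graph, b0, sig, m, fromSide = FALSE)
  }
  .cosineNamed(f, b)
}

# Exhaustive breadth-first reachability (hop counts, both directions).
oracleNeighborhood <- function(graph, start, depth) {
  tr <- kgTriples(graph)
  frontier <- start
  seen <- start
  for (i in seq_len(depth)) {
    nxt <- unique(c(tr$tail[tr$head %in% frontier],
                    tr$head[tr$tail %in% frontier]))
    frontier <- setdiff(nxt, seen)
    if (!length(frontier)) break
    seen <- union(seen, frontier)
  }
  sort(setdiff(seen, start))
}

# Small random typed multigraph for property tests.
randomGraph <- function(nNodes = 10L, nEdges = 18L,
                        types = c("a", "b", "c"),
                        rels = c("r", "s")) {
  cuis <- sprintf("N%02d", seq_len(nNodes))
  nodes <- data.frame(cui = cuis, name = cuis,
                      node_type = sample(types, nNodes, replace = TRUE))
  h <- sample(cuis, nEdges, replace = TRUE)
  t <- sample(cuis, nEdges, replace = TRUE)
  keep <- h != t
  triples <- unique(data.frame(head = h[keep],
                               relation = sample(rels, sum(keep), replace = TRUE),
                               tail = t[keep], pmids = ""))
  KnowledgeGraph(nodes, triples,
                 typeVocabulary = types, relationVocabulary = rels)
}

# Tiny deterministic chain graph used across kg_core tests.
chainGraph <- function() {
  KnowledgeGraph(
    data.frame(cui = c("a", "b", "c", "z"), name = c("a", "b", "c", "z"),
               node_type = c("aapp", "gngm", "dsyn", "aapp")),
    data.frame(head = c("a", "b"), relation = "affects",
               tail = c("b", "c"), pmids = c("1", "2")))
}
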