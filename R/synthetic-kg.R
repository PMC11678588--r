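# Synthetic heterogeneous knowledge graph with planted ground truth.
#
# The generator emulates the study design that the downstream pipeline
# expects: three disease target nodes (the UMLS concepts for Alzheimer's
# disease, amyotrophic lateral sclerosis and frontotemporal dementia), a
# population of AAPP source nodes whose disease memberships follow a
# seven-region Venn distribution, per-membership relevance tiers realized
# as planted 2-hop bridge paths (more distinct bridges = stronger HeteSim
# signal), optional direct length-1 edges, and node names that embed
# biological-process keywords so the lexicon mapper can recover planted
# labels.

#' Disease targets used throughout the package
#'
#' Named vector of the three study target CUIs: Alzheimer's Disease
#' (C0002395), Amyotrophic Lateral Sclerosis (C0002736), Frontotemporal
#' Dementia (C0338451).
#'
#' @return named character vector (names AD, ALS, FTD).
#' @export
diseaseTargets <- function() {
  c(AD = "C0002395", ALS = "C0002736", FTD = "C0338451")
}

diseaseNames <- function() {
  c(AD = "Alzheimer's Disease", ALS = "Amyotrophic Lateral Sclerosis",
    FTD = "Frontotemporal Dementia")
}

# Venn regions in sampling order; the eighth state is "none".
regionLabels <- function() {
  c("AD_only", "ALS_only", "FTD_only", "AD_ALS", "AD_FTD", "ALS_FTD",
    "all_three", "none")
}

regionMembers <- function(region) {
  switch(region,
         AD_only = "AD", ALS_only = "ALS", FTD_only = "FTD",
         AD_ALS = c("AD", "ALS"), AD_FTD = c("AD", "FTD"),
         ALS_FTD = c("ALS", "FTD"),
         all_three = c("AD", "ALS", "FTD"),
         none = character(0))
}

# One canonical keyword per process category embedded into node names; each
# appears in exactly one category's lexicon so recovery is unambiguous.
embedKeywords <- function() {
  c("cell cycle regulation" = "mitosis",
    "energy and metabolism" = "mitochondrial",
    "gene regulation and expression" = "transcription",
    "inflammation and immune response" = "cytokine",
    "membrane regulation" = "membrane",
    "protein aggregation" = "misfolded",
    "stress response regulation" = "thyroid",
    "synapse and neurotransmission" = "synaptic")
}

# Planted category weights, patterned on the overall process shares the
# pipeline is meant to recover (integers summing to 100).
categoryWeights <- function() {
  c("cell cycle regulation" = 15,
    "energy and metabolism" = 11,
    "gene regulation and expression" = 4,
    "inflammation and immune response" = 19,
    "membrane regulation" = 11,
    "protein aggregation" = 12,
    "stress response regulation" = 9,
    "synapse and neurotransmission" = 19)
}

#' Synthetic-graph generator configuration
#'
#' Parameters controlling [generateKG()]. Defaults reproduce the study
#' conditions the pipeline is designed for: region probabilities patterned
#' on the published three-disease Venn proportions, search-compatible 2-hop
#' bridge structure, and keyword-bearing names.
#'
#' @param n_aapp number of AAPP source nodes.
#' @param region_probs probabilities over the seven exclusive Venn regions
#'   plus an eighth "none" state, in the order
#'   \code{AD_only, ALS_only, FTD_only, AD_ALS, AD_FTD, ALS_FTD, all_three,
#'   none}; must sum to 1.
#' @param n_intermediates named counts of non-AAPP bridge nodes per
#'   semantic type (e.g., genes \code{gngm}, cell functions \code{celf},
#'   chemicals \code{orch}).
#' @param direct_edge_prob probability that a planted (node, disease)
#'   membership also gets a direct length-1 edge.
#' @param paths_per_strength named counts of distinct 2-hop bridge paths
#'   planted per membership, by relevance tier (\code{high}, \code{mid},
#'   \code{low}); strictly decreasing, or all zero (then
#'   \code{direct_edge_prob} must be 1 so membership stays realizable).
#' @param keyword_rate probability that a node's name embeds the keyword of
#'   each of its planted process categories.
#' @param seed integer seed for the generator's single pseudo-random
#'   stream, consumed in a fixed order (regions, then edges, then names).
#' @return a validated list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(n_aapp = 200L,
                            region_probs = c(AD_only = 0.065, ALS_only = 0.009,
                                             FTD_only = 0.001, AD_ALS = 0.267,
                                             AD_FTD = 0.004, ALS_FTD = 0.003,
                                             all_three = 0.601, none = 0.05),
                            n_intermediates = c(gngm = 30L, celf = 30L,
                                                orch = 30L),
                            direct_edge_prob = 0.5,
                            paths_per_strength = c(high = 6L, mid = 3L,
                                                   low = 1L),
                            keyword_rate = 1,
                            seed = 1L) {
  region_probs <- unlist(region_probs)
  if (length(region_probs) != 8L) {
    kgStop("kgConfigError", "region_probs: need 8 probabilities, got %d",
           length(region_probs))
  }
  if (is.null(names(region_probs)) || !all(names(region_probs) == regionLabels())) {
    names(region_probs) <- regionLabels()
  }
  if (any(region_probs < 0)) {
    kgStop("kgConfigError", "region_probs: probabilities must be non-negative")
  }
  if (abs(sum(region_probs) - 1) > 1e-12) {
    kgStop("kgConfigError", "region_probs: must sum to 1 (got %.15g)",
           sum(region_probs))
  }
  if (n_aapp < 0) kgStop("kgConfigError", "n_aapp: must be non-negative")
  n_intermediates <- unlist(n_intermediates)
  if (is.null(names(n_intermediates)) || any(!nzchar(names(n_intermediates)))) {
    kgStop("kgConfigError", "n_intermediates: must be named by semantic type")
  }
  if (any(n_intermediates < 0)) {
    kgStop("kgConfigError", "n_intermediates: counts must be non-negative")
  }
  if (direct_edge_prob < 0 || direct_edge_prob > 1) {
    kgStop("kgConfigError", "direct_edge_prob: must be in [0, 1]")
  }
  pps <- unlist(paths_per_strength)
  if (length(pps) != 3L) {
    kgStop("kgConfigError", "paths_per_strength: need high, mid, low")
  }
  names(pps) <- c("high", "mid", "low")
  if (any(pps < 0)) {
    kgStop("kgConfigError", "paths_per_strength: counts must be non-negative")
  }
  allZero <- all(pps == 0)
  if (!allZero && !(pps["high"] > pps["mid"] && pps["mid"] > pps["low"])) {
    kgStop("kgConfigError",
           "paths_per_strength: must be strictly decreasing high > mid > low (or all zero)")
  }
  if ((allZero || min(pps) == 0) && direct_edge_prob < 1) {
    kgStop("kgConfigError",
           "paths_per_strength: a tier plants no bridge path, so direct_edge_prob must be 1 to keep memberships realizable")
  }
  if (max(pps) > 0 && any(n_intermediates %/% 3L < max(pps))) {
    kgStop("kgConfigError",
           "n_intermediates: each type's per-disease sub-pool (a third of the pool) must hold at least max(paths_per_strength) nodes")
  }
  if (keyword_rate < 0 || keyword_rate > 1) {
    kgStop("kgConfigError", "keyword_rate: must be in [0, 1]")
  }
  structure(
    list(n_aapp = as.integer(n_aapp),
         region_probs = region_probs,
         n_intermediates = stats::setNames(as.integer(n_intermediates),
                                           names(n_intermediates)),
         direct_edge_prob = direct_edge_prob,
         paths_per_strength = stats::setNames(as.integer(pps), names(pps)),
         keyword_rate = keyword_rate,
         seed = as.integer(seed)),
    class = "GeneratorConfig"
  )
}

#' Generate a synthetic knowledge graph with planted ground truth
#'
#' Draws each AAPP node's Venn-region membership i.i.d. from
#' \code{region_probs}, assigns a relevance tier per (node, disease)
#' membership, realizes each membership as an optional direct edge plus the
#' tier's number of distinct 2-hop bridge paths (each through its own
#' intermediate node, so HeteSim strength grows with path count), and
#' plants biological-process labels whose keywords are embedded into node
#' names at rate \code{keyword_rate}. The pseudo-random stream is consumed
#' in a fixed order -- regions (membership, then tiers), then edges (direct
#' flags, then bridge choices), then names (labels, then keyword embedding)
#' -- so identical configurations give byte-identical output.
#'
#' @param config a \code{GeneratorConfig} from [generatorConfig()].
#' @return list with elements \code{graph} (a [KnowledgeGraph-class]) and
#'   \code{truth}: \code{region} (named character per AAPP cui),
#'   \code{membership} (named list of member disease labels),
#'   \code{tiers} (data.frame cui/disease/tier),
#'   \code{direct} (data.frame cui/disease/direct),
#'   \code{process_labels} (named list of planted categories).
#' @seealso [writeKGFixture()], [generatorConfig()]
#' @export
generateKG <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  n <- config$n_aapp
  targets <- diseaseTargets()
  diseases <- names(targets)
  tiersAvail <- c("high", "mid", "low")

  aappCui <- sprintf("P%05d", seq_len(n))

  # --- stage 1: regions, then tiers -------------------------------------
  regionIdx <- if (n) sample.int(8L, n, replace = TRUE,
                                 prob = config$region_probs) else integer(0)
  region <- stats::setNames(regionLabels()[regionIdx], aappCui)
  membership <- lapply(region, regionMembers)
  tierMat <- matrix(sample(tiersAvail, n * 3L, replace = TRUE),
                    nrow = n, ncol = 3L, dimnames = list(NULL, diseases))

  # --- stage 2: edges ----------------------------------------------------
  directMat <- matrix(stats::runif(n * 3L) < config$direct_edge_prob,
                      nrow = n, ncol = 3L, dimnames = list(NULL, diseases))
  itypes <- names(config$n_intermediates)
  interCui <- list()
  interPool <- list()   # per-type, per-disease sub-pools
  for (ty in itypes) {
    nI <- config$n_intermediates[[ty]]
    interCui[[ty]] <- sprintf("I%s%04d", ty, seq_len(nI))
    # bridge nodes are dedicated to one disease so the set of AAPP nodes
    # within 2 hops of a disease is exactly its planted membership
    m <- nI %/% 3L
    interPool[[ty]] <- lapply(seq_along(diseases), function(j) {
      interCui[[ty]][seq.int((j - 1L) * m + 1L, j * m)]
    })
    names(interPool[[ty]]) <- diseases
  }
  heads <- character(0); rels <- character(0); tails <- character(0)
  pmidCounter <- 0L
  addEdge <- function(h, r, t) {
    heads[[length(heads) + 1L]] <<- h
    rels[[length(rels) + 1L]] <<- r
    tails[[length(tails) + 1L]] <<- t
    pmidCounter <<- pmidCounter + 1L
    as.character(pmidCounter)
  }
  pmids <- character(0)
  truthTier <- list(); truthDirect <- list()
  for (i in seq_len(n)) {
    for (d in diseases) {
      if (!d %in% membership[[i]]) next
      tier <- tierMat[i, d]
      isDirect <- directMat[i, d]
      truthTier[[length(truthTier) + 1L]] <-
        data.frame(cui = aappCui[i], disease = d, tier = tier)
      truthDirect[[length(truthDirect) + 1L]] <-
        data.frame(cui = aappCui[i], disease = d, direct = isDirect)
      if (isDirect) {
        pmids[[length(pmids) + 1L]] <- addEdge(aappCui[i], "affects", targets[[d]])
      }
      k <- config$paths_per_strength[[tier]]
      if (k > 0L) {
        # all k bridge paths of one membership run through a single
        # intermediate type: they condense into one metapath signature
        # whose HeteSim value grows with the number of distinct bridges,
        # so the planted tier is monotone in the score
        ty <- sample(itypes, 1L)
        mids <- sample(interPool[[ty]][[d]], k, replace = FALSE)
        for (m in mids) {
          pmids[[length(pmids) + 1L]] <-
            addEdge(aappCui[i], "associated_with", m)
          pmids[[length(pmids) + 1L]] <-
            addEdge(m, "associated_with", targets[[d]])
        }
      }
    }
  }

  # --- stage 3: names (labels, then keyword embedding) -------------------
  cats <- names(categoryWeights())
  w <- categoryWeights() / sum(categoryWeights())
  processLabels <- vector("list", n)
  names(processLabels) <- aappCui
  aappNames <- character(n)
  for (i in seq_len(n)) {
    nlab <- 1L + (stats::runif(1L) < 0.3)
    labs <- sample(cats, nlab, replace = FALSE, prob = w)
    processLabels[[i]] <- sort(labs)
    nm <- sprintf("aapp concept %05d", i)
    for (cg in processLabels[[i]]) {
      if (stats::runif(1L) < config$keyword_rate) {
        nm <- paste(nm, embedKeywords()[[cg]])
      }
    }
    aappNames[i] <- nm
  }

  nodes <- rbind(
    data.frame(cui = unname(targets), name = unname(diseaseNames()[diseases]),
               node_type = "dsyn"),
    if (n) data.frame(cui = aappCui, name = aappNames, node_type = "aapp"),
    do.call(rbind, lapply(itypes, function(ty) {
      if (!length(interCui[[ty]])) return(NULL)
      data.frame(cui = interCui[[ty]],
                 name = sprintf("bridge %s %04d", ty,
                                seq_along(interCui[[ty]])),
                 node_type = ty)
    }))
  )
  triples <- data.frame(head = heads, relation = rels, tail = tails,
                        pmids = pmids, stringsAsFactors = FALSE)
  graph <- KnowledgeGraph(
    nodes, triples,
    typeVocabulary = sort(unique(c("dsyn", "aapp", itypes))),
    relationVocabulary = c("affects", "associated_with"))
  truth <- list(
    region = region,
    membership = membership,
    tiers = if (length(truthTier)) do.call(rbind, truthTier) else
      data.frame(cui = character(0), disease = character(0), tier = character(0)),
    direct = if (length(truthDirect)) do.call(rbind, truthDirect) else
      data.frame(cui = character(0), disease = character(0), direct = logical(0)),
    process_labels = processLabels
  )
  list(graph = graph, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Emits the node and edge TSV tables (the [loadKnowledgeGraph()] dialect),
#' the ground-truth record as JSON, and the generator configuration as
#' YAML, so the fixture can be reloaded or regenerated exactly.
#'
#' @param graph a [KnowledgeGraph-class] from [generateKG()].
#' @param truth the matching ground-truth record.
#' @param config the \code{GeneratorConfig} used.
#' @param dir output directory (created if missing).
#' @return invisibly, the four file paths.
#' @export
writeKGFixture <- function(graph, truth, config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) kgStop("kgIOError", "cannot create directory: %s", dir)
  }
  paths <- c(nodes = file.path(dir, "nodes.tsv"),
             edges = file.path(dir, "edges.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  writeKnowledgeGraph(graph, paths[["nodes"]], paths[["edges"]])
  tt <- truth
  tt$region <- as.list(tt$region)     # jsonlite drops atomic-vector names
  jsonlite::write_json(tt, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "list")
  cfg <- unclass(config)
  for (f in c("region_probs", "n_intermediates", "paths_per_strength")) {
    cfg[[f]] <- as.list(cfg[[f]])     # keep names in the YAML map
  }
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Read a synthetic fixture back from disk
#'
#' @param dir directory written by [writeKGFixture()].
#' @return list with \code{graph}, \code{truth}, \code{config}.
#' @export
readKGFixture <- function(dir) {
  graph <- loadKnowledgeGraph(file.path(dir, "nodes.tsv"),
                              file.path(dir, "edges.tsv"))
  tj <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                           simplifyVector = TRUE, simplifyDataFrame = TRUE)
  asChr <- function(m) if (length(m)) as.character(m) else character(0)
  emptyDF <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  tiers <- if (is.data.frame(tj$tiers)) tj$tiers else
    emptyDF(c("cui", "disease", "tier"))
  direct <- if (is.data.frame(tj$direct)) tj$direct else {
    d <- emptyDF(c("cui", "disease")); d$direct <- logical(0); d
  }
  truth <- list(
    region = unlist(tj$region),
    membership = lapply(tj$membership, asChr),
    tiers = tiers,
    direct = direct,
    process_labels = lapply(tj$process_labels, asChr)
  )
  cy <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- generatorConfig(
    n_aapp = cy$n_aapp,
    region_probs = unlist(cy$region_probs),
    n_intermediates = unlist(cy$n_intermediates),
    direct_edge_prob = cy$direct_edge_prob,
    paths_per_strength = unlist(cy$paths_per_strength),
    keyword_rate = cy$keyword_rate,
    seed = cy$seed)
  list(graph = graph, truth = truth, config = config)
}
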