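# Toy graph used across signature tests: target T, two g-type midpoints,
# two aapp sources sharing one of the target's two midpoint neighbors.
toyMeetingGraph <- function() {
  KnowledgeGraph(
    data.frame(cui = c("T", "m1", "m2", "s1", "s2"),
               name = c("T", "m1", "m2", "s1", "s2"),
               node_type = c("dsyn", "g", "g", "aapp", "aapp")),
    data.frame(head = c("s1", "s2", "s2", "T", "T"),
               relation = "r",
               tail = c("m1", "m1", "m2", "m1", "m2"), pmids = ""))
}

test_that("signature enumeration finds exactly the realized shapes", {
  g <- KnowledgeGraph(
    data.frame(cui = c("a", "T", "x", "y"), name = c("a", "T", "x", "y"),
               node_type = c("aapp", "dsyn", "g", "h")),
    data.frame(head = c("a", "a", "x", "a", "y"), relation = "r",
               tail = c("T", "x", "T", "y", "T"), pmids = ""))
  # direct triple: one signature of length 1 among the results
  sigs <- enumerateSignatures(g, "a", "T", 1)
  expect_length(sigs, 1L)
  expect_equal(length(sigs[[1L]]), 1L)
  expect_equal(sigs[[1L]]$relations, "r")
  # two parallel 2-hop routes through different intermediate types
  sigs2 <- enumerateSignatures(g, "a", "T", 2)
  two_hop <- Filter(function(s) length(s) == 2L, sigs2)
  expect_length(two_hop, 2L)
  expect_setequal(vapply(two_hop, function(s) s$nodeTypes[2L], ""),
                  c("g", "h"))
  # no path within reach
  iso <- KnowledgeGraph(
    data.frame(cui = c("a", "T"), name = c("a", "T"),
               node_type = c("aapp", "dsyn")),
    data.frame(), typeVocabulary = c("aapp", "dsyn"),
    relationVocabulary = "r")
  expect_length(enumerateSignatures(iso, "a", "T", 3), 0L)
  expect_error(enumerateSignatures(g, "nope", "T", 2),
               class = "kgLookupError")
})

test_that("hetesim equals the hand-computed cosine on the 5-node toy graph", {
  g <- toyMeetingGraph()
  sig <- metapathSignature(c("aapp", "g", "dsyn"), c("r", "r"),
                           c("forward", "reverse"))
  # s2 reaches both of the target's midpoints: identical meeting
  # distributions, cosine 1
  expect_equal(heteSim(g, "s2", "T", sig), 1, tolerance = 1e-12)
  # s1 reaches one of two: cos((1,0),(1/2,1/2)) = 1/sqrt(2)
  expect_equal(heteSim(g, "s1", "T", sig), 1 / sqrt(2), tolerance = 1e-12)
  # and both agree with the exhaustive path-instance oracle
  expect_equal(heteSim(g, "s1", "T", sig), oracleHeteSim(g, "s1", "T", sig),
               tolerance = 1e-12)
  expect_equal(heteSim(g, "s2", "T", sig), oracleHeteSim(g, "s2", "T", sig),
               tolerance = 1e-12)
})

test_that("self-relatedness under a palindromic signature is 1", {
  g <- KnowledgeGraph(
    data.frame(cui = c("x", "m"), name = c("x", "m"),
               node_type = c("aapp", "b")),
    data.frame(head = "x", relation = "r", tail = "m", pmids = ""))
  sig <- metapathSignature(c("aapp", "b", "aapp"), c("r", "r"),
                           c("forward", "reverse"))
  expect_equal(heteSim(g, "x", "x", sig), 1, tolerance = 1e-12)
})

test_that("an unmatched signature gives 0, not an error", {
  g <- toyMeetingGraph()
  g2 <- KnowledgeGraph(kgNodes(g), kgTriples(g),
                       typeVocabulary = c("aapp", "g", "dsyn"),
                       relationVocabulary = c("r", "s"))
  sig <- metapathSignature(c("aapp", "g", "dsyn"), c("s", "s"),
                           c("forward", "reverse"))
  expect_equal(heteSim(g2, "s1", "T", sig), 0)
  badSig <- metapathSignature(c("aapp", "g", "dsyn"), c("nope", "r"),
                              c("forward", "reverse"))
  expect_error(heteSim(g2, "s1", "T", badSig), class = "kgSignatureError")
})

test_that("odd-length signatures split the middle relation correctly", {
  # two sources with direct edges to T: each source's forward distribution
  # is a point mass on its own edge instance, T's backward distribution is
  # uniform over both, so hetesim = 1/sqrt(2)
  g <- KnowledgeGraph(
    data.frame(cui = c("a", "b", "T"), name = c("a", "b", "T"),
               node_type = c("aapp", "aapp", "dsyn")),
    data.frame(head = c("a", "b"), relation = "r", tail = "T", pmids = ""))
  sig <- metapathSignature(c("aapp", "dsyn"), "r", "forward")
  expect_equal(heteSim(g, "a", "T", sig), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(heteSim(g, "a", "T", sig), oracleHeteSim(g, "a", "T", sig),
               tolerance = 1e-12)
})

test_that("matrix hetesim equals the brute-force oracle on random graphs", {
  set.seed(23)
  checked <- 0L
  for (i in 1:60) {
    g <- randomGraph(nNodes = sample(5:10, 1L), nEdges = sample(8:16, 1L))
    cuis <- kgNodes(g)$cui
    st <- sample(cuis, 2L)
    sigs <- enumerateSignatures(g, st[1L], st[2L], 3)
    for (sig in sigs) {
      v <- heteSim(g, st[1L], st[2L], sig)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, oracleHeteSim(g, st[1L], st[2L], sig),
                   tolerance = 1e-9)
      # symmetry: reading the path backwards swaps the roles
      expect_equal(v, heteSim(g, st[2L], st[1L], reverseSignature(sig)),
                   tolerance = 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 30L)
})

test_that("an additional disjoint 2-hop path never lowers the score", {
  buildFamily <- function(k) {
    mids <- sprintf("m%d", seq_len(k))
    bg <- sprintf("b%d", 1:5)
    KnowledgeGraph(
      data.frame(cui = c("s", "T", mids, bg),
                 name = c("s", "T", mids, bg),
                 node_type = c("aapp", "dsyn", rep("g", k + 5L))),
      data.frame(head = c(rep("s", k), mids, bg), relation = "r",
                 tail = c(mids, rep("T", k + 5L)), pmids = ""))
  }
  prev <- -Inf
  for (k in 1:4) {
    tab <- rankSources(buildFamily(k), "T", sourceType = "aapp")
    expect_gte(tab$aggregate[1L], prev)
    prev <- tab$aggregate[1L]
  }
})

test_that("rankSources handles single-path and multi-target aggregation", {
  g <- KnowledgeGraph(
    data.frame(cui = c("s", "T1", "T2", "o"), name = c("s", "T1", "T2", "o"),
               node_type = c("aapp", "dsyn", "dsyn", "aapp")),
    data.frame(head = c("s", "s", "o"), relation = "r",
               tail = c("T1", "T2", "T1"), pmids = ""))
  one <- rankSources(g, "T1")
  srow <- one[one$source_cui == "s", ]
  sig <- enumerateSignatures(g, "s", "T1", 3)
  direct <- Filter(function(x) length(x) == 1L, sig)[[1L]]
  # per-target score for a node whose only length-1 signature is direct
  expect_equal(srow$hetesim,
               mean(vapply(sig, function(x) heteSim(g, "s", "T1", x), 0)))
  expect_equal(srow$n_signatures, length(sig))
  # multi-target aggregation is the exact mean of the per-target scores
  both <- rankSources(g, c("T1", "T2"))
  sboth <- both[both$source_cui == "s", ]
  expect_equal(unique(sboth$aggregate),
               mean(sboth$hetesim[order(sboth$target_cui)]))
  lonely <- KnowledgeGraph(
    data.frame(cui = c("T", "d2", "p"), name = c("T", "d2", "p"),
               node_type = c("dsyn", "dsyn", "aapp")),
    data.frame(head = "T", relation = "r", tail = "d2", pmids = ""))
  expect_warning(res <- rankSources(lonely, "T", sourceType = "aapp"),
                 "no source nodes")
  expect_equal(nrow(res), 0L)
})

test_that("ranking output is bit-identical across reruns", {
  gt <- generateKG(generatorConfig(n_aapp = 40L, seed = 31L))
  a <- rankSources(gt$graph, unname(diseaseTargets()))
  b <- rankSources(gt$graph, unname(diseaseTargets()))
  expect_identical(a, b)
})

test_that("planted high-tier nodes outrank low-tier nodes", {
  gt <- generateKG(generatorConfig(n_aapp = 150L, seed = 19L))
  rs <- rankSources(gt$graph, unname(diseaseTargets()))
  tr <- gt$truth
  reg <- names(tr$region)[tr$region == "all_three"]
  tab <- rs[rs$target_cui == diseaseTargets()[["AD"]], ]
  tab$rank <- rank(-tab$hetesim)
  tiers <- tr$tiers[tr$tiers$disease == "AD", ]
  hi <- intersect(tiers$cui[tiers$tier == "high"], reg)
  lo <- intersect(tiers$cui[tiers$tier == "low"], reg)
  expect_gt(length(hi), 5L); expect_gt(length(lo), 5L)
  expect_lt(mean(tab$rank[match(hi, tab$source_cui)]),
            mean(tab$rank[match(lo, tab$source_cui)]))
})
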