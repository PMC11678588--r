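test_that("degenerate region vectors plant exactly what they promise", {
  probs <- c(AD_only = 0, ALS_only = 0, FTD_only = 0, AD_ALS = 0,
             AD_FTD = 0, ALS_FTD = 0, all_three = 1, none = 0)
  gt <- generateKG(generatorConfig(n_aapp = 10L, region_probs = probs,
                                   seed = 3L))
  expect_length(gt$truth$membership, 10L)
  expect_true(all(vapply(gt$truth$membership,
                         function(m) setequal(m, c("AD", "ALS", "FTD")),
                         TRUE)))
})

test_that("forced directness classifies every member node as direct", {
  gt <- generateKG(generatorConfig(
    n_aapp = 15L, direct_edge_prob = 1,
    paths_per_strength = c(high = 0L, mid = 0L, low = 0L), seed = 4L))
  members <- names(Filter(length, gt$truth$membership))
  expect_gt(length(members), 0L)
  for (cui in members) {
    expect_equal(
      classifyEvidence(gt$graph, cui, unname(diseaseTargets())), "direct")
  }
})

test_that("region counts equal the multinomial draw recomputed independently", {
  cfg <- generatorConfig(n_aapp = 200L, seed = 7L)
  gt <- generateKG(cfg)
  # the documented stream order starts with one multinomial region draw
  set.seed(7L)
  idx <- sample.int(8L, 200L, replace = TRUE, prob = cfg$region_probs)
  expected <- table(factor(idx, levels = 1:8))
  observed <- table(factor(match(gt$truth$region,
                                 names(cfg$region_probs)), levels = 1:8))
  expect_equal(as.integer(observed), as.integer(expected))
})

test_that("identical config and seed give identical graph and truth", {
  cfg <- generatorConfig(n_aapp = 60L, seed = 21L)
  a <- generateKG(cfg)
  b <- generateKG(cfg)
  expect_identical(kgNodes(a$graph), kgNodes(b$graph))
  expect_identical(kgTriples(a$graph), kgTriples(b$graph))
  expect_identical(a$truth, b$truth)
})

test_that("every planted membership is realized within two hops", {
  gt <- generateKG(generatorConfig(n_aapp = 80L, direct_edge_prob = 0.3,
                                   seed = 13L))
  targets <- diseaseTargets()
  for (cui in names(gt$truth$membership)) {
    for (d in gt$truth$membership[[cui]]) {
      expect_true(targets[[d]] %in% oracleNeighborhood(gt$graph, cui, 2L),
                  label = sprintf("%s reaches %s within 2 hops", cui, d))
    }
  }
  # direct_flag true implies a literal length-1 edge
  tr <- kgTriples(gt$graph)
  dd <- gt$truth$direct
  for (i in seq_len(nrow(dd))) {
    if (!dd$direct[i]) next
    t <- targets[[dd$disease[i]]]
    expect_true(any(tr$head == dd$cui[i] & tr$tail == t) ||
                any(tr$tail == dd$cui[i] & tr$head == t))
  }
})

test_that("planted Venn regions are recovered exactly by overlap analysis", {
  gt <- generateKG(generatorConfig(n_aapp = 150L, seed = 9L))
  memb <- gt$truth$membership
  sets <- lapply(c("AD", "ALS", "FTD"), function(d) {
    names(Filter(function(m) d %in% m, memb))
  })
  v <- intersectSets(sets[[1]], sets[[2]], sets[[3]])
  planted <- table(factor(gt$truth$region, levels = names(vennRegions(v))))
  expect_equal(unname(vennRegions(v)), as.numeric(planted))
})

test_that("fixtures round-trip and regenerate identically from the saved config", {
  cfg <- generatorConfig(n_aapp = 40L, seed = 17L)
  gt <- generateKG(cfg)
  dir <- tempfile("fixture")
  writeKGFixture(gt$graph, gt$truth, cfg, dir)
  back <- readKGFixture(dir)
  expect_equal(kgNodes(back$graph), kgNodes(gt$graph))
  expect_equal(kgTriples(back$graph), kgTriples(gt$graph))
  expect_length(back$truth$process_labels, cfg$n_aapp)
  expect_equal(back$truth$region, gt$truth$region)
  expect_equal(back$truth$membership, gt$truth$membership)
  expect_equal(back$truth$direct$direct, gt$truth$direct$direct)
  # regenerating from the saved config reproduces the saved fixture
  regen <- generateKG(back$config)
  expect_identical(kgTriples(regen$graph), kgTriples(gt$graph))
  expect_identical(regen$truth$tiers, gt$truth$tiers)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generatorConfig(region_probs = rep(0.2, 8)), "region_probs")
  expect_error(generatorConfig(n_aapp = -1), "n_aapp")
  expect_error(generatorConfig(direct_edge_prob = 1.5), "direct_edge_prob")
  expect_error(
    generatorConfig(paths_per_strength = c(high = 1L, mid = 2L, low = 3L)),
    "paths_per_strength")
  expect_error(
    generatorConfig(paths_per_strength = c(high = 0L, mid = 0L, low = 0L),
                    direct_edge_prob = 0.5),
    "paths_per_strength")
  expect_error(generatorConfig(keyword_rate = -0.1), "keyword_rate")
  expect_error(
    generatorConfig(n_intermediates = c(gngm = 2L, celf = 30L, orch = 30L)),
    "n_intermediates")
})
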