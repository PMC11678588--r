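test_that("z-scores and Hazen percentiles match closed forms", {
  out <- normalizeScores(data.frame(cui = c("a", "b", "c"), raw_score = 1:3))
  expect_equal(out$z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(out$percentile, c(100 / 6, 50, 250 / 3), tolerance = 1e-4)

  single <- normalizeScores(data.frame(cui = "a", raw_score = 0.4))
  expect_equal(single$z, 0)
  expect_equal(single$percentile, 50)

  expect_warning(
    flat <- normalizeScores(data.frame(cui = letters[1:4], raw_score = 2)),
    "identical")
  expect_equal(flat$z, rep(0, 4))
  expect_equal(flat$percentile, rep(50, 4))

  expect_error(normalizeScores(data.frame(cui = character(0),
                                          raw_score = numeric(0))),
               class = "kgInputError")
})

test_that("normalized z has zero mean and unit population variance", {
  set.seed(41)
  x <- data.frame(cui = sprintf("n%04d", 1:1000), raw_score = rnorm(1000))
  out <- normalizeScores(x)
  expect_lt(abs(mean(out$z)), 1e-12)
  expect_lt(abs(mean(out$z^2) - 1), 1e-9)
  # percentile strictly increasing with raw score up to ties
  o <- order(out$raw_score)
  expect_true(all(diff(out$percentile[o]) >= 0))
})

test_that("re-normalizing changes values but never the ordering", {
  set.seed(43)
  tab <- normalizeScores(data.frame(cui = sprintf("n%03d", 1:50),
                                    raw_score = runif(50)))
  again <- normalizeScores(data.frame(cui = tab$cui, raw_score = tab$z))
  expect_equal(order(again$percentile), order(tab$percentile))
})

test_that("percentiles are equivariant under cui relabeling", {
  set.seed(47)
  raw <- runif(30)
  a <- normalizeScores(data.frame(cui = sprintf("x%02d", 1:30),
                                  raw_score = raw))
  b <- normalizeScores(data.frame(cui = sprintf("y%02d", 30:1),
                                  raw_score = raw))
  expect_equal(a$percentile, b$percentile)
})

test_that("topPercent applies the ceiling rule and cui tie-break", {
  set.seed(53)
  tab <- data.frame(cui = sprintf("n%03d", 1:250), raw_score = runif(250))
  expect_length(topPercent(tab, 1), 3L)       # ceil(2.5)
  expect_length(topPercent(tab, 100), 250L)
  expect_equal(topPercent(data.frame(cui = character(0),
                                     raw_score = numeric(0)), 1),
               character(0))
  # all-tied table: selection falls back to ascending cui
  tied <- data.frame(cui = c("c", "a", "b", "d"), raw_score = 1)
  expect_equal(topPercent(tied, 50), c("a", "b"))
  expect_error(topPercent(tab, 0))
})

test_that("top-percent enriches for planted high-tier nodes beyond the null", {
  gt <- generateKG(generatorConfig(n_aapp = 150L, seed = 29L))
  rs <- rankSources(gt$graph, unname(diseaseTargets()))
  tab <- rs[rs$target_cui == diseaseTargets()[["AD"]],
            c("source_cui", "hetesim")]
  top <- topPercent(tab, 10)
  tiers <- gt$truth$tiers
  hi <- tiers$cui[tiers$disease == "AD" & tiers$tier == "high"]
  hits <- length(intersect(top, hi))
  # null expectation of a uniformly random draw of the same size
  nullExp <- length(top) * length(intersect(hi, tab$source_cui)) / nrow(tab)
  expect_gt(hits, nullExp)
})

test_that("composite scores are means over present diseases", {
  # three-disease node: mean of the three published GRN protein scores
  grn <- compositeScores(list(
    AD = data.frame(cui = "GRN", raw_score = 0.888),
    ALS = data.frame(cui = "GRN", raw_score = 0.934),
    FTD = data.frame(cui = "GRN", raw_score = 0.988)))
  expect_equal(grn$composite, 0.93667, tolerance = 1e-5)
  expect_equal(grn$diseases, "AD;ALS;FTD")

  # single-disease node: composite equals the HeteSim score itself
  one <- compositeScores(list(AD = data.frame(cui = "X", raw_score = 0.991)))
  expect_equal(one$composite, 0.991)
  expect_equal(one$n_diseases, 1L)

  # extremes average to the midpoint
  half <- compositeScores(list(
    A = data.frame(cui = "n", raw_score = 0),
    B = data.frame(cui = "n", raw_score = 1)))
  expect_equal(half$composite, 0.5)
})

test_that("composite lies within the contributing per-disease scores", {
  set.seed(59)
  for (i in 1:20) {
    cuis <- sprintf("n%02d", 1:12)
    per <- list(
      AD = data.frame(cui = sample(cuis, 8), raw_score = runif(8)),
      ALS = data.frame(cui = sample(cuis, 8), raw_score = runif(8)),
      FTD = data.frame(cui = sample(cuis, 8), raw_score = runif(8)))
    comp <- compositeScores(per)
    long <- do.call(rbind, lapply(names(per), function(d) {
      data.frame(cui = per[[d]]$cui, score = per[[d]]$raw_score)
    }))
    for (j in seq_len(nrow(comp))) {
      sc <- long$score[long$cui == comp$cui[j]]
      expect_gte(comp$composite[j], min(sc) - 1e-12)
      expect_lte(comp$composite[j], max(sc) + 1e-12)
    }
  }
})
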