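test_that("keyword mapping is word-bounded, case-insensitive, multi-label", {
  nodes <- data.frame(
    cui = c("P1", "P2", "P3", "P4"),
    name = c("Synaptic vesicle protein X",
             "cytokine-induced kinase, cell cycle entry",
             "unrelatable concept",
             "transmembrane thing"))   # 'membrane' must not match inside a word
  expect_message(m <- mapNodes(nodes), "matched no")
  expect_equal(m$P1, "synapse and neurotransmission")
  expect_setequal(m$P2, c("inflammation and immune response",
                          "cell cycle regulation"))
  expect_length(m$P3, 0L)
  expect_length(m$P4, 0L)
})

test_that("taxonomy validation enforces the eight categories", {
  lex <- defaultLex <- processTaxonomy()$lexicon
  expect_error(processTaxonomy(lexicon = lex[-1]), class = "kgConfigError")
  lex[[1]] <- character(0)
  expect_error(processTaxonomy(lexicon = lex), class = "kgConfigError")
  # keywords are lower-cased and deduplicated
  lex <- defaultLex
  lex[["protein aggregation"]] <- c("Plaque", "plaque", "TANGLE")
  tx <- processTaxonomy(lexicon = lex)
  expect_equal(tx$lexicon[["protein aggregation"]], c("plaque", "tangle"))
})

test_that("planted process labels are recovered exactly at keyword_rate 1", {
  gt <- generateKG(generatorConfig(n_aapp = 120L, keyword_rate = 1,
                                   seed = 37L))
  aapp <- kgNodes(gt$graph)[kgNodes(gt$graph)$node_type == "aapp", ]
  m <- mapNodes(aapp)
  expect_equal(m[names(gt$truth$process_labels)],
               gt$truth$process_labels)
})

test_that("intersection counts equal an exhaustive hand tally", {
  mapping <- list(n1 = c("protein aggregation"),
                  n2 = c("protein aggregation",
                         "inflammation and immune response"),
                  n3 = character(0),
                  n4 = c("synapse and neurotransmission"))
  top <- list(AD = c("n1", "n2", "n3"), ALS = c("n2", "n3", "n4"),
              FTD = c("n4"))
  expect_warning(counts <- intersectionProfile(top, mapping), "AD:FTD")
  expect_equal(counts["protein aggregation", "AD:ALS"], 1L)
  expect_equal(counts["inflammation and immune response", "AD:ALS"], 1L)
  expect_equal(sum(counts[, "AD:ALS"]), 2L)   # n3 has no labels, adds nothing
  expect_equal(sum(counts[, "AD:FTD"]), 0L)
  expect_equal(counts["synapse and neurotransmission", "ALS:FTD"], 1L)
  # multi-label conservation: column sums equal total assignments
  shared <- intersect(top$AD, top$ALS)
  expect_equal(sum(counts[, "AD:ALS"]),
               length(unlist(mapping[shared])))
})

test_that("single shared node yields a single count and nothing else", {
  mapping <- list(x = "inflammation and immune response")
  top <- list(A = "x", B = "x")
  counts <- intersectionProfile(top, mapping)
  expect_equal(counts["inflammation and immune response", "A:B"], 1L)
  expect_equal(sum(counts), 1L)
})

test_that("normalization yields column percentages", {
  counts <- matrix(0, nrow = 8, ncol = 3,
                   dimnames = list(paste0("c", 1:8), paste0("i", 1:3)))
  counts[3, 1] <- 7
  expect_warning(norm <- normalizeProfile(counts), "all-zero")
  expect_equal(norm[3, 1], 100)
  expect_equal(sum(norm[, 2]), 0)

  uniform <- matrix(5, nrow = 8, ncol = 2)
  expect_equal(unique(as.vector(normalizeProfile(uniform))), 12.5)

  set.seed(71)
  rnd <- matrix(rpois(24, 6) + 1, nrow = 8)
  expect_true(all(abs(colSums(normalizeProfile(rnd)) - 100) < 1e-9))
})

test_that("process z-scores match the closed-form population version", {
  x <- matrix(c(10, 10, 10, 0, 0, 30), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "peaked"), paste0("i", 1:3)))
  expect_warning(z <- processZscores(x), "flat")
  expect_equal(unname(z["flat", ]), c(0, 0, 0))
  expect_equal(unname(z["peaked", ]), c(-0.7071, -0.7071, 1.4142),
               tolerance = 1e-4)
  set.seed(73)
  rnd <- matrix(runif(24), nrow = 8,
                dimnames = list(paste0("c", 1:8), paste0("i", 1:3)))
  zr <- processZscores(rnd)
  expect_true(all(abs(rowSums(zr)) < 1e-9))
  expect_error(processZscores(rnd[, 1, drop = FALSE]),
               class = "kgInputError")
})

test_that("overall shares aggregate across intersections", {
  counts <- matrix(0, nrow = 8, ncol = 3,
                   dimnames = list(paste0("c", 1:8), paste0("i", 1:3)))
  counts[1, ] <- c(2, 1, 1)
  ov <- overallPercentages(counts)
  expect_equal(ov$share_pct[1], 100)
  counts[2, ] <- c(1, 2, 1)
  ov <- overallPercentages(counts)
  expect_equal(ov$share_pct[1:2], c(50, 50))
  expect_equal(ov$share_rounded[1:2], c(50, 50))
  expect_error(overallPercentages(counts * 0), class = "kgInputError")
})

test_that("nodes without labels change no counts", {
  mapping <- list(a = "membrane regulation", b = character(0))
  withB <- intersectionProfile(list(X = c("a", "b"), Y = c("a", "b")),
                               mapping)
  withoutB <- intersectionProfile(list(X = "a", Y = "a"), mapping["a"])
  expect_equal(withB, withoutB)
})

test_that("overall shares recover the planted category distribution", {
  gt <- generateKG(generatorConfig(n_aapp = 400L, keyword_rate = 1,
                                   seed = 79L))
  labs <- unlist(gt$truth$process_labels, use.names = FALSE)
  planted <- table(factor(labs, levels = processTaxonomy()$categories))
  plantedPct <- 100 * as.numeric(planted) / sum(planted)
  # map every AAPP node and tally all assignments (single "intersection")
  aapp <- kgNodes(gt$graph)[kgNodes(gt$graph)$node_type == "aapp", ]
  m <- mapNodes(aapp)
  counts <- intersectionProfile(list(A = aapp$cui, B = aapp$cui), m)
  ov <- overallPercentages(counts[, 1, drop = FALSE])
  # multinomial 99% margin at this sample size
  margin <- 100 * 2.58 * sqrt(0.25 / length(labs))
  expect_true(all(abs(ov$share_pct - plantedPct) < margin))
})
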