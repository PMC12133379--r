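test_that("local webs are exact induced subgraphs of the metaweb", {
  mw <- fixtureMetaweb()
  w <- buildLocalWeb(c("A", "B", "C"), mw)
  got <- sort(paste0(w@edges$consumer, "->", w@edges$resource))
  expect_identical(got, sort(c("B->A", "C->B", "C->A")))

  w1 <- buildLocalWeb("A", mw)
  expect_identical(nSpecies(w1), 1L)
  expect_identical(nLinks(w1), 0L)

  w0 <- buildLocalWeb(character(0), mw)
  expect_identical(nSpecies(w0), 0L)

  expect_error(buildLocalWeb(c("A", "Z"), mw), "unknown species")
})

test_that("roles follow the bird-web convention", {
  expect_identical(unname(speciesRoles(chainWeb(3))[c("A", "B", "C")]),
                   c("basal", "intermediate", "top"))
  # isolated species count as basal (no bird prey)
  w <- webFromEdges(c("A", "B", "X"), c("B->A"))
  expect_identical(unname(speciesRoles(w)["X"]), "basal")
  # a 2-cycle gives two intermediates
  w2 <- webFromEdges(c("X", "Y"), c("X->Y", "Y->X"))
  expect_true(all(speciesRoles(w2) == "intermediate"))
})

test_that("prey-averaged trophic levels match closed forms", {
  tl <- trophicLevels(chainWeb(3))
  expect_equal(unname(tl[c("A", "B", "C")]), c(1, 2, 3))
  expect_equal(mean(tl), 2)

  w <- webFromEdges(c("A", "B", "C"), c("C->A", "C->B", "B->A"))
  tl <- trophicLevels(w)
  expect_equal(unname(tl["C"]), 2.5)
  expect_equal(mean(tl), (1 + 2 + 2.5) / 3)

  w0 <- webFromEdges(LETTERS[1:4], character(0))
  expect_equal(unname(trophicLevels(w0)), rep(1, 4))
})

test_that("mean food chain length matches closed forms and the path oracle", {
  expect_equal(meanFoodChainLength(chainWeb(3)), 2)
  w <- webFromEdges(c("A", "B", "C"), c("C->A", "C->B", "B->A"))
  expect_equal(meanFoodChainLength(w), 1.5)
  diamond <- webFromEdges(LETTERS[1:4],
                          c("D->B", "D->C", "B->A", "C->A"))
  expect_equal(meanFoodChainLength(diamond), oracleMFCL(diamond))
  expect_equal(meanFoodChainLength(diamond), 2)
  # cyclic web falls back to simple-path enumeration
  cyc <- webFromEdges(c("X", "Y"), c("X->Y", "Y->X"))
  expect_equal(meanFoodChainLength(cyc), oracleMFCL(cyc))
  expect_true(is.na(meanFoodChainLength(webFromEdges("A", character(0)))))
})

test_that("fraction of omnivory counts consumers spanning >= 2 prey levels", {
  w <- webFromEdges(c("A", "B", "C"), c("C->A", "C->B", "B->A"))
  expect_equal(fractionOmnivory(w), 1 / 3)
  expect_equal(fractionOmnivory(chainWeb(4)), 0)
  expect_equal(fractionOmnivory(webFromEdges(LETTERS[1:3], character(0))), 0)
})

test_that("generality and vulnerability average over the right denominators", {
  expect_equal(unname(dietMetrics(chainWeb(3))), c(1, 1))
  star <- webFromEdges(LETTERS[1:4], c("C->A", "C->B", "C->D"))
  expect_equal(unname(dietMetrics(star)), c(3, 1))
  e <- dietMetrics(webFromEdges(LETTERS[1:3], character(0)))
  expect_true(all(is.na(e)))
})

test_that("complexity metrics use S, L, L/S^2 and L/S", {
  expect_equal(unname(complexityMetrics(chainWeb(3))),
               c(3, 2, 2 / 9, 2 / 3))
  full3 <- webFromEdges(LETTERS[1:3],
                        c("A->B", "B->A", "A->C", "C->A", "B->C", "C->B"))
  expect_equal(unname(complexityMetrics(full3)["connectance"]), 6 / 9)
  expect_equal(unname(complexityMetrics(webFromEdges("A", character(0)))),
               c(1, 0, 0, 0))
})

test_that("modularity finds the known optima of simple graphs", {
  # two disjoint directed triangles: optimal undirected Q is 0.5
  tri2 <- webFromEdges(LETTERS[1:6],
                       c("A->B", "B->C", "C->A", "D->E", "E->F", "F->D"))
  expect_equal(webModularity(tri2, seed = 1), 0.5, tolerance = 1e-12)
  # complete graph: no partition beats the trivial one (Q = 0)
  full3 <- webFromEdges(LETTERS[1:3], c("A->B", "B->C", "C->A"))
  expect_equal(webModularity(full3, seed = 1), 0, tolerance = 1e-12)
  expect_true(is.na(webModularity(webFromEdges("A", character(0)))))
})

test_that("body mass per role averages the right species", {
  mw <- fixtureMetaweb()
  traits <- mwSpecies(mw)
  w <- buildLocalWeb(c("A", "B", "C"), mw)
  bm <- bodyMassByRole(w, traits)
  expect_equal(unname(bm), c(10, 100, 1000))
  # two tops with masses 200 and 400 average to 300
  tr <- data.frame(species_id = c("A", "T1", "T2"),
                   body_mass_g = c(10, 200, 400))
  w2 <- webFromEdges(c("A", "T1", "T2"), c("T1->A", "T2->A"))
  expect_equal(unname(bodyMassByRole(w2, tr)["bm_top"]), 300)
  expect_true(is.na(bodyMassByRole(w2, tr)["bm_intermediate"]))
})

test_that("the assembled metric vector is consistent and deterministic", {
  mw <- fixtureMetaweb()
  w <- buildLocalWeb(c("A", "B", "C"), mw)
  v <- computeAllMetrics(w, mwSpecies(mw), seed = 5)
  expect_named(v, METRIC_NAMES)
  expect_equal(unname(v["species_richness"]), 3)
  expect_equal(unname(v["mfcl"]), 1.5)
  expect_equal(unname(v["mean_trophic_level"]), (1 + 2 + 2.5) / 3)
  expect_equal(unname(v["n_basal"] + v["n_intermediate"] + v["n_top"]), 3)
  expect_identical(v, computeAllMetrics(w, mwSpecies(mw), seed = 5))

  v0 <- computeAllMetrics(buildLocalWeb(character(0), mw), mwSpecies(mw))
  expect_equal(unname(v0["species_richness"]), 0)
  expect_equal(unname(v0[c("n_basal", "n_intermediate", "n_top")]),
               c(0, 0, 0))
  expect_true(all(is.na(v0[c("mfcl", "mean_trophic_level", "modularity",
                             "connectance", "bm_top")])))
})

test_that("structural invariants hold on random webs", {
  for (s in 1:30) {
    n <- sample(3:8, 1)
    w <- randomWeb(n, runif(1, 0.15, 0.5), seed = 1000 + s)
    roles <- table(factor(speciesRoles(w),
                          c("basal", "intermediate", "top")))
    expect_identical(sum(roles), nSpecies(w))
    tl <- trophicLevels(w)
    if (all(is.finite(tl))) {
      expect_true(all(tl >= 1 - 1e-9))
      # the prey-averaging upper bound S only holds on acyclic webs
      if (igraph::is_dag(webIgraph(w)))
        expect_true(all(tl <= n + 1e-9))
      if (nLinks(w) == 0) expect_equal(unname(tl), rep(1, n))
    }
    mf <- meanFoodChainLength(w)
    if (nLinks(w) > 0 && !is.na(mf)) {
      expect_gte(mf, 1)
      expect_lte(mf, n - 1)
    }
    # adding one absent edge never decreases the complexity metrics
    all_pairs <- expand.grid(consumer = w@species, resource = w@species,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$consumer != all_pairs$resource, ]
    key <- paste(all_pairs$consumer, all_pairs$resource)
    have <- paste(w@edges$consumer, w@edges$resource)
    absent <- all_pairs[!key %in% have, , drop = FALSE]
    if (nrow(absent)) {
      w2 <- w
      w2@edges <- rbind(w@edges, absent[1, ])
      w2@roles <- classifyRoles(w2)
      c1 <- complexityMetrics(w)
      c2 <- complexityMetrics(w2)
      expect_true(all(c2[c("n_links", "connectance", "linkage_density")] >=
                        c1[c("n_links", "connectance", "linkage_density")]))
    }
  }
})
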