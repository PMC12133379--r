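# one 10 km cell centred at (5, 5) plus a second at (15, 5)
twoCells <- function() {
  data.frame(cell_id = c("c1", "c2"), x = c(5, 15), y = c(5, 5),
             region = "R1", stringsAsFactors = FALSE)
}

paRow <- function(id, cx, cy, r, level = 5, year = 2000, bird = FALSE,
                  region = "R1") {
  data.frame(pa_id = id, center_x = cx, center_y = cy, radius_km = r,
             area_km2 = pi * r^2, designation_year = year,
             protection_level = level, bird_directive = bird,
             region = region, stringsAsFactors = FALSE)
}

test_that("centre rule protects cells whose centre overlaps a PA", {
  cells <- twoCells()
  pas <- paRow("p1", 5, 5, 2)
  st <- assignProtectionStatus(cells, pas, coverageRule("center"))
  expect_identical(st$protected, c(TRUE, FALSE))
  expect_identical(st$pa_id, c("p1", NA_character_))
  # no PAs: everything non-protected
  st0 <- assignProtectionStatus(cells, pas[0, ], coverageRule("center"))
  expect_false(any(st0$protected))
  # invalid geometry is rejected with a message
  bad <- paRow("p2", 5, 5, -1)
  expect_message(stb <- assignProtectionStatus(cells, bad), "invalid geometry")
  expect_false(any(stb$protected))
})

test_that("area thresholds relabel partially covered cells", {
  cells <- twoCells()[1, ]
  # a huge disc whose boundary sits at x = 8: covers 80% of the cell
  R <- 1e4
  pas <- paRow("p1", 8 - R, 5, R)
  st50 <- assignProtectionStatus(cells, pas,
                                 coverageRule("area_threshold", 0.5))
  st90 <- assignProtectionStatus(cells, pas,
                                 coverageRule("area_threshold", 0.9))
  expect_true(st50$protected)
  expect_false(st90$protected)   # 80% covered < 90% threshold
})

test_that("overlap resolution follows the level -> age -> area -> random cascade", {
  a <- paRow("a", 0, 0, 5, level = 3, year = 1990)
  b <- paRow("b", 0, 0, 5, level = 7, year = 2005)
  expect_identical(resolveOverlaps(rbind(a, b))$pa_id, "b")

  a$protection_level <- b$protection_level <- 5
  expect_identical(resolveOverlaps(rbind(a, b))$pa_id, "a")  # oldest

  b$designation_year <- 1990
  a$area_km2 <- 120; b$area_km2 <- 400
  expect_identical(resolveOverlaps(rbind(a, b))$pa_id, "b")  # largest

  b$area_km2 <- 120
  pick1 <- resolveOverlaps(rbind(a, b), seed = 42)
  pick2 <- resolveOverlaps(rbind(a, b), seed = 42)
  expect_identical(pick1$pa_id, pick2$pa_id)                 # seeded, pure
  expect_error(resolveOverlaps(a[0, ]), "empty candidate")
})

test_that("the cascade resolves an exhaustive table of small candidate sets", {
  levels_ <- c(1, 2); years <- c(1990, 2005); areas <- c(100, 400)
  combos <- expand.grid(l1 = levels_, l2 = levels_, y1 = years, y2 = years,
                        a1 = areas, a2 = areas)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    cand <- rbind(
      paRow("x", 0, 0, 5, level = cb$l1, year = cb$y1),
      paRow("y", 0, 0, 5, level = cb$l2, year = cb$y2))
    cand$area_km2 <- c(cb$a1, cb$a2)
    got <- resolveOverlaps(cand, seed = 7)$pa_id
    # independent restatement of the cascade
    want <- if (cb$l1 != cb$l2) c("x", "y")[which.max(c(cb$l1, cb$l2))]
    else if (cb$y1 != cb$y2) c("x", "y")[which.min(c(cb$y1, cb$y2))]
    else if (cb$a1 != cb$a2) c("x", "y")[which.max(c(cb$a1, cb$a2))]
    else resolveOverlaps(cand, seed = 7)$pa_id   # random leg: determinism only
    expect_identical(got, want)
  }
})

test_that("PA grouping joins components under the 1-km boundary rule", {
  cells <- twoCells()
  mk <- function(gaps) {
    # PAs of radius 2 centred along a line with given boundary gaps
    xs <- cumsum(c(0, 4 + gaps))
    do.call(rbind, lapply(seq_along(xs), function(i)
      paRow(paste0("p", i), xs[i], 0, 2, year = 1990 + i)))
  }
  st <- assignProtectionStatus(cells, mk(0.5))
  expect_identical(nrow(networkTable(groupPANetworks(mk(0.5), st))), 1L)
  expect_identical(nrow(networkTable(groupPANetworks(mk(1.5), st))), 2L)
  # exactly 1 km is NOT connected (strict inequality)
  expect_identical(nrow(networkTable(groupPANetworks(mk(1.0), st))), 2L)
  # transitivity: A-B 0.8, B-C 0.8, A-C far
  nets <- groupPANetworks(mk(c(0.8, 0.8)), st)
  expect_identical(nrow(networkTable(nets)), 1L)
  # youngest designation year is the max over members
  expect_identical(networkTable(nets)$youngest_designation_year, 1993)
  # different regions never group
  pp <- mk(0.5)
  pp$region <- c("R1", "R2")
  expect_identical(nrow(networkTable(groupPANetworks(pp, st))), 2L)
})

test_that("grouping matches an independent union-find oracle on random sets", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:10, 1)
    pas <- do.call(rbind, lapply(seq_len(n), function(i)
      paRow(sprintf("p%02d", i), runif(1, 0, 60), runif(1, 0, 60),
            runif(1, 1, 4))))
    st <- assignProtectionStatus(
      data.frame(cell_id = "c0", x = -50, y = -50, region = "R1"), pas)
    got <- nrow(networkTable(groupPANetworks(pas, st)))
    d <- as.matrix(dist(pas[, c("center_x", "center_y")]))
    bd <- d - outer(pas$radius_km, pas$radius_km, "+")
    idx <- which(bd < 1 & upper.tri(bd), arr.ind = TRUE)
    want <- length(unique(ufComponents(n, idx)))
    expect_identical(got, want)
  }
})

test_that("buffers attach nearby same-region non-protected cells only", {
  cells <- data.frame(
    cell_id = c("prot", "near", "far", "othereg", "shared"),
    x = c(5, 45, 125, 45, 30), y = c(5, 5, 5, 5, 40),
    region = c("R1", "R1", "R1", "R2", "R1"), stringsAsFactors = FALSE)
  pas <- paRow("p1", 5, 5, 2)
  st <- assignProtectionStatus(cells, pas)
  nets <- attachBuffer(groupPANetworks(pas, st), st)
  mem <- cellMembership(nets)
  expect_true("near" %in% mem$cell_id)          # 38 km from the boundary
  expect_false("far" %in% mem$cell_id)          # ~118 km away
  expect_false("othereg" %in% mem$cell_id)      # close but other region
  # membership is a partition: no duplicated cells
  expect_false(anyDuplicated(mem$cell_id) > 0)
})

test_that("temporal filter keeps records from the youngest designation on", {
  mem <- data.frame(cell_id = c("c1", "c2"), network_id = "net001",
                    status = c("protected", "nonprotected"),
                    pa_id = c("pa1", NA), stringsAsFactors = FALSE)
  nets <- fixtureNetworkSet(mem, youngest = c(net001 = 2010L))
  occ <- rbind(occRows("a", "c1", year = 2008L),
               occRows("a", "c1", year = 2010L),
               occRows("a", "c2", year = 2009L),
               occRows("a", "free", year = 1999L))
  out <- temporalFilter(nets, occ)
  expect_identical(out$year, c(2010L, 1999L))   # buffer cell filtered too
})

test_that("network inclusion enforces cell counts and the sampled ratio", {
  mk_mem <- function(nid, np, nn, pref = nid) data.frame(
    cell_id = sprintf("%s_%03d", pref, seq_len(np + nn)),
    network_id = nid,
    status = rep(c("protected", "nonprotected"), c(np, nn)),
    pa_id = NA_character_, stringsAsFactors = FALSE)
  mem <- rbind(mk_mem("netA", 14, 200),   # too few protected
               mk_mem("netB", 40, 60),    # kept (ratio set below)
               mk_mem("netC", 20, 20))    # ratio too low
  nets <- fixtureNetworkSet(mem)
  retained <- c(sprintf("netB_%03d", 1:50),   # 40 prot + 10 nonprot? no:
                sprintf("netB_%03d", 51:70),  # ensure 15/15 and ratio 0.7
                sprintf("netC_%03d", 1:2),
                sprintf("netA_%03d", 1:214))
  out <- networkInclusionFilter(nets, retained, min_cells = 15,
                                min_ratio = 0.10)
  nt <- networkTable(out)
  expect_identical(nt$network_id, "netB")
  expect_gte(nt$sampled_cell_ratio, 0.10)
  # everything below the floor errors out
  expect_error(networkInclusionFilter(nets, character(0)), "no PA network")
})
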