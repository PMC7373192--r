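test_that("brayCurtis matches its closed form and domain contract", {
  expect_equal(brayCurtis(c(10, 0, 5), c(10, 0, 5)), 0)
  expect_equal(brayCurtis(c(10, 0), c(0, 7)), 1)
  expect_equal(brayCurtis(c(2, 2), c(2, 0)), 2 / 6)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "undefined")
  expect_error(brayCurtis(c(1, -1), c(1, 1)), "non-negative")
  expect_error(brayCurtis(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("brayCurtis is invariant to joint rescaling and, after relative
           abundance, to per-sample depth", {
  set.seed(11)
  for (i in 1:25) {
    x <- rgamma(12, 1); y <- rgamma(12, 1)
    expect_equal(brayCurtis(x, y), brayCurtis(7.3 * x, 7.3 * y))
    # depth invariance after total-sum scaling
    expect_equal(brayCurtis(x / sum(x), y / sum(y)),
                 brayCurtis(5 * x / sum(5 * x), 9 * y / sum(9 * y)))
  }
})

test_that("brayCurtisMatrix agrees with vegan's implementation", {
  set.seed(5)
  m <- matrix(rpois(80, 12) + 1, 8)
  rownames(m) <- paste0("s", 1:8)
  expect_equal(unname(brayCurtisMatrix(m)),
               unname(as.matrix(vegan::vegdist(m, "bray"))),
               tolerance = 1e-12)
  m[2, ] <- 0
  expect_error(brayCurtisMatrix(m), "zero-total")
})

test_that("intra/inter partition behaves on degenerate toy tables", {
  prof <- c(50L, 30L, 20L, 0L, 0L, 0L)
  cts <- rbind(a1 = prof, a2 = prof, b1 = prof, b2 = prof)
  colnames(cts) <- paste0("o", 1:6)
  x <- makeExperiment(cts, specimen = c("A", "A", "B", "B"),
                      kit = c("A", "A", "B", "B"), sample_type = "t")
  s <- intraInterDistances(x, "kit")
  expect_equal(intraDistances(s), c(0, 0))
  expect_equal(interDistances(s), c(0, 0, 0, 0))

  q <- c(0L, 0L, 0L, 20L, 30L, 50L)
  cts2 <- rbind(a1 = prof, a2 = prof, b1 = q, b2 = q)
  colnames(cts2) <- paste0("o", 1:6)
  x2 <- makeExperiment(cts2, specimen = c("A", "A", "B", "B"),
                       kit = c("A", "A", "B", "B"), sample_type = "t")
  s2 <- intraInterDistances(x2, "kit")
  expect_equal(intraDistances(s2), c(0, 0))
  expect_equal(interDistances(s2), c(1, 1, 1, 1))
})

test_that("intra/inter partition equals the double-loop oracle", {
  for (seed in 1:4) {
    x <- randomExperiment(nSpec = 3, r = 2, nOtu = 15, seed = seed)
    s <- intraInterDistances(x, "kit")
    design <- replicateDesign(x)
    oracle <- partitionOracle(otuCounts(x), design$kit,
                              design$sample_type)
    expect_equal(sort(intraDistances(s)), sort(oracle$intra),
                 tolerance = 1e-12)
    expect_equal(sort(interDistances(s)), sort(oracle$inter),
                 tolerance = 1e-12)
  }
})

test_that("pair provenance respects the stratum rule", {
  x <- randomExperiment(nSpec = 4, r = 3, nOtu = 10, seed = 3)
  s <- intraInterDistances(x, "specimen")
  expect_true(all(s@intra$group_a == s@intra$group_b))
  expect_true(all(s@inter$group_a != s@inter$group_b))
  expect_true(all(s@inter$level == s@intra$level[1]))
})

test_that("distance ops reject zero-total samples and singleton designs", {
  cts <- rbind(s1 = c(1L, 2L), s2 = c(0L, 0L))
  colnames(cts) <- c("o1", "o2")
  x <- makeExperiment(cts, specimen = c("A", "A"))
  expect_error(intraInterDistances(x, "specimen"), "zero-total.*s2")

  cts2 <- rbind(s1 = c(1L, 2L), s2 = c(3L, 1L))
  colnames(cts2) <- c("o1", "o2")
  x2 <- makeExperiment(cts2, specimen = c("A", "B"))
  expect_error(intraInterDistances(x2, "specimen"),
               "technical replicates")
})

test_that("bounded KDE has unit mass, correct modes and a bandwidth floor", {
  k <- kdeBounded(rep(0.5, 10))
  expect_lt(abs(sum(diff(k$grid) * (k$density[-1] + k$density[-512]) / 2) - 1),
            1e-6)
  expect_equal(k$grid[which.max(k$density)], 0.5, tolerance = 0.01)
  expect_equal(k$bw, 0.01)  # degenerate input falls back to the floor

  k2 <- kdeBounded(c(rep(0.1, 50), rep(0.9, 50)))
  dens <- k2$density
  expect_gt(dens[which.min(abs(k2$grid - 0.1))],
            dens[which.min(abs(k2$grid - 0.5))])
  expect_gt(dens[which.min(abs(k2$grid - 0.9))],
            dens[which.min(abs(k2$grid - 0.5))])
  expect_error(kdeBounded(0.4), "at least 2")
  expect_error(kdeBounded(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("KDE of a large uniform sample is flat near 1 (Monte Carlo)", {
  set.seed(42)
  k <- kdeBounded(runif(10000))
  central <- k$grid >= 0.1 & k$grid <= 0.9
  expect_true(all(abs(k$density[central] - 1) < 0.1))
})

test_that("overlap coefficient is 1 on identity, symmetric, near 0 on
           disjoint peaks", {
  set.seed(8)
  a <- kdeBounded(runif(200, 0.3, 0.7))
  b <- kdeBounded(runif(200, 0.2, 0.8))
  expect_equal(overlapCoefficient(a, a), 1, tolerance = 1e-9)
  expect_equal(overlapCoefficient(a, b), overlapCoefficient(b, a))
  lo <- kdeBounded(rep(0.05, 20)); hi <- kdeBounded(rep(0.95, 20))
  expect_lt(overlapCoefficient(lo, hi), 0.05)
  short <- list(grid = seq(0, 1, length.out = 100),
                density = rep(1, 100))
  expect_error(overlapCoefficient(a, short), "same grid")
})
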