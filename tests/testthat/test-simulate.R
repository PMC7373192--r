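test_that("every simulated sample sums exactly to the read depth", {
  cfg <- simConfig(seed = 2, readDepth = 5000L)
  for (args in list(list(kit = 1, replicate = 1, dilution = 1),
                    list(kit = 2, replicate = 3, dilution = 6),
                    list(kit = 3, replicate = 2, dilution = 4))) {
    v <- do.call(simulateReplicate, c(list(cfg), args))
    expect_equal(sum(v), 5000)
    expect_true(all(v >= 0))
  }
  x <- simulateControls(simConfig(seed = 4, readDepth = 2000L), nKits = 3,
                        contaminated = c(TRUE, FALSE, FALSE))
  expect_true(all(rowSums(otuCounts(x)) == 2000))
})

test_that("the same seed reproduces the experiment bit for bit", {
  cfg <- simConfig(seed = 99, readDepth = 2000L,
                   dilutionFactors = 10^(0:-2), nReplicates = 2L)
  x1 <- simulateDilutionSeries(cfg)
  x2 <- simulateDilutionSeries(cfg)
  expect_identical(otuCounts(x1), otuCounts(x2))
  x3 <- simulateDilutionSeries(simConfig(seed = 100, readDepth = 2000L,
                                         dilutionFactors = 10^(0:-2),
                                         nReplicates = 2L))
  expect_false(identical(otuCounts(x1), otuCounts(x3)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulateReplicate(simConfig(seed = 1)))
  expect_identical(runif(3), before)
})

test_that("abundant template with no noise puts every read in the signal
           OTU", {
  cfg <- simConfig(seed = 5, noiseScale = 0, inputCopies = 1e7)
  v <- simulateReplicate(cfg, kit = 1, replicate = 1, dilution = 1)
  expect_equal(unname(v["Paeruginosa"]), cfg@readDepth)
  expect_equal(sum(v) - v[["Paeruginosa"]], 0)
})

test_that("a config with no read source errors", {
  cfg <- simConfig(seed = 1, noiseScale = 0)
  expect_error(simulateReplicate(cfg, copies = 0), "no read source")
})

test_that("noise read fraction follows lambda / (N + lambda)", {
  cfg <- simConfig(seed = 8, inputCopies = 1e7, noiseScale = 1e3)
  expected <- 1e3 / (1e7 + 1e3)
  fr <- vapply(1:30, function(r) {
    v <- simulateReplicate(cfg, kit = 1, replicate = r, dilution = 1)
    1 - v[["Paeruginosa"]] / sum(v)
  }, numeric(1))
  # mean of 30 replicates within 3 binomial SDs of the model expectation
  tol <- 3 * sqrt(expected * (1 - expected) / (cfg@readDepth * 30))
  expect_lt(abs(mean(fr) - expected), tol)
})

test_that("pure-noise replicates are mutually irreproducible", {
  cfg <- simConfig(seed = 21, inputCopies = 0)
  d <- vapply(seq_len(40), function(i) {
    a <- simulateReplicate(cfg, kit = 1, replicate = 2 * i - 1, copies = 0)
    b <- simulateReplicate(cfg, kit = 1, replicate = 2 * i, copies = 0)
    brayCurtis(a / sum(a), b / sum(b))
  }, numeric(1))
  expect_gt(mean(d), 0.8)
})

test_that("the dilution series has the 3 x 4 x 6 design and biomass per
           specimen", {
  cfg <- simConfig(seed = 6, readDepth = 2000L)
  x <- simulateDilutionSeries(cfg)
  expect_equal(ncol(x), 72)
  d <- replicateDesign(x)
  expect_equal(length(unique(d$specimen_id)), 18)
  expect_equal(length(unique(d$kit)), 3)
  expect_equal(length(unique(d$dilution)), 6)
  bm <- biomassCopies(x)
  expect_equal(length(bm), 18)
  expect_equal(sort(unique(bm)), 1e8 * 10^(-5:0))
})

test_that("mean intra-replicate distance rises monotonically with
           dilution", {
  for (seed in c(13, 14)) {
    x <- simulateDilutionSeries(simConfig(seed = seed, readDepth = 5000L))
    s <- intraInterDistances(x, "kit")
    mi <- tapply(s@intra$distance, s@intra$level, mean)
    mi <- mi[order(names(mi))]  # D1 (neat) .. D6 (most dilute)
    expect_gt(cor(seq_along(mi), mi, method = "spearman"), 0)
    expect_true(all(diff(mi) >= -0.02))
  }
})

test_that("contaminated control kits are internally reproducible, clean
           kits are not", {
  cfg <- simConfig(seed = 17, noiseScale = 1e3)
  x <- simulateControls(cfg, nKits = 4,
                        contaminated = c(TRUE, TRUE, FALSE, FALSE))
  sums <- replicateSummaries(x, "kit")
  expect_lt(max(intraDistances(sums$CtlKit01)), 0.1)
  expect_lt(max(intraDistances(sums$CtlKit02)), 0.1)
  expect_gt(median(intraDistances(sums$CtlKit03)), 0.5)
  expect_gt(median(intraDistances(sums$CtlKit04)), 0.5)
})

test_that("clean noise-only controls yield at most stray contaminant
           flags", {
  hits <- vapply(1:3, function(seed) {
    x <- simulateControls(simConfig(seed = seed), nKits = 5,
                          contaminated = rep(FALSE, 5))
    nrow(identifyContaminants(x)@flagged)
  }, numeric(1))
  expect_lte(mean(hits), 1)
})

test_that("planted kit contaminants are recovered with few false
           positives", {
  fp <- 0; recovered <- TRUE
  for (seed in 1:5) {
    x <- simulateControls(simConfig(seed = seed))
    rep_ <- identifyContaminants(x)
    planted <- grepl("Contam", rep_@flagged$otu_id)
    fp <- fp + sum(!planted)
    recovered <- recovered && any(grepl("Kit01Contam", rep_@flagged$otu_id)) &&
      any(grepl("Kit02Contam", rep_@flagged$otu_id))
  }
  expect_true(recovered)        # both planted kits contribute flags
  expect_lte(fp / 5, 1)         # <= 1 false positive per run on average
})
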