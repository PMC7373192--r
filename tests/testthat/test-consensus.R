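mkCounts <- function(rows, otus = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- if (is.null(otus)) paste0("Otu", seq_len(ncol(m))) else otus
  storage.mode(m) <- "integer"
  m
}

test_that("replicate medians zero out minority OTUs and average across
           specimens", {
  # one specimen: OTU2 seen in a single replicate of three -> median 0
  cts <- mkCounts(list(r1 = c(100L, 0L), r2 = c(100L, 0L),
                       r3 = c(40L, 60L)))
  x <- makeExperiment(cts, specimen = rep("sp1", 3))
  cp <- meanOfReplicateMedians(x)
  expect_equal(cp$mean[cp$otu_id == "Otu1"], 1.0)
  expect_equal(cp$mean[cp$otu_id == "Otu2"], 0.0)

  cts2 <- mkCounts(list(r1 = c(20L, 80L), r2 = c(40L, 60L),
                        r3 = c(60L, 40L)))
  x2 <- makeExperiment(cts2, specimen = rep("sp1", 3))
  cp2 <- meanOfReplicateMedians(x2)
  expect_equal(cp2$mean[match(c("Otu1", "Otu2"), cp2$otu_id)], c(0.4, 0.6))

  # two specimens with medians (0.4, 0.6) and (0.8, 0.2)
  cts3 <- mkCounts(list(a1 = c(40L, 60L), a2 = c(40L, 60L),
                        b1 = c(80L, 20L), b2 = c(80L, 20L)))
  x3 <- makeExperiment(cts3, specimen = c("A", "A", "B", "B"))
  cp3 <- meanOfReplicateMedians(x3)
  expect_equal(cp3$mean[match(c("Otu1", "Otu2"), cp3$otu_id)], c(0.6, 0.4))
  expect_equal(cp3$sem[cp3$otu_id == "Otu1"], sd(c(0.4, 0.8)) / sqrt(2))
})

test_that("single-replicate specimens are excluded with a warning, or an
           error on request", {
  cts <- mkCounts(list(a1 = c(10L, 0L), a2 = c(10L, 0L), b1 = c(0L, 10L)))
  x <- makeExperiment(cts, specimen = c("A", "A", "B"))
  expect_warning(cp <- meanOfReplicateMedians(x), "fewer than 2")
  expect_equal(unique(cp$n_specimens), 1)
  expect_error(meanOfReplicateMedians(x, onSingle = "error"), "fewer than 2")
})

test_that("majority-absent OTUs always get consensus exactly 0", {
  # property: with r replicates (midpoint convention for even r), an OTU
  # detected in < ceiling(r/2) replicates of every specimen has consensus 0
  for (seed in 1:6) {
    r <- sample(3:5, 1)
    x <- randomExperiment(nSpec = 3, r = r, nOtu = 25, seed = seed,
                          depth = 60)
    cp <- meanOfReplicateMedians(x)
    cts <- otuCounts(x)
    spec <- replicateDesign(x)$specimen_id
    maj <- ceiling(r / 2)
    minority <- vapply(colnames(cts), function(o) {
      all(tapply(cts[, o] > 0, spec, sum) < maj)
    }, logical(1))
    expect_true(all(cp$mean[match(names(minority)[minority],
                                  cp$otu_id)] == 0))
  }
})

test_that("consensus is invariant to replicate and specimen ordering", {
  x <- randomExperiment(nSpec = 3, r = 3, nOtu = 12, seed = 9)
  cp <- meanOfReplicateMedians(x)
  set.seed(1)
  perm <- sample(9)
  cts <- otuCounts(x)[perm, ]
  d <- replicateDesign(x)[perm, ]
  d$sample_id <- rownames(cts)
  xp <- ReplicateExperiment(cts, d)
  expect_equal(meanOfReplicateMedians(xp), cp)
})

test_that("contaminant identification follows the abundance-and-prevalence
           rule", {
  # 2 control kits x 3 replicates; Otu1 at ~30% everywhere (contaminant),
  # Otu3 in one replicate of one kit only
  rows <- list(k1r1 = c(30L, 70L, 0L), k1r2 = c(30L, 70L, 0L),
               k1r3 = c(30L, 65L, 5L), k2r1 = c(32L, 68L, 0L),
               k2r2 = c(28L, 72L, 0L), k2r3 = c(31L, 69L, 0L))
  cts <- mkCounts(rows)
  x <- makeExperiment(cts, specimen = rep(c("c1", "c2"), each = 3),
                      kit = rep(c("K1", "K2"), each = 3),
                      is_control = TRUE, sample_type = "control")
  rep_ <- identifyContaminants(x)
  expect_true("Otu1" %in% rep_@flagged$otu_id)
  expect_false("Otu3" %in% rep_@flagged$otu_id)  # median 0, prevalence 1/3
  expect_true(all(rep_@flagged$prevalence >= 2 / 3))

  xs <- makeExperiment(cts, specimen = rep(c("c1", "c2"), each = 3),
                       is_control = FALSE)
  expect_error(identifyContaminants(xs), "no control samples")
})

test_that("contaminant removal accounts for read retention", {
  cts <- mkCounts(list(s1 = c(10L, 90L), s2 = c(50L, 50L),
                       s3 = c(100L, 0L)))
  x <- makeExperiment(cts, specimen = c("A", "A", "A"))
  res <- removeContaminants(x, "Otu1")
  expect_equal(res$report@retention$retained, c(0.90, 0.50, 0))
  expect_equal(res$report@meanRetained, mean(c(0.9, 0.5, 0)))
  expect_identical(res$report@emptied, "s3")          # flagged, not dropped
  expect_equal(ncol(res$experiment), 3)

  none <- removeContaminants(x, character(0))
  expect_true(all(none$report@retention$retained == 1))
  expect_error(removeContaminants(x, "OtuX"), "not in the table")
})

test_that("concordance score is the shared-OTU read fraction", {
  cts <- mkCounts(list(r1 = c(90L, 10L, 0L), r2 = c(90L, 0L, 10L)),
                  otus = c("A", "B", "C"))
  x <- makeExperiment(cts, specimen = c("sp", "sp"))
  expect_equal(concordanceScore(x, "sp"), 0.9)

  same <- mkCounts(list(r1 = c(5L, 5L), r2 = c(5L, 5L)))
  expect_equal(concordanceScore(
    makeExperiment(same, specimen = c("sp", "sp")), "sp"), 1)

  disj <- mkCounts(list(r1 = c(10L, 0L), r2 = c(0L, 10L)))
  expect_equal(concordanceScore(
    makeExperiment(disj, specimen = c("sp", "sp")), "sp"), 0)

  one <- mkCounts(list(r1 = c(1L, 1L)))
  expect_error(concordanceScore(
    makeExperiment(one, specimen = "sp"), "sp"), ">= 2 replicates")
})
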