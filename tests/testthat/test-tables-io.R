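test_that("readShared parses the mothur dialect and round-trips", {
  f <- tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\tOtu1\tOtu2\tOtu3",
               "0.03\tsampleA\t3\t10\t0\t5",
               "0.03\tsampleB\t3\t2\t7\t0"), f)
  cts <- readShared(f)
  expect_identical(dim(cts), c(2L, 3L))
  expect_identical(rownames(cts), c("sampleA", "sampleB"))
  expect_identical(unname(cts["sampleA", ]), c(10L, 0L, 5L))

  f2 <- tempfile(fileext = ".shared")
  writeShared(cts, f2)
  expect_identical(readShared(f2), cts)
})

test_that("readShared rejects malformed input with named diagnostics", {
  f <- tempfile()
  writeLines(c("label\tSample\tnumOtus\tOtu1", "0.03\ts1\t1\t5"), f)
  expect_error(readShared(f), "missing column 'Group'")

  writeLines(c("label\tGroup\tnumOtus\tOtu1\tOtu2", "0.03\ts1\t2\t5\t1.5"),
             f)
  expect_error(readShared(f), "row 1.*Otu2")

  writeLines(c("label\tGroup\tnumOtus\tOtu1\tOtu2", "0.03\ts1\t3\t5\t1"), f)
  expect_error(readShared(f), "numOtus")
})

test_that("readDesign enforces the replicate-design invariants", {
  f <- tempfile()
  rows <- expand.grid(kit = c("K1", "K2", "K3"), rep = 1:4)
  writeLines(c("sample_id\tspecimen_id\treplicate\tkit\tis_control\tsample_type\tdilution",
               sprintf("%s_r%d\t%s\t%d\t%s\tFALSE\tdilution\tD1",
                       rows$kit, rows$rep, rows$kit, rows$rep, rows$kit)), f)
  d <- readDesign(f)
  expect_equal(nrow(d), 12)
  expect_equal(length(unique(paste(d$kit, d$dilution))), 3)

  writeLines(c("sample_id\tspecimen_id\treplicate\tkit\tis_control\tsample_type",
               "s1\tsp1\t1\tK1\tFALSE\toral",
               "s1\tsp1\t2\tK1\tFALSE\toral"), f)
  expect_error(readDesign(f), "duplicate sample_id")

  writeLines(c("sample_id\tspecimen_id\treplicate\tkit\tis_control\tsample_type",
               "s1\tsp1\t0\tK1\tFALSE\toral"), f)
  expect_error(readDesign(f), "replicate")
})

test_that("readBiomass parses scientific notation and rejects duplicates", {
  f <- tempfile()
  writeLines(c("specimen_id\tcopies", "sp1\t1e6", "sp2\t350"), f)
  bm <- readBiomass(f)
  expect_identical(bm[["sp1"]], 1e6)
  writeLines(c("specimen_id\tcopies", "sp1\t1e6", "sp1\t2e6"), f)
  expect_error(readBiomass(f), "duplicate")
})

test_that("taxonomy is stored verbatim with rank splitting as a helper", {
  f <- system.file("extdata", "toy.cons.taxonomy", package = "replinoise")
  tx <- readTaxonomy(f)
  expect_match(tx[["Otu0001"]], "^Bacteria\\(100\\);", perl = TRUE)
  ranks <- splitTaxonomy(tx[["Otu0002"]])[[1]]
  expect_identical(ranks[6], "Prevotella")
})

test_that("ReplicateExperiment validity catches malformed input", {
  cts <- matrix(c(5L, 3L, 2L, 4L), 2,
                dimnames = list(c("s1", "s2"), c("o1", "o2")))
  des <- data.frame(sample_id = c("s1", "s2"), specimen_id = "sp",
                    replicate = 1:2, kit = "K", is_control = FALSE,
                    sample_type = "oral")
  expect_s4_class(ReplicateExperiment(cts, des), "ReplicateExperiment")
  expect_error(ReplicateExperiment(cts - 10L, des), "non-negative")
  expect_error(ReplicateExperiment(cts, des[1, ]), "missing sample")
  expect_error(ReplicateExperiment(cts, rbind(des, des[1, ])), "duplicate")
  expect_error(ReplicateExperiment(cts, des, taxonomy = c(oX = "t")),
               "not OTUs")
})

test_that("relative abundance rows sum to one for positive-total samples", {
  x <- randomExperiment(nSpec = 2, r = 2, nOtu = 30, seed = 7)
  ra <- relAbundance(x)
  expect_true(all(abs(rowSums(ra) - 1) < 1e-12))
})

test_that("demographics summary matches direct recomputation", {
  d <- demographicsTable()
  expect_equal(nrow(d), 20)
  # independent recomputation: the 20 ages sum to 1064, so the mean is
  # 53.2 and rounds to 53
  expect_equal(sum(d$age), 1064)
  s <- summarizeDemographics(d)
  expect_equal(s$mean_age, round(1064 / 20))
  expect_error(summarizeDemographics(d[0, ]), "empty")
  single <- summarizeDemographics(data.frame(sex = "Male", age = 40,
                                             race = "White"))
  expect_equal(single$mean_age, 40)
  expect_equal(single$sd_age, 0)
})
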