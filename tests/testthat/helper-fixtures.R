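# shared fixtures and independent brute-force oracles

# brute-force Bray-Curtis: elementwise loop, no vectorization shared with
# the implementation
bcOracle <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[[i]] - y[[i]])
    den <- den + x[[i]] + y[[i]]
  }
  num / den
}

# a small experiment with explicit counts: `layout` is a list of rows
# (sample_id = counts), design columns supplied in parallel
makeExperiment <- function(counts, specimen, kit = specimen,
                           replicate = NULL, is_control = FALSE,
                           sample_type = "oral", dilution = NULL,
                           biomass = NULL) {
  if (is.null(replicate))
    replicate <- as.integer(stats::ave(seq_along(specimen), specimen,
                                       FUN = seq_along))
  design <- data.frame(sample_id = rownames(counts),
                       specimen_id = specimen, replicate = replicate,
                       kit = kit, is_control = is_control,
                       sample_type = sample_type,
                       stringsAsFactors = FALSE)
  if (!is.null(dilution)) design$dilution <- dilution
  ReplicateExperiment(counts, design, biomass = biomass)
}

# random replicated count table: nSpec specimens x r replicates
randomExperiment <- function(nSpec = 3, r = 3, nOtu = 20, seed = 1,
                             depth = 500) {
  set.seed(seed)
  n <- nSpec * r
  counts <- t(vapply(seq_len(n), function(i)
    as.integer(rmultinom(1, depth, rgamma(nOtu, 0.5) + 1e-9)),
    integer(nOtu)))
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n)),
                           sprintf("Otu%03d", seq_len(nOtu)))
  makeExperiment(counts,
                 specimen = rep(sprintf("sp%d", seq_len(nSpec)), each = r),
                 kit = rep(sprintf("kit%d", seq_len(nSpec)), each = r))
}

# double-loop oracle for the intra/inter partition: pairs samples by the
# same rules (same level; same group -> intra, different group -> inter)
partitionOracle <- function(mat, group, level) {
  mat <- mat / rowSums(mat)
  intra <- c(); inter <- c()
  n <- nrow(mat)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || level[i] != level[j]) next
    d <- bcOracle(mat[i, ], mat[j, ])
    if (group[i] == group[j]) intra <- c(intra, d)
    else inter <- c(inter, d)
  }
  list(intra = intra, inter = inter)
}

# DistanceSummary built directly from distance values (for the classifier)
summaryFromValues <- function(intra, inter) {
  mk <- function(v, g) {
    n <- length(v)
    data.frame(sample_a = sprintf("a%d", seq_len(n)),
               sample_b = sprintf("b%d", seq_len(n)),
               group_a = rep(g, n), group_b = rep(g, n),
               level = rep("L", n), distance = v,
               stringsAsFactors = FALSE)
  }
  replinoise:::.makeSummary(mk(intra, "g1"), mk(inter, "g2"), "kit")
}
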