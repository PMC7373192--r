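#' Read and cross-check pipeline inputs
#'
#' Loads a `.shared` table, a design TSV, optional taxonomy and optional
#' biomass TSV, and verifies that they describe the same samples; a
#' mismatch errors with the offending ids listed.
#'
#' @param tablePath path to a mothur `.shared` file.
#' @param designPath path to a design TSV (see [readDesign()]).
#' @param biomassPath optional biomass TSV (see [readBiomass()]).
#' @param taxonomyPath optional `.cons.taxonomy` file.
#' @return a \linkS4class{ReplicateExperiment}.
#' @export
readPipelineInputs <- function(tablePath, designPath, biomassPath = NULL,
                               taxonomyPath = NULL) {
  counts <- readShared(tablePath)
  design <- readDesign(designPath)
  extra <- setdiff(design$sample_id, rownames(counts))
  miss <- setdiff(rownames(counts), design$sample_id)
  if (length(extra) || length(miss))
    stop("inconsistent sample ids between table and design;",
         if (length(miss)) paste0(" missing from design: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0(" missing from table: ",
                                   paste(extra, collapse = ", ")))
  taxonomy <- if (!is.null(taxonomyPath)) readTaxonomy(taxonomyPath)
  biomass <- if (!is.null(biomassPath)) readBiomass(biomassPath)
  ReplicateExperiment(counts, design, taxonomy = taxonomy,
                      biomass = biomass)
}

.writeTsv <- function(d, dir, name) {
  path <- file.path(dir, name)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full QC pipeline and write a report bundle
#'
#' Sequences the stages end-to-end on one experiment: distance
#' partitioning, per-group regime classification, low-biomass flagging,
#' optional contaminant identification/removal against a control table,
#' consensus profiles per sample type, and a sample-vs-control PERMANOVA
#' when both are present. Each stage writes a diff-able TSV into
#' \code{outDir}, the run configuration is serialized alongside
#' (\code{run_config.tsv}), and a human-readable \code{summary.txt} closes
#' the bundle. Outputs are a pure function of (inputs, config, seed):
#' rerunning with the same arguments reproduces the files byte for byte.
#'
#' @param x a \linkS4class{ReplicateExperiment} of study samples (may
#'   include matched controls via \code{is_control}).
#' @param outDir output directory (created if absent).
#' @param controls optional separate \linkS4class{ReplicateExperiment} of
#'   negative-control replicates used for contaminant identification.
#' @param stratum grouping level for the distance partition.
#' @param thresholds regime thresholds, see [regimeThresholds()].
#' @param normalize normalization mode for distances.
#' @param biomassThreshold low-biomass flag threshold in copies.
#' @param minAbund,minPrev contaminant criteria (see
#'   [identifyContaminants()]).
#' @param nPerm,seed PERMANOVA permutations and RNG seed.
#' @return invisibly, a list with the stage results (\code{regimes},
#'   \code{flags}, \code{contaminants}, \code{consensus},
#'   \code{permanova}, \code{files}).
#' @export
runPipeline <- function(x, outDir, controls = NULL,
                        stratum = c("specimen", "kit"),
                        thresholds = regimeThresholds(),
                        normalize = "relabund", biomassThreshold = 1e5,
                        minAbund = 0.01, minPrev = 2 / 3,
                        nPerm = 999L, seed = 1L) {
  stratum <- match.arg(stratum)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  cfg <- data.frame(
    key = c("stratum", "normalize", "biomass_threshold", "min_abund",
            "min_prevalence", "n_perm", "seed", "intra_low", "separation",
            "noise_floor", "overlap_min"),
    value = c(stratum, normalize, format(biomassThreshold), minAbund,
              minPrev, nPerm, seed, thresholds["intra_low"],
              thresholds["separation"], thresholds["noise_floor"],
              thresholds["overlap_min"]))
  files["config"] <- .writeTsv(cfg, outDir, "run_config.tsv")

  note("samples: ", ncol(x), "; OTUs: ", nrow(x))

  ## stage 1: distance partition (long format with provenance)
  sums <- replicateSummaries(x, stratum, normalize)
  long <- do.call(rbind, lapply(names(sums), function(g) {
    s <- sums[[g]]
    rbind(cbind(set = "intra", group = g, s@intra),
          cbind(set = "inter", group = g, s@inter))
  }))
  files["distances"] <- .writeTsv(long, outDir, "distances.tsv")
  note("distance pairs written: ", nrow(long))

  ## stage 2: regimes per group
  regimes <- classifyRegimes(x, stratum, thresholds, normalize)
  files["regimes"] <- .writeTsv(regimes, outDir, "regimes.tsv")
  note("groups classified: ", nrow(regimes))

  ## stage 3: biomass flags
  flags <- flagLowBiomass(x, threshold = biomassThreshold)
  files["biomass"] <- .writeTsv(flags, outDir, "biomass_flags.tsv")
  note("specimens flagged low-biomass: ",
       sum(flags$status == "flagged"), "/", nrow(flags))

  ## stage 4: contaminants (needs a control table)
  contamReport <- NULL
  xClean <- x
  if (!is.null(controls)) {
    contamReport <- identifyContaminants(controls, minAbund, minPrev)
    common <- intersect(contamReport@flagged$otu_id, rownames(x))
    res <- removeContaminants(x, common)
    xClean <- res$experiment
    contamReport <- res$report
    files["contaminants"] <- .writeTsv(contamReport@flagged, outDir,
                                       "contaminants.tsv")
    files["retention"] <- .writeTsv(contamReport@retention, outDir,
                                    "read_retention.tsv")
    note("contaminant OTUs removed: ", length(common),
         "; mean read retention: ",
         sprintf("%.3f", contamReport@meanRetained))
  }

  ## stage 5: consensus per sample type (non-control)
  design <- replicateDesign(xClean)
  types <- unique(design$sample_type[!design$is_control])
  consensus <- do.call(rbind, lapply(types, function(ty)
    cbind(sample_type = ty,
          suppressWarnings(meanOfReplicateMedians(xClean, ty)))))
  files["consensus"] <- .writeTsv(consensus, outDir, "consensus.tsv")
  note("consensus rows: ", nrow(consensus))

  ## stage 6: sample-vs-control PERMANOVA, when both present
  perm <- NULL
  if (any(design$is_control) && any(!design$is_control)) {
    dm <- brayCurtisMatrix(relAbundance(xClean))
    grp <- ifelse(design$is_control, "control", "sample")
    perm <- bcPermanova(dm, grp, nPerm = nPerm, seed = seed)
    pdf <- data.frame(pseudo_F = perm@pseudoF, p_value = perm@pValue,
                      n_perm = perm@nPermutations,
                      n_sample = sum(!design$is_control),
                      n_control = sum(design$is_control), seed = seed)
    files["permanova"] <- .writeTsv(pdf, outDir, "permanova.tsv")
    note(sprintf("permanova sample vs control: F = %.3f, p = %.4g",
                 perm@pseudoF, perm@pValue))
  }

  writeLines(c("replinoise pipeline summary", "---------------------------",
               log), file.path(outDir, "summary.txt"))
  files["summary"] <- file.path(outDir, "summary.txt")
  invisible(list(regimes = regimes, flags = flags,
                 contaminants = contamReport, consensus = consensus,
                 permanova = perm, files = files))
}
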