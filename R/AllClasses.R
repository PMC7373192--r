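#' @import methods
#' @importFrom stats median rbinom rgamma rmultinom rpois sd dnorm bw.nrd0
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Replicated OTU experiment container
#'
#' A \linkS4class{SummarizedExperiment} holding an OTU read-count matrix
#' (OTUs in rows, sequenced samples in columns) together with the technical
#' replicate design in \code{colData}, optional taxonomy strings in
#' \code{rowData}, and optional per-specimen 16S copy numbers (ddPCR) in
#' \code{metadata(x)$biomass}.
#'
#' Required design columns: \code{specimen_id}, \code{replicate} (1-based
#' index within specimen), \code{kit}, \code{is_control} (logical),
#' \code{sample_type}; an optional \code{dilution} column labels the level of
#' a dilution series. Counts must be non-negative whole numbers; zero-total
#' samples are retained in the container and rejected explicitly by the
#' distance operations.
#'
#' @seealso [ReplicateExperiment()], [otuCounts()], [intraInterDistances()]
#' @export
setClass("ReplicateExperiment", contains = "SummarizedExperiment")

.validReplicateExperiment <- function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be whole numbers")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("specimen_id", "replicate", "kit", "is_control", "sample_type")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("design is missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate OTU ids")
  if ("replicate" %in% colnames(cd) && length(cd$replicate) &&
      any(cd$replicate < 1))
    msg <- c(msg, "replicate indices must be >= 1")
  bm <- S4Vectors::metadata(object)$biomass
  if (!is.null(bm)) {
    if (is.null(names(bm)) || anyDuplicated(names(bm)))
      msg <- c(msg, "biomass must be uniquely named by specimen_id")
    if (any(bm < 0, na.rm = TRUE)) msg <- c(msg, "biomass copies must be >= 0")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ReplicateExperiment", .validReplicateExperiment)

#' Partitioned replicate distances
#'
#' Intra-replicate (within technical-replicate sets) and inter-replicate
#' (between kits or specimens at the same dilution/sample-type level)
#' Bray-Curtis distances with pair provenance, their kernel density
#' estimates on a common grid over [0, 1], and the overlap coefficient of
#' the two densities.
#'
#' @slot intra data.frame of within-group pair distances with provenance.
#' @slot inter data.frame of between-group pair distances with provenance.
#' @slot stratum grouping level used ("kit" or "specimen").
#' @slot grid common density grid on [0, 1].
#' @slot kdeIntra,kdeInter density values on \code{grid} (length 0 when the
#'   corresponding distance set has fewer than 2 members).
#' @slot overlap trapezoid integral of the pointwise minimum of the two
#'   densities; \code{NA} when either density is absent.
#' @export
setClass("DistanceSummary",
         representation(intra = "data.frame", inter = "data.frame",
                        stratum = "character", grid = "numeric",
                        kdeIntra = "numeric", kdeInter = "numeric",
                        overlap = "numeric"))

.validDistanceSummary <- function(object) {
  msg <- character(0)
  d <- c(object@intra$distance, object@inter$distance)
  if (length(d) && (any(d < -1e-12) || any(d > 1 + 1e-12)))
    msg <- c(msg, "distances must lie in [0, 1]")
  for (k in c("kdeIntra", "kdeInter")) {
    kd <- slot(object, k)
    if (length(kd)) {
      if (length(kd) != length(object@grid))
        msg <- c(msg, paste(k, "length must match grid"))
      else if (abs(.trapz(object@grid, kd) - 1) > 1e-6)
        msg <- c(msg, paste(k, "must integrate to 1 over [0, 1]"))
    }
  }
  if (length(object@overlap) && !is.na(object@overlap) &&
      (object@overlap < -1e-9 || object@overlap > 1 + 1e-9))
    msg <- c(msg, "overlap must lie in [0, 1]")
  if (length(msg)) msg else TRUE
}
setValidity("DistanceSummary", .validDistanceSummary)

#' Regime call for one specimen or kit
#'
#' Classification of a replicate set into one of the reproducibility
#' regimes: \code{signal_dominated}, \code{contamination_dominated},
#' \code{noise_dominated} or \code{indeterminate}, with the evidence
#' (median intra distance, median inter distance, density overlap) and the
#' thresholds that produced the call. The call is a pure function of
#' evidence and thresholds.
#'
#' @export
setClass("RegimeCall",
         representation(specimen = "character", regime = "character",
                        evidence = "numeric", thresholds = "numeric"))

#' Biomass-reproducibility transition fit
#'
#' Four-parameter logistic in log10(16S copies per sample) fitted to mean
#' intra-replicate distances, oriented so distance falls as biomass rises.
#' The transition range is the copy interval between 10% and 90% of the
#' logistic span.
#'
#' @slot lower,upper asymptotic distances (high- and low-biomass limits).
#' @slot midpoint inflection point on the log10 copy scale.
#' @slot slope logistic steepness (> 0).
#' @slot rangeLow,rangeHigh transition range in copies per sample.
#' @slot rss residual sum of squares.
#' @slot converged FALSE for flat or non-convergent data, in which case no
#'   range is reported.
#' @export
setClass("TransitionFit",
         representation(lower = "numeric", upper = "numeric",
                        midpoint = "numeric", slope = "numeric",
                        rangeLow = "numeric", rangeHigh = "numeric",
                        rss = "numeric", converged = "logical"))

setValidity("TransitionFit", function(object) {
  if (!object@converged) return(TRUE)
  msg <- character(0)
  if (object@lower >= object@upper)
    msg <- c(msg, "lower asymptote must be below upper asymptote")
  if (object@rangeLow >= object@rangeHigh)
    msg <- c(msg, "transition range low must be below high")
  if (length(msg)) msg else TRUE
})

#' Permutational MANOVA result
#'
#' One-factor pseudo-F permutation test on a dissimilarity matrix.
#'
#' @slot pseudoF observed pseudo-F statistic.
#' @slot pValue permutation p-value, \code{(1 + #\{F* >= F\}) / (1 + n_perm)}.
#' @slot nPermutations number of permutations used.
#' @slot groupSizes named integer vector of group sizes.
#' @slot seed RNG seed used for the permutations (NA if none supplied).
#' @export
setClass("PermanovaResult",
         representation(pseudoF = "numeric", pValue = "numeric",
                        nPermutations = "integer", groupSizes = "integer",
                        seed = "numeric"))

setValidity("PermanovaResult", function(object) {
  msg <- character(0)
  if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12 ||
      object@pValue > 1)
    msg <- c(msg, "p-value outside (1/(n_perm+1), 1]")
  if (is.na(object@pseudoF) || object@pseudoF < 0)
    msg <- c(msg, "pseudo-F must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Simulator configuration
#'
#' Full parameterization of the generative noise model: a true community
#' composition sampled with Poisson template stochasticity, optional per-kit
#' reagent contamination, and a per-replicate random noise pool that
#' competes with template for a fixed read depth with effective template
#' weight \code{noiseScale} (lambda).
#'
#' @slot trueProfile named composition over signal OTUs (sums to 1).
#' @slot inputCopies 16S copies per specimen for the undiluted template.
#' @slot contamination list of named per-kit contaminant compositions.
#' @slot contamCopies per-kit contaminant copy numbers (parallel to
#'   \code{contamination}).
#' @slot noiseScale lambda, the effective noise template count; the expected
#'   noise read fraction is lambda / (N + N_c + lambda).
#' @slot noisePoolSize,noiseSubsetSize,noiseConcentration size of the shared
#'   noise OTU pool, OTUs drawn per replicate, and symmetric Dirichlet
#'   concentration of the per-replicate noise weights.
#' @slot readDepth fixed reads per sample.
#' @slot nKits,nReplicates,dilutionFactors experimental shape of the
#'   dilution series.
#' @slot seed master seed; all randomness derives from it.
#' @export
setClass("SimConfig",
         representation(trueProfile = "numeric", inputCopies = "numeric",
                        contamination = "list", contamCopies = "numeric",
                        noiseScale = "numeric", noisePoolSize = "integer",
                        noiseSubsetSize = "integer",
                        noiseConcentration = "numeric",
                        readDepth = "integer", nKits = "integer",
                        nReplicates = "integer",
                        dilutionFactors = "numeric", seed = "numeric"))

.validSimConfig <- function(object) {
  msg <- character(0)
  if (length(object@trueProfile)) {
    if (abs(sum(object@trueProfile) - 1) > 1e-8)
      msg <- c(msg, "trueProfile must sum to 1")
    if (any(object@trueProfile < 0))
      msg <- c(msg, "trueProfile entries must be >= 0")
    if (is.null(names(object@trueProfile)))
      msg <- c(msg, "trueProfile must be named by OTU")
  }
  for (p in object@contamination) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0) || is.null(names(p)))
      msg <- c(msg, "each contamination profile must be a named composition")
  }
  if (length(object@contamination) &&
      length(object@contamCopies) != length(object@contamination))
    msg <- c(msg, "contamCopies must parallel contamination")
  if (any(c(object@inputCopies, object@contamCopies, object@noiseScale) < 0))
    msg <- c(msg, "copy numbers and noiseScale must be >= 0")
  if (object@noiseSubsetSize > object@noisePoolSize)
    msg <- c(msg, "noiseSubsetSize cannot exceed noisePoolSize")
  if (object@readDepth < 1) msg <- c(msg, "readDepth must be >= 1")
  if (!length(object@dilutionFactors) || any(object@dilutionFactors <= 0))
    msg <- c(msg, "dilutionFactors must be positive")
  if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)

#' Contaminant identification report
#'
#' Evidence for OTUs flagged as reagent contaminants from negative-control
#' replicates, and (after removal) per-sample read-retention accounting.
#'
#' @slot flagged data.frame: one row per flagged OTU with its control
#'   mean-of-replicate-medians abundance, the kit with the highest replicate
#'   prevalence, and that prevalence.
#' @slot criteria thresholds used (min_abund, min_prevalence).
#' @slot retention data.frame of per-sample reads before/after removal and
#'   the fraction retained (filled by [removeContaminants()]).
#' @slot meanRetained mean fraction of reads retained across samples.
#' @slot emptied sample ids whose retention fell to 0 (flagged, not dropped).
#' @export
setClass("ContaminantReport",
         representation(flagged = "data.frame", criteria = "numeric",
                        retention = "data.frame", meanRetained = "numeric",
                        emptied = "character"))

setValidity("ContaminantReport", function(object) {
  r <- object@retention$retained
  if (length(r) && (any(r < -1e-12) || any(r > 1 + 1e-12)))
    "retained fractions must lie in [0, 1]" else TRUE
})
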