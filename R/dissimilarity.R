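# trapezoid rule on an ordered grid
.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# Silverman's rule of thumb with a floor; all-equal inputs get the floor,
# giving a narrow peak instead of a crash or an arbitrary spread
.silvermanBw <- function(values, bwFloor = 0.01) {
  spread <- min(sd(values), stats::IQR(values) / 1.349)
  h <- 0.9 * spread * length(values)^(-1 / 5)
  if (!is.finite(h) || h < bwFloor) h <- bwFloor
  h
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \code{sum(|x - y|) / sum(x + y)}: 0 iff the vectors are elementwise
#' equal, 1 for disjoint support. Scale-dependent on raw counts but
#' invariant to rescaling both vectors jointly; compute it on per-sample
#' relative abundances to remove depth effects.
#'
#' @param x,y non-negative numeric vectors of equal length; at least one
#'   must have a positive total.
#' @return distance in [0, 1].
#' @examples
#' brayCurtis(c(2, 2), c(2, 0))  # 1/3
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0)
    stop("Bray-Curtis is undefined when both vectors have zero total")
  sum(abs(x - y)) / tot
}

#' All pairwise Bray-Curtis distances of a sample-by-OTU matrix
#'
#' @param mat non-negative matrix, samples in rows; every row total must be
#'   positive.
#' @return symmetric distance matrix with zero diagonal.
#' @export
brayCurtisMatrix <- function(mat) {
  if (any(mat < 0)) stop("abundances must be non-negative")
  tot <- rowSums(mat)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(rownames(mat)[tot == 0], collapse = ", "),
         "; Bray-Curtis is undefined for empty samples")
  num <- as.matrix(stats::dist(mat, method = "manhattan"))
  num / outer(tot, tot, "+")
}

#' Bounded-support kernel density estimate on [0, 1]
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, boundary
#' corrected by reflecting the kernel mass at 0 and 1, evaluated on an
#' equally spaced grid and renormalized to unit trapezoid mass. A floor
#' bandwidth keeps degenerate all-equal inputs (common for identical
#' control replicates) a narrow peak rather than a crash.
#'
#' @param values distances in [0, 1]; at least 2.
#' @param gridN grid resolution (default 512).
#' @param bwFloor minimum bandwidth (default 0.01).
#' @param bw optional fixed bandwidth overriding Silverman's rule (used to
#'   put two densities on a common smoothing scale before comparing them).
#' @return list with \code{grid}, \code{density} and \code{bw}.
#' @export
kdeBounded <- function(values, gridN = 512L, bwFloor = 0.01, bw = NULL) {
  if (length(values) < 2) stop("at least 2 values are required for a KDE")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  h <- if (is.null(bw)) .silvermanBw(values, bwFloor) else bw
  grid <- seq(0, 1, length.out = gridN)
  # reflection at both boundaries: g(x) + g(-x) + g(2 - x)
  dens <- vapply(grid, function(g) {
    mean(dnorm((g - values) / h) + dnorm((g + values) / h) +
           dnorm((g - (2 - values)) / h)) / h
  }, numeric(1))
  dens <- dens / .trapz(grid, dens)
  list(grid = grid, density = dens, bw = h)
}

#' Overlap coefficient of two density curves
#'
#' Trapezoid integral of the pointwise minimum of the two densities; 1 for
#' identical curves, near 0 for disjoint support. Quantifies how far the
#' intra- and inter-replicate distance distributions are distinguishable.
#'
#' @param kdeA,kdeB lists with \code{grid} and \code{density} on the same
#'   grid (as returned by [kdeBounded()]).
#' @return overlap in [0, 1].
#' @export
overlapCoefficient <- function(kdeA, kdeB) {
  if (length(kdeA$grid) != length(kdeB$grid) ||
      any(abs(kdeA$grid - kdeB$grid) > 1e-12))
    stop("density curves must share the same grid")
  min(max(.trapz(kdeA$grid, pmin(kdeA$density, kdeB$density)), 0), 1)
}

# level at which samples are comparable: dilution label when the design has
# one, otherwise sample type
.pairLevel <- function(design) {
  if ("dilution" %in% colnames(design) && any(!is.na(design$dilution)))
    as.character(design$dilution)
  else as.character(design$sample_type)
}

.normalizeCounts <- function(mat, normalize, rarefyDepth, seed) {
  switch(normalize,
    relabund = relAbundance(mat),
    none = mat,
    rarefy = {
      if (is.null(rarefyDepth)) rarefyDepth <- min(rowSums(mat))
      .withSeed(seed, as.matrix(vegan::rrarefy(mat, rarefyDepth)))
    },
    stop("unknown normalize mode: ", normalize))
}

# enumerate intra/inter pairs from a design; returns the two provenance
# data.frames given a precomputed distance matrix
.partitionPairs <- function(dm, design) {
  level <- .pairLevel(design)
  grp <- design$.group
  ids <- rownames(design)
  n <- length(ids)
  intra <- list(); inter <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (level[i] != level[j]) next
    row <- data.frame(sample_a = ids[i], sample_b = ids[j],
                      group_a = grp[i], group_b = grp[j],
                      level = level[i], distance = dm[i, j],
                      stringsAsFactors = FALSE)
    if (grp[i] == grp[j]) intra[[length(intra) + 1L]] <- row
    else inter[[length(inter) + 1L]] <- row
  }
  list(intra = do.call(rbind, intra), inter = do.call(rbind, inter))
}

.emptyPairs <- data.frame(sample_a = character(0), sample_b = character(0),
                          group_a = character(0), group_b = character(0),
                          level = character(0), distance = numeric(0),
                          stringsAsFactors = FALSE)

.makeSummary <- function(intra, inter, stratum, gridN = 512L) {
  if (is.null(intra)) intra <- .emptyPairs
  if (is.null(inter)) inter <- .emptyPairs
  grid <- seq(0, 1, length.out = gridN)
  # both densities are smoothed with the larger of the two Silverman
  # bandwidths: the sets usually differ greatly in size (a handful of
  # intra pairs vs many inter pairs) and their overlap should reflect
  # where the distances lie, not how many pairs estimated each curve
  bw <- if (nrow(intra) >= 2 && nrow(inter) >= 2)
    max(.silvermanBw(intra$distance), .silvermanBw(inter$distance))
  else NULL
  ki <- if (nrow(intra) >= 2) kdeBounded(intra$distance, gridN, bw = bw)
        else NULL
  ke <- if (nrow(inter) >= 2) kdeBounded(inter$distance, gridN, bw = bw)
        else NULL
  ov <- if (!is.null(ki) && !is.null(ke)) overlapCoefficient(ki, ke)
        else NA_real_
  new("DistanceSummary", intra = intra, inter = inter, stratum = stratum,
      grid = grid,
      kdeIntra = if (is.null(ki)) numeric(0) else ki$density,
      kdeInter = if (is.null(ke)) numeric(0) else ke$density,
      overlap = ov)
}

#' Partition replicate distances into intra- and inter-replicate sets
#'
#' Computes all pairwise Bray-Curtis distances (after per-sample
#' normalization) and partitions the pairs at the same dilution/sample-type
#' level: pairs within one stratum group's technical replicates are
#' intra-replicate, pairs between different stratum groups are
#' inter-replicate. For a dilution series stratify by \code{"kit"}
#' (within-kit vs between-kit at the same dilution); for clinical data
#' stratify by \code{"specimen"}.
#'
#' @param x a \linkS4class{ReplicateExperiment}.
#' @param stratum \code{"kit"} or \code{"specimen"}.
#' @param normalize \code{"relabund"} (total-sum scaling, the deterministic
#'   default), \code{"rarefy"} (subsample to \code{rarefyDepth} reads with
#'   \code{seed}, for sensitivity analysis), or \code{"none"}.
#' @param rarefyDepth,seed rarefaction depth and RNG seed (rarefy mode).
#' @param gridN KDE grid resolution.
#' @return a \linkS4class{DistanceSummary}.
#' @export
intraInterDistances <- function(x, stratum = c("kit", "specimen"),
                                normalize = c("relabund", "rarefy", "none"),
                                rarefyDepth = NULL, seed = 1L,
                                gridN = 512L) {
  stratum <- match.arg(stratum)
  normalize <- match.arg(normalize)
  mat <- otuCounts(x)
  tot <- rowSums(mat)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(rownames(mat)[tot == 0], collapse = ", "),
         "; remove them before computing distances")
  design <- replicateDesign(x)
  design$.group <- as.character(
    if (stratum == "kit") design$kit else design$specimen_id)
  mat <- .normalizeCounts(mat, normalize, rarefyDepth, seed)
  dm <- brayCurtisMatrix(mat)
  parts <- .partitionPairs(dm, design)
  if (is.null(parts$intra) || !nrow(parts$intra))
    stop("no intra-replicate pairs: technical replicates (>= 2 samples per ",
         stratum, " at the same level) are required")
  .makeSummary(parts$intra, parts$inter, stratum, gridN)
}

#' Per-group distance summaries
#'
#' One \linkS4class{DistanceSummary} per stratum group g, whose intra set is
#' g's own replicate pairs and whose inter set is every pair joining g to a
#' different group at the same level. This is the per-kit (or per-specimen)
#' view that the regime classifier consumes.
#'
#' @inheritParams intraInterDistances
#' @return named list of \linkS4class{DistanceSummary} objects.
#' @export
replicateSummaries <- function(x, stratum = c("kit", "specimen"),
                               normalize = c("relabund", "rarefy", "none"),
                               rarefyDepth = NULL, seed = 1L, gridN = 512L) {
  stratum <- match.arg(stratum)
  normalize <- match.arg(normalize)
  all <- intraInterDistances(x, stratum, normalize, rarefyDepth, seed, gridN)
  groups <- sort(unique(c(all@intra$group_a, all@inter$group_a,
                          all@inter$group_b)))
  out <- lapply(groups, function(g) {
    intra <- all@intra[all@intra$group_a == g, , drop = FALSE]
    inter <- all@inter[all@inter$group_a == g | all@inter$group_b == g, ,
                       drop = FALSE]
    .makeSummary(intra, inter, stratum, gridN)
  })
  names(out) <- groups
  out
}

#' @rdname distance-accessors
#' @name distance-accessors
#' @title Accessors for DistanceSummary
#' @param x a \linkS4class{DistanceSummary}.
#' @export
setMethod("intraDistances", "DistanceSummary", function(x) x@intra$distance)

#' @rdname distance-accessors
#' @export
setMethod("interDistances", "DistanceSummary", function(x) x@inter$distance)

#' @rdname distance-accessors
#' @export
setMethod("distanceOverlap", "DistanceSummary", function(x) x@overlap)

setMethod("show", "DistanceSummary", function(object) {
  cat("DistanceSummary (stratum:", object@stratum, ")\n")
  cat(sprintf("  intra: %d pairs, median %.3f\n", nrow(object@intra),
              median(object@intra$distance)))
  cat(sprintf("  inter: %d pairs, median %.3f\n", nrow(object@inter),
              if (nrow(object@inter)) median(object@inter$distance) else NA))
  cat(sprintf("  density overlap: %.3f\n", object@overlap))
})
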