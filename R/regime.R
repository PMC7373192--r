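#' Regime classification thresholds
#'
#' Defaults calibrated on the package's generative simulator (the source
#' material gives only the qualitative three-regime picture): a replicate
#' set is reproducible when its median intra-replicate distance is at most
#' \code{intraLow}; reproducible sets split into signal vs contamination by
#' whether the inter-replicate median sits close to (\code{< separation})
#' or far from the intra median; irreproducible sets whose intra and inter
#' distance densities overlap heavily are noise.
#'
#' @param intraLow maximum median intra distance for a reproducible call
#'   (default 0.35).
#' @param separation minimum median(inter) - median(intra) gap that marks
#'   kit-specific (contamination) structure (default 0.20).
#' @param noiseFloor minimum median intra distance for a noise call
#'   (default 0.50).
#' @param overlapMin minimum intra/inter density overlap for a noise call
#'   (default 0.50).
#' @return named numeric vector of thresholds.
#' @export
regimeThresholds <- function(intraLow = 0.35, separation = 0.20,
                             noiseFloor = 0.50, overlapMin = 0.50) {
  c(intra_low = intraLow, separation = separation,
    noise_floor = noiseFloor, overlap_min = overlapMin)
}

#' Classify a replicate set into a reproducibility regime
#'
#' Decision rule on the evidence of a \linkS4class{DistanceSummary}:
#' \itemize{
#'   \item \code{signal_dominated}: median(intra) <= intra_low and
#'     median(inter) - median(intra) < separation — replicates agree and
#'     carry the same community as the other groups;
#'   \item \code{contamination_dominated}: median(intra) <= intra_low and
#'     the gap >= separation — reproducible within the group but
#'     group-specific, the reagent-contamination signature;
#'   \item \code{noise_dominated}: median(intra) > noise_floor and density
#'     overlap >= overlap_min — replicates disagree with each other as much
#'     as with everything else;
#'   \item \code{indeterminate} otherwise.
#' }
#' The call is idempotent: it depends only on the evidence and thresholds.
#'
#' @param s a \linkS4class{DistanceSummary} with at least one intra and one
#'   inter distance.
#' @param thresholds see [regimeThresholds()].
#' @param specimen optional label carried into the call.
#' @return a \linkS4class{RegimeCall}.
#' @export
classifyRegime <- function(s, thresholds = regimeThresholds(),
                           specimen = NA_character_) {
  if (!nrow(s@intra) || !nrow(s@inter))
    stop("regime classification needs non-empty intra and inter distance sets")
  medIntra <- median(s@intra$distance)
  medInter <- median(s@inter$distance)
  ov <- s@overlap
  th <- thresholds
  regime <-
    if (medIntra <= th["intra_low"] &&
        (medInter - medIntra) < th["separation"]) "signal_dominated"
    else if (medIntra <= th["intra_low"]) "contamination_dominated"
    else if (medIntra > th["noise_floor"] && !is.na(ov) &&
             ov >= th["overlap_min"]) "noise_dominated"
    else "indeterminate"
  new("RegimeCall", specimen = as.character(specimen), regime = regime,
      evidence = c(median_intra = medIntra, median_inter = medInter,
                   overlap = ov),
      thresholds = th)
}

#' Classify every stratum group of an experiment
#'
#' Convenience wrapper: [replicateSummaries()] followed by
#' [classifyRegime()] per group.
#'
#' @inheritParams intraInterDistances
#' @param thresholds see [regimeThresholds()].
#' @return data.frame with one row per group: regime and evidence.
#' @export
classifyRegimes <- function(x, stratum = c("kit", "specimen"),
                            thresholds = regimeThresholds(),
                            normalize = "relabund") {
  sums <- replicateSummaries(x, stratum, normalize)
  calls <- lapply(names(sums), function(g)
    classifyRegime(sums[[g]], thresholds, specimen = g))
  data.frame(
    group = names(sums),
    regime = vapply(calls, function(cl) cl@regime, character(1)),
    median_intra = vapply(calls, function(cl)
      unname(cl@evidence["median_intra"]), numeric(1)),
    median_inter = vapply(calls, function(cl)
      unname(cl@evidence["median_inter"]), numeric(1)),
    overlap = vapply(calls, function(cl)
      unname(cl@evidence["overlap"]), numeric(1)),
    stringsAsFactors = FALSE)
}

setMethod("show", "RegimeCall", function(object) {
  cat("RegimeCall:", object@specimen, "->", object@regime, "\n")
  ev <- object@evidence
  cat(sprintf("  median intra %.3f | median inter %.3f | overlap %.3f\n",
              ev["median_intra"], ev["median_inter"], ev["overlap"]))
})

#' Fit the biomass-reproducibility transition
#'
#' Fits a monotone-decreasing four-parameter logistic of mean
#' intra-replicate Bray-Curtis distance against log10(16S copies per
#' sample):
#' \deqn{d(x) = lo + (hi - lo) / (1 + exp(s (x - m)))}
#' with \code{s > 0}, so distance falls from \code{hi} toward \code{lo} as
#' biomass rises. The transition range is the copy interval over which the
#' curve crosses from 90% down to 10% of its span.
#'
#' @param copies 16S copies per sample (> 0); at least 5 points spanning at
#'   least 2 decades.
#' @param meanIntra mean intra-replicate distance at each copy number.
#' @return a \linkS4class{TransitionFit}; \code{converged = FALSE} (and no
#'   range) for flat or non-convergent data.
#' @export
transitionFit <- function(copies, meanIntra) {
  if (length(copies) != length(meanIntra))
    stop("copies and meanIntra must have equal length")
  if (length(copies) < 5) stop("at least 5 points are required")
  if (any(copies <= 0)) stop("copies must be positive")
  x <- log10(copies)
  if (diff(range(x)) < 2)
    stop("points must span at least 2 decades of copies")
  y <- meanIntra
  degenerate <- function(rss) new("TransitionFit",
    lower = NA_real_, upper = NA_real_, midpoint = NA_real_,
    slope = NA_real_, rangeLow = NA_real_, rangeHigh = NA_real_,
    rss = rss, converged = FALSE)
  if (diff(range(y)) < 0.05) return(degenerate(sum((y - mean(y))^2)))
  start <- list(lo = max(min(y), 0), hi = min(max(y), 1),
                m = stats::weighted.mean(x, w = abs(y - mean(y)) + 1e-6),
                s = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ lo + (hi - lo) / (1 + exp(s * (x - m))),
                      start = start,
                      lower = c(lo = 0, hi = 0, m = min(x) - 2, s = 0.05),
                      upper = c(lo = 1, hi = 1, m = max(x) + 2, s = 50),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(degenerate(NA_real_))
  p <- stats::coef(fit)
  if (p["hi"] <= p["lo"]) return(degenerate(sum(stats::resid(fit)^2)))
  half <- log(9) / p["s"]  # offset of the 10%/90% span points from m
  new("TransitionFit",
      lower = unname(p["lo"]), upper = unname(p["hi"]),
      midpoint = unname(p["m"]), slope = unname(p["s"]),
      rangeLow = unname(10^(p["m"] - half)),
      rangeHigh = unname(10^(p["m"] + half)),
      rss = sum(stats::resid(fit)^2), converged = TRUE)
}

#' @rdname TransitionFit-accessors
#' @name TransitionFit-accessors
#' @title Accessors for TransitionFit
#' @param x a \linkS4class{TransitionFit}.
#' @return \code{transitionMidpoint}: the inflection point in copies per
#'   sample; \code{transitionRange}: the 10%-90% span interval in copies.
#' @export
setMethod("transitionMidpoint", "TransitionFit", function(x) {
  if (!x@converged) return(NA_real_)
  10^x@midpoint
})

#' @rdname TransitionFit-accessors
#' @export
setMethod("transitionRange", "TransitionFit", function(x) {
  if (!x@converged) return(c(low = NA_real_, high = NA_real_))
  c(low = x@rangeLow, high = x@rangeHigh)
})

setMethod("show", "TransitionFit", function(object) {
  if (!object@converged) {
    cat("TransitionFit: not converged (flat or degenerate data)\n")
  } else {
    cat(sprintf(
      "TransitionFit: midpoint %.3g copies, range %.3g-%.3g, span %.2f-%.2f\n",
      10^object@midpoint, object@rangeLow, object@rangeHigh,
      object@lower, object@upper))
  }
})

#' Flag specimens below the low-biomass noise threshold
#'
#' Specimens with fewer than \code{threshold} 16S rRNA gene copies per
#' sample (strict inequality, default 1e5) are flagged as likely to be
#' significantly affected by stochastic sequencing noise; specimens with no
#' biomass record are flagged \code{"unknown"} rather than passed silently.
#'
#' @param copies named numeric vector of copies per specimen, or a
#'   \linkS4class{ReplicateExperiment} carrying biomass metadata.
#' @param specimens optional specimen ids to report on (defaults to the
#'   names of \code{copies}; specimens absent from \code{copies} come back
#'   "unknown").
#' @param threshold flagging threshold in copies (default 1e5).
#' @return data.frame with columns \code{specimen_id}, \code{copies},
#'   \code{status} ("flagged", "ok" or "unknown") and \code{low_biomass}
#'   (logical, NA when unknown).
#' @examples
#' flagLowBiomass(c(a = 5e4, b = 1e5, c = 1e7))
#' @export
flagLowBiomass <- function(copies, specimens = NULL, threshold = 1e5) {
  if (is(copies, "ReplicateExperiment")) {
    if (is.null(specimens))
      specimens <- unique(replicateDesign(copies)$specimen_id)
    copies <- biomassCopies(copies)
    if (is.null(copies)) copies <- numeric(0)
  }
  if (any(copies < 0, na.rm = TRUE)) stop("copies must be >= 0")
  if (is.null(specimens)) specimens <- names(copies)
  if (is.null(specimens)) stop("specimen ids are required")
  cp <- unname(copies[match(specimens, names(copies))])
  flag <- cp < threshold
  data.frame(specimen_id = specimens, copies = cp,
             status = ifelse(is.na(cp), "unknown",
                             ifelse(flag, "flagged", "ok")),
             low_biomass = flag, stringsAsFactors = FALSE)
}
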