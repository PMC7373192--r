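# per-specimen matrix of replicate-median relative abundances
# rows = specimens, cols = OTUs
.specimenMedians <- function(x, sampleType = NULL, minReplicates = 2L,
                             onSingle = c("warn", "error")) {
  onSingle <- match.arg(onSingle)
  design <- replicateDesign(x)
  keep <- rep(TRUE, nrow(design))
  if (!is.null(sampleType)) keep <- design$sample_type %in% sampleType
  if (!any(keep)) stop("no samples of type ",
                       paste(sampleType, collapse = "/"))
  mat <- relAbundance(otuCounts(x)[keep, , drop = FALSE])
  spec <- as.character(design$specimen_id[keep])
  nrep <- table(spec)
  few <- names(nrep)[nrep < minReplicates]
  if (length(few)) {
    msg <- paste0("specimen(s) with fewer than ", minReplicates,
                  " replicates excluded: ", paste(few, collapse = ", "))
    if (onSingle == "error") stop(msg) else warning(msg)
  }
  specimens <- setdiff(unique(spec), few)
  if (!length(specimens))
    stop("no specimen has >= ", minReplicates, " replicates")
  med <- t(vapply(specimens, function(sp)
    apply(mat[spec == sp, , drop = FALSE], 2, median), numeric(ncol(mat))))
  rownames(med) <- specimens
  attr(med, "n_replicates") <- as.integer(nrep[specimens])
  med
}

#' Mean-of-replicate-medians consensus profile
#'
#' For each specimen, counts are converted to per-replicate relative
#' abundances and the per-OTU median across that specimen's replicates is
#' taken; medians are then averaged (with SEM) across specimens. An OTU
#' seen in only a minority of a specimen's replicates has median 0 there,
#' so irreproducible noise is de-emphasized while the reproducible core of
#' the community is kept. Because medians are taken per OTU, the consensus
#' vector need not sum to 1.
#'
#' @param x a \linkS4class{ReplicateExperiment}.
#' @param sampleType optional sample-type filter (e.g. \code{"CBAL"}).
#' @param minReplicates specimens with fewer replicates are excluded with a
#'   warning (default 2), or an error when \code{onSingle = "error"}.
#' @param onSingle \code{"warn"} (default) or \code{"error"}.
#' @return data.frame with one row per OTU: \code{otu_id},
#'   \code{taxonomy}, consensus \code{mean}, \code{sem} across specimens,
#'   and \code{n_specimens}; ordered by decreasing mean (the rank-abundance
#'   order).
#' @export
meanOfReplicateMedians <- function(x, sampleType = NULL,
                                   minReplicates = 2L,
                                   onSingle = c("warn", "error")) {
  med <- .specimenMedians(x, sampleType, minReplicates, onSingle)
  nspec <- nrow(med)
  mu <- colMeans(med)
  sem <- if (nspec > 1) apply(med, 2, sd) / sqrt(nspec) else rep(0, ncol(med))
  tx <- taxonomyLabels(x)
  out <- data.frame(otu_id = colnames(med),
                    taxonomy = unname(tx[colnames(med)]),
                    mean = unname(mu), sem = unname(sem),
                    n_specimens = nspec, stringsAsFactors = FALSE)
  out[order(-out$mean, out$otu_id), , drop = FALSE]
}

#' Identify contaminant OTUs from negative-control replicates
#'
#' An OTU is flagged as a reagent contaminant when (a) its
#' mean-of-replicate-medians abundance across the control specimens is at
#' least \code{minAbund} and (b) it is detected (count > 0) in at least a
#' fraction \code{minPrev} of the replicates of at least one control kit.
#' Condition (a) captures "reproducibly abundant in controls"; condition
#' (b) ties the abundance to a consistent within-kit presence rather than a
#' one-replicate spike.
#'
#' @param x a \linkS4class{ReplicateExperiment}; only samples with
#'   \code{is_control == TRUE} are used (error if there are none).
#' @param minAbund minimum control consensus abundance (default 0.01).
#' @param minPrev minimum within-kit replicate prevalence (default 2/3).
#' @return a \linkS4class{ContaminantReport} whose \code{flagged} slot has
#'   one row per contaminant with its evidence; retention fields are filled
#'   by [removeContaminants()].
#' @export
identifyContaminants <- function(x, minAbund = 0.01, minPrev = 2 / 3) {
  design <- replicateDesign(x)
  ctl <- design$is_control
  if (!any(ctl)) stop("no control samples (is_control == TRUE) in the table")
  xc <- x[, ctl]
  med <- .specimenMedians(xc, minReplicates = 2L)
  consensus <- colMeans(med)
  cts <- otuCounts(xc)
  kit <- as.character(replicateDesign(xc)$kit)
  prev <- vapply(unique(kit), function(k) {
    colMeans(cts[kit == k, , drop = FALSE] > 0)
  }, numeric(ncol(cts)))  # OTUs x kits
  bestPrev <- apply(prev, 1, max)
  bestKit <- unique(kit)[apply(prev, 1, which.max)]
  hit <- consensus >= minAbund & bestPrev >= minPrev
  flagged <- data.frame(otu_id = colnames(cts)[hit],
                        consensus_abund = unname(consensus[hit]),
                        kit = bestKit[hit],
                        prevalence = unname(bestPrev[hit]),
                        stringsAsFactors = FALSE)
  flagged <- flagged[order(-flagged$consensus_abund), , drop = FALSE]
  new("ContaminantReport", flagged = flagged,
      criteria = c(min_abund = minAbund, min_prevalence = minPrev),
      retention = data.frame(sample_id = character(0),
                             reads_before = numeric(0),
                             reads_after = numeric(0),
                             retained = numeric(0)),
      meanRetained = NA_real_, emptied = character(0))
}

#' Remove flagged contaminant OTUs with retention accounting
#'
#' Drops the flagged OTU columns from every sample and reports, per sample,
#' the read totals before and after and the fraction retained; removal that
#' empties a sample flags it in the report rather than dropping it. The
#' accounting is always emitted — comparing count totals before and after
#' removal is part of the procedure, not an option.
#'
#' @param x a \linkS4class{ReplicateExperiment}.
#' @param flagged character vector of OTU ids, or a
#'   \linkS4class{ContaminantReport} from [identifyContaminants()].
#' @return list with \code{experiment} (the filtered
#'   \linkS4class{ReplicateExperiment}) and \code{report} (the
#'   \linkS4class{ContaminantReport} with retention filled in).
#' @export
removeContaminants <- function(x, flagged) {
  report <- if (is(flagged, "ContaminantReport")) flagged
            else new("ContaminantReport",
                     flagged = data.frame(otu_id = as.character(flagged),
                                          stringsAsFactors = FALSE),
                     criteria = c(min_abund = NA_real_,
                                  min_prevalence = NA_real_),
                     retention = data.frame(), meanRetained = NA_real_,
                     emptied = character(0))
  otus <- report@flagged$otu_id
  unknown <- setdiff(otus, rownames(x))
  if (length(unknown))
    stop("flagged OTU(s) not in the table: ",
         paste(unknown, collapse = ", "))
  before <- colSums(SummarizedExperiment::assay(x, "counts"))
  out <- x[!rownames(x) %in% otus, ]
  after <- colSums(SummarizedExperiment::assay(out, "counts"))
  retained <- ifelse(before > 0, after / before, 1)
  retention <- data.frame(sample_id = colnames(x),
                          reads_before = unname(before),
                          reads_after = unname(after),
                          retained = unname(retained),
                          stringsAsFactors = FALSE)
  report@retention <- retention
  report@meanRetained <- mean(retained)
  report@emptied <- colnames(x)[before > 0 & after == 0]
  list(experiment = out, report = report)
}

setMethod("show", "ContaminantReport", function(object) {
  cat("ContaminantReport:", nrow(object@flagged), "flagged OTU(s)\n")
  if (nrow(object@flagged)) {
    for (i in seq_len(min(nrow(object@flagged), 10)))
      cat(sprintf("  %s: consensus %.3f, prevalence %.2f (%s)\n",
                  object@flagged$otu_id[i],
                  object@flagged$consensus_abund[i],
                  object@flagged$prevalence[i], object@flagged$kit[i]))
  }
  if (!is.na(object@meanRetained))
    cat(sprintf("  mean read retention after removal: %.3f%s\n",
                object@meanRetained,
                if (length(object@emptied))
                  paste0(" (emptied: ",
                         paste(object@emptied, collapse = ", "), ")")
                else ""))
})

#' Replicate concordance score of a specimen
#'
#' The fraction of a specimen's total reads (summed over its technical
#' replicates) that belong to OTUs detected in every replicate — the mass
#' that would fall on the diagonal if each replicate were an axis of a
#' scatter cube. 1 for identical replicates, 0 for replicates with disjoint
#' OTU sets.
#'
#' @param x a \linkS4class{ReplicateExperiment}.
#' @param specimen specimen id with at least 2 replicates of positive total.
#' @return score in [0, 1].
#' @export
concordanceScore <- function(x, specimen) {
  design <- replicateDesign(x)
  idx <- design$specimen_id == specimen
  if (sum(idx) < 2)
    stop("specimen '", specimen, "' needs >= 2 replicates")
  cts <- otuCounts(x)[idx, , drop = FALSE]
  if (any(rowSums(cts) == 0))
    stop("specimen '", specimen, "' has zero-total replicate(s)")
  shared <- colSums(cts > 0) == nrow(cts)
  sum(cts[, shared, drop = FALSE]) / sum(cts)
}
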