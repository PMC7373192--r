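#' Build a ReplicateExperiment
#'
#' Assemble a replicated OTU experiment from a sample-by-OTU count matrix,
#' a replicate design table, optional taxonomy and optional per-specimen
#' biomass (16S copies from ddPCR).
#'
#' @param counts numeric matrix of non-negative whole read counts, samples
#'   in rows (the `.shared` orientation), OTUs in columns; dimnames required.
#' @param design data.frame with one row per sample. Sample ids are taken
#'   from a \code{sample_id} column or from the row names. Required columns:
#'   \code{specimen_id}, \code{replicate}, \code{kit}, \code{is_control},
#'   \code{sample_type}; \code{dilution} is optional. Every sample of
#'   \code{counts} must appear exactly once.
#' @param taxonomy optional named character vector of taxonomy strings;
#'   every name must be an OTU of \code{counts}.
#' @param biomass optional named numeric vector of 16S copies per specimen.
#' @return A \linkS4class{ReplicateExperiment}. Internally counts are stored
#'   OTUs-by-samples, the Bioconductor convention; [otuCounts()] returns the
#'   samples-by-OTUs orientation used throughout the analysis functions.
#' @examples
#' cts <- matrix(c(10L, 0L, 5L, 8L, 1L, 6L), nrow = 2, byrow = TRUE,
#'               dimnames = list(c("s1", "s2"), c("Otu1", "Otu2", "Otu3")))
#' des <- data.frame(sample_id = c("s1", "s2"), specimen_id = "sp1",
#'                   replicate = 1:2, kit = "A", is_control = FALSE,
#'                   sample_type = "oral")
#' ReplicateExperiment(cts, des)
#' @export
ReplicateExperiment <- function(counts, design, taxonomy = NULL,
                                biomass = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  design <- as.data.frame(design)
  ids <- if ("sample_id" %in% colnames(design)) as.character(design$sample_id)
         else rownames(design)
  if (anyDuplicated(ids))
    stop("duplicate sample_id in design: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(rownames(counts), ids)
  if (length(missing))
    stop("design is missing sample(s): ", paste(missing, collapse = ", "))
  design <- design[match(rownames(counts), ids), , drop = FALSE]
  rownames(design) <- rownames(counts)
  design$sample_id <- NULL
  if (!is.null(taxonomy)) {
    bad <- setdiff(names(taxonomy), colnames(counts))
    if (length(bad))
      stop("taxonomy names are not OTUs of the table: ",
           paste(bad, collapse = ", "))
  }
  rd <- S4Vectors::DataFrame(row.names = colnames(counts))
  rd$taxonomy <- if (is.null(taxonomy)) NA_character_
                 else unname(taxonomy[colnames(counts)])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)),
    colData = S4Vectors::DataFrame(design),
    rowData = rd)
  if (!is.null(biomass)) S4Vectors::metadata(se)$biomass <- biomass
  new("ReplicateExperiment", se)
}

#' Read counts, samples in rows
#'
#' @param x a \linkS4class{ReplicateExperiment}.
#' @param ... unused.
#' @return integer matrix, samples x OTUs.
#' @export
setMethod("otuCounts", "ReplicateExperiment", function(x, ...) {
  t(SummarizedExperiment::assay(x, "counts"))
})

#' Per-sample relative abundances
#'
#' Total-sum scaling: each sample row is divided by its read total, so rows
#' with positive totals sum to 1. Zero-total rows stay all-zero.
#'
#' @param x a \linkS4class{ReplicateExperiment} or a samples-by-OTUs matrix.
#' @param ... unused.
#' @return numeric matrix, samples x OTUs.
#' @export
setMethod("relAbundance", "matrix", function(x, ...) {
  tot <- rowSums(x)
  out <- x / ifelse(tot > 0, tot, 1)
  out
})

#' @rdname relAbundance
#' @export
setMethod("relAbundance", "ReplicateExperiment", function(x, ...) {
  relAbundance(otuCounts(x))
})

#' Accessors for ReplicateExperiment metadata
#'
#' \code{replicateDesign} returns the per-sample design as a data.frame;
#' \code{biomassCopies} the named per-specimen 16S copy numbers (or NULL);
#' \code{taxonomyLabels} the named taxonomy strings (NA where unknown).
#'
#' @param x a \linkS4class{ReplicateExperiment}.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("replicateDesign", "ReplicateExperiment", function(x, ...) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname accessors
#' @export
setMethod("biomassCopies", "ReplicateExperiment", function(x, ...) {
  S4Vectors::metadata(x)$biomass
})

#' @rdname accessors
#' @export
setMethod("taxonomyLabels", "ReplicateExperiment", function(x, ...) {
  tx <- SummarizedExperiment::rowData(x)$taxonomy
  names(tx) <- rownames(x)
  tx
})

setMethod("show", "ReplicateExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ReplicateExperiment:", ncol(object), "samples x", nrow(object),
      "OTUs\n")
  cat("  specimens:", length(unique(cd$specimen_id)),
      " kits:", length(unique(cd$kit)),
      " controls:", sum(cd$is_control), "\n")
  if (!is.null(S4Vectors::metadata(object)$biomass))
    cat("  biomass records:",
        length(S4Vectors::metadata(object)$biomass), "specimens\n")
})
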