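#' Read a mothur `.shared` OTU table
#'
#' Parses the tab-delimited mothur shared format (columns \code{label},
#' \code{Group}, \code{numOtus}, then one column per OTU) into a
#' samples-by-OTUs integer count matrix. \code{Group} is the sample id.
#' Zero-total samples are retained; downstream distance operations reject
#' them explicitly.
#'
#' @param path path to a `.shared` file.
#' @return integer matrix, samples in rows, OTUs in columns.
#' @examples
#' f <- system.file("extdata", "toy.shared", package = "replinoise")
#' readShared(f)[, 1:3]
#' @export
readShared <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  for (col in c("label", "Group", "numOtus"))
    if (!col %in% colnames(tab))
      stop("malformed .shared header: missing column '", col, "'")
  otuCols <- setdiff(colnames(tab), c("label", "Group", "numOtus"))
  nOtu <- suppressWarnings(as.integer(tab$numOtus))
  if (any(is.na(nOtu)) || any(nOtu != length(otuCols)))
    stop("numOtus column (", paste(unique(tab$numOtus), collapse = ","),
         ") inconsistent with ", length(otuCols), " parsed OTU columns")
  if (anyDuplicated(tab$Group))
    stop("duplicate Group (sample) ids: ",
         paste(unique(tab$Group[duplicated(tab$Group)]), collapse = ", "))
  cts <- matrix(NA_integer_, nrow(tab), length(otuCols),
                dimnames = list(tab$Group, otuCols))
  for (j in seq_along(otuCols)) {
    v <- suppressWarnings(as.numeric(tab[[otuCols[j]]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad))
      stop("non-integer count at row ", bad[1], ", column '", otuCols[j],
           "' (value '", tab[[otuCols[j]]][bad[1]], "')")
    cts[, j] <- as.integer(v)
  }
  cts
}

#' Write a count matrix as a mothur `.shared` file
#'
#' @param counts samples-by-OTUs count matrix with dimnames.
#' @param path output file.
#' @param label mothur distance label column (conventionally the OTU
#'   clustering cutoff).
#' @return \code{path}, invisibly.
#' @export
writeShared <- function(counts, path, label = "0.03") {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  out <- data.frame(label = label, Group = rownames(counts),
                    numOtus = ncol(counts), check.names = FALSE)
  out <- cbind(out, as.data.frame(counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mothur `.cons.taxonomy` file
#'
#' Returns the taxonomy strings verbatim (no rank splitting), named by OTU.
#' Use [splitTaxonomy()] to break a string into ranks.
#'
#' @param path path to a `.cons.taxonomy` file (columns OTU, Size, Taxonomy).
#' @return named character vector.
#' @export
readTaxonomy <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  for (col in c("OTU", "Taxonomy"))
    if (!col %in% colnames(tab))
      stop("malformed taxonomy header: missing column '", col, "'")
  if (anyDuplicated(tab$OTU)) stop("duplicate OTU ids in taxonomy")
  structure(tab$Taxonomy, names = tab$OTU)
}

#' Split a mothur taxonomy string into ranks
#'
#' Helper over the verbatim storage format: strips bootstrap confidence
#' values in parentheses and splits on ';'.
#'
#' @param tax character vector of taxonomy strings.
#' @return list of rank character vectors.
#' @export
splitTaxonomy <- function(tax) {
  lapply(strsplit(sub(";$", "", tax), ";", fixed = TRUE),
         function(x) gsub("\\(\\d+\\)$", "", x))
}

#' Read a replicate design table
#'
#' Tab-separated with required columns \code{sample_id}, \code{specimen_id},
#' \code{replicate}, \code{kit}, \code{is_control}, \code{sample_type};
#' \code{dilution} optional; unknown columns are kept but ignored by the
#' analysis functions.
#'
#' @param path path to a design TSV.
#' @return data.frame with one row per sample.
#' @export
readDesign <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  need <- c("sample_id", "specimen_id", "replicate", "kit", "is_control",
            "sample_type")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  tab$replicate <- as.integer(tab$replicate)
  if (any(is.na(tab$replicate)) || any(tab$replicate < 1))
    stop("replicate indices must be integers >= 1")
  tab$is_control <- as.logical(tab$is_control)
  tab
}

#' Read per-specimen 16S copy numbers (ddPCR)
#'
#' Tab-separated with columns \code{specimen_id} and \code{copies}
#' (16S rRNA gene copies per sample; scientific notation accepted).
#'
#' @param path path to a biomass TSV.
#' @return named numeric vector of copies per specimen.
#' @export
readBiomass <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  for (col in c("specimen_id", "copies"))
    if (!col %in% colnames(tab))
      stop("biomass table is missing column '", col, "'")
  if (anyDuplicated(tab$specimen_id))
    stop("duplicate specimen_id in biomass table")
  copies <- as.numeric(tab$copies)
  if (any(is.na(copies)) || any(copies < 0))
    stop("copies must be non-negative numbers")
  structure(copies, names = as.character(tab$specimen_id))
}

#' Demographics of the study cohort
#'
#' The packaged table of the 20 healthy volunteers whose respiratory
#' specimens span the high- to ultralow-biomass range: sex, age, race,
#' smoking history and spirometry (FEV1, FVC and their ratio).
#'
#' @return data.frame with 20 rows.
#' @export
demographicsTable <- function() {
  f <- system.file("extdata", "table1_demographics.tsv",
                   package = "replinoise", mustWork = TRUE)
  read.delim(f, check.names = FALSE)
}

#' Summarize cohort demographics
#'
#' Mean (rounded to integer years) and SD of age, percent female, and the
#' percent breakdown by race, each over all participants.
#'
#' @param d demographics data.frame with columns \code{sex}, \code{age},
#'   \code{race} (see [demographicsTable()]).
#' @return list with \code{n}, \code{mean_age}, \code{sd_age},
#'   \code{pct_female}, \code{pct_race}.
#' @examples
#' summarizeDemographics(demographicsTable())
#' @export
summarizeDemographics <- function(d) {
  if (!NROW(d)) stop("empty demographics table")
  n <- nrow(d)
  list(n = n,
       mean_age = round(mean(d$age)),
       sd_age = if (n < 2) 0 else sd(d$age),
       pct_female = 100 * sum(d$sex == "Female") / n,
       pct_race = 100 * table(d$race) / n)
}
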