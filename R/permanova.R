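# within-group sum of squared distances, Anderson's direct formula:
# SS_W = sum over groups of (1 / n_g) * sum_{i<j in g} d_ij^2
.ssWithin <- function(d2, groups) {
  s <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' One-factor pseudo-F statistic of a distance matrix
#'
#' \code{F = (SS_between / (g - 1)) / (SS_within / (n - g))} with the sums
#' of squares taken directly from the (squared) distances, equivalent to
#' the Gower-centred decomposition. Returns 0 when the total sum of squares
#' is 0.
#'
#' @param dm square symmetric distance matrix (or \code{dist}).
#' @param groups group labels, one per sample.
#' @return the pseudo-F statistic.
#' @export
permanovaF <- function(dm, groups) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  g <- length(unique(groups))
  d2 <- dm^2
  ssT <- sum(d2) / (2 * n)
  ssW <- .ssWithin(d2, groups)
  ssB <- ssT - ssW
  if (ssT <= 1e-15 || ssW <= 1e-15) {
    if (ssB <= 1e-15) return(0)
    return(Inf)
  }
  # semimetric distances can give a (meaningless) negative SS_between under
  # some labelings; report 0, consistently for observed and permuted F
  max((ssB / (g - 1)) / (ssW / (n - g)), 0)
}

#' Permutational MANOVA on a dissimilarity matrix
#'
#' One-factor permutation test of whether groups differ in their location
#' in dissimilarity space, using the pseudo-F statistic and
#' \code{p = (1 + #\{F* >= F\}) / (1 + nPerm)}. Free permutation of sample
#' labels is the default; when \code{block} labels are supplied (e.g.
#' specimen ids), whole blocks are permuted together, because technical
#' replicates of one specimen are not exchangeable units — treating them as
#' free samples is exactly the pitfall that makes irreproducible noise look
#' "significant".
#'
#' @param dm square symmetric zero-diagonal distance matrix (or
#'   \code{dist}).
#' @param groups group labels; at least 2 groups with at least 2 members
#'   each.
#' @param nPerm number of permutations (>= 99; default 999).
#' @param seed optional RNG seed for the permutations.
#' @param block optional block labels (constant group within block).
#' @return a \linkS4class{PermanovaResult}.
#' @examples
#' m <- relAbundance(matrix(rpois(60, 20), 6,
#'                   dimnames = list(paste0("s", 1:6), NULL)))
#' dm <- brayCurtisMatrix(m)
#' bcPermanova(dm, rep(c("a", "b"), each = 3), nPerm = 199, seed = 1)
#' @export
bcPermanova <- function(dm, groups, nPerm = 999L, seed = NULL,
                        block = NULL) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-10))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be 0")
  groups <- as.character(groups)
  if (length(groups) != nrow(dm))
    stop("one group label per sample is required")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop(">= 2 groups with >= 2 members each are required")
  nPerm <- as.integer(nPerm)
  if (nPerm < 99) stop("nPerm must be >= 99")
  if (!is.null(block)) {
    block <- as.character(block)
    bg <- tapply(groups, block, function(v) {
      if (length(unique(v)) != 1)
        stop("group must be constant within a block")
      v[1]
    })
  }
  d2 <- dm^2
  n <- nrow(dm)
  g <- length(sizes)
  ssT <- sum(d2) / (2 * n)
  fStat <- function(lab) {
    ssW <- .ssWithin(d2, lab)
    ssB <- ssT - ssW
    if (ssT <= 1e-15 || ssW <= 1e-15)
      return(if (ssB <= 1e-15) 0 else Inf)
    max((ssB / (g - 1)) / (ssW / (n - g)), 0)
  }
  fObs <- fStat(groups)
  permuteLabels <- if (is.null(block)) {
    function() sample(groups)
  } else {
    blocks <- names(bg)
    function() {
      newbg <- stats::setNames(sample(as.character(bg)), blocks)
      unname(newbg[block])
    }
  }
  fPerm <- .withSeed(seed, vapply(seq_len(nPerm),
                                  function(i) fStat(permuteLabels()),
                                  numeric(1)))
  p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + nPerm)
  new("PermanovaResult", pseudoF = fObs, pValue = p,
      nPermutations = nPerm,
      groupSizes = stats::setNames(as.integer(sizes), names(sizes)),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PermanovaResult: pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              object@pseudoF, object@pValue, object@nPermutations))
  cat("  groups:", paste(names(object@groupSizes), object@groupSizes,
                         sep = "=", collapse = ", "), "\n")
})
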