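# run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic per-replicate substream seed derived from the master seed
# and the replicate coordinates; kept below 2^31 - 1
.streamSeed <- function(seed, kit, rep, dil) {
  as.integer((seed %% 2147483647 + kit * 1000003 + rep * 75619 +
                dil * 7919111) %% 2147483646 + 1)
}

#' Construct a simulator configuration
#'
#' Defaults mirror the dilution-series experiment the simulator emulates: a
#' single-strain community (one signal OTU) at \code{1e8} 16S copies neat,
#' diluted tenfold five times, extracted with 3 kits and sequenced in
#' quadruplicate at a fixed depth of 20,000 reads, with no reagent
#' contamination and a noise scale lambda of 5,000 effective templates so
#' the noise share of reads, lambda / (N + N_c + lambda), becomes dominant
#' in the last two dilutions.
#'
#' @param trueProfile named composition over signal OTUs (default a single
#'   OTU, as for a pure-culture dilution series).
#' @param inputCopies 16S copies per specimen before dilution.
#' @param contamination list of per-kit named contaminant compositions
#'   (default none).
#' @param contamCopies per-kit contaminant copy numbers.
#' @param noiseScale lambda, the effective noise template count.
#' @param noisePoolSize,noiseSubsetSize,noiseConcentration shared noise OTU
#'   pool size (default 2000), OTUs drawn per replicate (default 200), and
#'   symmetric Dirichlet concentration of the per-replicate weights
#'   (default 0.05).
#' @param readDepth reads per sample (default 20000).
#' @param nKits,nReplicates,dilutionFactors design shape (defaults 3 kits,
#'   4 replicates, factors 1 down to 1e-5).
#' @param seed master seed; together with the config it fully determines
#'   the output.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(trueProfile = c(Paeruginosa = 1),
                      inputCopies = 1e8,
                      contamination = list(), contamCopies = numeric(0),
                      noiseScale = 5e3, noisePoolSize = 2000L,
                      noiseSubsetSize = 200L, noiseConcentration = 0.05,
                      readDepth = 20000L, nKits = 3L, nReplicates = 4L,
                      dilutionFactors = 10^(0:-5), seed = 1L) {
  new("SimConfig", trueProfile = trueProfile, inputCopies = inputCopies,
      contamination = contamination, contamCopies = contamCopies,
      noiseScale = noiseScale, noisePoolSize = as.integer(noisePoolSize),
      noiseSubsetSize = as.integer(noiseSubsetSize),
      noiseConcentration = noiseConcentration,
      readDepth = as.integer(readDepth), nKits = as.integer(nKits),
      nReplicates = as.integer(nReplicates),
      dilutionFactors = dilutionFactors, seed = as.numeric(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@trueProfile), "signal OTU(s),",
      "N =", format(object@inputCopies, big.mark = ","),
      "copies, lambda =", object@noiseScale, "\n")
  cat("  design:", object@nKits, "kits x", object@nReplicates,
      "replicates x", length(object@dilutionFactors), "dilutions, depth",
      object@readDepth, "\n")
  cat("  noise pool:", object@noisePoolSize, "OTUs, K =",
      object@noiseSubsetSize, ", alpha =", object@noiseConcentration, "\n")
})

.noiseNames <- function(cfg) sprintf("Noise%04d", seq_len(cfg@noisePoolSize))

# full OTU namespace of a run: signal, every kit's contaminants, noise pool
.otuNamespace <- function(cfg, extraContam = list()) {
  contamOtus <- unlist(lapply(c(cfg@contamination, extraContam), names),
                       use.names = FALSE)
  unique(c(names(cfg@trueProfile), contamOtus, .noiseNames(cfg)))
}

# core generative draw; assumes the RNG state is already positioned
.simReads <- function(cfg, copies, contamProfile, contamCopies, otus) {
  R <- cfg@readDepth
  lam <- cfg@noiseScale
  tT <- if (copies > 0) rpois(1, copies) else 0
  tC <- if (contamCopies > 0) rpois(1, contamCopies) else 0
  if (tT + tC + lam <= 0)
    stop("no read source: template, contaminant and noise scale all zero")
  w <- (tT + tC) / (tT + tC + lam)
  tmplReads <- rbinom(1, R, w)
  counts <- stats::setNames(integer(length(otus)), otus)
  if (tmplReads > 0) {
    props <- tT * cfg@trueProfile
    if (tC > 0 && length(contamProfile))
      props <- c(props, tC * contamProfile)
    props <- tapply(props, names(props), sum)  # merge shared OTU ids
    draw <- rmultinom(1, tmplReads, props / sum(props))[, 1]
    counts[names(draw)] <- counts[names(draw)] + as.integer(draw)
  }
  noiseReads <- R - tmplReads
  if (noiseReads > 0) {
    idx <- sample.int(cfg@noisePoolSize, cfg@noiseSubsetSize)
    wts <- rgamma(cfg@noiseSubsetSize, shape = cfg@noiseConcentration)
    wts <- pmax(wts, 1e-300)
    draw <- rmultinom(1, noiseReads, wts / sum(wts))[, 1]
    nm <- .noiseNames(cfg)[idx]
    counts[nm] <- counts[nm] + as.integer(draw)
  }
  counts
}

#' Simulate one technical replicate
#'
#' Generative model of a sequencing lane at fixed depth R: effective
#' template counts are Poisson draws T ~ Pois(N) (signal) and
#' T_c ~ Pois(N_c) (the kit's contaminant); template reads are
#' Binomial(R, w) with signal weight w = (T + T_c) / (T + T_c + lambda) and
#' are spread multinomially over proportions T * trueProfile + T_c * c_k;
#' the remaining reads are noise, spread over a composition drawn fresh for
#' this replicate (K OTUs chosen uniformly from the shared pool, weights
#' symmetric Dirichlet(alpha)). Counts always sum exactly to R.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param kit,replicate,dilution 1-based coordinates; they select the
#'   deterministic RNG substream and (for \code{kit}) the contaminant
#'   profile from \code{cfg}.
#' @param copies signal template copies N for this draw (default the
#'   config's \code{inputCopies} scaled by the chosen dilution factor).
#' @param contamProfile,contamCopies override the kit contaminant (named
#'   composition and copy number); default taken from the config.
#' @return named integer vector over the run's full OTU namespace.
#' @export
simulateReplicate <- function(cfg, kit = 1L, replicate = 1L, dilution = 1L,
                              copies = cfg@inputCopies *
                                cfg@dilutionFactors[dilution],
                              contamProfile = NULL, contamCopies = NULL) {
  if (is.null(contamProfile) && kit <= length(cfg@contamination))
    contamProfile <- cfg@contamination[[kit]]
  if (is.null(contamCopies))
    contamCopies <- if (kit <= length(cfg@contamCopies))
      cfg@contamCopies[kit] else 0
  if (copies == 0 && contamCopies == 0 && cfg@noiseScale == 0)
    stop("no read source: template, contaminant and noise scale all zero")
  extra <- if (is.null(contamProfile)) list() else list(contamProfile)
  otus <- .otuNamespace(cfg, extra)
  .withSeed(.streamSeed(cfg@seed, kit, replicate, dilution),
            .simReads(cfg, copies, contamProfile,
                      if (is.null(contamCopies)) 0 else contamCopies, otus))
}

#' Simulate a dilution series experiment
#'
#' The default shape is 3 kits x 4 technical replicates x 6 levels (neat
#' plus five tenfold dilutions) of a single-strain template, each specimen
#' being one kit extraction at one dilution. Biomass records carry the
#' nominal template copies per specimen. The result is a pure function of
#' the config (including its seed).
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{ReplicateExperiment} with design, taxonomy-free
#'   counts and per-specimen biomass metadata.
#' @export
simulateDilutionSeries <- function(cfg) {
  otus <- .otuNamespace(cfg)
  rows <- list(); design <- list(); biomass <- c()
  for (k in seq_len(cfg@nKits)) for (d in seq_along(cfg@dilutionFactors)) {
    N <- cfg@inputCopies * cfg@dilutionFactors[d]
    spec <- sprintf("K%dD%d", k, d)
    biomass[spec] <- N
    for (r in seq_len(cfg@nReplicates)) {
      id <- sprintf("K%dD%dR%d", k, d, r)
      rows[[id]] <- simulateReplicate(cfg, kit = k, replicate = r,
                                      dilution = d, copies = N)
      design[[id]] <- data.frame(
        sample_id = id, specimen_id = spec, replicate = r,
        kit = sprintf("Kit%d", k), is_control = FALSE,
        sample_type = "dilution",
        dilution = sprintf("D%d_%0.0e", d, cfg@dilutionFactors[d]),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)[, otus, drop = FALSE]
  ReplicateExperiment(counts, do.call(rbind, design), biomass = biomass)
}

#' Simulate negative-control (reagent-only) sequencing
#'
#' Isolation controls carry no biological template (N = 0). Contaminated
#' kits receive a kit-specific contaminant community (reproducible within
#' the kit, hence low intra-replicate distances); clean kits yield pure
#' per-replicate noise (irreproducible). The default 2-of-7 contaminated
#' design reproduces the structural dichotomy seen across reagent-control
#' kits.
#'
#' @param cfg a \linkS4class{SimConfig}; \code{noiseScale} must be > 0 so
#'   clean kits have a read source.
#' @param nKits,nReplicates control design (defaults 7 kits x 3
#'   replicates).
#' @param contaminated logical per kit (default the first 2 of 7).
#' @param contamCopies copies of the contaminant community in a
#'   contaminated kit (default 1e6).
#' @param nContamOtus contaminant OTUs per contaminated kit (default 10);
#'   their within-kit composition is a Dirichlet draw from the kit's
#'   deterministic substream.
#' @param profiles optional list of per-kit contaminant compositions (named
#'   numeric, NULL for clean kits), overriding the generated ones — use
#'   this to plant the same contaminant community in controls and samples.
#' @return a \linkS4class{ReplicateExperiment} of control samples.
#' @export
simulateControls <- function(cfg, nKits = 7L, nReplicates = 3L,
                             contaminated = c(rep(TRUE, 2), rep(FALSE, 5)),
                             contamCopies = 1e6, nContamOtus = 10L,
                             profiles = NULL) {
  if (length(contaminated) != nKits)
    stop("'contaminated' must have one flag per kit")
  if (cfg@noiseScale <= 0)
    stop("control simulation requires noiseScale > 0 (clean kits have no ",
         "other read source)")
  if (is.null(profiles)) profiles <- lapply(seq_len(nKits), function(k) {
    if (!contaminated[k]) return(NULL)
    nm <- sprintf("Kit%02dContam%02d", k, seq_len(nContamOtus))
    w <- .withSeed(.streamSeed(cfg@seed, k, 0L, 0L),
                   rgamma(nContamOtus, shape = 1))
    stats::setNames(w / sum(w), nm)
  })
  if (length(profiles) != nKits)
    stop("'profiles' must have one entry per kit")
  otus <- unique(c(unlist(lapply(profiles, names), use.names = FALSE),
                   .noiseNames(cfg)))
  rows <- list(); design <- list()
  for (k in seq_len(nKits)) for (r in seq_len(nReplicates)) {
    id <- sprintf("Ctl%02dR%d", k, r)
    v <- .withSeed(.streamSeed(cfg@seed, k, r, 999L),
                   .simReads(cfg, 0, profiles[[k]],
                             if (contaminated[k]) contamCopies else 0,
                             otus))
    # controls carry no biological template, so drop signal-OTU columns
    rows[[id]] <- v[otus]
    design[[id]] <- data.frame(
      sample_id = id, specimen_id = sprintf("ControlKit%02d", k),
      replicate = r, kit = sprintf("CtlKit%02d", k), is_control = TRUE,
      sample_type = "isolation_control", stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- otus
  ReplicateExperiment(counts, do.call(rbind, design))
}

#' Simulate clinical-style specimens of chosen biomass
#'
#' Each specimen is sequenced in \code{n_replicates} technical replicates
#' at its own template copy number, sharing the config's community profile
#' (controls get none). High-copy specimens emulate signal-rich samples
#' (e.g. oral rinses); specimens far below the noise scale emulate
#' ultralow-biomass samples (e.g. exhaled breath condensate), whose reads
#' are mostly per-replicate noise.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param specimens data.frame with columns \code{specimen_id},
#'   \code{sample_type}, \code{copies}, optional \code{n_replicates}
#'   (default 3), \code{is_control} (default FALSE), \code{kit}
#'   (default one kit per specimen) and \code{contam_copies} (default 0).
#' @param contamination optional named contaminant composition shared by
#'   all specimens with \code{contam_copies > 0} (one reagent lot).
#' @return a \linkS4class{ReplicateExperiment} with biomass metadata.
#' @export
simulateSpecimens <- function(cfg, specimens, contamination = NULL) {
  specimens <- as.data.frame(specimens)
  if (!all(c("specimen_id", "sample_type", "copies") %in%
             colnames(specimens)))
    stop("specimens needs columns specimen_id, sample_type, copies")
  if (is.null(specimens$n_replicates)) specimens$n_replicates <- 3L
  if (is.null(specimens$is_control)) specimens$is_control <- FALSE
  if (is.null(specimens$contam_copies)) specimens$contam_copies <- 0
  if (any(specimens$contam_copies > 0) && is.null(contamination))
    stop("contam_copies > 0 requires a contamination profile")
  if (is.null(specimens$kit))
    specimens$kit <- sprintf("Kit%02d", seq_len(nrow(specimens)))
  otus <- .otuNamespace(cfg, if (is.null(contamination)) list()
                        else list(contamination))
  rows <- list(); design <- list()
  biomass <- stats::setNames(specimens$copies, specimens$specimen_id)
  for (i in seq_len(nrow(specimens))) {
    sp <- specimens[i, ]
    for (r in seq_len(sp$n_replicates)) {
      id <- sprintf("%s_r%d", sp$specimen_id, r)
      rows[[id]] <- .withSeed(
        .streamSeed(cfg@seed, i, r, 555L),
        .simReads(cfg, if (sp$is_control) 0 else sp$copies, contamination,
                  sp$contam_copies, otus))
      design[[id]] <- data.frame(
        sample_id = id, specimen_id = sp$specimen_id, replicate = r,
        kit = sp$kit, is_control = sp$is_control,
        sample_type = sp$sample_type, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- otus
  ReplicateExperiment(counts, do.call(rbind, design),
                      biomass = biomass[!specimens$is_control])
}
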