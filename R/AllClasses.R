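#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- colData rowData
NULL

#' Simulation configuration for synthetic capture experiments
#'
#' Parameters of the generative model used by [generateGroundTruth()] and
#' [simulatePeptideReport()]. The model draws a base peptide intensity from a
#' log-normal distribution, multiplies it in capture samples of true binders
#' by \code{enrichmentFold} times the probe-specific affinity (and by the
#' method-N efficiency when capture is run without probe activation), adds
#' multiplicative replicate noise with coefficient of variation
#' \code{cvReplicate}, and censors low intensities through a logistic
#' detection probability on the natural-log intensity.
#'
#' @slot nProteins number of proteins in the catalog.
#' @slot binderFraction proportion of proteins that are true probe binders.
#' @slot enrichmentFold capture/control abundance multiplier for binders
#'   (before the probe-affinity multiplier).
#' @slot probeAffinity named numeric vector of per-probe affinity multipliers
#'   applied to binders, e.g. \code{c(Q8 = 4, Q6 = 1, K8 = 0.25)}.
#' @slot peptidesLambda Poisson rate; peptides per protein are
#'   \code{1 + Poisson(peptidesLambda)}.
#' @slot intensityLocation,intensityScale meanlog and sdlog of the log-normal
#'   base peptide intensity (natural-log scale).
#' @slot binderIntensityShift additive offset (natural-log scale) applied to
#'   binder base intensity; negative values make binders low-abundance so
#'   that they fall below detection in probe-less controls.
#' @slot cvReplicate coefficient of variation of multiplicative replicate
#'   noise.
#' @slot detectionMidpoint,detectionSlope logistic detection parameters on
#'   log intensity; \code{detectionMidpoint = -Inf} disables missingness.
#' @slot methodNEfficiency capture-efficiency multiplier in (0, 1] applied in
#'   capture samples under method N (no oxidative probe activation).
#' @slot nReplicates replicates per sample group.
#' @slot redundancyRate proportion of proteins duplicated under alternative
#'   accessions in the redundant database variant.
#' @slot identityTiers sequence identities at which query-similar sequences
#'   are generated by point mutation.
#' @slot nSimilarPerTier how many binder sequences are generated per identity
#'   tier.
#' @slot seed integer seed making the whole bundle reproducible.
#'
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    nProteins = "integer",
    binderFraction = "numeric",
    enrichmentFold = "numeric",
    probeAffinity = "numeric",
    peptidesLambda = "numeric",
    intensityLocation = "numeric",
    intensityScale = "numeric",
    binderIntensityShift = "numeric",
    cvReplicate = "numeric",
    detectionMidpoint = "numeric",
    detectionSlope = "numeric",
    methodNEfficiency = "numeric",
    nReplicates = "integer",
    redundancyRate = "numeric",
    identityTiers = "numeric",
    nSimilarPerTier = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  bad <- function(field, msg) sprintf("invalid '%s': %s", field, msg)
  msgs <- character()
  if (object@nProteins < 0L)
    msgs <- c(msgs, bad("nProteins", "must be >= 0"))
  if (object@binderFraction < 0 || object@binderFraction > 1)
    msgs <- c(msgs, bad("binderFraction", "must lie in [0, 1]"))
  if (object@enrichmentFold <= 1)
    msgs <- c(msgs, bad("enrichmentFold", "must be > 1"))
  if (length(object@probeAffinity) == 0L || is.null(names(object@probeAffinity)) ||
      any(!nzchar(names(object@probeAffinity))))
    msgs <- c(msgs, bad("probeAffinity", "must be a named numeric vector"))
  if (any(object@probeAffinity <= 0))
    msgs <- c(msgs, bad("probeAffinity", "multipliers must be > 0"))
  if (object@peptidesLambda <= 0)
    msgs <- c(msgs, bad("peptidesLambda", "must be > 0"))
  if (object@intensityScale <= 0)
    msgs <- c(msgs, bad("intensityScale", "must be > 0"))
  if (object@cvReplicate < 0)
    msgs <- c(msgs, bad("cvReplicate", "must be >= 0"))
  if (object@detectionSlope <= 0)
    msgs <- c(msgs, bad("detectionSlope", "must be > 0"))
  if (object@methodNEfficiency <= 0 || object@methodNEfficiency > 1)
    msgs <- c(msgs, bad("methodNEfficiency", "must lie in (0, 1]"))
  if (object@nReplicates < 2L)
    msgs <- c(msgs, bad("nReplicates", "must be >= 2"))
  if (object@redundancyRate < 0 || object@redundancyRate > 1)
    msgs <- c(msgs, bad("redundancyRate", "must lie in [0, 1]"))
  if (any(object@identityTiers <= 0 | object@identityTiers > 1))
    msgs <- c(msgs, bad("identityTiers", "identities must lie in (0, 1]"))
  if (object@nSimilarPerTier < 0L)
    msgs <- c(msgs, bad("nSimilarPerTier", "must be >= 0"))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the reference synthetic experiment: 500 proteins, 10%
#' true binders, 16-fold capture enrichment, triplicates, probe affinities
#' Q8 : Q6 : K8 = 16 : 4 : 1 (so the Q8/Q6 selectivity ratio is 4), 20%
#' replicate CV, and left-censored missingness that keeps the abundant
#' nonspecific background detectable while placing low-abundance binders
#' below detection in probe-less controls.
#'
#' @param nProteins,binderFraction,enrichmentFold,probeAffinity,peptidesLambda
#'   see [SimulationConfig-class].
#' @param intensityLocation,intensityScale,binderIntensityShift,cvReplicate
#'   see [SimulationConfig-class].
#' @param detectionMidpoint,detectionSlope,methodNEfficiency,nReplicates
#'   see [SimulationConfig-class].
#' @param redundancyRate,identityTiers,nSimilarPerTier,seed
#'   see [SimulationConfig-class].
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nProteins = 100, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nProteins = 500L,
                             binderFraction = 0.1,
                             enrichmentFold = 16,
                             probeAffinity = c(Q8 = 4, Q6 = 1, K8 = 0.25),
                             peptidesLambda = 6,
                             intensityLocation = 14,
                             intensityScale = 1.0,
                             binderIntensityShift = -3,
                             cvReplicate = 0.2,
                             detectionMidpoint = 14,
                             detectionSlope = 8,
                             methodNEfficiency = 0.5,
                             nReplicates = 3L,
                             redundancyRate = 0,
                             identityTiers = c(0.9, 0.6, 0.3),
                             nSimilarPerTier = 2L,
                             seed = 1L) {
  new("SimulationConfig",
    nProteins = as.integer(nProteins),
    binderFraction = as.numeric(binderFraction),
    enrichmentFold = as.numeric(enrichmentFold),
    probeAffinity = probeAffinity,
    peptidesLambda = as.numeric(peptidesLambda),
    intensityLocation = as.numeric(intensityLocation),
    intensityScale = as.numeric(intensityScale),
    binderIntensityShift = as.numeric(binderIntensityShift),
    cvReplicate = as.numeric(cvReplicate),
    detectionMidpoint = as.numeric(detectionMidpoint),
    detectionSlope = as.numeric(detectionSlope),
    methodNEfficiency = as.numeric(methodNEfficiency),
    nReplicates = as.integer(nReplicates),
    redundancyRate = as.numeric(redundancyRate),
    identityTiers = as.numeric(identityTiers),
    nSimilarPerTier = as.integer(nSimilarPerTier),
    seed = as.integer(seed)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nProteins, "proteins,",
      sprintf("%.0f%% binders,", 100 * object@binderFraction),
      "enrichment fold", object@enrichmentFold, "\n")
  cat("  probe affinities:",
      paste(names(object@probeAffinity), object@probeAffinity,
            sep = "=", collapse = ", "), "\n")
  cat("  replicates:", object@nReplicates,
      " CV:", object@cvReplicate,
      " detection midpoint/slope:", object@detectionMidpoint, "/",
      object@detectionSlope, " seed:", object@seed, "\n")
})

#' Ground truth of a synthetic capture experiment
#'
#' Holds the simulated protein catalog (accession, sequence, binder flag,
#' per-probe affinity, annotation category, identity to the hydroxylase-like
#' query sequence), the duplicate-accession map of the redundant database
#' variant, the query sequence itself, and an echo of the generating
#' configuration.
#'
#' @slot catalog data.frame with one row per canonical protein.
#' @slot duplicateMap data.frame mapping each duplicate accession to exactly
#'   one canonical accession.
#' @slot querySequence named character: the amino-acid query sequence that
#'   similarity tiers were generated against.
#' @slot config the [SimulationConfig-class] used.
#' @seealso [generateGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    catalog = "data.frame",
    duplicateMap = "data.frame",
    querySequence = "character",
    config = "SimulationConfig"
  )
)

setValidity("GroundTruth", function(object) {
  msgs <- character()
  need <- c("accession", "is_binder", "category", "sequence", "identity_to_query")
  miss <- setdiff(need, names(object@catalog))
  if (length(miss))
    msgs <- c(msgs, paste("catalog lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(object@duplicateMap)) {
    if (!all(c("duplicate_accession", "canonical_accession") %in% names(object@duplicateMap)))
      msgs <- c(msgs, "duplicateMap needs duplicate_accession and canonical_accession")
    else if (anyDuplicated(object@duplicateMap$duplicate_accession))
      msgs <- c(msgs, "each duplicate accession must map to exactly one canonical accession")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@catalog), "proteins (",
      sum(object@catalog$is_binder), "binders ),",
      nrow(object@duplicateMap), "duplicate accessions\n")
})

#' Container for a normalized protein-by-sample capture experiment
#'
#' Extends \linkS4class{SummarizedExperiment} with two mandatory assays:
#' \code{"abundance"} (protein abundance per sample, \code{NA} = not
#' detected, a state distinct from zero) and \code{"npep"} (unique-peptide
#' count per protein and sample). Column data carries the sample design
#' (\code{species}, \code{probe}, \code{method}, \code{replicate});
#' probe \code{"none"} marks probe-less negative controls.
#'
#' @seealso [aggregateAbundance()], [normalizeAbundance()],
#'   [filterMinPeptides()]
#' @export
setClass("CaptureExperiment", contains = "SummarizedExperiment")

setValidity("CaptureExperiment", function(object) {
  msgs <- character()
  if (!all(c("abundance", "npep") %in% names(assays(object))))
    msgs <- c(msgs, "assays must include 'abundance' and 'npep'")
  need <- c("species", "probe", "method", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msgs <- c(msgs, paste("colData lacks columns:", paste(miss, collapse = ", ")))
  if ("abundance" %in% names(assays(object))) {
    ab <- assay(object, "abundance")
    if (any(ab < 0, na.rm = TRUE))
      msgs <- c(msgs, "abundances must be non-negative")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "CaptureExperiment", function(object) {
  callNextMethod()
  cat("normalized:", isNormalized(object), "\n")
})

#' Significance thresholds for capture classification
#'
#' Encodes the tiered capture-significance rule: a protein passing the
#' reproducibility filter is \emph{highly significant} when it is absent
#' from all probe-less control replicates, or when log2 fold change exceeds
#' \code{log2RMin} and -log10(p) exceeds \code{negLogPMin} (both strictly);
#' otherwise it is \emph{significant} when p < \code{pMax}, else merely
#' \emph{detected}.
#'
#' @slot pMax ANOVA p-value gate for the "significant" tier (default 0.05).
#' @slot log2RMin strict lower bound on log2 fold change for the enriched
#'   highly-significant branch (default 2).
#' @slot negLogPMin strict lower bound on -log10(p) for the enriched
#'   highly-significant branch (default 2.5).
#' @slot minReplicatesDetected capture replicates required for a protein to
#'   count as reproducibly captured (default 2 of 3).
#' @slot maxControlDetected maximum control replicates in which a protein may
#'   appear and still qualify as "not present in the negative control"
#'   (default 0, the literal reading).
#' @seealso [classifyCapture()], [significanceThresholds()]
#' @export
setClass("SignificanceThresholds",
  representation(
    pMax = "numeric",
    log2RMin = "numeric",
    negLogPMin = "numeric",
    minReplicatesDetected = "integer",
    maxControlDetected = "integer"
  )
)

setValidity("SignificanceThresholds", function(object) {
  msgs <- character()
  if (object@pMax <= 0 || object@pMax > 1)
    msgs <- c(msgs, "invalid 'pMax': must lie in (0, 1]")
  if (object@log2RMin <= 0)
    msgs <- c(msgs, "invalid 'log2RMin': must be > 0")
  if (object@negLogPMin <= 0)
    msgs <- c(msgs, "invalid 'negLogPMin': must be > 0")
  if (object@minReplicatesDetected < 1L)
    msgs <- c(msgs, "invalid 'minReplicatesDetected': must be >= 1")
  if (object@maxControlDetected < 0L)
    msgs <- c(msgs, "invalid 'maxControlDetected': must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname SignificanceThresholds-class
#' @param pMax,log2RMin,negLogPMin,minReplicatesDetected,maxControlDetected
#'   see slots above.
#' @return a validated [SignificanceThresholds-class] object.
#' @examples
#' significanceThresholds()
#' @export
significanceThresholds <- function(pMax = 0.05, log2RMin = 2, negLogPMin = 2.5,
                                   minReplicatesDetected = 2L,
                                   maxControlDetected = 0L) {
  new("SignificanceThresholds",
    pMax = as.numeric(pMax),
    log2RMin = as.numeric(log2RMin),
    negLogPMin = as.numeric(negLogPMin),
    minReplicatesDetected = as.integer(minReplicatesDetected),
    maxControlDetected = as.integer(maxControlDetected)
  )
}

setMethod("show", "SignificanceThresholds", function(object) {
  cat("SignificanceThresholds: p <", object@pMax,
      "| highly significant: log2(r) >", object@log2RMin,
      "and -log10(p) >", object@negLogPMin, "\n")
  cat("  reproducibility: >=", object@minReplicatesDetected,
      "capture replicates; control absence: <=",
      object@maxControlDetected, "control replicates\n")
})

#' Local-alignment scoring scheme
#'
#' Substitution matrix and affine gap penalties used by [localAlign()] and
#' [searchDatabase()]. Defaults match protein BLAST (BLOSUM62, gap open 11,
#' gap extend 1; a gap of length L costs open + L * extend).
#'
#' @slot matrixName name of a substitution matrix shipped with Biostrings.
#' @slot gapOpen,gapExtend positive gap penalties.
#' @seealso [scoringScheme()]
#' @export
setClass("ScoringScheme",
  representation(matrixName = "character", gapOpen = "numeric", gapExtend = "numeric")
)

setValidity("ScoringScheme", function(object) {
  msgs <- character()
  if (object@gapOpen <= 0) msgs <- c(msgs, "invalid 'gapOpen': must be > 0")
  if (object@gapExtend <= 0) msgs <- c(msgs, "invalid 'gapExtend': must be > 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname ScoringScheme-class
#' @param matrixName,gapOpen,gapExtend see slots above.
#' @return a validated [ScoringScheme-class] object.
#' @examples
#' scoringScheme()
#' @export
scoringScheme <- function(matrixName = "BLOSUM62", gapOpen = 11, gapExtend = 1) {
  new("ScoringScheme", matrixName = matrixName,
      gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend))
}

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme:", object@matrixName,
      "gap open/extend:", object@gapOpen, "/", object@gapExtend, "\n")
})
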