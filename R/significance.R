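captureClassLevels <- c("not_detected", "detected", "significant",
                        "highly_significant_enriched",
                        "highly_significant_absent_control")

#' Classify capture significance of proteins
#'
#' Implements the tiered capture call for one contrast (capture vs
#' probe-less control). The classes, mutually exclusive and exhaustive,
#' are, in order of precedence:
#' \enumerate{
#'   \item \code{not_detected} — captured in fewer than
#'     \code{minReplicatesDetected} capture replicates (fails the
#'     replicate-reproducibility filter);
#'   \item \code{highly_significant_absent_control} — reproducibly
#'     captured and present in at most \code{maxControlDetected} (default
#'     zero) control replicates;
#'   \item \code{highly_significant_enriched} — \code{log2(r) >
#'     log2RMin} and \code{-log10(p) > negLogPMin} (both strict);
#'   \item \code{significant} — \code{p < pMax};
#'   \item \code{detected} — everything else, including undefined r or p.
#' }
#'
#' @param r fold change(s) capture/control (\code{NA} when undefined).
#' @param p ANOVA p-value(s) (\code{NA} when undefined).
#' @param nDetectedCapture,nDetectedControl replicate detection counts.
#' @param thresholds a [SignificanceThresholds-class].
#' @return factor of capture classes with levels
#'   \code{not_detected < detected < significant <
#'   highly_significant_enriched < highly_significant_absent_control}.
#' @examples
#' classifyCapture(r = 16, p = 0.001, nDetectedCapture = 3,
#'                 nDetectedControl = 3)
#' classifyCapture(r = NA, p = NA, nDetectedCapture = 3,
#'                 nDetectedControl = 0)
#' @export
classifyCapture <- function(r, p, nDetectedCapture, nDetectedControl,
                            thresholds = significanceThresholds()) {
  validObject(thresholds)
  n <- max(length(r), length(p), length(nDetectedCapture), length(nDetectedControl))
  r <- rep_len(as.numeric(r), n)
  p <- rep_len(as.numeric(p), n)
  nDetectedCapture <- rep_len(nDetectedCapture, n)
  nDetectedControl <- rep_len(nDetectedControl, n)

  cls <- rep("detected", n)
  defined <- !is.na(r) & !is.na(p) & r > 0
  enriched <- defined & log2(r) > thresholds@log2RMin &
    -log10(p) > thresholds@negLogPMin
  sig <- !is.na(p) & p < thresholds@pMax
  cls[sig] <- "significant"
  cls[enriched] <- "highly_significant_enriched"
  cls[nDetectedControl <= thresholds@maxControlDetected] <-
    "highly_significant_absent_control"
  cls[nDetectedCapture < thresholds@minReplicatesDetected] <- "not_detected"
  factor(cls, levels = captureClassLevels, ordered = TRUE)
}

#' Replicate-reproducibility filter
#'
#' Retains proteins captured in at least \code{minReplicatesDetected}
#' capture replicates; everything else is considered not reproducibly
#' captured in that assay.
#'
#' @param stats a capture-statistics data.frame with columns
#'   \code{accession} and \code{n_detected_capture} (as from
#'   [captureStats()]).
#' @param minReplicatesDetected required capture replicate detections.
#' @param nReplicates total capture replicates in the assay; used to reject
#'   unsatisfiable thresholds.
#' @return character vector of retained accessions.
#' @export
reproducibilityFilter <- function(stats, minReplicatesDetected = 2L,
                                  nReplicates = max(stats$n_detected_capture, 0L)) {
  stopIfMissingColumns(stats, c("accession", "n_detected_capture"),
                       "capture statistics")
  if (minReplicatesDetected > nReplicates)
    stop(sprintf(paste0("invalid 'minReplicatesDetected': %d exceeds the ",
                        "number of capture replicates (%d)"),
                 minReplicatesDetected, nReplicates), call. = FALSE)
  stats$accession[stats$n_detected_capture >= minReplicatesDetected]
}

#' Full capture statistics for one assay
#'
#' Computes, for every protein of a normalized experiment, the grouped
#' fold change r of capture vs probe-less control, the one-way ANOVA
#' p-value on log2 abundances, replicate detection counts, derived
#' \code{log2_r} / \code{neg_log10_p}, and the capture class.
#'
#' @param ce a normalized [CaptureExperiment-class].
#' @param captureSamples,controlSamples character vectors of sample ids.
#' @param thresholds a [SignificanceThresholds-class].
#' @param label contrast label stored in the result.
#' @param groupFun grouping statistic for the fold change ("mean" or
#'   "median").
#' @param log2Transform compute the ANOVA on log2 abundances (default).
#' @return data.frame with one row per protein: \code{accession},
#'   \code{contrast}, \code{r}, \code{flag}, \code{p}, \code{log2_r},
#'   \code{neg_log10_p}, \code{n_detected_capture},
#'   \code{n_detected_control}, \code{capture_class}.
#' @examples
#' cfg <- simulationConfig(nProteins = 60, seed = 3)
#' truth <- generateGroundTruth(cfg)
#' design <- captureDesign(probes = "Q8")
#' ce <- normalizeAbundance(filterMinPeptides(
#'   aggregateAbundance(simulatePeptideReport(truth, design), design)))
#' st <- captureStats(ce,
#'   captureSamples = design$sample_id[design$probe == "Q8"],
#'   controlSamples = design$sample_id[design$probe == "none"])
#' table(st$capture_class)
#' @export
captureStats <- function(ce, captureSamples, controlSamples,
                         thresholds = significanceThresholds(),
                         label = "capture_vs_control",
                         groupFun = "mean", log2Transform = TRUE) {
  rat <- groupRatio(ce, captureSamples, controlSamples, groupFun = groupFun)
  p <- anovaPvalue(ce, list(capture = captureSamples, control = controlSamples),
                   log2Transform = log2Transform)
  out <- data.frame(
    accession = rat$accession,
    contrast = label,
    r = rat$r,
    flag = rat$flag,
    p = as.numeric(p[rat$accession]),
    stringsAsFactors = FALSE
  )
  out$log2_r <- ifelse(!is.na(out$r) & out$r > 0, log2(out$r), NA_real_)
  out$neg_log10_p <- ifelse(!is.na(out$p), -log10(out$p), NA_real_)
  out$n_detected_capture <- rat$n_detected_num
  out$n_detected_control <- rat$n_detected_den
  out$capture_class <- classifyCapture(out$r, out$p,
                                       out$n_detected_capture,
                                       out$n_detected_control,
                                       thresholds)
  out
}

#' Count capture classes per assay
#'
#' Tabulates the capture classes of one or several assays; the
#' highly-significant total is the sum of the absent-in-control and
#' enriched branches.
#'
#' @param statsList named list of capture-statistics data.frames (one per
#'   assay, names like \code{"Rudbeckia.Q8.O"}).
#' @return data.frame with one row per assay: per-class counts,
#'   \code{highly_significant} total and \code{evaluated} (row total).
#' @export
summarizeAssay <- function(statsList) {
  if (is.null(names(statsList)) || any(!nzchar(names(statsList))))
    stop("statsList must be a named list", call. = FALSE)
  rows <- lapply(names(statsList), function(nm) {
    st <- statsList[[nm]]
    counts <- table(factor(st$capture_class, levels = captureClassLevels))
    data.frame(assay = nm, as.list(counts),
               highly_significant = sum(counts[c("highly_significant_enriched",
                                                 "highly_significant_absent_control")]),
               evaluated = sum(counts),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accessions called highly significant in a stats table
#'
#' @param stats a capture-statistics data.frame from [captureStats()].
#' @return character vector of accessions in either highly-significant
#'   branch.
#' @export
highlySignificant <- function(stats) {
  stats$accession[stats$capture_class %in%
                    c("highly_significant_enriched",
                      "highly_significant_absent_control")]
}
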