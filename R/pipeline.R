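#' Pipeline configuration
#'
#' Bundles everything [runPipeline()] needs. Exactly one input mode is
#' active: \emph{simulation mode} (a [SimulationConfig-class] in
#' \code{simulation}; all inputs are generated) or \emph{file mode}
#' (paths to a peptide report and design, with optional annotation,
#' homologue-map, FASTA and BLAST-tabular files; stages whose inputs are
#' absent are skipped and recorded in the manifest).
#'
#' @param simulation a [SimulationConfig-class], or \code{NULL} for file
#'   mode.
#' @param peptideReport,design,annotations,homologueMap,fasta,queryFasta,blast
#'   input file paths (file mode; \code{design} may also be a data.frame).
#' @param thresholds a [SignificanceThresholds-class].
#' @param minPeptides minimum unique peptides per protein (default 2).
#' @param groupFun replicate grouping statistic, "mean" or "median".
#' @param log2Transform ANOVA on log2 abundances (default TRUE).
#' @param selectivityProbes the two probes contrasted in the selectivity
#'   volcano.
#' @param scheme a [ScoringScheme-class] for in-package alignment.
#' @param reportFloor,highCut,lowCut alignment score floor and tier cuts.
#' @param outDir output directory for the report bundle.
#' @param seed integer seed; in simulation mode it overrides the seed
#'   stored in \code{simulation}.
#' @param stages stages to run after quantification/significance.
#' @return a validated \code{pipelineConfig} list.
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(simulation = NULL,
                           peptideReport = NULL, design = NULL,
                           annotations = NULL, homologueMap = NULL,
                           fasta = NULL, queryFasta = NULL, blast = NULL,
                           thresholds = significanceThresholds(),
                           minPeptides = 2L,
                           groupFun = "mean", log2Transform = TRUE,
                           selectivityProbes = c("Q8", "Q6"),
                           scheme = scoringScheme(),
                           reportFloor = 50, highCut = 500, lowCut = 300,
                           outDir = tempfile("capture_run_"),
                           seed = NULL,
                           stages = c("comparison", "annotation", "shortlist")) {
  simMode <- !is.null(simulation)
  if (simMode && !is.null(peptideReport))
    stop("exactly one of simulation mode and file mode must be active",
         call. = FALSE)
  if (!simMode && is.null(peptideReport))
    stop("file mode requires a peptide report path", call. = FALSE)
  if (!simMode && is.null(design))
    stop("file mode requires a design", call. = FALSE)
  if (simMode) validObject(simulation)
  validObject(thresholds)
  validObject(scheme)
  if (length(selectivityProbes) != 2L)
    stop("selectivityProbes must name exactly two probes", call. = FALSE)
  structure(list(
    simulation = simulation, peptideReport = peptideReport, design = design,
    annotations = annotations, homologueMap = homologueMap,
    fasta = fasta, queryFasta = queryFasta, blast = blast,
    thresholds = thresholds, minPeptides = as.integer(minPeptides),
    groupFun = groupFun, log2Transform = isTRUE(log2Transform),
    selectivityProbes = selectivityProbes,
    scheme = scheme, reportFloor = reportFloor,
    highCut = highCut, lowCut = lowCut,
    outDir = outDir, seed = if (is.null(seed)) NULL else as.integer(seed),
    stages = stages
  ), class = "pipelineConfig")
}

stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full capture-analysis pipeline
#'
#' Executes quantification (peptide aggregation, minimum-peptide filter,
#' total-amount normalization), capture-significance classification per
#' assay, probe/method set comparisons and probe selectivity, the
#' annotation screen with GO enrichment, and similarity shortlisting, then
#' writes a report bundle of TSV files plus a JSON manifest to
#' \code{config$outDir}. Identical configuration and seed produce a
#' byte-identical bundle.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list of class \code{captureReportBundle}:
#'   \code{files} (named paths), \code{manifest}, and the in-memory
#'   results (\code{experiment}, \code{stats}, \code{summary},
#'   \code{venn}, \code{selectivity}, \code{heatmap}, \code{enrichment},
#'   \code{shortlist}).
#' @examples
#' cfg <- pipelineConfig(simulation = simulationConfig(nProteins = 80),
#'                       outDir = tempfile())
#' bundle <- runPipeline(cfg)
#' bundle$summary
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  skipped <- character()
  emit <- function(name, x, fname) {
    p <- file.path(config$outDir, fname)
    writeTsv(x, p)
    files[[name]] <<- p
    p
  }

  # ---- inputs -------------------------------------------------------------
  simMode <- !is.null(config$simulation)
  if (simMode) {
    sim <- config$simulation
    if (!is.null(config$seed)) sim@seed <- config$seed
    truth <- stageError("simulate", generateGroundTruth(sim))
    design <- captureDesign(probes = names(sim@probeAffinity),
                            nReplicates = sim@nReplicates)
    peptides <- stageError("simulate",
                           simulatePeptideReport(truth, design, sim))
    annotations <- simulateAnnotations(truth)
    homologueMap <- NULL
    sequences <- stats::setNames(truth@catalog$sequence, truth@catalog$accession)
    queries <- querySequence(truth)
  } else {
    peptides <- stageError("read", readPeptideReport(config$peptideReport))
    design <- if (is.data.frame(config$design)) config$design else
      readDesign(config$design)
    validateDesign(design)
    annotations <- if (is.null(config$annotations)) NULL else
      readAnnotations(config$annotations)
    homologueMap <- if (is.null(config$homologueMap)) NULL else
      readHomologueMap(config$homologueMap)
    sequences <- if (is.null(config$fasta)) NULL else
      readProteinFasta(config$fasta)
    queries <- if (is.null(config$queryFasta)) NULL else
      readProteinFasta(config$queryFasta)
  }

  # ---- quantification -----------------------------------------------------
  ce <- stageError("quantification", {
    raw <- aggregateAbundance(peptides, design)
    normalizeAbundance(filterMinPeptides(raw, config$minPeptides))
  })
  files[["abundance"]] <- file.path(config$outDir, "abundance_matrix.tsv")
  writeAbundanceTsv(ce, files[["abundance"]])

  # ---- significance -------------------------------------------------------
  cd <- as.data.frame(colData(ce))
  cd$sample_id <- rownames(cd)
  assayKeys <- unique(cd[cd$probe != "none", c("species", "probe", "method")])
  statsList <- stageError("significance", {
    out <- list()
    for (i in seq_len(nrow(assayKeys))) {
      sp <- assayKeys$species[i]; pr <- assayKeys$probe[i]; me <- assayKeys$method[i]
      cap <- cd$sample_id[cd$species == sp & cd$probe == pr & cd$method == me]
      ctl <- cd$sample_id[cd$species == sp & cd$probe == "none"]
      if (!length(ctl))
        stop("no probe-less control samples for species ", sp)
      nm <- paste(sp, pr, me, sep = ".")
      out[[nm]] <- captureStats(ce, cap, ctl, thresholds = config$thresholds,
                                label = nm, groupFun = config$groupFun,
                                log2Transform = config$log2Transform)
    }
    out
  })
  classification <- do.call(rbind, lapply(statsList, function(st) st))
  rownames(classification) <- NULL
  emit("classification", classification, "classification.tsv")
  summaryTab <- summarizeAssay(statsList)
  emit("summary", summaryTab, "counts_summary.tsv")

  # ---- comparison ---------------------------------------------------------
  venn <- selectivity <- NULL
  if ("comparison" %in% config$stages) {
    stageError("comparison", {
      sp1 <- assayKeys$species[1L]
      me1 <- assayKeys$method[1L]
      probes <- unique(assayKeys$probe[assayKeys$species == sp1 &
                                         assayKeys$method == me1])
      hsSets <- lapply(probes, function(pr)
        highlySignificant(statsList[[paste(sp1, pr, me1, sep = ".")]]))
      names(hsSets) <- probes
      if (length(hsSets) >= 2L) {
        venn <- setOverlap(hsSets[seq_len(min(3L, length(hsSets)))])
        emit("venn", venn, "venn_counts.tsv")
      }
      pa <- config$selectivityProbes[1L]; pb <- config$selectivityProbes[2L]
      if (all(c(pa, pb) %in% probes)) {
        stA <- statsList[[paste(sp1, pa, me1, sep = ".")]]
        stB <- statsList[[paste(sp1, pb, me1, sep = ".")]]
        eligible <- intersect(
          highlySignificant(stA)[stA$n_detected_control[
            match(highlySignificant(stA), stA$accession)] <=
              config$thresholds@maxControlDetected],
          highlySignificant(stB)[stB$n_detected_control[
            match(highlySignificant(stB), stB$accession)] <=
              config$thresholds@maxControlDetected])
        selA <- cd$sample_id[cd$species == sp1 & cd$probe == pa & cd$method == me1]
        selB <- cd$sample_id[cd$species == sp1 & cd$probe == pb & cd$method == me1]
        selectivity <- probeSelectivity(ce, selA, selB, eligible,
                                         pMax = config$thresholds@pMax)
        emit("selectivity", selectivity, "selectivity.tsv")
      }
    })
  } else skipped <- c(skipped, "comparison")

  # ---- annotation screen --------------------------------------------------
  heatmap <- enrichment <- NULL
  if ("annotation" %in% config$stages && !is.null(annotations)) {
    stageError("annotation", {
      heatmap <- buildHeatmapTable(statsList, annotations, homologueMap)
      emit("heatmap", heatmap, "heatmap_long.tsv")
      background <- rownames(ce)
      firstAssay <- statsList[[1L]]
      target <- firstAssay$accession[
        firstAssay$capture_class >= "significant" &
          firstAssay$accession %in% background]
      enrichment <- goEnrichment(target, background, annotations)
      emit("enrichment", enrichment, "go_enrichment.tsv")
    })
  } else skipped <- c(skipped, "annotation")

  # ---- similarity shortlist ----------------------------------------------
  shortlist <- NULL
  if ("shortlist" %in% config$stages &&
      (!is.null(config$blast) || (!is.null(sequences) && !is.null(queries)))) {
    stageError("shortlist", {
      hits <- if (!is.null(config$blast))
        parseBlastTabular(config$blast, highCut = config$highCut,
                          lowCut = config$lowCut)
      else
        searchDatabase(queries, sequences, scheme = config$scheme,
                       reportFloor = config$reportFloor,
                       highCut = config$highCut, lowCut = config$lowCut)
      shortlist <- crossrefShortlist(hits, classification)
      emit("shortlist", shortlist$shortlist, "shortlist.tsv")
      emit("shortlist_side_hits", shortlist$hitsWithoutCapture,
           "hits_without_capture.tsv")
      emit("shortlist_side_captures", shortlist$capturesWithoutHit,
           "captures_without_hit.tsv")
    })
  } else skipped <- c(skipped, "shortlist")

  # ---- manifest -----------------------------------------------------------
  rowCounts <- vapply(files, function(p) length(readLines(p)) - 1L, integer(1))
  manifest <- list(
    package = "probeCapture",
    version = as.character(utils::packageVersion("probeCapture")),
    mode = if (simMode) "simulation" else "file",
    seed = if (simMode) config$simulation@seed else config$seed,
    effective_seed = if (simMode && !is.null(config$seed)) config$seed else NULL,
    n_samples = ncol(ce), n_proteins = nrow(ce),
    thresholds = list(pMax = config$thresholds@pMax,
                      log2RMin = config$thresholds@log2RMin,
                      negLogPMin = config$thresholds@negLogPMin,
                      minReplicatesDetected = config$thresholds@minReplicatesDetected,
                      maxControlDetected = config$thresholds@maxControlDetected),
    min_peptides = config$minPeptides,
    skipped_stages = as.list(skipped),
    files = as.list(stats::setNames(basename(unlist(files)), names(files))),
    row_counts = as.list(rowCounts)
  )
  manifestPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  files[["manifest"]] <- manifestPath

  invisible(structure(list(
    files = unlist(files), manifest = manifest,
    experiment = ce, stats = statsList, summary = summaryTab,
    venn = venn, selectivity = selectivity, heatmap = heatmap,
    enrichment = enrichment, shortlist = shortlist
  ), class = "captureReportBundle"))
}

#' @export
print.captureReportBundle <- function(x, ...) {
  cat("captureReportBundle:", x$manifest$n_proteins, "proteins x",
      x$manifest$n_samples, "samples (mode:", x$manifest$mode, ")\n")
  cat("  outputs:\n")
  for (nm in names(x$files))
    cat(sprintf("    %-22s %s\n", nm, basename(x$files[[nm]])))
  if (length(x$manifest$skipped_stages))
    cat("  skipped stages:",
        paste(unlist(x$manifest$skipped_stages), collapse = ", "), "\n")
  invisible(x)
}
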