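#' Build a capture-assay sample design
#'
#' One row per sample: every probe/method combination plus one probe-less
#' negative control group (probe \code{"none"}) per species, each in
#' \code{nReplicates} replicates. Probe-less controls receive vehicle
#' instead of probe, so proteins retrieved there represent nonspecific
#' bead binding.
#'
#' @param species species label(s).
#' @param probes probe identifiers with configured affinities.
#' @param methods capture methods: \code{"O"} (oxidative probe activation)
#'   and/or \code{"N"} (no activation).
#' @param nReplicates replicates per group.
#' @return data.frame with columns \code{species}, \code{probe},
#'   \code{method}, \code{replicate}, \code{sample_id}.
#' @examples
#' captureDesign(probes = c("Q8", "Q6"))
#' @export
captureDesign <- function(species = "Rudbeckia", probes = c("Q8", "Q6", "K8"),
                          methods = "O", nReplicates = 3L) {
  groups <- do.call(rbind, c(
    lapply(species, function(sp)
      expand.grid(species = sp, probe = probes, method = methods,
                  stringsAsFactors = FALSE)),
    lapply(species, function(sp)
      data.frame(species = sp, probe = "none", method = "O"))
  ))
  attr(groups, "out.attrs") <- NULL
  design <- groups[rep(seq_len(nrow(groups)), each = nReplicates), ]
  design$replicate <- rep(seq_len(nReplicates), times = nrow(groups))
  design$sample_id <- paste(design$species, design$probe, design$method,
                            design$replicate, sep = "_")
  rownames(design) <- NULL
  design
}

#' Generate the ground truth of a synthetic capture experiment
#'
#' Draws a protein catalog under \code{config}: binder flags
#' (\code{round(binderFraction * nProteins)} binders), annotation categories
#' (binders lean toward oxidase/methyltransferase/glycosyltransferase
#' classes, background proteins toward housekeeping functions), amino-acid
#' sequences, and a duplicate-accession map for the redundant database
#' variant. A hydroxylase-like query sequence is generated, and
#' \code{nSimilarPerTier} binders plus \code{nSimilarPerTier} non-binders
#' receive sequences point-mutated from it at each identity tier, so that
#' similarity-score tiers exist among both captured and uncaptured proteins.
#'
#' Deterministic for a fixed \code{config@seed}.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruth-class].
#' @examples
#' truth <- generateGroundTruth(simulationConfig(nProteins = 50, seed = 7))
#' head(truthCatalog(truth))
#' @export
generateGroundTruth <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    n <- config@nProteins
    accession <- sprintf("PROT%04d", seq_len(n))
    nBinders <- round(config@binderFraction * n)
    isBinder <- rep(FALSE, n)
    if (nBinders > 0) isBinder[sample(n, nBinders)] <- TRUE

    cats <- c("A_oxidase", "B_methyltransferase", "C_glycosyltransferase", "D_other")
    category <- character(n)
    if (any(isBinder))
      category[isBinder] <- sample(cats, sum(isBinder), replace = TRUE,
                                   prob = c(0.45, 0.2, 0.2, 0.15))
    if (any(!isBinder))
      category[!isBinder] <- sample(cats, sum(!isBinder), replace = TRUE,
                                    prob = c(0.08, 0.05, 0.05, 0.82))

    query <- randomAASeq(300L)
    sequence <- vapply(seq_len(n),
                       function(i) randomAASeq(sample(200:400, 1L)),
                       character(1))
    identityToQuery <- rep(NA_real_, n)
    for (tier in config@identityTiers) {
      for (pool in list(which(isBinder & is.na(identityToQuery)),
                        which(!isBinder & is.na(identityToQuery)))) {
        take <- utils::head(pool, 0L)
        if (length(pool) && config@nSimilarPerTier > 0L)
          take <- pool[sample.int(length(pool),
                                  min(config@nSimilarPerTier, length(pool)))]
        for (i in take) {
          sequence[i] <- mutateToIdentity(query, tier)
          identityToQuery[i] <- tier
        }
      }
    }

    affinity <- matrix(NA_real_, n, length(config@probeAffinity),
                       dimnames = list(NULL, paste0("affinity_", names(config@probeAffinity))))
    for (j in seq_along(config@probeAffinity))
      affinity[isBinder, j] <- config@probeAffinity[[j]]

    catalog <- data.frame(accession = accession, is_binder = isBinder,
                          category = category, sequence = sequence,
                          identity_to_query = identityToQuery,
                          stringsAsFactors = FALSE)
    catalog <- cbind(catalog, as.data.frame(affinity))

    nDup <- round(config@redundancyRate * n)
    duplicateMap <- data.frame(duplicate_accession = character(),
                               canonical_accession = character(),
                               stringsAsFactors = FALSE)
    if (nDup > 0) {
      dupIdx <- sort(sample(n, nDup))
      duplicateMap <- data.frame(
        duplicate_accession = paste0(accession[dupIdx], "_ALT"),
        canonical_accession = accession[dupIdx],
        stringsAsFactors = FALSE
      )
    }

    new("GroundTruth", catalog = catalog, duplicateMap = duplicateMap,
        querySequence = c(QUERY_F6H = query), config = config)
  })
}

#' Simulate a peptide-level label-free intensity report
#'
#' For each protein, \code{1 + Poisson(peptidesLambda)} tryptic-like
#' peptides are drawn with log-normal base intensities (binders offset by
#' \code{binderIntensityShift} on the natural-log scale). In capture
#' samples the intensity is multiplied by the capture efficiency of the
#' method (1 for O, \code{methodNEfficiency} for N) and, for binders, by
#' \code{enrichmentFold} times the probe affinity. Multiplicative replicate
#' noise with coefficient of variation \code{cvReplicate} is applied, and
#' each peptide observation survives with logistic probability
#' \code{plogis(detectionSlope * (log(I) - detectionMidpoint))} — rows
#' below detection are absent from the report (left-censoring), never zero.
#'
#' With the redundant database variant, peptides of duplicated proteins are
#' reported against both accessions (\code{"ACC;ACC_ALT"}), emulating
#' shared peptides caused by redundant database entries.
#'
#' @param truth a [GroundTruth-class].
#' @param design a sample design as from [captureDesign()].
#' @param config a [SimulationConfig-class]; defaults to the one stored in
#'   \code{truth}.
#' @param redundant report duplicated proteins under both accessions?
#' @param seed RNG seed; defaults to \code{config@seed + 1} so that truth
#'   and report draws are independent but jointly reproducible.
#' @return data.frame with columns \code{peptide_id},
#'   \code{peptide_sequence}, \code{protein_accession}, \code{sample_id},
#'   \code{intensity}.
#' @examples
#' truth <- generateGroundTruth(simulationConfig(nProteins = 20, seed = 1))
#' rep <- simulatePeptideReport(truth, captureDesign(probes = "Q8"))
#' head(rep)
#' @export
simulatePeptideReport <- function(truth, design, config = truth@config,
                                  redundant = FALSE, seed = config@seed + 1L) {
  stopIfMissingColumns(design, c("species", "probe", "method", "replicate", "sample_id"),
                       "design")
  probesUsed <- setdiff(unique(design$probe), "none")
  unknown <- setdiff(probesUsed, names(config@probeAffinity))
  if (length(unknown))
    stop("design references probe(s) without a configured affinity: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  catalog <- truth@catalog
  if (nrow(catalog) == 0L)
    return(data.frame(peptide_id = character(), peptide_sequence = character(),
                      protein_accession = character(), sample_id = character(),
                      intensity = numeric(), stringsAsFactors = FALSE))

  withSeed(seed, {
    nPep <- 1L + stats::rpois(nrow(catalog), config@peptidesLambda)
    protIdx <- rep(seq_len(nrow(catalog)), nPep)
    pepSeq <- vapply(seq_along(protIdx), function(i)
      paste0(randomAASeq(sample(7:19, 1L)), sample(c("K", "R"), 1L)),
      character(1))
    pepId <- sprintf("%s_pep%02d", catalog$accession[protIdx],
                     sequence(nPep))
    baseMu <- stats::rnorm(length(protIdx),
                           mean = config@intensityLocation +
                             ifelse(catalog$is_binder[protIdx],
                                    config@binderIntensityShift, 0),
                           sd = config@intensityScale)

    sdRep <- sqrt(log(1 + config@cvReplicate^2))
    accOut <- catalog$accession
    if (redundant && nrow(truth@duplicateMap)) {
      m <- match(accOut, truth@duplicateMap$canonical_accession)
      accOut <- ifelse(is.na(m), accOut,
                       paste(accOut, truth@duplicateMap$duplicate_accession[m], sep = ";"))
    }

    out <- vector("list", nrow(design))
    for (s in seq_len(nrow(design))) {
      probe <- design$probe[s]
      isCapture <- probe != "none"
      eff <- if (isCapture && design$method[s] == "N") config@methodNEfficiency else 1
      mult <- rep(eff, nrow(catalog))
      if (isCapture) {
        aff <- config@probeAffinity[[probe]]
        mult[catalog$is_binder] <- eff * config@enrichmentFold * aff
      }
      logI <- baseMu + log(mult)[protIdx] +
        stats::rnorm(length(protIdx), mean = -sdRep^2 / 2, sd = sdRep)
      pDetect <- stats::plogis(config@detectionSlope * (logI - config@detectionMidpoint))
      keep <- stats::runif(length(protIdx)) < pDetect
      if (any(keep))
        out[[s]] <- data.frame(
          peptide_id = pepId[keep],
          peptide_sequence = pepSeq[keep],
          protein_accession = accOut[protIdx[keep]],
          sample_id = design$sample_id[s],
          intensity = exp(logI[keep]),
          stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out))
      out <- data.frame(peptide_id = character(), peptide_sequence = character(),
                        protein_accession = character(), sample_id = character(),
                        intensity = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

categoryVocabulary <- list(
  A_oxidase = list(
    desc = c("cytochrome P450 monooxygenase", "flavonoid 3'-hydroxylase",
             "peroxidase 12", "polyphenol oxidase"),
    go = "GO:0016491|oxidoreductase activity",
    ipr = "IPR001128|Cytochrome P450"
  ),
  B_methyltransferase = list(
    desc = c("probable methyltransferase 3", "caffeoyl-CoA O-methyltransferase"),
    go = "GO:0008168|methyltransferase activity",
    ipr = "IPR029063|S-adenosyl-L-methionine-dependent methyltransferase"
  ),
  C_glycosyltransferase = list(
    desc = c("UDP-glycosyltransferase 73C", "anthocyanidin 3-O-glucosyltransferase"),
    go = "GO:0016757|glycosyltransferase activity",
    ipr = "IPR002213|UDP-glucuronosyl/UDP-glucosyltransferase"
  ),
  D_other = list(
    desc = c("uncharacterized protein", "heat shock protein 70",
             "ATP synthase subunit beta", "ribosomal protein L3",
             "tubulin beta chain"),
    go = "GO:0005524|ATP binding",
    ipr = "IPR027417|P-loop containing nucleoside triphosphate hydrolase"
  )
)

#' Derive an annotation table from a ground truth
#'
#' Deterministically assigns each catalog protein a description, GO terms
#' and InterPro terms consistent with its truth category, cycling through a
#' per-category vocabulary. Category-D proteins landing on the
#' "uncharacterized protein" description exercise the uncharacterized
#' branch of the annotation screen.
#'
#' @param truth a [GroundTruth-class].
#' @return data.frame with columns \code{accession}, \code{description},
#'   \code{go_terms}, \code{ipr_terms} (";"-separated
#'   \code{id|name} tokens).
#' @export
simulateAnnotations <- function(truth) {
  catalog <- truth@catalog
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    voc <- categoryVocabulary[[catalog$category[i]]]
    desc <- voc$desc[1L + (i - 1L) %% length(voc$desc)]
    data.frame(accession = catalog$accession[i], description = desc,
               go_terms = voc$go, ipr_terms = voc$ipr,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), description = character(),
               go_terms = character(), ipr_terms = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Derive a homologue map from a ground truth
#'
#' Maps every local accession to a reference-proteome accession (1:1 by
#' construction; duplicate accessions map to the same reference entry as
#' their canonical accession, emulating transcriptome redundancy collapsing
#' onto one reference protein).
#'
#' @param truth a [GroundTruth-class].
#' @param prefix accession prefix of the reference proteome.
#' @return data.frame with columns \code{local_accession},
#'   \code{reference_accession}.
#' @export
simulateHomologueMap <- function(truth, prefix = "HANN") {
  catalog <- truth@catalog
  ref <- sprintf("%s%04d", prefix, seq_len(nrow(catalog)))
  out <- data.frame(local_accession = catalog$accession,
                    reference_accession = ref, stringsAsFactors = FALSE)
  if (nrow(truth@duplicateMap)) {
    m <- match(truth@duplicateMap$canonical_accession, catalog$accession)
    out <- rbind(out, data.frame(
      local_accession = truth@duplicateMap$duplicate_accession,
      reference_accession = ref[m], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write a complete fixture bundle to disk
#'
#' Emits every input the pipeline consumes: the peptide report, sample
#' design, annotation table, homologue map, ground-truth catalog (all TSV),
#' and protein sequences as FASTA in a canonical and a redundant variant
#' (the latter repeats duplicated proteins under their alternative
#' accessions), plus the query sequence FASTA. All tables round-trip
#' losslessly through the package's readers.
#'
#' @param truth a [GroundTruth-class].
#' @param report a peptide report from [simulatePeptideReport()].
#' @param design the sample design used.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixtureBundle <- function(truth, report, design, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2L) != 0L)
    stop("cannot write fixture bundle: directory not writable: ", dir,
         call. = FALSE)
  paths <- c(
    report = file.path(dir, "peptide_report.tsv"),
    design = file.path(dir, "design.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    homologues = file.path(dir, "homologue_map.tsv"),
    truth = file.path(dir, "truth.tsv"),
    fasta = file.path(dir, "proteins.fasta"),
    fasta_redundant = file.path(dir, "proteins_redundant.fasta"),
    query_fasta = file.path(dir, "query.fasta")
  )
  writeTsv(report, paths[["report"]])
  writeTsv(design, paths[["design"]])
  writeTsv(simulateAnnotations(truth), paths[["annotations"]])
  writeTsv(simulateHomologueMap(truth), paths[["homologues"]])
  writeTsv(truth@catalog, paths[["truth"]])

  seqs <- Biostrings::AAStringSet(stats::setNames(truth@catalog$sequence,
                                                  truth@catalog$accession))
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])
  red <- seqs
  if (nrow(truth@duplicateMap)) {
    m <- match(truth@duplicateMap$canonical_accession, truth@catalog$accession)
    extra <- Biostrings::AAStringSet(stats::setNames(
      truth@catalog$sequence[m], truth@duplicateMap$duplicate_accession))
    red <- c(seqs, extra)
  }
  Biostrings::writeXStringSet(red, paths[["fasta_redundant"]])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(truth@querySequence), paths[["query_fasta"]])
  invisible(paths)
}
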