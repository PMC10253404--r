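#' Default keyword lists of the candidate screen
#'
#' Keyword vocabularies defining the three candidate classes of
#' flavonoid-pathway enzymes searched for among captured proteins:
#' oxidases (A), methyltransferases (B) and glycosyltransferases (C).
#' Matching is case-insensitive substring search over the protein
#' description and the names of its GO and InterPro terms.
#'
#' @return named list of character vectors for categories
#'   \code{A_oxidase}, \code{B_methyltransferase},
#'   \code{C_glycosyltransferase}.
#' @export
defaultScreenKeywords <- function() {
  list(
    A_oxidase = c("oxidase", "oxidoreductase", "hydroxylase", "monooxygenase",
                  "cytochrome P450", "peroxidase", "dioxygenase"),
    B_methyltransferase = c("methyltransferase", "O-methyltransferase"),
    C_glycosyltransferase = c("glycosyltransferase", "glucosyltransferase",
                              "GlcNAc transferase", "UDP-glycosyl")
  )
}

parseTerms <- function(field) {
  if (is.na(field) || !nzchar(field)) return(character())
  tokens <- strsplit(field, ";", fixed = TRUE)[[1]]
  vapply(strsplit(tokens, "|", fixed = TRUE), function(tok)
    if (length(tok) >= 2L) tok[[2L]] else tok[[1L]], character(1))
}

termIds <- function(field) {
  if (is.na(field) || !nzchar(field)) return(character())
  tokens <- strsplit(field, ";", fixed = TRUE)[[1]]
  vapply(strsplit(tokens, "|", fixed = TRUE), `[[`, character(1), 1L)
}

#' Categorize captured proteins into candidate classes
#'
#' Assigns each annotated protein to one of the screen categories by
#' case-insensitive keyword search over its description and GO/InterPro
#' term names. When keywords of several classes match, priority is
#' A (oxidase) > B (methyltransferase) > C (glycosyltransferase);
#' unmatched or unannotated proteins fall into D.
#'
#' @param annotations annotation data.frame with columns \code{accession},
#'   \code{description}, \code{go_terms}, \code{ipr_terms}
#'   (";"-separated \code{id|name} tokens; see [readAnnotations()]).
#' @param keywords per-category keyword lists as from
#'   [defaultScreenKeywords()]; lists for A-C must be non-empty.
#' @return data.frame with columns \code{accession}, \code{category}
#'   (factor with levels A_oxidase, B_methyltransferase,
#'   C_glycosyltransferase, D_other) and \code{characterized} (FALSE when
#'   the description marks an uncharacterized protein).
#' @examples
#' ann <- data.frame(accession = "P1",
#'                   description = "probable methyltransferase 3",
#'                   go_terms = "", ipr_terms = "")
#' categorizeCandidates(ann)
#' @export
categorizeCandidates <- function(annotations, keywords = defaultScreenKeywords()) {
  stopIfMissingColumns(annotations,
                       c("accession", "description", "go_terms", "ipr_terms"),
                       "annotation table")
  need <- c("A_oxidase", "B_methyltransferase", "C_glycosyltransferase")
  if (!all(need %in% names(keywords)) ||
      any(lengths(keywords[need]) == 0L))
    stop("keyword lists for categories A-C must be non-empty", call. = FALSE)

  category <- vapply(seq_len(nrow(annotations)), function(i) {
    text <- tolower(paste(c(annotations$description[i],
                            parseTerms(annotations$go_terms[i]),
                            parseTerms(annotations$ipr_terms[i])),
                          collapse = " | "))
    for (cat in need) {
      if (any(vapply(tolower(keywords[[cat]]),
                     function(kw) grepl(kw, text, fixed = TRUE), logical(1))))
        return(cat)
    }
    "D_other"
  }, character(1))

  characterized <- !grepl("uncharacterized protein",
                          annotations$description, ignore.case = TRUE)
  data.frame(accession = annotations$accession,
             category = factor(category,
                               levels = c(need, "D_other")),
             characterized = characterized,
             row.names = NULL, stringsAsFactors = FALSE)
}

mapToReference <- function(accessions, homologueMap) {
  if (is.null(homologueMap)) return(accessions)
  m <- match(accessions, homologueMap$local_accession)
  unmapped <- accessions[is.na(m)]
  if (length(unmapped))
    warning("accession(s) without homologue mapping kept under local accession: ",
            paste(unique(unmapped), collapse = ", "), call. = FALSE)
  ifelse(is.na(m), accessions, homologueMap$reference_accession[m])
}

#' Long-format capture heatmap table across assays
#'
#' Merges per-assay capture statistics into one long table keyed by
#' reference accession (via the homologue map) and assay, carrying the
#' capture class, the fold change when defined, and the screen category.
#' Proteins highly significant under exactly one of the two isomeric
#' quercetin probes (Q8 xor Q6, within a species) are flagged
#' \code{exclusive_quercetin}. When two local accessions map to the same
#' reference protein in one assay (transcriptome redundancy), the cell
#' with the lower p-value wins.
#'
#' @param statsList named list of capture-statistics data.frames; names
#'   follow \code{"species.probe.method"} (e.g. \code{"Rudbeckia.Q8.O"}).
#' @param annotations optional annotation table (local accessions).
#' @param homologueMap optional data.frame with \code{local_accession},
#'   \code{reference_accession}; unmappable accessions are kept under
#'   their local accession with a warning.
#' @return long data.frame: \code{accession} (reference namespace),
#'   \code{species}, \code{probe}, \code{method}, \code{capture_class},
#'   \code{r}, \code{category}, \code{exclusive_quercetin}. One row per
#'   (reference accession, assay) pair with any detection.
#' @export
buildHeatmapTable <- function(statsList, annotations = NULL, homologueMap = NULL) {
  if (is.null(names(statsList)) || any(!nzchar(names(statsList))))
    stop("statsList must be a named list ('species.probe.method')", call. = FALSE)
  keys <- strsplit(names(statsList), ".", fixed = TRUE)
  if (any(lengths(keys) != 3L))
    stop("assay names must have the form 'species.probe.method'", call. = FALSE)

  cat <- NULL
  if (!is.null(annotations)) {
    cc <- categorizeCandidates(annotations)
    cc$accession <- mapToReference(cc$accession, homologueMap)
    cat <- cc[!duplicated(cc$accession), ]
  }

  rows <- lapply(seq_along(statsList), function(i) {
    st <- statsList[[i]]
    st <- st[st$n_detected_capture > 0L | st$n_detected_control > 0L, , drop = FALSE]
    if (!nrow(st)) return(NULL)
    data.frame(accession = mapToReference(st$accession, homologueMap),
               species = keys[[i]][1L], probe = keys[[i]][2L],
               method = keys[[i]][3L],
               capture_class = as.character(st$capture_class),
               r = st$r, p = st$p,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(long))
    long <- data.frame(accession = character(), species = character(),
                       probe = character(), method = character(),
                       capture_class = character(), r = numeric(),
                       p = numeric(), stringsAsFactors = FALSE)

  # redundancy collapse: best (lowest p, then highest r) cell per assay
  ord <- order(long$accession, long$species, long$probe, long$method,
               is.na(long$p), long$p, -xtfrm(long$r))
  long <- long[ord, , drop = FALSE]
  key <- paste(long$accession, long$species, long$probe, long$method, sep = "\r")
  long <- long[!duplicated(key), , drop = FALSE]

  hsClasses <- c("highly_significant_enriched", "highly_significant_absent_control")
  hs <- long[long$capture_class %in% hsClasses, , drop = FALSE]
  exclusive <- vapply(seq_len(nrow(long)), function(i) {
    here <- hs[hs$accession == long$accession[i] & hs$species == long$species[i], ]
    probes <- unique(here$probe)
    sum(c("Q8", "Q6") %in% probes) == 1L
  }, logical(1))
  long$exclusive_quercetin <- exclusive

  if (!is.null(cat)) {
    m <- match(long$accession, cat$accession)
    long$category <- as.character(cat$category)[m]
  } else {
    long$category <- NA_character_
  }
  long$p <- NULL
  rownames(long) <- NULL
  long
}

#' Cross-species coherence of capture calls
#'
#' Returns the reference accessions highly significant in at least one
#' assay of each species, i.e. captures confirmed from both proteomes.
#'
#' @param statsSpecies1,statsSpecies2 lists of capture-statistics
#'   data.frames for the two species (local accessions).
#' @param homologueMap1,homologueMap2 homologue maps taking each species'
#'   local accessions into the shared reference namespace (optional when a
#'   species already uses reference accessions).
#' @return character vector of confirmed reference accessions.
#' @export
crossSpeciesCoherence <- function(statsSpecies1, statsSpecies2,
                                  homologueMap1 = NULL, homologueMap2 = NULL) {
  hsOf <- function(statsList, map) {
    unique(unlist(lapply(statsList, function(st)
      mapToReference(highlySignificant(st), map))))
  }
  intersect(hsOf(statsSpecies1, homologueMap1),
            hsOf(statsSpecies2, homologueMap2))
}

#' GO-term overrepresentation analysis
#'
#' One-sided hypergeometric test per GO term: the probability of observing
#' at least the seen number of term-annotated proteins in the target set,
#' drawing \code{|target|} proteins from the background without
#' replacement. P-values are Benjamini-Hochberg adjusted across the tested
#' terms; terms absent from the target set are not tested.
#'
#' @param target accession set of interest (e.g. proteins significantly
#'   captured by one probe); must be a subset of \code{background}.
#' @param background accession universe (e.g. all proteins detected in the
#'   total microsome proteome).
#' @param annotations annotation table with ";"-separated
#'   \code{id|name} GO tokens.
#' @return data.frame sorted by p-value: \code{term}, \code{name},
#'   \code{count_target}, \code{count_background}, \code{p}, \code{padj}.
#' @export
goEnrichment <- function(target, background, annotations) {
  if (anyDuplicated(target) || anyDuplicated(background))
    stop("target and background must be duplicate-free accession sets",
         call. = FALSE)
  if (!all(target %in% background))
    stop("target must be a subset of background", call. = FALSE)
  stopIfMissingColumns(annotations, c("accession", "go_terms"), "annotation table")

  ann <- annotations[annotations$accession %in% background, , drop = FALSE]
  termRows <- lapply(seq_len(nrow(ann)), function(i) {
    ids <- termIds(ann$go_terms[i])
    if (!length(ids)) return(NULL)
    data.frame(accession = ann$accession[i], term = ids,
               name = parseTerms(ann$go_terms[i]),
               stringsAsFactors = FALSE)
  })
  termTab <- do.call(rbind, termRows[!vapply(termRows, is.null, logical(1))])
  empty <- data.frame(term = character(), name = character(),
                      count_target = integer(), count_background = integer(),
                      p = numeric(), padj = numeric(), stringsAsFactors = FALSE)
  if (is.null(termTab)) return(empty)

  N <- length(background)
  n <- length(target)
  res <- lapply(split(termTab, termTab$term), function(tt) {
    K <- length(unique(tt$accession))
    k <- length(unique(intersect(tt$accession, target)))
    if (k == 0L) return(NULL)
    data.frame(term = tt$term[1L], name = tt$name[1L],
               count_target = k, count_background = K,
               p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
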