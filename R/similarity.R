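validateAASequence <- function(seq, what) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!length(chars))
    stop(sprintf("%s sequence is empty", what), call. = FALSE)
  ok <- chars %in% c(AA20, "X")
  if (!all(ok))
    stop(sprintf("invalid residue '%s' at position %d of %s sequence",
                 chars[which(!ok)[1L]], which(!ok)[1L], what), call. = FALSE)
  paste(chars, collapse = "")
}

substitutionMatrix <- function(scheme) {
  mat <- tryCatch(
    get(data(list = scheme@matrixName, package = "Biostrings",
             envir = environment())),
    error = function(e) stop("unknown substitution matrix: ",
                             scheme@matrixName, call. = FALSE))
  mat
}

#' Optimal local alignment score of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of
#' length L costs \code{gapOpen + L * gapExtend}), scored with the
#' scheme's substitution matrix. The score is symmetric in its arguments
#' and never negative (the empty alignment scores 0).
#'
#' @param query,subject amino-acid sequences (character strings over the
#'   20-letter alphabet plus X).
#' @param scheme a [ScoringScheme-class].
#' @return numeric local alignment score.
#' @examples
#' localAlign("HEAGAWGHEE", "PAWHEAE")
#' @export
localAlign <- function(query, subject, scheme = scoringScheme()) {
  validObject(scheme)
  query <- validateAASequence(as.character(query), "query")
  subject <- validateAASequence(as.character(subject), "subject")
  mat <- substitutionMatrix(scheme)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend,
    scoreOnly = TRUE)
  max(0, pa)
}

#' Assign similarity tiers to alignment scores
#'
#' Mirrors the two-band reading of similarity scores used when
#' shortlisting: \code{"high"} above \code{highCut}, \code{"low"} at or
#' below \code{lowCut}, \code{"none"} in between.
#'
#' @param score numeric alignment scores.
#' @param highCut,lowCut tier thresholds (defaults 500 and 300).
#' @return factor with levels \code{none}, \code{low}, \code{high}.
#' @export
assignTiers <- function(score, highCut = 500, lowCut = 300) {
  tier <- ifelse(score > highCut, "high",
                 ifelse(score <= lowCut, "low", "none"))
  factor(tier, levels = c("none", "low", "high"))
}

#' Score all query-subject pairs of a sequence database
#'
#' Computes local alignment scores of every query against every database
#' sequence, keeps pairs scoring at least \code{reportFloor}, assigns
#' similarity tiers, and ranks hits per query by descending score (ties
#' broken by subject accession).
#'
#' @param queries,database named character vectors or
#'   \code{Biostrings::AAStringSet} of amino-acid sequences.
#' @param scheme a [ScoringScheme-class].
#' @param reportFloor minimum score to report.
#' @param highCut,lowCut tier thresholds (see [assignTiers()]).
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{score}, \code{tier}, \code{rank}.
#' @export
searchDatabase <- function(queries, database, scheme = scoringScheme(),
                           reportFloor = 50, highCut = 500, lowCut = 300) {
  toVec <- function(x, what) {
    if (methods::is(x, "AAStringSet")) x <- as.character(x)
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
      stop(what, " sequences must be named", call. = FALSE)
    x
  }
  queries <- toVec(queries, "query")
  database <- toVec(database, "database")
  if (!length(database))
    stop("database must be non-empty", call. = FALSE)
  validObject(scheme)
  mat <- substitutionMatrix(scheme)
  qs <- Biostrings::AAStringSet(vapply(queries, validateAASequence,
                                       character(1), what = "query"))
  db <- Biostrings::AAStringSet(vapply(database, validateAASequence,
                                       character(1), what = "database"))
  rows <- lapply(names(qs), function(qn) {
    sc <- Biostrings::pairwiseAlignment(
      db, qs[[qn]], type = "local", substitutionMatrix = mat,
      gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend,
      scoreOnly = TRUE)
    sc <- pmax(0, sc)
    keep <- sc >= reportFloor
    if (!any(keep)) return(NULL)
    df <- data.frame(query = qn, subject = names(db)[keep],
                     score = sc[keep], stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$subject), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(query = character(), subject = character(),
                      score = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  out$tier <- assignTiers(out$score, highCut = highCut, lowCut = lowCut)
  rownames(out) <- NULL
  out[, c("query", "subject", "score", "tier", "rank")]
}

blastColumns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column protein BLAST tabular format and returns
#' alignment hits scored by bit score. Malformed lines are rejected with
#' their line numbers.
#'
#' @param path path to a BLAST \code{-outfmt 6} file.
#' @param highCut,lowCut tier thresholds applied to the bit score.
#' @return data.frame with the 12 BLAST columns plus \code{query},
#'   \code{subject}, \code{score} (bit score) and \code{tier}.
#' @export
parseBlastTabular <- function(path, highCut = 500, lowCut = 300) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(matrix(ncol = length(blastColumns), nrow = 0,
                             dimnames = list(NULL, blastColumns)))
  if (!length(lines)) {
    out <- cbind(empty, query = character(), subject = character(),
                 score = numeric(), tier = assignTiers(numeric()))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("malformed BLAST tabular line(s) (expected 12 columns): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  m <- do.call(rbind, fields)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- blastColumns
  numCols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send", "evalue", "bitscore")
  for (cc in numCols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v))
      stop(sprintf("malformed numeric field '%s' at line %d", cc,
                   which(is.na(v))[1L]), call. = FALSE)
    out[[cc]] <- v
  }
  out$query <- out$qseqid
  out$subject <- out$sseqid
  out$score <- out$bitscore
  out$tier <- assignTiers(out$score, highCut = highCut, lowCut = lowCut)
  out
}

classSeverity <- c(highly_significant_absent_control = 1L,
                   highly_significant_enriched = 1L,
                   significant = 2L,
                   detected = 3L,
                   not_detected = 4L)

#' Cross-reference alignment hits with capture significance
#'
#' Inner-joins alignment hits (by subject accession) with capture calls to
#' produce the candidate shortlist: proteins that both resemble the query
#' enzyme and were significantly captured by the probes. Ranking is by
#' capture-class severity (the two highly-significant branches first, then
#' significant), then by alignment score descending, with remaining ties
#' broken by accession. Hits whose protein was detected but not
#' significant, or not captured at all, and captures without any hit, are
#' returned as side tables.
#'
#' @param hits alignment-hit data.frame (from [searchDatabase()] or
#'   [parseBlastTabular()]) with columns \code{query}, \code{subject},
#'   \code{score}, \code{tier}.
#' @param capture capture-statistics data.frame from [captureStats()] (or
#'   several assays' rows bound together; the best class per accession is
#'   used and classes per assay are aggregated into a label).
#' @return list with \code{shortlist} (columns \code{accession},
#'   \code{best_query}, \code{score}, \code{tier}, \code{capture_class},
#'   \code{assays}, \code{rank}), \code{hitsWithoutCapture} and
#'   \code{capturesWithoutHit}.
#' @export
crossrefShortlist <- function(hits, capture) {
  stopIfMissingColumns(hits, c("query", "subject", "score", "tier"),
                       "alignment hits")
  stopIfMissingColumns(capture, c("accession", "contrast", "capture_class"),
                       "capture statistics")

  # best alignment per subject
  hord <- order(hits$subject, -hits$score, hits$query)
  bestHit <- hits[hord, , drop = FALSE]
  bestHit <- bestHit[!duplicated(bestHit$subject), , drop = FALSE]

  capture$severity <- classSeverity[as.character(capture$capture_class)]
  cord <- order(capture$accession, capture$severity)
  bestCap <- capture[cord, , drop = FALSE]
  assays <- tapply(paste0(bestCap$contrast, ":", bestCap$capture_class),
                   bestCap$accession, paste, collapse = ";")
  bestCap <- bestCap[!duplicated(bestCap$accession), , drop = FALSE]
  bestCap$assays <- as.character(assays[bestCap$accession])

  joined <- merge(bestHit, bestCap, by.x = "subject", by.y = "accession")
  significant <- joined$severity <= 2L
  main <- joined[significant, , drop = FALSE]
  side <- joined[!significant, , drop = FALSE]

  ord <- order(main$severity, -main$score, main$subject)
  main <- main[ord, , drop = FALSE]
  shortlist <- data.frame(accession = main$subject,
                          best_query = main$query,
                          score = main$score, tier = main$tier,
                          capture_class = as.character(main$capture_class),
                          assays = main$assays,
                          rank = seq_len(nrow(main)),
                          row.names = NULL, stringsAsFactors = FALSE)

  hitsWithoutCapture <- rbind(
    bestHit[!bestHit$subject %in% capture$accession,
            c("subject", "query", "score", "tier")],
    side[, c("subject", "query", "score", "tier")])
  hitsWithoutCapture <- hitsWithoutCapture[order(-hitsWithoutCapture$score), ]
  rownames(hitsWithoutCapture) <- NULL

  capturesWithoutHit <- bestCap[!bestCap$accession %in% bestHit$subject &
                                  bestCap$severity <= 2L,
                                c("accession", "capture_class", "assays")]
  rownames(capturesWithoutHit) <- NULL

  list(shortlist = shortlist,
       hitsWithoutCapture = hitsWithoutCapture,
       capturesWithoutHit = capturesWithoutHit)
}
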