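#' Venn region counts for two or three accession sets
#'
#' Exact region cardinalities, by set algebra, for all \code{2^k - 1}
#' non-empty regions of k labeled sets. Region labels are
#' \code{"&"}-joined set labels; a region counts elements belonging to
#' exactly those sets and no others.
#'
#' @param sets named list of 2 or 3 character vectors; each must be
#'   duplicate-free.
#' @return data.frame with columns \code{region} and \code{count}.
#' @examples
#' setOverlap(list(A = c("p1", "p2", "p3"), B = c("p2", "p3")))
#' @export
setOverlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop("sets must be a named list of 2 or 3 accession vectors", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0L
  if (any(dup))
    stop("duplicate accessions within set(s): ",
         paste(names(sets)[dup], collapse = ", "), call. = FALSE)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1L, function(pat) {
    sum(apply(member, 1L, function(m) all(m == pat)))
  })
  region <- apply(patterns, 1L, function(pat)
    paste(names(sets)[as.logical(pat)], collapse = "&"))
  data.frame(region = region, count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Probe-vs-probe selectivity volcano statistics
#'
#' For proteins captured by two different probes but absent from the
#' probe-less controls, the usual capture/control fold change is
#' uncomputable; selectivity is instead measured probe against probe:
#' \code{lg2_r} is the log2 ratio of mean abundance in probe A capture
#' samples over probe B capture samples, and the p-value comes from the
#' same two-group ANOVA machinery as the main pipeline (equivalent to a
#' pooled-variance t-test).
#'
#' @param ce a normalized [CaptureExperiment-class].
#' @param samplesA,samplesB capture sample ids for probes A and B.
#' @param eligible accessions eligible for the volcano — by construction
#'   the proteins highly significant in both probes' assays and not
#'   detected in negative controls.
#' @param pMax significance gate on the two-group p-value (default 0.05).
#' @return data.frame with columns \code{accession}, \code{lg2_r},
#'   \code{p}, \code{neg_log10_p}, \code{significant}; proteins missing in
#'   every replicate of either probe are excluded and reported in the
#'   \code{"excluded"} attribute with a reason.
#' @export
probeSelectivity <- function(ce, samplesA, samplesB, eligible, pMax = 0.05) {
  rat <- groupRatio(ce, samplesA, samplesB)
  rat <- rat[rat$accession %in% eligible, , drop = FALSE]
  excluded <- rat[rat$flag != "ok",
                  c("accession", "flag"), drop = FALSE]
  names(excluded) <- c("accession", "reason")
  rat <- rat[rat$flag == "ok", , drop = FALSE]
  p <- anovaPvalue(ce, list(A = samplesA, B = samplesB))
  out <- data.frame(
    accession = rat$accession,
    lg2_r = log2(rat$r),
    p = as.numeric(p[rat$accession]),
    stringsAsFactors = FALSE
  )
  out$neg_log10_p <- ifelse(is.na(out$p), NA_real_, -log10(out$p))
  out$significant <- !is.na(out$p) & out$p < pMax
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Partition selectivity records by direction of significant enrichment
#'
#' @param records a selectivity table from [probeSelectivity()].
#' @return list with accession vectors \code{enrichedA} (significant,
#'   \code{lg2_r > 0}), \code{enrichedB} (significant, \code{lg2_r < 0}),
#'   \code{nonsignificant}, and a \code{counts} vector.
#' @export
selectivityPartition <- function(records) {
  stopIfMissingColumns(records, c("accession", "lg2_r", "significant"),
                       "selectivity records")
  enrichedA <- records$accession[records$significant & records$lg2_r > 0]
  enrichedB <- records$accession[records$significant & records$lg2_r < 0]
  nonsignificant <- setdiff(records$accession, c(enrichedA, enrichedB))
  list(enrichedA = enrichedA, enrichedB = enrichedB,
       nonsignificant = nonsignificant,
       counts = c(enrichedA = length(enrichedA),
                  enrichedB = length(enrichedB),
                  nonsignificant = length(nonsignificant)))
}
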