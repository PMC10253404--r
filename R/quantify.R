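#' Aggregate a peptide report into a protein abundance matrix
#'
#' Protein abundance in a sample is the sum of the intensities of the
#' peptides unique to that protein in that sample. Peptides whose
#' accession field lists more than one protein (";"-separated) are shared
#' and contribute to no protein. Proteins with no observed unique peptide
#' in a sample are missing (\code{NA}) there — a state distinct from zero
#' abundance. Unique-peptide counts per protein and sample are recorded in
#' the \code{"npep"} assay.
#'
#' @param peptides a peptide report data.frame with columns
#'   \code{peptide_id}, \code{protein_accession}, \code{sample_id},
#'   \code{intensity} (see [readPeptideReport()]).
#' @param design sample design table; its \code{sample_id} values define the
#'   columns of the result, in design order.
#' @param catalog optional character vector of known accessions; peptides
#'   referencing accessions outside it raise an error.
#' @return a raw (unnormalized) [CaptureExperiment-class].
#' @examples
#' design <- captureDesign(probes = "Q8", nReplicates = 2)
#' pep <- data.frame(peptide_id = c("a", "b"), peptide_sequence = "PEPTIDEK",
#'                   protein_accession = "P1",
#'                   sample_id = design$sample_id[1],
#'                   intensity = c(100, 200))
#' ce <- aggregateAbundance(pep, design)
#' abundance(ce)
#' @export
aggregateAbundance <- function(peptides, design, catalog = NULL) {
  stopIfMissingColumns(peptides,
                       c("peptide_id", "protein_accession", "sample_id", "intensity"),
                       "peptide report")
  stopIfMissingColumns(design, c("species", "probe", "method", "replicate", "sample_id"),
                       "design")
  if (any(peptides$intensity < 0, na.rm = TRUE))
    stop("peptide intensities must be non-negative", call. = FALSE)
  badSample <- setdiff(unique(peptides$sample_id), design$sample_id)
  if (length(badSample))
    stop("peptide report references sample(s) absent from the design: ",
         paste(badSample, collapse = ", "), call. = FALSE)

  shared <- grepl(";", peptides$protein_accession, fixed = TRUE)
  uniq <- peptides[!shared, , drop = FALSE]

  if (!is.null(catalog)) {
    unknown <- setdiff(unique(uniq$protein_accession), catalog)
    if (length(unknown))
      stop("peptide report references unknown accession(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  proteins <- sort(unique(uniq$protein_accession))
  samples <- design$sample_id
  ab <- matrix(NA_real_, length(proteins), length(samples),
               dimnames = list(proteins, samples))
  np <- matrix(0L, length(proteins), length(samples),
               dimnames = list(proteins, samples))
  if (nrow(uniq)) {
    i <- match(uniq$protein_accession, proteins)
    j <- match(uniq$sample_id, samples)
    sums <- tapply(uniq$intensity, list(factor(i, seq_along(proteins)),
                                        factor(j, seq_along(samples))),
                   sum)
    counts <- tapply(uniq$peptide_id, list(factor(i, seq_along(proteins)),
                                           factor(j, seq_along(samples))),
                     function(x) length(unique(x)))
    ab[] <- as.numeric(sums)
    np[] <- ifelse(is.na(counts), 0L, as.integer(counts))
  }

  cd <- DataFrame(design[, c("species", "probe", "method", "replicate")],
                  row.names = design$sample_id)
  se <- SummarizedExperiment(assays = list(abundance = ab, npep = np),
                             colData = cd)
  metadata(se)$normalized <- FALSE
  new("CaptureExperiment", se)
}

#' Normalize abundances on total protein amounts
#'
#' Each sample column is rescaled so that its total abundance (summed over
#' observed cells) equals the grand mean of all column totals. Within-sample
#' ratios are untouched; the operation is idempotent.
#'
#' @param ce a [CaptureExperiment-class].
#' @return the normalized [CaptureExperiment-class].
#' @export
normalizeAbundance <- function(ce) {
  ab <- abundance(ce)
  totals <- colSums(ab, na.rm = TRUE)
  empty <- colSums(!is.na(ab)) == 0L
  if (any(empty))
    stop("cannot normalize: sample(s) with no observed abundance: ",
         paste(colnames(ab)[empty], collapse = ", "), call. = FALSE)
  target <- mean(totals)
  scaled <- sweep(ab, 2L, target / totals, `*`)
  assays(ce)$abundance <- scaled
  metadata(ce)$normalized <- TRUE
  ce
}

#' Drop proteins quantified by fewer than k unique peptides
#'
#' A protein is retained when its unique-peptide count reaches \code{k} in
#' at least one sample (maximum-per-sample rule), so that proteins
#' confidently quantified anywhere survive sporadic single-peptide
#' sightings elsewhere.
#'
#' @param ce a [CaptureExperiment-class].
#' @param k minimum unique-peptide count (default 2).
#' @return the filtered [CaptureExperiment-class].
#' @export
filterMinPeptides <- function(ce, k = 2L) {
  if (k < 1L)
    stop("k must be >= 1", call. = FALSE)
  keep <- apply(peptideCounts(ce), 1L, max) >= k
  ce[keep, ]
}

#' Grouped fold change between two sample groups
#'
#' The ratio r is the mean observed abundance across the numerator samples
#' over the mean observed abundance across the denominator samples.
#' A protein missing in every denominator sample is flagged
#' \code{"absent_in_denominator"} (the not-present-in-control state) rather
#' than given an infinite ratio; missing in every numerator sample yields
#' \code{"absent_in_numerator"}; missing in both, \code{"absent_in_both"}.
#'
#' @param ce a [CaptureExperiment-class].
#' @param numerator,denominator disjoint non-empty character vectors of
#'   sample ids.
#' @param groupFun how replicate abundances are grouped: \code{"mean"}
#'   (default) or \code{"median"}.
#' @return data.frame with columns \code{accession}, \code{r}
#'   (\code{NA} when flagged), \code{flag} (\code{"ok"} or an absence
#'   flag), \code{n_detected_num}, \code{n_detected_den}.
#' @export
groupRatio <- function(ce, numerator, denominator, groupFun = c("mean", "median")) {
  groupFun <- match.arg(groupFun)
  fun <- if (groupFun == "mean") mean else stats::median
  checkGroups(ce, list(numerator = numerator, denominator = denominator))
  if (length(intersect(numerator, denominator)))
    stop("numerator and denominator groups must be disjoint", call. = FALSE)
  ab <- abundance(ce)
  num <- ab[, numerator, drop = FALSE]
  den <- ab[, denominator, drop = FALSE]
  nNum <- rowSums(!is.na(num))
  nDen <- rowSums(!is.na(den))
  mNum <- apply(num, 1L, function(x) fun(x[!is.na(x)]))
  mDen <- apply(den, 1L, function(x) fun(x[!is.na(x)]))
  flag <- rep("ok", nrow(ab))
  flag[nNum == 0L] <- "absent_in_numerator"
  flag[nDen == 0L] <- "absent_in_denominator"
  flag[nNum == 0L & nDen == 0L] <- "absent_in_both"
  r <- ifelse(flag == "ok", mNum / mDen, NA_real_)
  data.frame(accession = rownames(ab), r = r, flag = flag,
             n_detected_num = nNum, n_detected_den = nDen,
             row.names = NULL, stringsAsFactors = FALSE)
}

checkGroups <- function(ce, groups) {
  if (length(groups) < 2L)
    stop("at least two sample groups are required", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("sample groups must be non-empty", call. = FALSE)
  unknown <- setdiff(unlist(groups), colnames(ce))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(groups)
}

#' Per-protein one-way ANOVA across sample groups
#'
#' Fixed-effects one-way ANOVA on (by default) log2-transformed abundances.
#' The p-value is undefined (\code{NA}) for proteins with fewer than two
#' observed values in any group, and for degenerate zero-variance data
#' where the F statistic does not exist.
#'
#' @param ce a [CaptureExperiment-class].
#' @param groups list of >= 2 character vectors of sample ids.
#' @param log2Transform analyse log2 abundances (default) or raw.
#' @return named numeric vector of p-values (one per protein; \code{NA}
#'   when undefined).
#' @export
anovaPvalue <- function(ce, groups, log2Transform = TRUE) {
  checkGroups(ce, groups)
  ab <- abundance(ce)[, unlist(groups), drop = FALSE]
  if (log2Transform) ab <- log2(ab)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  p <- apply(ab, 1L, function(x) {
    ok <- !is.na(x)
    if (any(tapply(ok, g, sum) < 2L)) return(NA_real_)
    xs <- split(x[ok], g[ok])
    if (all(vapply(xs, function(v) stats::var(v) == 0, logical(1))) &&
        length(unique(vapply(xs, mean, numeric(1)))) > 1L)
      return(NA_real_)
    res <- tryCatch(stats::oneway.test(x[ok] ~ g[ok], var.equal = TRUE),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$p.value)) NA_real_ else res$p.value
  })
  stats::setNames(as.numeric(p), rownames(ab))
}
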