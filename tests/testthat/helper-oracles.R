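# Independent oracles, written from first principles and kept free of any
# package internals so they can cross-check the implementation.

# one-way fixed-effects ANOVA p-value via explicit sum-of-squares decomposition
anovaOracle <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  grand <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1
  dfw <- sum(ns) - k
  f <- (ssb / dfb) / (ssw / dfw)
  stats::pf(f, dfb, dfw, lower.tail = FALSE)
}

# hypergeometric upper tail by exhaustive pmf summation over lchoose
hyperOracle <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Venn region counts by brute-force membership enumeration
vennOracle <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  k <- length(sets)
  for (bits in 1:(2^k - 1)) {
    inSets <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    outSets <- setdiff(seq_len(k), inSets)
    cnt <- sum(vapply(universe, function(el) {
      all(vapply(inSets, function(s) el %in% sets[[s]], logical(1))) &&
        !any(vapply(outSets, function(s) el %in% sets[[s]], logical(1)))
    }, logical(1)))
    out[[paste(names(sets)[inSets], collapse = "&")]] <- cnt
  }
  out
}

# Smith-Waterman affine-gap local alignment score by quadratic Gotoh DP;
# a gap of length L costs open + L * extend
swOracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- E <- F <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# literal re-statement of the tiered capture rule, for truth-table checks
classifyOracle <- function(r, p, ctlDetected, capDetected = 3,
                           minRep = 2, log2Cut = 2, nlpCut = 2.5, pMax = 0.05) {
  if (capDetected < minRep) return("not_detected")
  if (ctlDetected == 0) return("highly_significant_absent_control")
  if (!is.na(r) && !is.na(p) && r > 0 &&
      log2(r) > log2Cut && -log10(p) > nlpCut)
    return("highly_significant_enriched")
  if (!is.na(p) && p < pMax) return("significant")
  "detected"
}

randomAA <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# small hand-built experiment: 2 proteins x (2 capture + 2 control) samples
tinyDesign <- function(probes = "Q8", nReplicates = 2L) {
  captureDesign(probes = probes, nReplicates = nReplicates)
}

# build a CaptureExperiment directly from an abundance matrix (all peptide
# counts set to `npep`), bypassing aggregation
ceFromMatrix <- function(ab, design, npep = 2L) {
  pep <- do.call(rbind, lapply(seq_len(ncol(ab)), function(j) {
    obs <- which(!is.na(ab[, j]))
    if (!length(obs)) return(NULL)
    do.call(rbind, lapply(obs, function(i) {
      data.frame(
        peptide_id = sprintf("%s_p%d", rownames(ab)[i], seq_len(npep)),
        peptide_sequence = "PEPTIDEK",
        protein_accession = rownames(ab)[i],
        sample_id = colnames(ab)[j],
        intensity = rep(ab[i, j] / npep, npep),
        stringsAsFactors = FALSE)
    }))
  }))
  aggregateAbundance(pep, design)
}

readTsvForTest <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
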