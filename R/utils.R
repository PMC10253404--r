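# Internal helpers shared across modules.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Write a table as TSV
#'
#' All tabular outputs of the package share this format: tab-separated,
#' UTF-8, header row, no quoting, \code{NA} for missing cells.
#'
#' @param x a data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

randomAASeq <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Point-mutate a sequence down to the requested fractional identity.
mutateToIdentity <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  nMut <- round((1 - identity) * length(chars))
  if (nMut > 0) {
    pos <- sample(length(chars), nMut)
    chars[pos] <- vapply(chars[pos], function(a) {
      sample(setdiff(AA20, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

stopIfMissingColumns <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(sprintf("%s lacks required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(x)
}
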