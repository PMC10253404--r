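#' Read a peptide-level intensity report
#'
#' Expects a TSV with header columns \code{peptide_id},
#' \code{peptide_sequence}, \code{protein_accession}, \code{sample_id},
#' \code{intensity}. Accession fields listing several proteins
#' (";"-separated) are kept verbatim and flagged \code{multi_mapped};
#' downstream aggregation excludes them from all protein sums.
#'
#' @param path path to the TSV file.
#' @return data.frame of peptide records with an added
#'   \code{multi_mapped} logical column.
#' @export
readPeptideReport <- function(path) {
  x <- readTsv(path)
  stopIfMissingColumns(x, c("peptide_id", "peptide_sequence",
                            "protein_accession", "sample_id", "intensity"),
                       sprintf("peptide report '%s'", path))
  if (!nrow(x)) {
    warning("peptide report is empty (header only): ", path, call. = FALSE)
    x$multi_mapped <- logical()
    return(x)
  }
  x$intensity <- as.numeric(x$intensity)
  bad <- which(is.na(x$intensity) | x$intensity < 0)
  if (length(bad))
    stop(sprintf("invalid intensity at data line %d of %s", bad[1L], path),
         call. = FALSE)
  x$multi_mapped <- grepl(";", x$protein_accession, fixed = TRUE)
  x
}

#' Read a sample design table
#'
#' @param path TSV with columns \code{species}, \code{probe},
#'   \code{method}, \code{replicate}, \code{sample_id}.
#' @param validate run [validateDesign()] on the result (default TRUE).
#' @return validated design data.frame.
#' @export
readDesign <- function(path, validate = TRUE) {
  x <- readTsv(path)
  if (validate) validateDesign(x) else x
}

#' Validate a sample design
#'
#' Checks that sample ids are unique (error), that every species has a
#' probe-less control group (error — the absent-in-control branch of the
#' capture call is undefined without controls) and that every
#' (species, probe, method) cell has at least 2, ideally 3, replicates
#' (warnings when triplicates are incomplete).
#'
#' @param design design data.frame.
#' @return the design, invisibly, if valid.
#' @export
validateDesign <- function(design) {
  stopIfMissingColumns(design, c("species", "probe", "method", "replicate",
                                 "sample_id"), "design")
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s) in design: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  for (sp in unique(design$species)) {
    if (!any(design$probe[design$species == sp] == "none"))
      stop("species without probe-less negative control group: ", sp,
           call. = FALSE)
  }
  cellSize <- table(paste(design$species, design$probe, design$method))
  if (any(cellSize < 2L))
    warning("design cell(s) with fewer than 2 replicates: ",
            paste(names(cellSize)[cellSize < 2L], collapse = ", "),
            call. = FALSE)
  else if (any(cellSize < 3L))
    warning("design cell(s) with incomplete triplicates: ",
            paste(names(cellSize)[cellSize < 3L], collapse = ", "),
            call. = FALSE)
  invisible(design)
}

#' Read a protein annotation table
#'
#' @param path TSV with columns \code{accession}, \code{description},
#'   \code{go_terms}, \code{ipr_terms}; term fields are ";"-separated
#'   \code{id|name} tokens.
#' @return annotation data.frame with empty term fields normalized to "".
#' @export
readAnnotations <- function(path) {
  x <- readTsv(path)
  stopIfMissingColumns(x, c("accession", "description", "go_terms", "ipr_terms"),
                       sprintf("annotation table '%s'", path))
  for (cc in c("go_terms", "ipr_terms"))
    x[[cc]] <- ifelse(is.na(x[[cc]]), "", as.character(x[[cc]]))
  x
}

#' Read a homologue map
#'
#' @param path TSV with columns \code{local_accession},
#'   \code{reference_accession}; each local accession must map to at most
#'   one reference accession.
#' @return homologue map data.frame.
#' @export
readHomologueMap <- function(path) {
  x <- readTsv(path)
  stopIfMissingColumns(x, c("local_accession", "reference_accession"),
                       sprintf("homologue map '%s'", path))
  dup <- x$local_accession[duplicated(x$local_accession)]
  if (length(dup))
    stop("local accession(s) mapped to more than one reference accession: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  x
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around \code{Biostrings::readAAStringSet} that truncates
#' FASTA headers at the first whitespace so names are plain accessions.
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
readProteinFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Write a CaptureExperiment abundance matrix as TSV
#'
#' Proteins in rows, samples in columns, \code{NA} for missing cells, with
#' the accession in the first column.
#'
#' @param ce a [CaptureExperiment-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTsv <- function(ce, path) {
  ab <- abundance(ce)
  writeTsv(data.frame(accession = rownames(ab), ab, check.names = FALSE,
                      stringsAsFactors = FALSE), path)
}
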