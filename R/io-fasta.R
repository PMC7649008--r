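#' Read a FASTA file into a named character vector
#'
#' Names are truncated at the first whitespace.  Duplicate names and empty
#' sequences are errors.
#'
#' @param x Path to a FASTA file (plain or gzip).
#' @return Named character vector of uppercase sequences, input order
#'   preserved.
#' @export
read_fasta <- function(x) {
  set <- Biostrings::readDNAStringSet(x)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("FASTA: duplicate sequence name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("FASTA: empty sequence: ", nm[Biostrings::width(set) == 0L][1L])
  }
  setNames(toupper(as.character(set)), nm)
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param line_width Wrap width (default 80).
#' @export
write_fasta <- function(records, path, line_width = 80L) {
  if (!is(records, "DNAStringSet")) {
    if (is.null(names(records)) || anyDuplicated(names(records))) {
      stop("FASTA records must have unique names")
    }
    if (any(nchar(records) == 0L)) stop("FASTA: empty sequence")
    records <- Biostrings::DNAStringSet(records)
  }
  Biostrings::writeXStringSet(records, path, width = line_width)
  invisible(path)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
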