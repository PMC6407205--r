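#' Read a DNA FASTA file
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' `{A, C, G, T, N}`. Sequence records are represented throughout the
#' package as a named character vector (names are record ids).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences, one element
#'   per FASTA record, in file order. An empty file yields an empty vector.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(character(0))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- names(set)
  if (any(!nzchar(ids))) stop("malformed FASTA header: empty record id")
  # header lines may carry descriptions; keep the first word as the id
  ids <- vapply(strsplit(ids, "[ \t]+"), `[`, character(1), 1L)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
    stop("illegal character '", ch, "' in sequence record '", ids[bad][1], "'")
  }
  if (any(nchar(seqs) < 1)) stop("empty sequence in record '",
                                 ids[nchar(seqs) < 1][1], "'")
  stats::setNames(seqs, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' @param records Named character vector of DNA sequences (as returned by
#'   [read_fasta()]).
#' @param path Output path.
#' @param wrap Line width for wrapping sequence lines.
#' @return `path`, invisibly. `read_fasta(write_fasta(r, path))` returns `r`.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (length(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  set <- Biostrings::DNAStringSet(unname(toupper(records)))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
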