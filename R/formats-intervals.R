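#' Read genomic intervals from BED or RepeatMasker output
#'
#' All intervals are returned 0-based, half-open. BED input is passed
#' through unchanged; RepeatMasker `.out` rows (1-based, inclusive) are
#' converted. The repeat family name of a RepeatMasker row (or BED column 4)
#' is kept in the `name` field, so annotation sets can be restricted to one
#' family, e.g. the LTR class of the ERV lineage under study.
#'
#' @param path Input file.
#' @param dialect `"bed"` (3-6 column BED) or `"repeatmasker_out"`.
#' @param name_filter Optional substring; only intervals whose `name`
#'   contains it are returned.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `strand` (`+`, `-`, or `.`).
#' @export
read_intervals <- function(path, dialect = c("bed", "repeatmasker_out"),
                           name_filter = NULL) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "bed") read_bed6(path) else read_rm_out(path)
  if (!is.null(name_filter)) out <- out[grepl(name_filter, out$name, fixed = TRUE), ]
  rownames(out) <- NULL
  out
}

read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(".", length(gr))
  nm[is.na(nm)] <- "."
  std <- as.character(BiocGenerics::strand(gr))
  std[std == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,  # GRanges is 1-based
             end = BiocGenerics::end(gr),
             name = nm, strand = std, stringsAsFactors = FALSE)
}

read_rm_out <- function(path) {
  lines <- readLines(path)
  # RepeatMasker .out: banner lines then whitespace-delimited rows whose
  # first field is the Smith-Waterman score (an integer)
  dat <- grepl("^\\s*[0-9]+\\s", lines)
  if (!any(dat)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  rows <- strsplit(trimws(lines[dat]), "\\s+")
  nfield <- lengths(rows)
  if (any(nfield < 11)) {
    stop("RepeatMasker .out parse error at line ",
         which(dat)[which(nfield < 11)[1]], ": expected >= 11 columns, got ",
         nfield[nfield < 11][1])
  }
  get <- function(i) vapply(rows, `[`, character(1), i)
  start1 <- suppressWarnings(as.integer(get(6)))
  end1 <- suppressWarnings(as.integer(get(7)))
  if (anyNA(start1) || anyNA(end1)) {
    stop("RepeatMasker .out parse error at line ",
         which(dat)[which(is.na(start1) | is.na(end1))[1]],
         ": non-numeric begin/end")
  }
  strand <- get(9)
  strand <- ifelse(strand == "C", "-", ifelse(strand == "+", "+", "."))
  data.frame(chrom = get(5),
             start = start1 - 1L,   # 1-based inclusive -> 0-based half-open
             end = end1,
             name = get(10), strand = strand, stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param intervals `data.frame` as returned by [read_intervals()]
#'   (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  std <- intervals$strand
  std[std == "."] <- "."
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   intervals$name, 0L, std)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
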