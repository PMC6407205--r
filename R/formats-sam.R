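#' Read a SAM file (subset of fields)
#'
#' Parses the plain-text SAM subset the package exchanges with mappers:
#' flags 0x1 (paired), 0x2 (proper pair), 0x4 (unmapped), 0x8 (mate
#' unmapped), 0x10/0x20 (read/mate reverse strand), 0x40/0x80 (first/second
#' of pair) are interpreted; CIGAR operations are restricted to
#' `M`, `I`, `D`, `S`. Coordinates are converted from SAM's 1-based
#' convention to the package-wide 0-based convention.
#'
#' @param path Path to a SAM file with header.
#' @return `data.frame` of aligned reads with columns `qname`, `mate`
#'   (1 or 2; 0 if unpaired), `mapped` (logical), `chrom`, `pos` (0-based
#'   leftmost; NA if unmapped), `strand`, `cigar`, `mapq`, `seq`,
#'   `mate_chrom`, `mate_pos`, `mate_strand`, `is_proper_pair`,
#'   `insert_size`.
#' @export
read_sam_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments())
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 11)) {
    stop("SAM parse error: fewer than 11 fields at record ",
         which(lengths(f) < 11)[1])
  }
  get <- function(i) vapply(f, `[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  seq <- toupper(get(10))
  mapped <- bitwAnd(flag, 4L) == 0L
  ops <- gsub("[0-9]", "", cigar)
  bad <- mapped & grepl("[^MIDS]", ops)
  if (any(bad)) {
    op <- regmatches(ops[bad][1], regexpr("[^MIDS]", ops[bad][1]))
    stop("unsupported CIGAR operation '", op, "' in read '", get(1)[bad][1], "'")
  }
  # CIGAR consistency: M + I + S must equal the sequence length
  qlen <- cigar_query_length(cigar)
  inc <- mapped & seq != "*" & !is.na(qlen) & qlen != nchar(seq)
  if (any(inc)) {
    stop("CIGAR/sequence length mismatch for read '", get(1)[inc][1], "'")
  }
  mapq <- as.integer(get(5))
  if (any(mapq < 0 | mapq > 60)) stop("MAPQ outside [0,60]")
  rnext <- get(7)
  mchrom <- ifelse(rnext == "=", get(3), rnext)
  mchrom[mchrom == "*"] <- NA_character_
  data.frame(
    qname = get(1),
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                  ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L)),
    mapped = mapped,
    chrom = ifelse(mapped, get(3), NA_character_),
    pos = ifelse(mapped, as.integer(get(4)) - 1L, NA_integer_),
    strand = ifelse(!mapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    cigar = ifelse(mapped, cigar, NA_character_),
    mapq = mapq,
    seq = seq,
    mate_chrom = mchrom,
    mate_pos = ifelse(bitwAnd(flag, 8L) > 0L, NA_integer_,
                      as.integer(get(8)) - 1L),
    mate_strand = ifelse(bitwAnd(flag, 8L) > 0L, NA_character_,
                         ifelse(bitwAnd(flag, 32L) > 0L, "-", "+")),
    is_proper_pair = bitwAnd(flag, 2L) > 0L,
    insert_size = as.integer(get(9)),
    stringsAsFactors = FALSE
  )
}

cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
    sum(n[op %in% c("M", "I", "S")])
  }, integer(1), USE.NAMES = FALSE)
}

empty_alignments <- function() {
  data.frame(qname = character(0), mate = integer(0), mapped = logical(0),
             chrom = character(0), pos = integer(0), strand = character(0),
             cigar = character(0), mapq = integer(0), seq = character(0),
             mate_chrom = character(0), mate_pos = integer(0),
             mate_strand = character(0), is_proper_pair = logical(0),
             insert_size = integer(0), stringsAsFactors = FALSE)
}

#' Write alignments as a SAM file (subset of fields)
#'
#' Inverse of [read_sam_subset()]. A minimal header with `@SQ` lines is
#' written from `reference` (or from `seq_lengths` when the reference
#' sequences themselves are not at hand).
#'
#' @param aln Alignment `data.frame` (see [read_sam_subset()]).
#' @param path Output path.
#' @param reference Optional named character vector of reference sequences.
#' @param seq_lengths Optional named integer vector of reference lengths.
#' @return `path`, invisibly.
#' @export
write_sam_subset <- function(aln, path, reference = NULL, seq_lengths = NULL) {
  if (is.null(seq_lengths) && !is.null(reference))
    seq_lengths <- stats::setNames(nchar(reference), names(reference))
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(seq_lengths)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                          as.integer(seq_lengths)))
  }
  flag <- rep(0L, nrow(aln))
  paired <- aln$mate %in% c(1L, 2L)
  flag <- flag + ifelse(paired, 1L, 0L)
  flag <- flag + ifelse(aln$is_proper_pair, 2L, 0L)
  flag <- flag + ifelse(!aln$mapped, 4L, 0L)
  flag <- flag + ifelse(paired & is.na(aln$mate_pos), 8L, 0L)
  flag <- flag + ifelse(aln$mapped & !is.na(aln$strand) & aln$strand == "-", 16L, 0L)
  flag <- flag + ifelse(!is.na(aln$mate_strand) & aln$mate_strand == "-", 32L, 0L)
  flag <- flag + ifelse(aln$mate == 1L, 64L, ifelse(aln$mate == 2L, 128L, 0L))
  same <- !is.na(aln$mate_chrom) & !is.na(aln$chrom) & aln$mate_chrom == aln$chrom
  rec <- paste(
    aln$qname, flag,
    ifelse(aln$mapped, aln$chrom, "*"),
    ifelse(aln$mapped, aln$pos + 1L, 0L),
    ifelse(aln$mapped, aln$mapq, 0L),
    ifelse(aln$mapped, aln$cigar, "*"),
    ifelse(is.na(aln$mate_chrom), "*", ifelse(same, "=", aln$mate_chrom)),
    ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos + 1L),
    ifelse(is.na(aln$insert_size), 0L, aln$insert_size),
    aln$seq, "*", sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}
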