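#' Majority-rule consensus from a multiple alignment
#'
#' Per alignment column the most frequent non-gap residue is taken; columns
#' in which the gap character is the strict majority are dropped from the
#' consensus. Ties between residues are broken alphabetically (A < C < G <
#' T) and logged.
#'
#' @param aligned Named character vector of equal-length gapped sequences
#'   (>= 2).
#' @param gene_intervals Optional `data.frame` (`gene`, `start`, `end`;
#'   1-based inclusive on the consensus) carried through to the model.
#' @param ltr_intervals Optional `data.frame` (`start`, `end`) of LTR spans
#'   on the consensus.
#' @return List of class `consensus_model`: `consensus_seq`,
#'   `gene_intervals`, `ltr_intervals`, `ties` (`data.frame` of tie
#'   columns and the residue chosen), `dropped_columns` (alignment columns
#'   removed as gap-majority).
#' @export
build_consensus <- function(aligned, gene_intervals = NULL,
                            ltr_intervals = NULL) {
  if (length(aligned) < 2) stop("need >= 2 sequences")
  if (length(unique(nchar(aligned))) != 1) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  ncol_a <- ncol(m)
  nseq <- nrow(m)
  cons <- character(0); ties <- list(); dropped <- integer(0)
  lvl <- c("A", "C", "G", "T", "N")
  for (j in seq_len(ncol_a)) {
    col <- m[, j]
    ngap <- sum(col == "-")
    if (ngap > nseq / 2) { dropped <- c(dropped, j); next }
    tab <- table(factor(col[col != "-"], levels = lvl))
    best <- which(tab == max(tab))
    if (length(best) > 1) {
      ties[[length(ties) + 1L]] <- data.frame(
        column = j, chosen = lvl[best[1]],
        tied = paste(lvl[best], collapse = "/"), stringsAsFactors = FALSE)
    }
    cons <- c(cons, lvl[best[1]])
  }
  structure(list(
    consensus_seq = paste(cons, collapse = ""),
    gene_intervals = gene_intervals,
    ltr_intervals = ltr_intervals,
    ties = if (length(ties)) do.call(rbind, ties) else
      data.frame(column = integer(0), chosen = character(0),
                 tied = character(0)),
    dropped_columns = dropped
  ), class = "consensus_model")
}

#' Find open reading frames on the forward strand
#'
#' Scans the three forward frames for ATG-initiated, stop-terminated spans
#' of at least `min_aa` codons. Overlapping ORFs in different frames are
#' all reported (proviral env genes commonly overlap the 3' end of pol in
#' an alternate frame).
#'
#' @param seq DNA sequence.
#' @param min_aa Minimum peptide length in amino acids (Met included, stop
#'   excluded).
#' @return `data.frame`: `start` (1-based first base of ATG), `end` (last
#'   base of the stop codon), `frame` (0-2), `aa_length`.
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (f in 0:2) {
    starts <- seq(1 + f, L - 2, by = 3)
    codons <- substring(seq, starts, starts + 2)
    is_stop <- codons %in% stops
    is_atg <- codons == "ATG"
    # segment between consecutive stops; first ATG of each segment opens
    # the maximal ORF
    seg <- cumsum(c(TRUE, utils::head(is_stop, -1)))
    for (s in split(seq_along(codons), seg)) {
      stop_i <- s[is_stop[s]][1]
      if (is.na(stop_i)) next
      atg_i <- s[is_atg[s] & s < stop_i][1]
      if (is.na(atg_i)) next
      aa <- stop_i - atg_i
      if (aa >= min_aa) {
        out[[length(out) + 1L]] <- data.frame(
          start = starts[atg_i], end = starts[stop_i] + 2L, frame = f,
          aa_length = aa)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), aa_length = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Catalog defects of a provirus against the consensus
#'
#' The provirus is globally aligned to the consensus and, within each gene
#' interval, indels are classified (`frameshift_indel` when the length is
#' not a multiple of 3, `inframe_indel` otherwise, `large_deletion` for
#' deletions of at least 100 bp) and premature stop codons are called by
#' translating the provirus gene sequence in the consensus reading frame.
#' Positions are reported 1-based on the consensus (`consensus_pos`), to
#' match the "bp from the consensus start" convention used for shared
#' defects.
#'
#' @param provirus_seq Provirus sequence.
#' @param consensus_model `consensus_model` with `gene_intervals`.
#' @param provirus_id Identifier recorded in the catalog.
#' @return `data.frame` of class `defect_catalog`: `provirus_id`, `kind`
#'   (`premature_stop`, `frameshift_indel`, `inframe_indel`,
#'   `large_deletion`), `consensus_pos`, `gene`, `length` (indel length; NA
#'   for stops), `truncated` attribute when the provirus aligns over less
#'   than half the consensus.
#' @export
catalog_defects <- function(provirus_seq, consensus_model,
                            provirus_id = "provirus") {
  cons <- consensus_model$consensus_seq
  genes <- consensus_model$gene_intervals
  if (is.null(genes)) stop("consensus model lacks gene intervals")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(provirus_seq, cons, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 6, gapExtension = 0.2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ac <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  cpos <- cumsum(ac != "-")          # consensus coordinate per column
  aligned_frac <- sum(ap != "-" & ac != "-") / nchar(cons)
  truncated <- aligned_frac < 0.5
  recs <- list()
  add <- function(kind, pos, gene, len = NA_integer_) {
    recs[[length(recs) + 1L]] <<- data.frame(
      provirus_id = provirus_id, kind = kind, consensus_pos = as.integer(pos),
      gene = gene, length = as.integer(len), stringsAsFactors = FALSE)
  }
  gene_at <- function(pos) {
    hit <- genes$gene[pos >= genes$start & pos <= genes$end]
    if (length(hit)) hit[1] else NA_character_
  }
  # indel events from alignment gap runs
  gap_p <- ap == "-"; gap_c <- ac == "-"
  for (run in gap_runs(gap_p)) {   # deletion in the provirus
    len <- run[2] - run[1] + 1L
    pos <- cpos[run[1]]
    g <- gene_at(pos)
    if (is.na(g)) next
    if (len >= 100L) add("large_deletion", pos, g, len)
    else if (len %% 3L != 0L) add("frameshift_indel", pos, g, len)
    else add("inframe_indel", pos, g, len)
  }
  for (run in gap_runs(gap_c)) {   # insertion in the provirus
    len <- run[2] - run[1] + 1L
    pos <- if (run[1] > 1) cpos[run[1] - 1L] else 0L
    g <- gene_at(pos)
    if (is.na(g)) next
    if (len %% 3L != 0L) add("frameshift_indel", pos, g, len)
    else add("inframe_indel", pos, g, len)
  }
  # premature stops: translate the provirus bases across each gene span in
  # the consensus frame
  stops <- c("TAA", "TAG", "TGA")
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    colsel <- which(cpos >= g$start & cpos <= g$end & ac != "-" |
                      (cpos >= g$start & cpos < g$end & ac == "-"))
    pseq <- ap[colsel]
    keep <- pseq != "-"
    pseq <- pseq[keep]
    col_of_base <- colsel[keep]
    if (length(pseq) < 6) next
    ncod <- length(pseq) %/% 3L
    codons <- vapply(seq_len(ncod), function(i)
      paste(pseq[(3 * i - 2):(3 * i)], collapse = ""), character(1))
    stop_idx <- which(codons %in% stops)
    # the gene's own terminator is the final codon; anything earlier is
    # premature
    stop_idx <- stop_idx[stop_idx < ncod]
    for (si in stop_idx) {
      col1 <- col_of_base[3 * si - 2]
      add("premature_stop", cpos[col1], g$gene)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(provirus_id = character(0), kind = character(0),
               consensus_pos = integer(0), gene = character(0),
               length = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$consensus_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  class(out) <- c("defect_catalog", class(out))
  out
}

gap_runs <- function(gap) {
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) c(starts[i], ends[i]))
}

#' Detect defects shared across proviruses
#'
#' Groups defects identical in kind, gene, and indel length whose consensus
#' positions agree within +/- 3 bp (single-linkage over sorted positions);
#' groups with at least two distinct proviruses are reported. Shared
#' inherited defects are the molecular signature of proliferation by trans
#' complementation of defective proviral genomes.
#'
#' @param catalogs A `defect_catalog` or list of them (rbind-ed).
#' @param pos_tol Position tolerance in bp.
#' @return `data.frame`: `kind`, `gene`, `length`, `consensus_pos` (median
#'   of member positions), `n_members`, `members` (comma-joined provirus
#'   ids), sorted by `consensus_pos`.
#' @export
find_shared_defects <- function(catalogs, pos_tol = 3L) {
  cat_all <- if (is.data.frame(catalogs)) catalogs else
    do.call(rbind, lapply(catalogs, as.data.frame))
  if (!nrow(cat_all)) {
    return(data.frame(kind = character(0), gene = character(0),
                      length = integer(0), consensus_pos = integer(0),
                      n_members = integer(0), members = character(0)))
  }
  key <- paste(cat_all$kind, cat_all$gene,
               ifelse(is.na(cat_all$length), "NA", cat_all$length))
  groups <- list()
  for (k in unique(key)) {
    d <- cat_all[key == k, , drop = FALSE]
    d <- d[order(d$consensus_pos), , drop = FALSE]
    brk <- c(0L, cumsum(diff(d$consensus_pos) > pos_tol))
    for (cl in split(seq_len(nrow(d)), brk)) {
      mem <- unique(d$provirus_id[cl])
      if (length(mem) < 2) next
      groups[[length(groups) + 1L]] <- data.frame(
        kind = d$kind[cl[1]], gene = d$gene[cl[1]], length = d$length[cl[1]],
        consensus_pos = as.integer(round(stats::median(d$consensus_pos[cl]))),
        n_members = length(mem), members = paste(mem, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(groups)) {
    return(data.frame(kind = character(0), gene = character(0),
                      length = integer(0), consensus_pos = integer(0),
                      n_members = integer(0), members = character(0)))
  }
  out <- do.call(rbind, groups)
  out <- out[order(out$consensus_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the recurrent env deletion subgroup
#'
#' Returns the proviruses whose catalog contains a large deletion in env
#' with length within `tol` bp of the expected recurrent deletion length
#' (canonically 1073 bp).
#'
#' @param catalogs A `defect_catalog` or list of them.
#' @param expected_len Expected deletion length (bp).
#' @param tol Length tolerance (bp).
#' @return `data.frame`: `provirus_id`, `consensus_pos`, `length`,
#'   `subgroup` (label `env_del<expected_len>`).
#' @export
detect_env_deletion <- function(catalogs, expected_len = 1073L, tol = 10L) {
  cat_all <- if (is.data.frame(catalogs)) catalogs else
    do.call(rbind, lapply(catalogs, as.data.frame))
  sel <- cat_all$kind == "large_deletion" & cat_all$gene == "env" &
    !is.na(cat_all$length) & abs(cat_all$length - expected_len) <= tol
  out <- cat_all[sel, c("provirus_id", "consensus_pos", "length")]
  out$subgroup <- rep(paste0("env_del", expected_len), nrow(out))
  rownames(out) <- NULL
  out
}
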