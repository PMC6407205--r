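#' Identify ERV-anchored read pairs
#'
#' Keeps pairs in which exactly one mate is mapped to the reference and the
#' unmapped mate matches the ERV consensus (LTR or internal) at
#' `min_identity` over at least `min_bp` bases. The mapped mate anchors the
#' insertion to a genomic neighborhood; the ERV-matching mate classifies it.
#'
#' @param alignments Alignment `data.frame` ([read_sam_subset()] layout;
#'   the bundled mapper's [map_read_pairs()] output works directly).
#' @param erv_consensus Named character vector with elements `ltr` and
#'   (optionally) `internal`.
#' @param min_identity Minimum identity of the mate against the consensus.
#' @param min_bp Minimum matched length.
#' @return `data.frame` of anchors: `qname`, `chrom`, `pos`, `strand`,
#'   `mapq` (the anchoring mate), `erv_part` (`ltr`/`internal`),
#'   `erv_identity`, `erv_bp`, `mate_seq`.
#' @export
find_anchor_pairs <- function(alignments, erv_consensus, min_identity = 0.9,
                              min_bp = 30L) {
  m1 <- alignments[alignments$mate == 1L, , drop = FALSE]
  m2 <- alignments[alignments$mate == 2L, , drop = FALSE]
  m2 <- m2[match(m1$qname, m2$qname), , drop = FALSE]
  one_mapped <- xor(m1$mapped, m2$mapped)
  m1 <- m1[one_mapped, , drop = FALSE]
  m2 <- m2[one_mapped, , drop = FALSE]
  if (!nrow(m1)) return(empty_anchors())
  anchor <- ifelse(m1$mapped, "m1", "m2")
  anc <- m1; anc[anchor == "m2", ] <- m2[anchor == "m2", ]
  mate <- m2; mate[anchor == "m2", ] <- m1[anchor == "m2", ]
  keep_len <- nchar(mate$seq) >= min_bp
  anc <- anc[keep_len, , drop = FALSE]; mate <- mate[keep_len, , drop = FALSE]
  if (!nrow(anc)) return(empty_anchors())
  cons_idx <- build_reference_index(erv_consensus,
                                    k = min(20L, min(nchar(erv_consensus))))
  hit <- map_reads(mate$seq, cons_idx, min_identity)
  ok <- hit$mapped & (nchar(mate$seq) - hit$nm) >= min_bp
  data.frame(qname = anc$qname[ok], chrom = anc$chrom[ok], pos = anc$pos[ok],
             strand = anc$strand[ok], mapq = anc$mapq[ok],
             erv_part = hit$chrom[ok],
             erv_identity = (nchar(mate$seq[ok]) - hit$nm[ok]) /
               nchar(mate$seq[ok]),
             erv_bp = nchar(mate$seq[ok]),
             mate_seq = mate$seq[ok], stringsAsFactors = FALSE)
}

empty_anchors <- function() {
  data.frame(qname = character(0), chrom = character(0), pos = integer(0),
             strand = character(0), mapq = integer(0), erv_part = character(0),
             erv_identity = numeric(0), erv_bp = integer(0),
             mate_seq = character(0), stringsAsFactors = FALSE)
}

#' Cluster anchored pairs into candidate insertion loci
#'
#' Single-linkage clustering of anchor positions within `window_bp`.
#' Clusters with fewer than `min_support` pairs are discarded; clusters
#' whose window intersects a known ERV annotation padded by `exclusion_bp`
#' are dropped with the reason recorded (they re-detect known elements).
#'
#' @param anchors Anchor `data.frame` from [find_anchor_pairs()].
#' @param known_erv_intervals Interval `data.frame` (0-based half-open) of
#'   annotated ERV elements, or NULL.
#' @param min_support Minimum supporting pairs per emitted candidate.
#' @param exclusion_bp Padding around known ERV annotations.
#' @param window_bp Single-linkage distance.
#' @return List: `candidates` (`candidate_id`, `chrom`, `window_start`,
#'   `window_end`, `support_pairs`) and `dropped` (with `reason`).
#' @export
cluster_candidates <- function(anchors, known_erv_intervals = NULL,
                               min_support = 2L, exclusion_bp = 500L,
                               window_bp = 200L) {
  empty <- data.frame(candidate_id = character(0), chrom = character(0),
                      window_start = integer(0), window_end = integer(0),
                      support_pairs = integer(0), stringsAsFactors = FALSE)
  if (!nrow(anchors)) return(list(candidates = empty,
                                  dropped = cbind(empty, reason = character(0))))
  anchors <- anchors[order(anchors$chrom, anchors$pos), , drop = FALSE]
  newc <- c(TRUE, diff(anchors$pos) > window_bp |
              anchors$chrom[-1] != anchors$chrom[-nrow(anchors)])
  cl <- cumsum(newc)
  rows <- lapply(split(seq_len(nrow(anchors)), cl), function(ix) {
    data.frame(chrom = anchors$chrom[ix[1]],
               window_start = min(anchors$pos[ix]),
               window_end = max(anchors$pos[ix]),
               support_pairs = length(unique(anchors$qname[ix])),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  cand <- cand[cand$support_pairs >= min_support, , drop = FALSE]
  if (!nrow(cand)) return(list(candidates = empty,
                               dropped = cbind(empty, reason = character(0))))
  cand$candidate_id <- sprintf("cand%03d", seq_len(nrow(cand)))
  cand <- cand[c("candidate_id", "chrom", "window_start", "window_end",
                 "support_pairs")]
  drop <- rep(FALSE, nrow(cand))
  if (!is.null(known_erv_intervals) && nrow(known_erv_intervals)) {
    for (i in seq_len(nrow(cand))) {
      k <- known_erv_intervals
      hit <- k$chrom == cand$chrom[i] &
        k$start - exclusion_bp < cand$window_end[i] &
        k$end + exclusion_bp > cand$window_start[i]
      drop[i] <- any(hit)
    }
  }
  dropped <- cand[drop, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "near_known_erv"
  else dropped$reason <- character(0)
  rownames(cand) <- rownames(dropped) <- NULL
  list(candidates = cand[!drop, , drop = FALSE], dropped = dropped)
}

# --- greedy overlap-layout-consensus assembler ------------------------------

BASES <- c("A", "C", "G", "T")

read_to_mat <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  m <- matrix(0L, nrow = 4L, ncol = length(ch), dimnames = list(BASES, NULL))
  hit <- match(ch, BASES)
  ok <- !is.na(hit)
  m[cbind(hit[ok], which(ok))] <- 1L
  m
}

mat_consensus <- function(m) {
  paste(BASES[max.col(t(m), ties.method = "first")], collapse = "")
}

mat_rc <- function(m) {
  m <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(m) <- BASES
  m
}

#' Greedy overlap-layout-consensus assembly of a read set
#'
#' Iteratively merges the highest-scoring suffix-prefix overlap of at least
#' `min_overlap` bases at identity `min_overlap_identity` or better,
#' considering reverse complements, until no merge is possible. The contig
#' consensus is the per-column majority over all merged reads, so sparse
#' sequencing errors are voted out.
#'
#' @param reads Character vector of read sequences.
#' @param min_overlap Minimum overlap length (bp).
#' @param min_overlap_identity Minimum overlap identity fraction.
#' @return Character vector of contig consensus sequences, longest first.
#'   Unmerged reads remain as singleton contigs.
#' @export
assemble_junction <- function(reads, min_overlap = 25L,
                              min_overlap_identity = 0.95) {
  reads <- toupper(reads[nchar(reads) > 0])
  if (!length(reads)) return(character(0))
  mats <- lapply(reads, read_to_mat)
  cons <- vapply(mats, mat_consensus, character(1))
  repeat {
    best <- find_best_overlap(cons, min_overlap, min_overlap_identity)
    if (is.null(best)) break
    a <- best$a; b <- best$b
    mb <- if (best$orient == "-") mat_rc(mats[[b]]) else mats[[b]]
    merged <- merge_mats(mats[[a]], mb, best$offset)
    keep <- setdiff(seq_along(mats), c(a, b))
    mats <- c(mats[keep], list(merged))
    cons <- c(cons[keep], mat_consensus(merged))
  }
  cons[order(-nchar(cons))]
}

# best pairwise overlap among contig consensus strings, or NULL.
# Anchoring: every suffix-prefix overlap of b onto a (in either
# orientation) places b's first k bases inside a, so only each contig's
# prefix k-mer (forward and reverse-complement) is queried against a
# positional k-mer table of all contigs. Candidates are verified lazily in
# order of decreasing possible overlap; since the verified score is at
# most the overlap length, the search stops as soon as no remaining
# candidate can beat the best verified merge.
find_best_overlap <- function(cons, min_overlap, min_identity, k = NULL) {
  n <- length(cons)
  if (n < 2) return(NULL)
  if (is.null(k)) k <- as.integer(min_overlap)
  Ls <- nchar(cons)
  idx_ok <- which(Ls >= k)
  if (length(idx_ok) < 2) return(NULL)
  st_list <- lapply(idx_ok, function(i) seq_len(Ls[i] - k + 1L))
  kmers <- unlist(lapply(seq_along(idx_ok), function(ii) {
    i <- idx_ok[ii]
    substring(cons[i], st_list[[ii]], st_list[[ii]] + k - 1L)
  }))
  kc <- rep(idx_ok, lengths(st_list))
  kp <- unlist(st_list)
  o <- order(kmers, method = "radix")
  kmers <- kmers[o]; kc <- kc[o]; kp <- kp[o]
  uk <- !duplicated(kmers)
  ukmer <- kmers[uk]
  gstart <- which(uk)
  gend <- c(gstart[-1] - 1L, length(kmers))
  rcs <- revcomp(cons[idx_ok])
  # queries: prefix k-mer of each contig, both orientations
  qa <- integer(0); qo <- character(0); qk <- character(0)
  for (ii in seq_along(idx_ok)) {
    qk <- c(qk, substr(cons[idx_ok[ii]], 1L, k), substr(rcs[ii], 1L, k))
    qa <- c(qa, idx_ok[ii], idx_ok[ii])
    qo <- c(qo, "+", "-")
  }
  m <- match(qk, ukmer)
  ca <- integer(0); cb <- integer(0); coff <- integer(0); cor <- character(0)
  for (qi in seq_along(m)) {
    if (is.na(m[qi])) next
    rows <- gstart[m[qi]]:gend[m[qi]]
    b <- qa[qi]
    sel <- kc[rows] != b
    if (!any(sel)) next
    ca <- c(ca, kc[rows][sel])
    cb <- c(cb, rep.int(b, sum(sel)))
    coff <- c(coff, kp[rows][sel] - 1L)   # 0-based start of b within a
    cor <- c(cor, rep.int(qo[qi], sum(sel)))
  }
  if (!length(ca)) return(NULL)
  dup <- duplicated(paste(ca, cb, coff, cor))
  ca <- ca[!dup]; cb <- cb[!dup]; coff <- coff[!dup]; cor <- cor[!dup]
  ov_max <- pmin(Ls[ca] - coff, Ls[cb])
  keep <- ov_max >= min_overlap
  if (!any(keep)) return(NULL)
  ca <- ca[keep]; cb <- cb[keep]; coff <- coff[keep]; cor <- cor[keep]
  ov_max <- ov_max[keep]
  ord <- order(-ov_max)
  best <- NULL
  for (i in ord) {
    if (!is.null(best) && best$score >= ov_max[i]) break
    sb <- if (cor[i] == "-") rcs[match(cb[i], idx_ok)] else cons[cb[i]]
    lo <- coff[i]; hi <- min(Ls[ca[i]], coff[i] + nchar(sb))
    ov <- hi - lo
    if (ov < min_overlap) next
    va <- utf8ToInt(substr(cons[ca[i]], lo + 1L, hi))
    vb <- utf8ToInt(substr(sb, 1L, ov))
    mm <- sum(va != vb)
    if ((ov - mm) / ov < min_identity) next
    score <- ov - mm
    if (is.null(best) || score > best$score) {
      best <- list(a = ca[i], b = cb[i], offset = coff[i], orient = cor[i],
                   score = score)
    }
  }
  best
}

merge_mats <- function(ma, mb, offset) {
  La <- ncol(ma); Lb <- ncol(mb)
  lo <- min(0L, offset)
  width <- max(La, offset + Lb) - lo
  m <- matrix(0L, nrow = 4L, ncol = width, dimnames = list(BASES, NULL))
  ia <- (1L - lo):(La - lo)
  ib <- (offset + 1L - lo):(offset + Lb - lo)
  m[, ia] <- m[, ia] + ma
  m[, ib] <- m[, ib] + mb
  m
}

# --- junction classification and breakpoint mapping -------------------------

#' Classify an assembled contig as an LTR-genome junction
#'
#' Locally aligns the contig (both orientations) to the LTR consensus and
#' requires at least `min_junction_bp` of LTR-derived and of genomic
#' (non-LTR) sequence. `side` is genome-relative: `five_prime` when genomic
#' sequence precedes the LTR on the contig, `three_prime` when it follows,
#' `full_ltr` when a (near-)complete LTR is flanked by genomic sequence on
#' both sides.
#'
#' @param contig Contig sequence (>= 60 bp to possibly satisfy both spans).
#' @param ltr_consensus LTR consensus sequence.
#' @param min_junction_bp Minimum LTR-derived and genomic span lengths.
#' @return List of class `junction_contig`: `contig_seq`, `ltr_span`
#'   (1-based on contig), `genomic_spans` (list `left`/`right`, NULL when
#'   absent), `side`, `ltr_orientation` (`+` if the contig carries the
#'   consensus strand of the LTR), or `NULL` with attribute `reason` when
#'   rejected.
#' @export
classify_junction <- function(contig, ltr_consensus, min_junction_bp = 30L) {
  reject <- function(reason) structure(list(NULL), class = "junction_reject",
                                       reason = reason)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  try_orient <- function(seq) {
    al <- Biostrings::pairwiseAlignment(seq, ltr_consensus, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 4, gapExtension = 0.5)
    rng <- al@pattern@range
    list(score = Biostrings::score(al),
         start = BiocGenerics::start(rng), end = BiocGenerics::end(rng))
  }
  fw <- try_orient(contig)
  rv <- try_orient(revcomp(contig))
  L <- nchar(contig)
  if (max(fw$score, rv$score) < min_junction_bp * 0.8)
    return(reject("no_ltr_match"))
  if (fw$score >= rv$score) {
    hit <- fw; orient <- "+"
  } else {
    # report spans in original contig coordinates
    hit <- list(score = rv$score, start = L - rv$end + 1L,
                end = L - rv$start + 1L)
    orient <- "-"
  }
  ltr_len <- hit$end - hit$start + 1L
  if (ltr_len < min_junction_bp) return(reject("ltr_span_too_short"))
  left <- hit$start - 1L
  right <- L - hit$end
  if (left < min_junction_bp && right < min_junction_bp)
    return(reject("entirely_ltr"))
  near_full <- ltr_len >= 0.9 * nchar(ltr_consensus)
  side <- if (near_full && left >= min_junction_bp && right >= min_junction_bp)
    "full_ltr"
  else if (left >= min_junction_bp && right < min_junction_bp) "five_prime"
  else if (right >= min_junction_bp && left < min_junction_bp) "three_prime"
  else if (left >= min_junction_bp && right >= min_junction_bp) "full_ltr"
  else return(reject("genomic_span_too_short"))
  structure(list(
    contig_seq = contig,
    ltr_span = c(hit$start, hit$end),
    genomic_spans = list(
      left = if (left >= min_junction_bp) c(1L, hit$start - 1L) else NULL,
      right = if (right >= min_junction_bp) c(hit$end + 1L, L) else NULL),
    side = side, ltr_orientation = orient
  ), class = "junction_contig")
}

#' Map junction contigs to the reference and resolve breakpoint and TSD
#'
#' Genomic spans of the classified junction contigs are mapped to the
#' reference; contigs assembled in reverse orientation are normalized to
#' the forward genome strand first. The breakpoint is reported as the
#' leftmost TSD start on the forward strand regardless of insertion
#' orientation. When both junctions are present the TSD is the
#' `tsd_length`-mer duplicated between the two genomic abutments (the
#' 5'-junction genomic end must equal the 3'-junction genomic start offset
#' by `tsd_length`); a mismatched duplication is reported as `tsd = NA`
#' with `tsd_ok = FALSE`.
#'
#' @param junctions List of `junction_contig` objects for one locus.
#' @param reference Named character vector, or an `erv_index`.
#' @param tsd_length TSD length.
#' @return List: `breakpoint` (0-based), `tsd`, `tsd_ok`, `orientation`,
#'   `n_junctions`, `ltr_allele_seq` (assembled LTR for full-LTR contigs,
#'   else NA), `chrom`; or `NULL` if no genomic span maps uniquely.
#' @export
locate_breakpoint_tsd <- function(junctions, reference, tsd_length = 5L) {
  index <- if (inherits(reference, "erv_index")) reference
  else build_reference_index(reference)
  ref <- index$reference
  ends5 <- integer(0); starts3 <- integer(0); chroms <- character(0)
  orientations <- character(0); ltr_seqs <- character(0)
  unmapped_flanks <- character(0)
  for (jc in junctions) {
    if (!inherits(jc, "junction_contig")) next
    norm <- normalize_junction(jc, index)
    if (is.null(norm)) next
    chroms <- c(chroms, norm$chrom)
    orientations <- c(orientations, norm$orientation)
    if (!is.null(norm$end5)) ends5 <- c(ends5, norm$end5)
    if (!is.null(norm$start3)) starts3 <- c(starts3, norm$start3)
    if (!is.na(norm$ltr_allele_seq)) ltr_seqs <- c(ltr_seqs,
                                                   norm$ltr_allele_seq)
    unmapped_flanks <- c(unmapped_flanks, norm$unmapped_flanks)
  }
  if (!length(chroms)) return(NULL)
  chrom <- names(sort(table(chroms), decreasing = TRUE))[1]
  orientation <- names(sort(table(orientations), decreasing = TRUE))[1]
  e5 <- if (length(ends5)) stats::median(ends5) else NA_real_
  s3 <- if (length(starts3)) stats::median(starts3) else NA_real_
  tsd <- NA_character_; tsd_ok <- NA
  if (!is.na(e5) && !is.na(s3)) {
    breakpoint <- as.integer(s3)
    tsd_ok <- (e5 - tsd_length) == s3
    if (tsd_ok) tsd <- substr(ref[[chrom]], breakpoint + 1L,
                              breakpoint + tsd_length)
  } else if (!is.na(e5)) {
    breakpoint <- as.integer(e5 - tsd_length)
  } else {
    breakpoint <- as.integer(s3)
  }
  list(breakpoint = breakpoint, tsd = tsd, tsd_ok = tsd_ok,
       orientation = orientation,
       n_junctions = as.integer(length(ends5) > 0) +
         as.integer(length(starts3) > 0),
       ltr_allele_seq = if (length(ltr_seqs))
         ltr_seqs[which.max(nchar(ltr_seqs))] else NA_character_,
       unmapped_flanks = unmapped_flanks,
       chrom = chrom)
}

# map a junction contig's non-LTR flanks to the reference; flip the contig
# if they map to the reverse strand; flanks that fail to map to the
# reference (e.g. internal proviral sequence at a provirus junction) are
# reported in `unmapped_flanks` instead of discarding the junction
normalize_junction <- function(jc, index, min_identity = 0.9) {
  span_seq <- function(contig, span) substr(contig, span[1], span[2])
  attempt <- function(contig, gs, ltr_orient) {
    end5 <- NULL; start3 <- NULL; chrom <- NULL
    unmapped <- character(0)
    n_mapped <- 0L
    if (!is.null(gs$left)) {
      sq <- span_seq(contig, gs$left)
      m <- map_read(sq, index, min_identity)
      if (!is.null(m) && m$strand == "+") {
        chrom <- m$chrom
        end5 <- m$pos + (gs$left[2] - gs$left[1] + 1L)
        n_mapped <- n_mapped + 1L
      } else unmapped <- c(unmapped, sq)
    }
    if (!is.null(gs$right)) {
      sq <- span_seq(contig, gs$right)
      m <- map_read(sq, index, min_identity)
      if (!is.null(m) && m$strand == "+" &&
          (is.null(chrom) || m$chrom == chrom)) {
        chrom <- m$chrom
        start3 <- m$pos
        n_mapped <- n_mapped + 1L
      } else unmapped <- c(unmapped, sq)
    }
    if (is.null(chrom)) return(NULL)
    list(chrom = chrom, end5 = end5, start3 = start3,
         orientation = ltr_orient, n_mapped = n_mapped,
         unmapped_flanks = unmapped)
  }
  gs <- jc$genomic_spans
  L <- nchar(jc$contig_seq)
  flip <- function(span) if (is.null(span)) NULL else
    c(L - span[2] + 1L, L - span[1] + 1L)
  gs_f <- list(left = flip(gs$right), right = flip(gs$left))
  orient_f <- if (jc$ltr_orientation == "+") "-" else "+"
  res_n <- attempt(jc$contig_seq, gs, jc$ltr_orientation)
  res_f <- attempt(revcomp(jc$contig_seq), gs_f, orient_f)
  use_flip <- is.null(res_n) ||
    (!is.null(res_f) && res_f$n_mapped > res_n$n_mapped)
  res <- if (use_flip) res_f else res_n
  if (is.null(res)) return(NULL)
  contig_use <- if (use_flip) revcomp(jc$contig_seq) else jc$contig_seq
  ltr_span_use <- if (use_flip) flip(jc$ltr_span) else jc$ltr_span
  # an assembled solo-LTR allele needs both flanks anchored in the genome
  res$ltr_allele_seq <- if (jc$side == "full_ltr" && res$n_mapped == 2L)
    substr(contig_use, ltr_span_use[1], ltr_span_use[2]) else NA_character_
  res
}

#' Scan alignments for deletion-supporting insert sizes at reference ERVs
#'
#' The proper-pair insert-size distribution (median and MAD) is estimated
#' from FR same-chromosome pairs with both mapping qualities at or above
#' `min_mapq`; pairs whose span exceeds `median + mad_cutoff * MAD` support
#' a deletion of the intervening sequence. Overlapping supports are merged,
#' the implied deletion size is the median supported span minus the median
#' insert, and only calls intersecting a known ERV annotation with a size
#' in the solo-LTR (400-500 bp) or provirus (7-9 kb) range are reported.
#'
#' @param alignments Alignment `data.frame` with both mates mapped
#'   ([map_read_pairs()] or [read_sam_subset()] output).
#' @param known_erv_intervals Interval `data.frame` (0-based half-open).
#' @param mad_cutoff MAD-score cutoff.
#' @param min_mapq Minimum mapping quality on both mates.
#' @param min_support Minimum supporting pairs per call.
#' @param solo_size_range,provirus_size_range Size-class windows (bp).
#' @return `data.frame`: `chrom`, `del_start`, `del_end` (0-based
#'   half-open merged inner span), `size` (implied deletion size),
#'   `size_class` (`solo_ltr`/`provirus`), `support_pairs`.
#' @export
scan_reference_deletions <- function(alignments, known_erv_intervals,
                                     mad_cutoff = 7, min_mapq = 20L,
                                     min_support = 2L,
                                     solo_size_range = c(400, 500),
                                     provirus_size_range = c(7000, 9000)) {
  m1 <- alignments[alignments$mate == 1L, , drop = FALSE]
  m2 <- alignments[alignments$mate == 2L, , drop = FALSE]
  m2 <- m2[match(m1$qname, m2$qname), , drop = FALSE]
  ok <- m1$mapped & m2$mapped & !is.na(m1$chrom) & !is.na(m2$chrom) &
    m1$chrom == m2$chrom & m1$strand != m2$strand &
    m1$mapq >= min_mapq & m2$mapq >= min_mapq
  ok[is.na(ok)] <- FALSE
  m1 <- m1[ok, , drop = FALSE]; m2 <- m2[ok, , drop = FALSE]
  if (nrow(m1) < 200L)
    stop("need >= 200 high-quality proper pairs to estimate the insert-size ",
         "distribution (got ", nrow(m1), ")")
  L1 <- nchar(m1$seq); L2 <- nchar(m2$seq)
  lo <- pmin(m1$pos, m2$pos)
  hi <- pmax(m1$pos + L1, m2$pos + L2)
  span <- hi - lo
  med <- stats::median(span)
  md <- stats::mad(span)
  thresh <- med + mad_cutoff * md
  sup <- span > thresh
  empty <- data.frame(chrom = character(0), del_start = integer(0),
                      del_end = integer(0), size = numeric(0),
                      size_class = character(0), support_pairs = integer(0),
                      stringsAsFactors = FALSE)
  if (!any(sup)) return(empty)
  # inner span between the mates is the putatively deleted interval
  inner_lo <- pmin(m1$pos + L1, m2$pos + L2)[sup]
  inner_hi <- pmax(m1$pos, m2$pos)[sup]
  chrom <- m1$chrom[sup]
  spans_sup <- span[sup]
  calls <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ir <- IRanges::IRanges(inner_lo[sel] + 1L, pmax(inner_hi[sel],
                                                    inner_lo[sel] + 1L))
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    for (g in seq_along(red)) {
      members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == g]
      if (length(members) < min_support) next
      size <- stats::median(spans_sup[sel][members]) - med
      size_class <- if (size >= solo_size_range[1] &&
                        size <= solo_size_range[2]) "solo_ltr"
      else if (size >= provirus_size_range[1] &&
               size <= provirus_size_range[2]) "provirus"
      else "other"
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch,
        del_start = BiocGenerics::start(red)[g] - 1L,
        del_end = BiocGenerics::end(red)[g],
        size = size, size_class = size_class,
        support_pairs = length(members), stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  # keep only calls at annotated ERVs in a plausible size class
  keep <- rep(FALSE, nrow(out))
  if (!is.null(known_erv_intervals) && nrow(known_erv_intervals)) {
    for (i in seq_len(nrow(out))) {
      k <- known_erv_intervals
      keep[i] <- any(k$chrom == out$chrom[i] & k$start < out$del_end[i] &
                       k$end > out$del_start[i])
    }
  }
  out <- out[keep & out$size_class != "other", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discover non-reference ERV insertions in a cohort
#'
#' End-to-end discovery: reads of every sample are mapped to the reference
#' with the bundled mapper, ERV-anchored pairs are pooled across samples
#' and clustered into candidate loci, reads around each candidate are
#' assembled, junction contigs classified against the LTR consensus, and
#' breakpoints with TSDs resolved against the reference.
#'
#' @param sample_pairs Named list (sample -> read-pair `data.frame` from
#'   [simulate_reads()]), or a single pooled `data.frame`.
#' @param reference Named character vector of chromosome sequences.
#' @param erv_consensus Named character vector with `ltr` and optionally
#'   `internal` consensus sequences.
#' @param known_erv_intervals Annotated ERV intervals (0-based), or NULL.
#' @param cfg [erv_config()].
#' @param max_assembly_reads Cap on reads fed to the assembler per
#'   candidate window.
#' @return List of class `erv_discovery`: `loci` (`data.frame`: `locus_id`,
#'   `chrom`, `breakpoint`, `orientation`, `tsd`, `tsd_ok`, `form`,
#'   `support_pairs`, `n_junctions`, `element_seq`, `element_filled`),
#'   `candidates`, `dropped`, `alignments` (per-sample list), `index`.
#' @export
discover_insertions <- function(sample_pairs, reference, erv_consensus,
                                known_erv_intervals = NULL,
                                cfg = erv_config(),
                                max_assembly_reads = 150L) {
  if (is.data.frame(sample_pairs)) sample_pairs <- list(pooled = sample_pairs)
  index <- build_reference_index(reference, cfg$map_k)
  alns <- lapply(sample_pairs, map_read_pairs, index = index,
                 min_identity = cfg$map_min_identity)
  pooled <- do.call(rbind, lapply(names(alns), function(s) {
    a <- alns[[s]]
    a$qname <- paste0(s, ":", a$qname)
    a
  }))
  anchors <- find_anchor_pairs(pooled, erv_consensus,
                               min_identity = cfg$min_identity,
                               min_bp = cfg$min_anchor_bp)
  cl <- cluster_candidates(anchors, known_erv_intervals,
                           min_support = cfg$min_support_pairs,
                           exclusion_bp = cfg$known_erv_exclusion_bp,
                           window_bp = cfg$assembly_window_bp)
  loci <- list()
  m1p <- pooled[pooled$mate == 1L, , drop = FALSE]
  m2p <- pooled[pooled$mate == 2L, , drop = FALSE]
  m2p <- m2p[match(m1p$qname, m2p$qname), , drop = FALSE]
  for (i in seq_len(nrow(cl$candidates))) {
    cand <- cl$candidates[i, ]
    ws <- cand$window_start - 150L
    we <- cand$window_end + 150L
    in_win <- function(m) m$mapped & !is.na(m$chrom) & m$chrom == cand$chrom &
      m$pos + nchar(m$seq) > ws & m$pos < we
    w1 <- in_win(m1p); w2 <- in_win(m2p)
    # unmapped mates anchored in the window carry the junctions and the
    # element; window-mapped reads only extend the genomic flanks, so they
    # must not crowd the junction reads out of the assembly budget
    un <- c(m2p$seq[w1 & !m2p$mapped], m1p$seq[w2 & !m1p$mapped])
    mp <- c(m1p$seq[w1 & m1p$mapped], m2p$seq[w2 & m2p$mapped])
    un <- un[!is.na(un)]; mp <- mp[!is.na(mp)]
    n_un <- min(length(un), max(as.integer(0.75 * max_assembly_reads), 1L))
    if (length(un) > n_un) un <- un[seq(1L, length(un), length.out = n_un)]
    n_mp <- min(length(mp), max_assembly_reads - length(un))
    if (length(mp) > n_mp && n_mp > 0)
      mp <- mp[seq(1L, length(mp), length.out = n_mp)]
    reads <- c(un, if (n_mp > 0) mp)
    contigs <- assemble_junction(reads, cfg$assembly_min_overlap,
                                 cfg$assembly_min_identity)
    contigs <- contigs[nchar(contigs) >= 2 * cfg$min_junction_bp]
    juncs <- list()
    for (ct in contigs) {
      jc <- classify_junction(ct, erv_consensus[["ltr"]],
                              cfg$min_junction_bp)
      if (inherits(jc, "junction_contig")) juncs[[length(juncs) + 1L]] <- jc
    }
    if (!length(juncs)) next
    loc <- locate_breakpoint_tsd(juncs, index, cfg$tsd_length)
    if (is.null(loc)) next
    anchors_here <- anchors$chrom == cand$chrom &
      anchors$pos >= cand$window_start & anchors$pos <= cand$window_end
    n_internal <- sum(anchors$erv_part[anchors_here] == "internal")
    # a junction flank that maps to the internal consensus rather than the
    # genome means the LTR abuts internal proviral sequence at this locus
    internal_adjacent <- FALSE
    if (length(loc$unmapped_flanks) && "internal" %in% names(erv_consensus)) {
      int_idx <- build_reference_index(
        c(internal = erv_consensus[["internal"]]), cfg$map_k)
      hits <- map_reads(loc$unmapped_flanks, int_idx, cfg$min_identity)
      internal_adjacent <- any(hits$mapped)
    }
    form <- if (internal_adjacent || n_internal >= cfg$min_support_pairs)
      "provirus" else "solo_ltr"
    filled <- is.na(loc$ltr_allele_seq)
    # element_seq is stored in consensus (forward) orientation; the
    # assembled allele lies on the forward genome strand, so flip it back
    # for reverse-orientation insertions
    element <- if (!filled) {
      if (loc$orientation == "-") revcomp(loc$ltr_allele_seq)
      else loc$ltr_allele_seq
    } else {
      if (form == "provirus" && "internal" %in% names(erv_consensus))
        paste0(erv_consensus[["ltr"]], erv_consensus[["internal"]],
               erv_consensus[["ltr"]])
      else erv_consensus[["ltr"]]
    }
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = cand$candidate_id, chrom = loc$chrom,
      breakpoint = loc$breakpoint, orientation = loc$orientation,
      tsd = loc$tsd, tsd_ok = loc$tsd_ok, form = form,
      support_pairs = cand$support_pairs, n_junctions = loc$n_junctions,
      element_seq = element, element_filled = filled,
      stringsAsFactors = FALSE)
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(locus_id = character(0), chrom = character(0),
               breakpoint = integer(0), orientation = character(0),
               tsd = character(0), tsd_ok = logical(0), form = character(0),
               support_pairs = integer(0), n_junctions = integer(0),
               element_seq = character(0), element_filled = logical(0),
               stringsAsFactors = FALSE)
  structure(list(loci = loci, candidates = cl$candidates,
                 dropped = cl$dropped, anchors = anchors,
                 alignments = alns, index = index),
            class = "erv_discovery")
}
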