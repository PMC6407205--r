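#' Build an exact k-mer seed index over a reference
#'
#' The bundled read mapper seeds alignments with exact k-mers taken from the
#' forward strand of every reference sequence, then scores candidate
#' placements by ungapped extension (match +1, mismatch -1). It exists so
#' the pipeline is exercisable end to end without an external aligner;
#' alignments from any mapper can be supplied instead as a SAM subset.
#'
#' @param reference Named character vector of reference sequences.
#' @param k Seed length.
#' @return An object of class `erv_index`.
#' @export
build_reference_index <- function(reference, k = 20L) {
  stopifnot(length(reference) >= 1, !is.null(names(reference)))
  kmers <- character(0); chrom <- integer(0); pos <- integer(0)
  for (ci in seq_along(reference)) {
    s <- reference[[ci]]
    L <- nchar(s)
    if (L < k) next
    st <- seq_len(L - k + 1L)
    kmers <- c(kmers, substring(s, st, st + k - 1L))
    chrom <- c(chrom, rep.int(ci, length(st)))
    pos <- c(pos, st - 1L)  # 0-based
  }
  o <- order(kmers, method = "radix")
  kmers <- kmers[o]; chrom <- chrom[o]; pos <- pos[o]
  uk <- !duplicated(kmers)
  structure(list(
    reference = reference, k = as.integer(k),
    chrom_names = names(reference),
    kmer = kmers[uk],
    start = which(uk),                       # run start in chrom/pos arrays
    len = diff(c(which(uk), length(kmers) + 1L)),
    chrom_arr = chrom, pos_arr = pos
  ), class = "erv_index")
}

# expand candidate seed placements for a vector of k-mers into parallel
# vectors (query index, chrom index, 0-based pos), capped per k-mer
lookup_kmers_flat <- function(index, kmers, cap = 16L) {
  m <- match(kmers, index$kmer)
  hit <- which(!is.na(m))
  if (!length(hit)) {
    return(list(query = integer(0), chrom = integer(0), pos = integer(0)))
  }
  mm <- m[hit]
  n <- pmin(index$len[mm], cap)
  rows <- sequence(n, from = index$start[mm])
  list(query = rep.int(hit, n),
       chrom = index$chrom_arr[rows],
       pos = index$pos_arr[rows])
}

# vectorized mismatch counts between equal-length string vectors
count_mismatches <- function(a, b) {
  L <- nchar(a)
  maxL <- if (length(L)) max(L) else 0L
  mm <- integer(length(a))
  for (i in seq_len(maxL)) {
    ai <- substr(a, i, i); bi <- substr(b, i, i)
    mm <- mm + (ai != bi & ai != "" & bi != "")
  }
  mm
}

#' Map reads to a reference by seed-and-extend
#'
#' Each read is seeded with exact k-mers at up to three offsets on both
#' strands; every seed placement is extended ungapped over the full read
#' (score = matches - mismatches) and the best placement is reported when
#' its identity reaches `min_identity`. The mapping-quality proxy is
#' `min(60, round(-10 * log10(max(1e-6, second_best/best))))`, 60 for
#' unique hits and 0 for placements tied with an equally good second hit.
#'
#' @param reads Character vector of read sequences.
#' @param index `erv_index` from [build_reference_index()].
#' @param min_identity Minimum fraction of matching bases.
#' @return `data.frame` with one row per read: `mapped`, `chrom`, `pos`
#'   (0-based leftmost), `strand`, `score`, `mapq` (the proxy above),
#'   `nm` (mismatches). Unmapped reads have NA coordinates.
#' @export
map_reads <- function(reads, index, min_identity = 0.9) {
  k <- index$k
  n <- length(reads)
  res <- data.frame(mapped = logical(n), chrom = NA_character_,
                    pos = NA_integer_, strand = NA_character_,
                    score = NA_real_, mapq = NA_integer_, nm = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!n) return(res)
  L <- nchar(reads)
  doable <- L >= k
  rc <- revcomp(reads)
  cand <- gather_candidates(reads, rc, index, which(doable))
  if (is.null(cand) || !nrow(cand)) return(res)
  # score candidates in bulk
  reflen <- nchar(index$reference)[cand$chrom_i]
  ok <- cand$pos >= 0L & cand$pos + L[cand$read_i] <= reflen
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(res)
  refseq <- substring(index$reference[cand$chrom_i], cand$pos + 1L,
                      cand$pos + L[cand$read_i])
  qry <- ifelse(cand$strand == "+", reads[cand$read_i], rc[cand$read_i])
  mm <- count_mismatches(qry, refseq)
  sc <- L[cand$read_i] - 2 * mm
  # best and second best per read (candidates were deduplicated by
  # placement in the gather step, so rank 2 is a genuinely distinct hit)
  o <- order(cand$read_i, -sc)
  ri <- cand$read_i[o]
  first <- !duplicated(ri)
  rank_in_read <- sequence(rle(ri)$lengths)
  second_idx <- which(rank_in_read == 2L)
  besti <- o[first]
  bscore <- sc[besti]
  ident <- (L[cand$read_i[besti]] - mm[besti]) / L[cand$read_i[besti]]
  keep <- ident >= min_identity
  rid <- cand$read_i[besti][keep]
  res$mapped[rid] <- TRUE
  res$chrom[rid] <- index$chrom_names[cand$chrom_i[besti][keep]]
  res$pos[rid] <- cand$pos[besti][keep]
  res$strand[rid] <- cand$strand[besti][keep]
  res$score[rid] <- bscore[keep]
  res$nm[rid] <- mm[besti][keep]
  # mapq proxy
  s2 <- rep(NA_real_, n)
  if (length(second_idx)) {
    oi <- o[second_idx]
    s2[cand$read_i[oi]] <- sc[oi]
  }
  b <- res$score[rid]; s2r <- s2[rid]
  ratio <- ifelse(is.na(s2r) | s2r <= 0, 1e-6,
                  pmax(1e-6, pmin(1, s2r / pmax(b, 1e-6))))
  res$mapq[rid] <- pmin(60L, as.integer(round(-10 * log10(ratio))))
  res
}

# collect deduplicated candidate placements (read_i, chrom_i, pos, strand)
gather_candidates <- function(reads, rc, index, idx) {
  if (!length(idx)) return(NULL)
  k <- index$k
  L <- nchar(reads)[idx]
  ri <- list(); ci <- list(); po <- list(); st <- list()
  off_mat <- cbind(0L, pmax(as.integer(L / 2) - as.integer(k / 2), 0L), L - k)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") reads[idx] else rc[idx]
    for (oi in 1:3) {
      off <- pmin(off_mat[, oi], L - k)
      seeds <- substring(q, off + 1L, off + k)
      h <- lookup_kmers_flat(index, seeds)
      if (!length(h$query)) next
      ri[[length(ri) + 1L]] <- idx[h$query]
      ci[[length(ci) + 1L]] <- h$chrom
      po[[length(po) + 1L]] <- h$pos - off[h$query]
      st[[length(st) + 1L]] <- rep.int(strand, length(h$query))
    }
  }
  if (!length(ri)) return(NULL)
  cand <- data.frame(read_i = unlist(ri), chrom_i = unlist(ci),
                     pos = unlist(po), strand = unlist(st),
                     stringsAsFactors = FALSE)
  key <- paste(cand$read_i, cand$chrom_i, cand$pos, cand$strand)
  cand[!duplicated(key), , drop = FALSE]
}

#' Map a single read
#'
#' Single-read convenience wrapper around [map_reads()].
#'
#' @param read_seq Read sequence.
#' @param reference_index `erv_index`.
#' @param min_identity Minimum identity fraction.
#' @return List `(chrom, pos, strand, score, mapq)` or `NULL` when the read
#'   is unmapped (including reads shorter than the seed length).
#' @export
map_read <- function(read_seq, reference_index, min_identity = 0.9) {
  r <- map_reads(read_seq, reference_index, min_identity)
  if (!r$mapped[1]) return(NULL)
  list(chrom = r$chrom[1], pos = r$pos[1], strand = r$strand[1],
       score = r$score[1], mapq = r$mapq[1])
}

#' Map simulated read pairs against a reference
#'
#' Maps both mates of every pair and derives pairing fields (proper-pair
#' flag by FR orientation on one chromosome within `max_insert`; signed
#' insert size as rightmost end minus leftmost start).
#'
#' @param pairs `data.frame` from [simulate_reads()] (columns `qname`,
#'   `seq1`, `seq2`).
#' @param index `erv_index`.
#' @param min_identity Minimum identity for a mate to map.
#' @param max_insert Pairs spanning more than this are not "proper".
#' @return Alignment `data.frame` in [read_sam_subset()] layout.
#' @export
map_read_pairs <- function(pairs, index, min_identity = 0.9,
                           max_insert = 10000L) {
  m1 <- map_reads(pairs$seq1, index, min_identity)
  m2 <- map_reads(pairs$seq2, index, min_identity)
  mk <- function(m, mate, seqs, other) {
    L <- nchar(seqs)
    Lo <- nchar(other$seq)
    data.frame(
      qname = pairs$qname, mate = mate, mapped = m$mapped,
      chrom = m$chrom, pos = m$pos, strand = m$strand,
      cigar = ifelse(m$mapped, paste0(L, "M"), NA_character_),
      mapq = ifelse(m$mapped, m$mapq, 0L),
      seq = seqs,
      mate_chrom = other$m$chrom, mate_pos = other$m$pos,
      mate_strand = other$m$strand,
      is_proper_pair = FALSE, insert_size = 0L,
      score = m$score, stringsAsFactors = FALSE)
  }
  a1 <- mk(m1, 1L, pairs$seq1, list(m = m2, seq = pairs$seq2))
  a2 <- mk(m2, 2L, pairs$seq2, list(m = m1, seq = pairs$seq1))
  both <- m1$mapped & m2$mapped & !is.na(m1$chrom) & !is.na(m2$chrom) &
    m1$chrom == m2$chrom & m1$strand != m2$strand
  lo <- pmin(m1$pos, m2$pos)
  hi <- pmax(m1$pos + nchar(pairs$seq1), m2$pos + nchar(pairs$seq2))
  span <- hi - lo
  proper <- both & span <= max_insert &
    ifelse(m1$strand == "+", m1$pos <= m2$pos, m2$pos <= m1$pos)
  proper[is.na(proper)] <- FALSE
  sign1 <- ifelse(!is.na(m1$strand) & m1$strand == "+", 1L, -1L)
  a1$is_proper_pair <- proper
  a2$is_proper_pair <- proper
  a1$insert_size <- ifelse(proper, sign1 * span, 0L)
  a2$insert_size <- ifelse(proper, -sign1 * span, 0L)
  rbind(a1, a2)
}
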