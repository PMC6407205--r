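#' Reconstruct insertion and pre-insertion alleles for a locus
#'
#' Both alleles carry the identical outer flanks (+/- `flank_bp` around the
#' insertion point). For a non-reference insertion the reference allele is
#' the unoccupied site with a single TSD copy and the alternate allele
#' carries the element between duplicated TSDs; for a reference insertion
#' the roles are swapped (the assembly carries the insertion and the
#' alternate allele is the excision leaving one TSD copy).
#'
#' @param locus One-row `data.frame` (or list) with `locus_id`, `chrom`,
#'   `breakpoint` (0-based TSD start in unoccupied coordinates for
#'   non-reference loci; for reference loci, the 0-based TSD start of the
#'   occupied reference), `orientation`, and for reference loci
#'   `element_end` (0-based end of the second TSD copy in the reference).
#' @param reference Named character vector of chromosome sequences.
#' @param element_seq Element sequence in forward (consensus) orientation;
#'   for non-reference loci with unresolved interior, pass the portions you
#'   have and set `fill_consensus`.
#' @param fill_consensus Optional consensus used to fill an unresolved
#'   interior (sets `element_filled`).
#' @param is_reference_locus Whether the reference assembly carries the
#'   insertion.
#' @param flank_bp Flank length on both sides.
#' @param tsd_length TSD length.
#' @return List of class `allele_pair`: `locus_id`, `ref_allele_seq`,
#'   `alt_allele_seq`, `element_filled`, `breakpoint`, `junctions` (0-based
#'   positions of the discriminating junctions on each allele), and
#'   `internal_interval` (0-based span of the element's internal, non-LTR
#'   portion on the insertion-carrying allele, or NULL).
#' @export
reconstruct_alleles <- function(locus, reference, element_seq = NULL,
                                fill_consensus = NULL,
                                is_reference_locus = FALSE,
                                flank_bp = 600L, tsd_length = 5L) {
  ch <- locus$chrom; b <- locus$breakpoint
  s <- reference[[ch]]
  if (is.null(s)) stop("chromosome ", ch, " not in reference")
  element_filled <- FALSE
  if (is.null(element_seq)) {
    if (is.null(fill_consensus)) stop("unfillable: no element and no consensus")
    element_seq <- fill_consensus
    element_filled <- TRUE
  }
  if (!is_reference_locus) {
    if (b < flank_bp || b + tsd_length + flank_bp > nchar(s))
      stop("breakpoint too close to a chromosome end for ", flank_bp,
           " bp flanks")
    el <- if (!is.null(locus$orientation) && locus$orientation == "-")
      revcomp(element_seq) else element_seq
    ref_allele <- substr(s, b - flank_bp + 1L, b + tsd_length + flank_bp)
    alt_allele <- paste0(substr(s, b - flank_bp + 1L, b + tsd_length),
                         el,
                         substr(s, b + 1L, b + tsd_length + flank_bp))
    junctions <- list(ref = flank_bp + tsd_length,
                      alt = c(flank_bp + tsd_length,
                              flank_bp + tsd_length + nchar(el)))
    insertion_allele <- "alt"
    el_len <- nchar(el)
  } else {
    # reference carries: flank | TSD | element | TSD | flank
    e <- locus$element_end
    if (is.null(e)) stop("reference locus needs element_end")
    if (b < flank_bp || e + flank_bp > nchar(s))
      stop("locus too close to a chromosome end for ", flank_bp, " bp flanks")
    ref_allele <- substr(s, b - flank_bp + 1L, e + flank_bp)
    alt_allele <- paste0(substr(s, b - flank_bp + 1L, b + tsd_length),
                         substr(s, e + 1L, e + flank_bp))
    junctions <- list(ref = c(flank_bp + tsd_length,
                              flank_bp + (e - b) - tsd_length),
                      alt = flank_bp + tsd_length)
    insertion_allele <- "ref"
    el_len <- e - b - 2L * tsd_length
  }
  internal_interval <- NULL
  ltr_len <- attr(element_seq, "ltr_length")
  if (!is.null(ltr_len) && el_len > 2L * ltr_len) {
    off <- flank_bp + tsd_length
    internal_interval <- c(off + ltr_len, off + el_len - ltr_len)
  }
  structure(list(locus_id = locus$locus_id,
                 ref_allele_seq = ref_allele, alt_allele_seq = alt_allele,
                 element_filled = element_filled,
                 breakpoint = b, chrom = ch,
                 insertion_allele = insertion_allele,
                 junctions = junctions,
                 internal_interval = internal_interval),
            class = "allele_pair")
}

#' Assign read pairs to the alleles of a locus
#'
#' Both mates of each pair are mapped to both allele sequences; the pair
#' supports the allele with the higher summed alignment score. Ties are
#' uninformative and dropped; pairs with both mates wholly inside the
#' element's internal interval on the insertion-carrying allele are dropped
#' (reads from other element copies elsewhere in the genome would mimic
#' them); a supporting pair must overlap a discriminating junction of its
#' allele by at least one base on each side.
#'
#' @param pairs `data.frame` with `qname`, `seq1`, `seq2`.
#' @param allele_pair `allele_pair` from [reconstruct_alleles()].
#' @param min_identity Mapper identity threshold.
#' @return `data.frame`: `qname`, `allele` (`ref`/`alt`/`none`), `mapq`,
#'   `score_ref`, `score_alt`, `reason` for dropped pairs.
#' @export
assign_reads <- function(pairs, allele_pair, min_identity = 0.9) {
  if (!nrow(pairs)) {
    return(data.frame(qname = character(0), allele = character(0),
                      mapq = integer(0), score_ref = numeric(0),
                      score_alt = numeric(0), reason = character(0)))
  }
  idx_ref <- build_reference_index(c(ref = allele_pair$ref_allele_seq))
  idx_alt <- build_reference_index(c(alt = allele_pair$alt_allele_seq))
  score_on <- function(idx) {
    m1 <- map_reads(pairs$seq1, idx, min_identity)
    m2 <- map_reads(pairs$seq2, idx, min_identity)
    list(m1 = m1, m2 = m2,
         total = ifelse(m1$mapped, m1$score, 0) +
           ifelse(m2$mapped, m2$score, 0))
  }
  r <- score_on(idx_ref)
  a <- score_on(idx_alt)
  n <- nrow(pairs)
  allele <- rep("none", n)
  reason <- rep(NA_character_, n)
  mapq <- rep(NA_integer_, n)
  spans_junction <- function(m, seqs, juncs) {
    # junction j sits between 0-based positions j-1 and j; require >= 1
    # aligned base on each side
    ok <- rep(FALSE, nrow(m))
    for (j in juncs) {
      ok <- ok | (m$mapped & !is.na(m$pos) & m$pos < j &
                    m$pos + nchar(seqs) > j)
    }
    ok
  }
  jr <- allele_pair$junctions$ref
  ja <- allele_pair$junctions$alt
  ref_j <- spans_junction(r$m1, pairs$seq1, jr) |
    spans_junction(r$m2, pairs$seq2, jr)
  alt_j <- spans_junction(a$m1, pairs$seq1, ja) |
    spans_junction(a$m2, pairs$seq2, ja)
  # internal-internal exclusion on the insertion-carrying allele
  ii <- allele_pair$internal_interval
  internal_both <- rep(FALSE, n)
  if (!is.null(ii)) {
    mm <- if (allele_pair$insertion_allele == "alt") a else r
    inside <- function(m, seqs) m$mapped & m$pos >= ii[1] &
      m$pos + nchar(seqs) <= ii[2]
    internal_both <- inside(mm$m1, pairs$seq1) & inside(mm$m2, pairs$seq2)
  }
  for (i in seq_len(n)) {
    if (internal_both[i]) { reason[i] <- "internal_internal"; next }
    if (r$total[i] == a$total[i]) { reason[i] <- "uninformative_tie"; next }
    win <- if (r$total[i] > a$total[i]) "ref" else "alt"
    jok <- if (win == "ref") ref_j[i] else alt_j[i]
    if (!jok) { reason[i] <- "no_junction_overlap"; next }
    allele[i] <- win
    m <- if (win == "ref") r else a
    q <- c(m$m1$mapq[i], m$m2$mapq[i])
    mapq[i] <- if (all(is.na(q))) 0L else max(q, na.rm = TRUE)
  }
  data.frame(qname = pairs$qname, allele = allele, mapq = mapq,
             score_ref = r$total, score_alt = a$total, reason = reason,
             stringsAsFactors = FALSE)
}

#' Select a sample's candidate read pairs for one locus
#'
#' Pairs with either mate mapped within `window` bp of the breakpoint, or
#' unmapped with its mate in that window, are candidates for remapping to
#' the locus's allele pair.
#'
#' @param alignments Sample alignment `data.frame` (vs. the reference).
#' @param pairs The sample's read-pair `data.frame` (`qname`, `seq1`,
#'   `seq2`).
#' @param chrom,breakpoint Locus position (0-based).
#' @param window Candidate window half-width (bp).
#' @return Subset of `pairs`.
#' @export
locus_candidate_pairs <- function(alignments, pairs, chrom, breakpoint,
                                  window = 700L) {
  lo <- breakpoint - window; hi <- breakpoint + window
  near <- alignments$mapped & !is.na(alignments$chrom) &
    alignments$chrom == chrom &
    alignments$pos + nchar(alignments$seq) > lo & alignments$pos < hi
  qn_near <- unique(alignments$qname[near])
  pairs[pairs$qname %in% qn_near, , drop = FALSE]
}

#' Genotype likelihoods from allele-supporting read pairs
#'
#' Per supporting observation with mapping quality `q`, the error
#' probability is `e = 10^(-q/10)`; the observation has probability `1 - e`
#' under the homozygote matching its supported allele, `e` under the other
#' homozygote, and `1/2` under the heterozygote. Log10 likelihoods are
#' summed; the genotype is the maximum-likelihood one (no prior). With no
#' informative observations the call is missing (`./.`).
#'
#' @param ref_reads,alt_reads Counts of pairs supporting each allele.
#' @param mapqs Integer vector of mapping qualities, ref-supporting first,
#'   length `ref_reads + alt_reads`.
#' @param sample_id,locus_id Identifiers carried into the call.
#' @return `data.frame` (one row): `sample_id`, `locus_id`, `gt`, `gl_rr`,
#'   `gl_ra`, `gl_aa`, `ad_ref`, `ad_alt`.
#' @export
genotype_likelihoods <- function(ref_reads, alt_reads, mapqs,
                                 sample_id = "sample", locus_id = "locus") {
  stopifnot(ref_reads >= 0, alt_reads >= 0)
  if (length(mapqs) != ref_reads + alt_reads)
    stop("mapq list length must equal read count")
  if (ref_reads + alt_reads == 0) {
    return(data.frame(sample_id = sample_id, locus_id = locus_id, gt = "./.",
                      gl_rr = NA_real_, gl_ra = NA_real_, gl_aa = NA_real_,
                      ad_ref = 0L, ad_alt = 0L, stringsAsFactors = FALSE))
  }
  eps <- pmax(10^(-mapqs / 10), 1e-6)
  is_ref <- c(rep(TRUE, ref_reads), rep(FALSE, alt_reads))
  gl_rr <- sum(log10(ifelse(is_ref, 1 - eps, eps)))
  gl_aa <- sum(log10(ifelse(is_ref, eps, 1 - eps)))
  gl_ra <- (ref_reads + alt_reads) * log10(0.5)
  gts <- c("0/0", "0/1", "1/1")
  gt <- gts[which.max(c(gl_rr, gl_ra, gl_aa))]
  data.frame(sample_id = sample_id, locus_id = locus_id, gt = gt,
             gl_rr = gl_rr, gl_ra = gl_ra, gl_aa = gl_aa,
             ad_ref = as.integer(ref_reads), ad_alt = as.integer(alt_reads),
             stringsAsFactors = FALSE)
}

#' Genotype a cohort at a set of loci and summarize allele frequencies
#'
#' For each locus, candidate read pairs per sample are remapped to the
#' reconstructed allele pair, pairs are assigned to alleles, genotype
#' likelihoods computed, and per-population insertion-allele frequencies
#' estimated over genotyped samples only. Loci flagged unsuitable
#' (mismatched TSD, single junction, encompassing duplication) are skipped
#' with a reason.
#'
#' @param allele_pairs List of `allele_pair` objects (one per locus).
#' @param sample_pairs Named list (sample id -> `data.frame` of candidate
#'   read pairs with `qname`, `seq1`, `seq2`) or a function
#'   `(sample_id, locus_id) -> data.frame`.
#' @param population_table `data.frame` with `sample_id`, `population`.
#' @param skip `data.frame` with `locus_id`, `reason` for loci excluded
#'   from genotyping (may be empty).
#' @param min_identity Mapper identity threshold.
#' @return List of class `cohort_genotypes`: `calls` (all per-sample calls),
#'   `frequencies` (`locus_id`, `population`, `alt_count`, `total_alleles`,
#'   `frequency`; the insertion allele is counted whether or not it is the
#'   reference allele), `skipped`.
#' @export
cohort_genotype <- function(allele_pairs, sample_pairs, population_table,
                            skip = NULL, min_identity = 0.9) {
  samples <- population_table$sample_id
  miss <- if (is.list(sample_pairs) && !is.function(sample_pairs))
    setdiff(names(sample_pairs), samples) else character(0)
  if (length(miss)) stop("sample(s) absent from population table: ",
                         paste(miss, collapse = ", "))
  calls <- list()
  for (ap in allele_pairs) {
    for (s in samples) {
      pr <- if (is.function(sample_pairs)) sample_pairs(s, ap$locus_id)
      else sample_pairs[[s]]
      asn <- assign_reads(pr, ap, min_identity)
      nref <- sum(asn$allele == "ref")
      nalt <- sum(asn$allele == "alt")
      mq <- c(asn$mapq[asn$allele == "ref"], asn$mapq[asn$allele == "alt"])
      calls[[length(calls) + 1L]] <-
        genotype_likelihoods(nref, nalt, mq, s, ap$locus_id)
    }
  }
  calls <- do.call(rbind, calls)
  # allele frequencies per population: count insertion alleles
  ins_is_alt <- vapply(allele_pairs, function(ap)
    ap$insertion_allele == "alt", logical(1))
  names(ins_is_alt) <- vapply(allele_pairs, `[[`, character(1), "locus_id")
  freq <- list()
  for (lc in names(ins_is_alt)) {
    cc <- calls[calls$locus_id == lc & calls$gt != "./.", , drop = FALSE]
    pop <- population_table$population[match(cc$sample_id,
                                             population_table$sample_id)]
    alt_copies <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[cc$gt]
    ins_copies <- if (ins_is_alt[lc]) alt_copies else 2L - alt_copies
    for (p in unique(population_table$population)) {
      sel <- pop == p
      tot <- 2L * sum(sel)
      freq[[length(freq) + 1L]] <- data.frame(
        locus_id = lc, population = p,
        alt_count = as.integer(sum(ins_copies[sel])),
        total_alleles = as.integer(tot),
        frequency = if (tot > 0) sum(ins_copies[sel]) / tot else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(calls = calls,
                 frequencies = do.call(rbind, freq),
                 skipped = if (is.null(skip))
                   data.frame(locus_id = character(0), reason = character(0))
                 else skip),
            class = "cohort_genotypes")
}

#' Build the VCF locus table for a set of discovered or annotated loci
#'
#' Convenience bridge from a discovery table to [write_vcf()]: looks up the
#' reference base at each breakpoint and sets the symbolic ALT class
#' (`INS` for non-reference insertions, `DEL` for unfixed reference loci).
#'
#' @param loci `data.frame` with `locus_id`, `chrom`, `breakpoint`, and
#'   optionally `tsd`, `form`, `is_reference_locus`.
#' @param reference Named character vector of chromosome sequences.
#' @return `data.frame` suitable as the `loci` argument of [write_vcf()].
#' @export
loci_vcf_table <- function(loci, reference) {
  data.frame(
    locus_id = loci$locus_id, chrom = loci$chrom, pos = loci$breakpoint,
    ref_base = substr_vec(reference[loci$chrom], loci$breakpoint + 1L,
                          loci$breakpoint + 1L),
    svtype = if (!is.null(loci$is_reference_locus))
      ifelse(loci$is_reference_locus, "DEL", "INS") else "INS",
    tsd = if (!is.null(loci$tsd)) loci$tsd else NA_character_,
    form = if (!is.null(loci$form)) loci$form else NA_character_,
    stringsAsFactors = FALSE)
}

#' Overall insertion-allele frequency across genotyped samples
#'
#' @param n_insertion_alleles Insertion-allele count.
#' @param n_genotyped_samples Diploid samples genotyped at the locus.
#' @return Frequency in percent.
#' @examples
#' overall_frequency_percent(1, 347)  # 0.14 (single heterozygote)
#' @export
overall_frequency_percent <- function(n_insertion_alleles,
                                      n_genotyped_samples) {
  100 * n_insertion_alleles / (2 * n_genotyped_samples)
}
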