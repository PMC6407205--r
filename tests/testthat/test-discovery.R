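test_that("seed-and-extend mapper places reads with sensible map quality", {
  ref <- fx_reference()
  idx <- build_reference_index(ref)
  read <- substr(ref[["chrA"]], 5001, 5100)
  m <- map_read(read, idx)
  expect_identical(m$chrom, "chrA")
  expect_identical(m$pos, 5000L)
  expect_identical(m$mapq, 60L)

  # reverse-complement placement
  mrc <- map_read(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read))), idx)
  expect_identical(mrc$pos, 5000L)
  expect_identical(mrc$strand, "-")

  # sequence absent from the reference, and reads shorter than the seed
  expect_null(map_read(strrep("AT", 50), idx))
  expect_null(map_read("ACGTACGT", idx))

  # a read matching two identical loci equally has map quality 0
  twin <- c(chr1 = paste0(substr(ref[["chrA"]], 1, 500), "TTTT",
                          substr(ref[["chrA"]], 1, 500)))
  m2 <- map_read(substr(ref[["chrA"]], 101, 200),
                 build_reference_index(twin))
  expect_identical(m2$mapq, 0L)
})

test_that("anchor pairs require one genome mate and one ERV-matching mate", {
  cons <- fx_consensus()
  mk_aln <- function(qname, mate, mapped, seq, chrom = "chr1", pos = 1000L) {
    data.frame(qname = qname, mate = mate, mapped = mapped,
               chrom = ifelse(mapped, chrom, NA), pos = ifelse(mapped, pos, NA),
               strand = ifelse(mapped, "+", NA), cigar = NA, mapq = 60L,
               seq = seq, mate_chrom = NA, mate_pos = NA, mate_strand = NA,
               is_proper_pair = FALSE, insert_size = 0L,
               stringsAsFactors = FALSE)
  }
  genome_read <- strrep("ACGGT", 20)
  ltr_read <- substr(cons$ltr, 101, 200)
  junk <- paste0(substr(cons$ltr, 101, 150), strrep("TA", 25))  # 50% LTR
  aln <- rbind(
    mk_aln("p1", 1L, TRUE, genome_read), mk_aln("p1", 2L, FALSE, ltr_read),
    mk_aln("p2", 1L, TRUE, genome_read), mk_aln("p2", 2L, TRUE, genome_read),
    mk_aln("p3", 1L, TRUE, genome_read), mk_aln("p3", 2L, FALSE, junk))
  anc <- find_anchor_pairs(aln, c(ltr = cons$ltr, internal = cons$internal))
  expect_identical(anc$qname, "p1")
  expect_identical(anc$erv_part, "ltr")
  expect_gte(anc$erv_identity, 0.9)
})

test_that("candidate clustering enforces support and known-ERV exclusion", {
  anc <- data.frame(qname = c("a", "b", "c", "d"),
                    chrom = "chr1", pos = c(1000L, 1100L, 1150L, 9000L),
                    strand = "+", mapq = 60L, erv_part = "ltr",
                    erv_identity = 1, erv_bp = 100L, mate_seq = "A",
                    stringsAsFactors = FALSE)
  cl <- cluster_candidates(anc, min_support = 2)
  expect_identical(nrow(cl$candidates), 1L)  # singleton at 9000 discarded
  expect_identical(cl$candidates$support_pairs, 3L)

  # a cluster 300 bp from an annotated ERV is dropped with a reason
  known <- data.frame(chrom = "chr1", start = 1450L, end = 1900L,
                      name = "CfERVF1_LTR", strand = "+")
  cl2 <- cluster_candidates(anc, known, min_support = 2)
  expect_identical(nrow(cl2$candidates), 0L)
  expect_identical(cl2$dropped$reason, "near_known_erv")
})

test_that("greedy assembly merges true overlaps and respects identity", {
  withr::with_seed(30, {
    base <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                  collapse = "")
  })
  r1 <- substr(base, 1, 60)
  r2 <- substr(base, 31, 90)
  out <- assemble_junction(c(r1, r2), min_overlap = 25)
  expect_identical(out, base)

  # no sufficient overlap: reads stay separate
  out2 <- assemble_junction(c(substr(base, 1, 40), substr(base, 61, 90)),
                            min_overlap = 25)
  expect_identical(length(out2), 2L)

  # 3 mismatches in a 25-bp overlap (88% identity) blocks the merge
  r2_bad <- r2
  substr(r2_bad, 5, 5) <- "A"; substr(r2_bad, 10, 10) <- "A"
  substr(r2_bad, 15, 15) <- "A"
  r2_bad <- paste0(substr(r2_bad, 1, 30), substr(base, 61, 90))
  out3 <- assemble_junction(c(substr(base, 1, 55), r2_bad),
                            min_overlap = 25, min_overlap_identity = 0.95)
  expect_identical(length(out3), 2L)

  # reverse-complement overlaps merge into one contig
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2)))
  out4 <- assemble_junction(c(r1, rc), min_overlap = 25)
  expect_identical(length(out4), 1L)
  expect_true(out4 == base ||
                out4 == as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(base))))
})

test_that("assembly is order-invariant for unique-overlap read sets", {
  toy <- fx_toy_locus()
  b <- toy$truth$breakpoint
  region <- substr(toy$hap[["chr1"]], b - 100, b + 599)  # 700 bp
  starts <- seq(1, nchar(region) - 79, by = 20)
  reads <- substring(region, starts, starts + 79)
  ref_out <- assemble_junction(reads)
  withr::with_seed(31, {
    for (i in 1:3) {
      shuf <- sample(reads)
      expect_identical(sort(assemble_junction(shuf)), sort(ref_out))
    }
  })
  expect_identical(length(ref_out), 1L)
  expect_identical(ref_out, region)
})

test_that("junction classification needs both LTR-derived and genomic spans", {
  cons <- fx_consensus()
  ref <- fx_reference()
  gen_l <- substr(ref[["chrA"]], 2001, 2040)
  gen_r <- substr(ref[["chrA"]], 8001, 8040)

  full <- classify_junction(paste0(gen_l, cons$ltr, gen_r), cons$ltr)
  expect_s3_class(full, "junction_contig")
  expect_identical(full$side, "full_ltr")
  expect_identical(full$ltr_span, c(41L, 41L + 456L))

  five <- classify_junction(paste0(substr(gen_l, 1, 35),
                                   substr(cons$ltr, 1, 50)), cons$ltr)
  expect_identical(five$side, "five_prime")
  expect_identical(five$ltr_orientation, "+")

  short_gen <- classify_junction(paste0(substr(gen_l, 1, 25),
                                        substr(cons$ltr, 1, 100)), cons$ltr)
  expect_s3_class(short_gen, "junction_reject")

  all_ltr <- classify_junction(substr(cons$ltr, 1, 200), cons$ltr)
  expect_s3_class(all_ltr, "junction_reject")

  all_gen <- classify_junction(substr(ref[["chrA"]], 3001, 3200), cons$ltr)
  expect_s3_class(all_gen, "junction_reject")
})

test_that("breakpoint and TSD are recovered from junction contigs", {
  toy <- fx_toy_locus()
  cons <- fx_consensus()
  ref <- toy$ref
  b <- toy$truth$breakpoint
  tsd <- toy$truth$tsd
  occ <- toy$hap[["chr1"]]
  el_len <- nchar(toy$truth$element_seq)

  # occupied coordinates: [b, b+5) TSD1, element, TSD2, flank
  contig5 <- substr(occ, b + 5 - 59, b + 5 + 80)    # 60 bp genome + LTR start
  contig3 <- substr(occ, b + 5 + el_len - 79, b + 5 + el_len + 5 + 60)
  j5 <- classify_junction(contig5, cons$ltr)
  j3 <- classify_junction(contig3, cons$ltr)
  expect_identical(j5$side, "five_prime")
  expect_identical(j3$side, "three_prime")

  loc <- locate_breakpoint_tsd(list(j5, j3), ref)
  expect_identical(loc$breakpoint, b)
  expect_identical(loc$tsd, tsd)
  expect_true(loc$tsd_ok)
  expect_identical(loc$n_junctions, 2L)

  # single five-prime junction: breakpoint set, no TSD
  loc5 <- locate_breakpoint_tsd(list(j5), ref)
  expect_identical(loc5$breakpoint, b)
  expect_true(is.na(loc5$tsd))

  # a full solo-LTR contig recovers the assembled LTR allele
  full <- classify_junction(substr(occ, b - 59, b + 5 + el_len + 5 + 60),
                            cons$ltr)
  locf <- locate_breakpoint_tsd(list(full), ref)
  expect_identical(locf$breakpoint, b)
  expect_identical(locf$tsd, tsd)
  expect_identical(nchar(locf$ltr_allele_seq), el_len)

  # mismatched duplication (genomic abutment off by 3 bp): flagged
  bad3 <- paste0(substr(occ, b + 5 + el_len - 79, b + 5 + el_len),
                 substr(ref[["chr1"]], b + 4, b + 4 + 65))
  jb <- classify_junction(bad3, cons$ltr)
  locb <- locate_breakpoint_tsd(list(j5, jb), ref)
  expect_false(isTRUE(locb$tsd_ok))
  expect_true(is.na(locb$tsd))
})

test_that("insert-size scan finds unfixed reference elements in size class", {
  cons <- fx_consensus()
  ref <- make_reference(404, c(chr1 = 50000))
  truth <- make_truth_insertions(ref, 1, cons$ltr, forms = "solo_ltr",
                                 seed = 6)
  occ <- implant_insertions(ref, truth)   # reference carries the solo LTR
  b <- truth$breakpoint
  el <- nchar(truth$element_seq)
  known <- data.frame(chrom = "chr1", start = b + 5L, end = b + 5L + el,
                      name = "ERV_LTR", strand = truth$orientation)
  idx <- build_reference_index(occ)
  # the sample is homozygous for the pre-integration (empty) allele
  pairs <- simulate_reads(list(ref, ref), coverage = 20, base_error = 0.001,
                          seed = 11)
  aln <- map_read_pairs(pairs, idx)
  del <- scan_reference_deletions(aln, known)
  expect_identical(nrow(del), 1L)
  expect_identical(del$size_class, "solo_ltr")
  expect_gte(del$size, 400)
  expect_lte(del$size, 500)
  expect_lt(del$del_start, b + 5 + el)
  expect_gt(del$del_end, b + 5)

  # no insert-size deviation: no calls
  aln_flat <- map_read_pairs(simulate_reads(list(occ, occ), coverage = 10,
                                            base_error = 0, seed = 12), idx)
  expect_identical(nrow(scan_reference_deletions(aln_flat, known)), 0L)

  # deviant pairs with low map quality are ignored
  aln_low <- aln
  aln_low$mapq <- 10L
  expect_error(scan_reference_deletions(aln_low, known), "200")

  expect_error(scan_reference_deletions(aln[1:100, ], known), "200")
})

test_that("discovery recovers implanted insertions and excludes known ERVs", {
  cons <- fx_consensus()
  ref <- make_reference(505, c(chr1 = 35000))
  truth <- make_truth_insertions(ref, 2, cons$ltr, forms = "solo_ltr",
                                 seed = 15, min_gap = 8000L)
  hap <- implant_insertions(ref, truth)
  pairs <- simulate_reads(list(hap, hap), coverage = 20, base_error = 0,
                          seed = 16)
  disc <- discover_insertions(list(s1 = pairs), ref,
                              c(ltr = cons$ltr, internal = cons$internal))
  expect_identical(nrow(disc$loci), 2L)
  got <- disc$loci[order(disc$loci$breakpoint), ]
  tr <- truth[order(truth$breakpoint), ]
  expect_true(all(abs(got$breakpoint - tr$breakpoint) <= 5))
  expect_identical(got$tsd, tr$tsd)
  expect_identical(got$orientation, tr$orientation)

  # annotating one locus as a known ERV suppresses its rediscovery
  known <- data.frame(chrom = tr$chrom[1], start = tr$breakpoint[1] - 200L,
                      end = tr$breakpoint[1] + 200L, name = "CfERVF1_LTR",
                      strand = "+")
  disc2 <- discover_insertions(list(s1 = pairs), ref,
                               c(ltr = cons$ltr, internal = cons$internal),
                               known_erv_intervals = known)
  expect_identical(nrow(disc2$loci), 1L)
  expect_true(all(abs(disc2$loci$breakpoint - tr$breakpoint[2]) <= 5))
  expect_true("near_known_erv" %in% disc2$dropped$reason)
})

test_that("a provirus insertion yields both junctions and internal evidence", {
  cons <- fx_consensus()
  ref <- make_reference(12, c(chr1 = 40000))
  truth <- make_truth_insertions(ref, 1, cons$ltr, cons$internal,
                                 forms = "provirus", seed = 5)
  hap <- implant_insertions(ref, truth)
  pairs <- simulate_reads(list(hap, hap), coverage = 20, base_error = 0.001,
                          seed = 9)
  disc <- discover_insertions(list(s1 = pairs), ref,
                              c(ltr = cons$ltr, internal = cons$internal))
  expect_identical(nrow(disc$loci), 1L)
  expect_identical(disc$loci$breakpoint, truth$breakpoint)
  expect_identical(disc$loci$tsd, truth$tsd)
})
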