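test_that("allele reconstruction duplicates the TSD on the insertion allele", {
  toy <- fx_toy_locus()
  lc <- toy$truth
  ap <- reconstruct_alleles(lc, toy$ref, lc$element_seq)
  expect_identical(nchar(ap$alt_allele_seq) - nchar(ap$ref_allele_seq),
                   nchar(lc$element_seq) + 5L)
  # ref allele: one TSD copy; alt allele: two copies around the element
  expect_identical(substr(ap$ref_allele_seq, 601, 605), lc$tsd)
  expect_identical(substr(ap$alt_allele_seq, 601, 605), lc$tsd)
  el_end <- 605L + nchar(lc$element_seq)
  expect_identical(substr(ap$alt_allele_seq, el_end + 1, el_end + 5), lc$tsd)
  # both alleles share identical outer flanks
  expect_identical(substr(ap$ref_allele_seq, 1, 600),
                   substr(ap$alt_allele_seq, 1, 600))
  expect_identical(substring(ap$ref_allele_seq, nchar(ap$ref_allele_seq) - 599),
                   substring(ap$alt_allele_seq, nchar(ap$alt_allele_seq) - 599))

  # unresolved interior filled from the consensus is flagged
  cons <- fx_consensus()
  ap2 <- reconstruct_alleles(lc, toy$ref, element_seq = NULL,
                             fill_consensus = cons$ltr)
  expect_true(ap2$element_filled)
  expect_error(reconstruct_alleles(lc, toy$ref, NULL), "unfillable")

  # a reference provirus locus: the alternate allele is the shorter excision
  cons_pv <- cons$provirus
  ref2 <- make_reference(33, c(chr1 = 22000))
  tr2 <- make_truth_insertions(ref2, 1, cons$ltr, cons$internal,
                               forms = "provirus", seed = 3)
  occ <- implant_insertions(ref2, tr2)
  b <- tr2$breakpoint
  e <- b + 10L + nchar(tr2$element_seq)
  ap3 <- reconstruct_alleles(
    list(locus_id = "ref1", chrom = "chr1", breakpoint = b, element_end = e),
    occ, element_seq = tr2$element_seq, is_reference_locus = TRUE)
  expect_identical(nchar(ap3$ref_allele_seq) - nchar(ap3$alt_allele_seq),
                   nchar(tr2$element_seq) + 5L)
  expect_identical(ap3$insertion_allele, "ref")
})

test_that("read pairs support the allele they span a junction of", {
  toy <- fx_toy_locus()
  lc <- toy$truth
  ap <- reconstruct_alleles(lc, toy$ref, lc$element_seq)
  alt <- ap$alt_allele_seq
  ref_al <- ap$ref_allele_seq
  mk_pair <- function(qname, s1, s2) data.frame(qname = qname, seq1 = s1,
                                                seq2 = s2,
                                                stringsAsFactors = FALSE)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  # spans the left TSD-LTR junction of the alt allele
  p_alt <- mk_pair("alt1", substr(alt, 561, 660), rc(substr(alt, 861, 960)))
  # spans the unoccupied junction of the ref allele
  p_ref <- mk_pair("ref1", substr(ref_al, 561, 660),
                   rc(substr(ref_al, 700, 799)))
  # far from the breakpoint: identical on both alleles
  p_far <- mk_pair("far1", substr(ref_al, 1, 100), rc(substr(ref_al, 301, 400)))
  asn <- assign_reads(rbind(p_alt, p_ref, p_far), ap)
  expect_identical(asn$allele[asn$qname == "alt1"], "alt")
  expect_identical(asn$allele[asn$qname == "ref1"], "ref")
  expect_identical(asn$allele[asn$qname == "far1"], "none")
  expect_identical(asn$reason[asn$qname == "far1"], "uninformative_tie")

  # both mates inside the internal region of a provirus allele are dropped
  cons <- fx_consensus()
  pv_truth <- toy$truth
  pv_truth$element_seq <- cons$provirus
  el <- cons$provirus
  attr(el, "ltr_length") <- 457L
  ap_pv <- reconstruct_alleles(pv_truth, toy$ref, el)
  expect_false(is.null(ap_pv$internal_interval))
  alt_pv <- ap_pv$alt_allele_seq
  mid <- 605L + 2000L
  p_int <- mk_pair("int1", substr(alt_pv, mid, mid + 99),
                   rc(substr(alt_pv, mid + 250, mid + 349)))
  asn_pv <- assign_reads(p_int, ap_pv)
  expect_identical(asn_pv$allele, "none")
  expect_identical(asn_pv$reason, "internal_internal")
})

test_that("genotype likelihoods follow the mapping-quality error model", {
  g_rr <- genotype_likelihoods(10, 0, rep(60L, 10))
  expect_identical(g_rr$gt, "0/0")

  g_het <- genotype_likelihoods(5, 5, rep(60L, 10))
  expect_identical(g_het$gt, "0/1")
  expect_equal(g_het$gl_ra, 10 * log10(0.5), tolerance = 1e-9)
  # the het likelihood dominates both homozygote likelihoods by orders of
  # magnitude (each homozygote pays ~ 5 factors of the error probability)
  expect_lt(g_het$gl_rr, g_het$gl_ra - 20)

  g_miss <- genotype_likelihoods(0, 0, integer(0))
  expect_identical(g_miss$gt, "./.")
  expect_identical(c(g_miss$ad_ref, g_miss$ad_alt), c(0L, 0L))

  expect_error(genotype_likelihoods(2, 1, c(60L, 60L)), "length")

  # argmax is stable under uniform map-quality shifts (mapq >= 20)
  for (q in c(20L, 30L, 40L, 60L)) {
    expect_identical(genotype_likelihoods(8, 0, rep(q, 8))$gt, "0/0")
    expect_identical(genotype_likelihoods(4, 4, rep(q, 8))$gt, "0/1")
    expect_identical(genotype_likelihoods(0, 8, rep(q, 8))$gt, "1/1")
  }

  # adding an alt-supporting read never increases P(data | hom_ref)
  prev <- genotype_likelihoods(5, 0, rep(40L, 5))$gl_rr
  for (nalt in 1:4) {
    cur <- genotype_likelihoods(5, nalt, rep(40L, 5 + nalt))$gl_rr
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("cohort frequencies count insertion alleles over genotyped samples", {
  toy <- fx_toy_locus()
  lc <- toy$truth
  ap <- reconstruct_alleles(lc, toy$ref, lc$element_seq)
  ref_al <- ap$ref_allele_seq; alt <- ap$alt_allele_seq
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  alt_pair <- data.frame(qname = "a", seq1 = substr(alt, 561, 660),
                         seq2 = rc(substr(alt, 861, 960)))
  ref_pair <- data.frame(qname = "r", seq1 = substr(ref_al, 561, 660),
                         seq2 = rc(substr(ref_al, 700, 799)))
  # 10 genotyped samples: 2 het, 1 hom-alt, 7 hom-ref -> 4/20 = 20%
  pops <- data.frame(sample_id = sprintf("s%02d", 1:10), population = "pop1")
  sp <- list()
  for (i in 1:10) {
    sp[[pops$sample_id[i]]] <-
      if (i <= 2) rbind(alt_pair, ref_pair)
      else if (i == 3) rbind(alt_pair, alt_pair)
      else rbind(ref_pair, ref_pair)
  }
  res <- cohort_genotype(list(ap), sp, pops)
  expect_identical(res$frequencies$alt_count, 4L)
  expect_identical(res$frequencies$total_alleles, 20L)
  expect_equal(res$frequencies$frequency, 0.2)
  gts <- res$calls$gt
  expect_identical(sum(gts == "0/1"), 2L)
  expect_identical(sum(gts == "1/1"), 1L)

  expect_error(cohort_genotype(list(ap), sp,
                               pops[1:5, , drop = FALSE]),
               "absent from population table")

  # the reported overall-frequency convention: percent over diploid samples
  expect_equal(round(overall_frequency_percent(1, 347), 2), 0.14)
  expect_equal(overall_frequency_percent(20, 10), 100)
})
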