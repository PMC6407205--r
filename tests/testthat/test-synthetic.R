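test_that("reference simulation is seeded, GC-controlled, length-exact", {
  r1 <- make_reference(1, c(chr1 = 5000, chr2 = 2000))
  r2 <- make_reference(1, c(chr1 = 5000, chr2 = 2000))
  expect_identical(r1, r2)
  expect_identical(unname(nchar(r1)), c(5000L, 2000L))

  gc_only <- make_reference(2, c(chr1 = 3000), gc = 1.0)
  expect_false(grepl("[AT]", gc_only[["chr1"]]))

  expect_error(make_reference(1, c(chr1 = 0)), "positive")
})

test_that("LTR pair mutation inverts the dating model", {
  m0 <- mutate_ltr_pair(strrep("ACGT", 120), 0, 1.33e-9, seed = 1)
  expect_identical(m0$ltr5, m0$ltr3)
  expect_identical(m0$n_changes, 0L)

  ma <- mutate_ltr_pair(strrep("ACGT", 120), 5e6, 1.33e-9, seed = 9)
  mb <- mutate_ltr_pair(strrep("ACGT", 120), 5e6, 1.33e-9, seed = 9)
  expect_identical(ma, mb)

  expect_error(mutate_ltr_pair("ACGT", -1), "non-negative")

  # E[D] = age * rate * L = 1 for the canonical 457/1.33e-9/1.645 My case
  cons <- fx_consensus()
  ds <- withr::with_seed(11, vapply(seq_len(4000), function(i)
    mutate_ltr_pair(cons$ltr, 1.645e6, 1.33e-9)$n_changes, integer(1)))
  lambda <- 1.645e6 * 1.33e-9 * nchar(cons$ltr)
  expect_lt(abs(mean(ds) - lambda), 3 * sqrt(lambda / 4000))
})

test_that("insertion implanting duplicates the target site around the element", {
  ref <- c(chr1 = "AAAACGTATTTT")
  truth <- data.frame(chrom = "chr1", breakpoint = 3L, orientation = "+",
                      element_seq = "GGGG", stringsAsFactors = FALSE)
  cfg <- erv_config(flank_bp = 1L)
  hap <- implant_insertions(ref, truth, cfg)
  expect_identical(hap[["chr1"]], "AAAACGTAGGGGACGTATTTT")

  truth$orientation <- "-"
  truth$element_seq <- "GGGC"
  hap <- implant_insertions(ref, truth, cfg)
  expect_identical(hap[["chr1"]], "AAAACGTAGCCCACGTATTTT")

  truth$breakpoint <- 11L
  expect_error(implant_insertions(ref, truth, cfg), "chromosome end")
})

test_that("truth sets respect the TSD invariant and solo-LTR length", {
  cons <- fx_consensus()
  ref <- fx_reference()
  truth <- make_truth_insertions(ref, 4, cons$ltr, cons$internal,
                                 forms = c("solo_ltr", "provirus"), seed = 12)
  for (i in seq_len(nrow(truth))) {
    expect_identical(truth$tsd[i],
                     substr(ref[[truth$chrom[i]]], truth$breakpoint[i] + 1,
                            truth$breakpoint[i] + 5))
  }
  solo_len <- nchar(truth$element_seq[truth$form == "solo_ltr"])
  expect_true(all(abs(solo_len - 457) <= 5))
  # a provirus element begins and ends with (near-consensus) LTR sequence
  pv <- truth$element_seq[truth$form == "provirus"][1]
  expect_gt(nchar(pv), 7000)
  mm_head <- sum(utf8ToInt(substr(pv, 1, 457)) != utf8ToInt(cons$ltr))
  mm_tail <- sum(utf8ToInt(substr(pv, nchar(pv) - 456, nchar(pv))) !=
                   utf8ToInt(cons$ltr))
  expect_lt(mm_head, 15)
  expect_lt(mm_tail, 15)
})

test_that("cohort genotypes follow Hardy-Weinberg sampling", {
  cons <- fx_consensus()
  ref <- fx_reference()
  truth <- make_truth_insertions(ref, 3, cons$ltr, seed = 13)
  truth$freq_popA <- c(0, 1, 0.5)
  big <- data.frame(sample_id = sprintf("s%04d", 1:1000), population = "popA")
  co <- simulate_cohort(truth, big, seed = 4)
  expect_true(all(co$genotypes[1, ] == 0L))
  expect_true(all(co$genotypes[2, ] == 2L))
  expect_lt(abs(mean(co$genotypes[3, ]) - 1), 0.05)

  truth$freq_popA <- c(0.5, 0.5, 1.5)
  expect_error(simulate_cohort(truth, big, seed = 4), "frequency")
  expect_error(simulate_cohort(truth,
                               data.frame(sample_id = "x", population = "popZ"),
                               seed = 1),
               "popZ")
})

test_that("read simulation honors coverage, error rate, and seed", {
  ref <- make_reference(3, c(chr1 = 50000))
  pairs <- simulate_reads(list(ref, ref), coverage = 20, base_error = 0,
                          seed = 6)
  # coverage * len / (2 * read_len) pairs per haplotype, two haplotypes
  expect_lt(abs(nrow(pairs) - 10000) / 10000, 0.05)

  # with no errors every read is an exact substring of its haplotype
  some <- pairs[sample(nrow(pairs), 50), ]
  expect_true(all(vapply(seq_len(nrow(some)), function(i) {
    grepl(some$seq1[i], ref[[some$chrom[i]]], fixed = TRUE) &&
      grepl(revcomp_chr(some$seq2[i]), ref[[some$chrom[i]]], fixed = TRUE)
  }, logical(1))))

  tmp <- withr::local_tempdir()
  p1 <- simulate_reads(list(ref, ref), coverage = 0.5, seed = 8,
                       fastq_prefix = file.path(tmp, "a"))
  p2 <- simulate_reads(list(ref, ref), coverage = 0.5, seed = 8,
                       fastq_prefix = file.path(tmp, "b"))
  expect_identical(readLines(file.path(tmp, "a_1.fastq")),
                   readLines(file.path(tmp, "b_1.fastq")))
  expect_identical(p1$seq2, p2$seq2)
  r1 <- read_fastq(file.path(tmp, "a_1.fastq"))
  expect_identical(unname(r1), p1$seq1)

  expect_error(simulate_reads(list(ref, ref), coverage = 0), "positive")
  expect_error(simulate_reads(list(ref, ref), coverage = 1, read_len = 500,
                              frag_mean = 400), "exceed")
})

test_that("synthetic consensus has canonical LTR termini and clean ORFs", {
  cons <- fx_consensus()
  expect_identical(nchar(cons$ltr), 457L)
  expect_identical(substr(cons$ltr, 1, 2), "TG")
  expect_identical(substr(cons$ltr, 456, 457), "CA")
  expect_identical(cons$provirus,
                   paste0(cons$ltr, cons$internal, cons$ltr))
  # every annotated gene is an intact ATG...stop ORF in the provirus
  for (i in seq_len(nrow(cons$genes))) {
    g <- cons$genes[i, ]
    orf <- substr(cons$provirus, g$start, g$end)
    expect_identical(substr(orf, 1, 3), "ATG")
    codons <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    expect_true(utils::tail(codons, 1) %in% c("TAA", "TAG", "TGA"))
    expect_false(any(utils::head(codons, -1) %in% c("TAA", "TAG", "TGA")))
  }
})
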