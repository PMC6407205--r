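test_that("FASTA reading normalizes case, keeps order, checks alphabet", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), f)
  expect_identical(read_fasta(f), c(x = "ACGT"))

  writeLines(c(">a", "AC", ">b", "GT"), f)
  expect_identical(read_fasta(f), c(a = "AC", b = "GT"))

  writeLines(c(">x", "AC-GT"), f)
  expect_error(read_fasta(f), "illegal character")

  file.create(f2 <- withr::local_tempfile(fileext = ".fa"))
  expect_identical(read_fasta(f2), character(0))
})

test_that("FASTA writer round-trips and wraps lines", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(x = "ACGT"), f)
  expect_identical(readLines(f), c(">x", "ACGT"))

  long <- c(s = paste(rep("ACGTA", 26), collapse = ""))  # 130 bases
  write_fasta(long, f, wrap = 60)
  lines <- readLines(f)
  expect_identical(length(lines), 4L)  # header + 3 sequence lines
  expect_identical(read_fasta(f), long)

  write_fasta(character(0), f)
  expect_identical(file.size(f), 0)

  recs <- c(a = "ACGTACGTAA", b = strrep("GATTACA", 20))
  write_fasta(recs, f)
  expect_identical(read_fasta(f), recs)
})

test_that("BED and RepeatMasker intervals convert to 0-based half-open", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tCfERVF1_LTR\t0\t+", bed)
  iv <- read_intervals(bed, "bed")
  expect_identical(iv$start, 10L)
  expect_identical(iv$end, 20L)
  expect_identical(iv$strand, "+")
  expect_identical(iv$name, "CfERVF1_LTR")

  rm <- withr::local_tempfile(fileext = ".out")
  writeLines(fx_rm_out_text(), rm)
  iv <- read_intervals(rm, "repeatmasker_out")
  expect_identical(nrow(iv), 3L)
  expect_identical(iv$start[1], 10L)  # 1-based 11 -> 0-based 10
  expect_identical(iv$end[1], 20L)
  expect_identical(iv$strand[2], "-")  # 'C' means reverse

  flt <- read_intervals(rm, "repeatmasker_out", name_filter = "CfERVF1")
  expect_identical(nrow(flt), 2L)
  expect_false("SINE_Cf" %in% flt$name)

  bad <- withr::local_tempfile(fileext = ".out")
  writeLines(c(fx_rm_out_text(), "  12 1.0 0.0"), bad)
  expect_error(read_intervals(bad, "repeatmasker_out"), "line")

  # coordinate conversion is an involution through write_bed
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, bed2)
  expect_identical(read_intervals(bed2, "bed")[, c("chrom", "start", "end")],
                   iv[, c("chrom", "start", "end")])
})

test_that("SAM subset parses coordinates, flags, and checks CIGAR", {
  sam <- withr::local_tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000")
  rec <- function(qname, flag, pos, cigar, seq,
                  rnext = "=", pnext = 200, tlen = 150) {
    paste(qname, flag, "chr1", pos, 60, cigar, rnext, pnext, tlen, seq, "*",
          sep = "\t")
  }
  writeLines(c(hdr,
               rec("r1", 99, 100, "4M", "ACGT"),
               paste("r2", 4 + 1 + 64, "*", 0, 0, "*", "chr1", 200, 0,
                     "ACGT", "*", sep = "\t")), sam)
  aln <- read_sam_subset(sam)
  expect_identical(aln$pos[1], 99L)          # 1-based 100 -> 0-based 99
  expect_true(aln$mapped[1])
  expect_false(aln$mapped[2])                # flag 0x4
  expect_identical(aln$mate[1], 1L)
  expect_true(aln$is_proper_pair[1])

  writeLines(c(hdr, rec("r3", 0, 100, "50M", strrep("A", 49))), sam)
  expect_error(read_sam_subset(sam), "mismatch")

  writeLines(c(hdr, rec("r4", 0, 100, "2M1N1M", "ACGT")), sam)
  expect_error(read_sam_subset(sam), "N")
})

test_that("SAM subset round-trips through writer and reader", {
  toy <- fx_toy_locus()
  idx <- build_reference_index(toy$ref)
  pairs <- simulate_reads(list(toy$ref, toy$ref), coverage = 1,
                          base_error = 0, seed = 5)
  aln <- map_read_pairs(pairs, idx)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_subset(aln, sam, reference = toy$ref)
  back <- read_sam_subset(sam)
  ord <- order(back$qname, back$mate)
  aln2 <- aln[order(aln$qname, aln$mate), ]
  back <- back[ord, ]
  expect_identical(back$pos, aln2$pos)
  expect_identical(back$mapped, aln2$mapped)
  expect_identical(back$strand, aln2$strand)
  expect_identical(back$seq, aln2$seq)
  expect_identical(back$insert_size, aln2$insert_size)
})

test_that("VCF writer emits valid VCF 4.2 with symbolic ALT and missing calls", {
  skip_if_not_installed("VariantAnnotation")
  loci <- data.frame(locus_id = c("L1", "L2"), chrom = "chr1",
                     pos = c(99L, 499L), ref_base = c("A", "G"),
                     svtype = c("INS", "DEL"), tsd = c("ACGTA", NA),
                     form = c("solo_ltr", NA), stringsAsFactors = FALSE)
  calls <- data.frame(
    locus_id = c("L1", "L1", "L2"),
    sample_id = c("s1", "s2", "s1"),
    gt = c("0/1", "./.", "1/1"),
    gl_rr = c(-10, NA, -20), gl_ra = c(-1, NA, -5), gl_aa = c(-12, NA, -0.1),
    ad_ref = c(5L, 0L, 0L), ad_alt = c(4L, 0L, 9L), stringsAsFactors = FALSE)
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(loci, calls, samples = c("s1", "s2"), "synthetic_ref", vcf_path)
  v <- VariantAnnotation::readVcf(vcf_path)
  expect_identical(unname(dim(v)[1]), 2L)
  gt <- VariantAnnotation::geno(v)$GT
  expect_identical(unname(gt["L1", ]), c("0/1", "./."))
  # sample s2 has no call at L2 -> missing
  expect_identical(unname(gt["L2", "s2"]), "./.")
  alt <- as.character(unlist(VariantAnnotation::alt(v)))
  expect_identical(alt, c("<INS:ME:ERV>", "<DEL:ME:ERV>"))
  expect_identical(as.character(VariantAnnotation::info(v)$TSD[1]), "ACGTA")

  # empty call set -> header-only file
  write_vcf(loci[0, ], calls[0, ], c("s1"), "synthetic_ref", vcf_path)
  lines <- readLines(vcf_path)
  expect_true(all(startsWith(lines, "#")))
})
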