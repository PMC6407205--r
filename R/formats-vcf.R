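#' Write mobile-element insertion genotypes as VCF 4.2
#'
#' One record per locus with symbolic alternate alleles: `<INS:ME:ERV>` for
#' insertions absent from the reference assembly and `<DEL:ME:ERV>` for
#' unfixed reference insertions (where the alternate allele is the excision
#' leaving a single TSD copy). Genotypes are emitted as `GT:GL:AD`; samples
#' without informative remapped reads at a locus are emitted as `./.`.
#'
#' @param loci `data.frame` with one row per locus: `locus_id`, `chrom`,
#'   `pos` (0-based breakpoint: leftmost TSD start), `ref_base` (reference
#'   base at the breakpoint), `svtype` (`"INS"` or `"DEL"`), and optionally
#'   `tsd` (TSD string or NA) and `form` (`solo_ltr`/`provirus`/NA).
#' @param calls `data.frame` of genotype calls: `locus_id`, `sample_id`,
#'   `gt` (`"0/0"`, `"0/1"`, `"1/1"`, or `"./."`), `gl_rr`, `gl_ra`, `gl_aa`
#'   (log10 genotype likelihoods), `ad_ref`, `ad_alt`. Samples missing from
#'   a locus's call set are emitted as missing.
#' @param samples Character vector fixing the sample column order.
#' @param reference_name Name recorded in the `##reference` header line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(loci, calls, samples, reference_name, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", reference_name),
    "##ALT=<ID=INS:ME:ERV,Description=\"ERV mobile element insertion\">",
    "##ALT=<ID=DEL:ME:ERV,Description=\"Deletion of reference ERV mobile element\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication\">",
    "##INFO=<ID=MEFORM,Number=1,Type=String,Description=\"Allele form: solo_ltr or provirus\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 genotype likelihoods (0/0,0/1,1/1)\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Supporting read pairs per allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  recs <- character(0)
  if (nrow(loci)) {
    ord <- order(loci$chrom, loci$pos)
    loci <- loci[ord, , drop = FALSE]
    for (i in seq_len(nrow(loci))) {
      lc <- loci[i, ]
      info <- paste0("SVTYPE=", lc$svtype)
      if (!is.null(lc$tsd) && !is.na(lc$tsd)) info <- paste0(info, ";TSD=", lc$tsd)
      if (!is.null(lc$form) && !is.na(lc$form)) info <- paste0(info, ";MEFORM=", lc$form)
      cc <- calls[calls$locus_id == lc$locus_id, , drop = FALSE]
      gt <- rep("./.:.:.", length(samples))
      m <- match(cc$sample_id, samples)
      keep <- !is.na(m)
      gt[m[keep]] <- ifelse(
        cc$gt[keep] == "./.", "./.:.:.",
        sprintf("%s:%.2f,%.2f,%.2f:%d,%d", cc$gt[keep], cc$gl_rr[keep],
                cc$gl_ra[keep], cc$gl_aa[keep], cc$ad_ref[keep], cc$ad_alt[keep]))
      recs <- c(recs, paste(c(
        lc$chrom, lc$pos + 1L, lc$locus_id, lc$ref_base,
        paste0("<", lc$svtype, ":ME:ERV>"), ".", "PASS", info,
        "GT:GL:AD", gt), collapse = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
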