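# shared fixtures, built once per test run

fx <- new.env()

fx_consensus <- function() {
  if (is.null(fx$cons)) fx$cons <- synthetic_erv_consensus()
  fx$cons
}

# tiny deterministic reference for mapper/discovery unit tests
fx_reference <- function() {
  if (is.null(fx$ref)) fx$ref <- make_reference(101, c(chrA = 30000,
                                                       chrB = 12000))
  fx$ref
}

# a RepeatMasker .out snippet: banner, header, blank line, then rows
fx_rm_out_text <- function() {
  c("   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "",
    "  463  10.5  0.0  0.0  chr1           11      20  (979) +  CfERVF1_LTR    LTR/ERV1                 1  10  (447)     1",
    " 1200   2.1  0.1  0.0  chr2          501     957  (43) C  CfERVF1_LTR    LTR/ERV1              (0)  457    1     2",
    "  300  15.0  0.0  0.0  chr1          100     199  (900) +  SINE_Cf        SINE/tRNA                 1  100  (0)      3")
}

# the 61 sense codons, written out independently of the package internals
sense_codons_prov <- function() {
  setdiff(as.vector(outer(outer(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"), paste0),
                          c("A", "C", "G", "T"), paste0)),
          c("TAA", "TAG", "TGA"))
}

# reverse complement helper kept independent of the package internals
revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# small toy locus used across discovery/genotyping tests:
# reference with one implanted solo LTR at a known breakpoint
fx_toy_locus <- function() {
  if (!is.null(fx$toy)) return(fx$toy)
  cons <- fx_consensus()
  ref <- make_reference(202, c(chr1 = 20000))
  truth <- make_truth_insertions(ref, 1, cons$ltr, forms = "solo_ltr",
                                 seed = 7)
  fx$toy <- list(ref = ref, truth = truth,
                 hap = implant_insertions(ref, truth))
  fx$toy
}
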