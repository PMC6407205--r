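#' Simulate a reference genome
#'
#' Bases are drawn i.i.d. at the given GC content — adequate as a host
#' genome stand-in for exercising insertion discovery and genotyping, where
#' only local sequence uniqueness matters.
#'
#' @param seed Integer seed; the same seed always yields the same genome.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc GC content in `[0, 1]`.
#' @return Named character vector of chromosome sequences.
#' @examples
#' ref <- make_reference(1, c(chr1 = 1000), gc = 0.41)
#' nchar(ref)
#' @export
make_reference <- function(seed, chrom_lengths, gc = 0.41) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    vapply(chrom_lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
}

random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate post-insertion divergence of a proviral LTR pair
#'
#' At integration the two LTRs of a provirus are identical; they then accrue
#' substitutions independently under a neutral clock. The total number of
#' changes over the pair is drawn as `D ~ Poisson(age * rate * L)` — the
#' exact inverse of the LTR-divergence dating formula, which divides the
#' observed change count by `L * rate` without a factor of two — and each
#' change is placed at a uniform site on one LTR chosen at random.
#'
#' @param ltr_seq The ancestral LTR sequence (identical pair at age 0).
#' @param age_years Age of the provirus in years (>= 0).
#' @param rate Substitution rate per site per year.
#' @param seed Optional integer seed.
#' @return List with `ltr5`, `ltr3` (the diverged pair) and `n_changes`
#'   (the realized Poisson draw `D`).
#' @export
mutate_ltr_pair <- function(ltr_seq, age_years, rate = 1.33e-9, seed = NULL) {
  if (age_years < 0) stop("age must be non-negative")
  if (rate <= 0) stop("rate must be positive")
  L <- nchar(ltr_seq)
  with_seed(seed, {
    d <- stats::rpois(1L, age_years * rate * L)
    pair <- strsplit(ltr_seq, "")[[1]]
    ltrs <- list(pair, pair)
    if (d > 0) {
      which_ltr <- sample(2L, d, replace = TRUE)
      site <- sample(L, d, replace = TRUE)
      for (i in seq_len(d)) {
        cur <- ltrs[[which_ltr[i]]][site[i]]
        ltrs[[which_ltr[i]]][site[i]] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    list(ltr5 = paste(ltrs[[1]], collapse = ""),
         ltr3 = paste(ltrs[[2]], collapse = ""),
         n_changes = d)
  })
}

#' Build an insertion truth set over a simulated reference
#'
#' Chooses well-separated breakpoints, records the 5-bp target site
#' duplication (the reference 5-mer at the breakpoint), assigns each locus
#' an allele form (solo LTR or full provirus), an orientation, a true age
#' (used to diversify each locus's LTR from the consensus), and
#' per-population insertion allele frequencies.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param n Number of insertion loci.
#' @param ltr_consensus LTR consensus sequence (canonically 457 bp).
#' @param internal_consensus Internal proviral consensus (between the LTRs);
#'   required if any `forms` is `"provirus"`.
#' @param forms Character vector recycled over loci: `"solo_ltr"` or
#'   `"provirus"`.
#' @param populations Character vector of population names.
#' @param freq_range Range from which per-population insertion frequencies
#'   are drawn uniformly.
#' @param age_range Range (years) of true ages, uniform.
#' @param min_gap Minimum distance between breakpoints (and to chromosome
#'   ends, together with `end_margin`).
#' @param end_margin Breakpoints are kept at least this far from chromosome
#'   ends (must cover the genotyping flank).
#' @param seed Integer seed.
#' @param cfg [erv_config()].
#' @return `data.frame` (one row per locus): `locus_id`, `chrom`,
#'   `breakpoint` (0-based TSD start in the pre-insertion reference),
#'   `orientation`, `form`, `tsd`, `element_seq` (forward orientation),
#'   `true_age_years`, and one `freq_<population>` column per population.
#' @export
make_truth_insertions <- function(reference, n, ltr_consensus,
                                  internal_consensus = NULL,
                                  forms = "solo_ltr",
                                  populations = c("popA", "popB"),
                                  freq_range = c(0.2, 0.9),
                                  age_range = c(2e5, 2e6),
                                  min_gap = 3000L, end_margin = 1500L,
                                  seed = NULL, cfg = erv_config()) {
  forms <- rep_len(forms, n)
  if (any(forms == "provirus") && is.null(internal_consensus))
    stop("internal_consensus required for provirus loci")
  with_seed(seed, {
    # place breakpoints chromosome-proportionally, enforcing separation
    lens <- nchar(reference)
    picks <- data.frame(chrom = character(0), breakpoint = integer(0))
    tries <- 0L
    while (nrow(picks) < n && tries < 200L * n) {
      tries <- tries + 1L
      chrom <- sample(names(reference), 1L, prob = lens)
      b <- sample(seq(end_margin, lens[[chrom]] - end_margin), 1L)
      ok <- !any(picks$chrom == chrom & abs(picks$breakpoint - b) < min_gap)
      if (ok) picks <- rbind(picks, data.frame(chrom = chrom, breakpoint = b))
    }
    if (nrow(picks) < n) stop("could not place ", n, " separated breakpoints")
    picks <- picks[order(picks$chrom, picks$breakpoint), ]
    ages <- stats::runif(n, age_range[1], age_range[2])
    elements <- character(n)
    for (i in seq_len(n)) {
      # diversify each locus's LTR from the consensus under its true age
      mut <- mutate_ltr_pair(ltr_consensus, ages[i], cfg$rate_per_site_year)
      if (forms[i] == "solo_ltr") {
        elements[i] <- mut$ltr5
      } else {
        elements[i] <- paste0(mut$ltr5, internal_consensus, mut$ltr3)
      }
    }
    tsd <- substr_vec(reference[picks$chrom], picks$breakpoint + 1L,
                      picks$breakpoint + cfg$tsd_length)
    out <- data.frame(
      locus_id = sprintf("ins%02d", seq_len(n)),
      chrom = picks$chrom,
      breakpoint = as.integer(picks$breakpoint),
      orientation = sample(c("+", "-"), n, replace = TRUE),
      form = forms,
      tsd = tsd,
      element_seq = elements,
      true_age_years = ages,
      stringsAsFactors = FALSE)
    for (p in populations) {
      out[[paste0("freq_", p)]] <- stats::runif(n, freq_range[1], freq_range[2])
    }
    out
  })
}

substr_vec <- function(x, start, stop) {
  vapply(seq_along(x), function(i) substr(x[[i]], start[i], stop[i]),
         character(1), USE.NAMES = FALSE)
}

#' Implant ERV insertions into a reference haplotype
#'
#' Builds the occupied haplotype for a set of insertions: at breakpoint `b`
#' (0-based) the haplotype is `ref[0:b+5) + element + ref[b:b+5) + ref[b+5:)`,
#' i.e. the 5-bp target site is duplicated on both sides of the element.
#' Reverse-orientation elements are inserted reverse-complemented. Loci not
#' listed leave the reference unchanged (the unoccupied haplotype is the
#' reference itself).
#'
#' @param reference Named character vector of chromosome sequences.
#' @param truth `data.frame` with columns `chrom`, `breakpoint`,
#'   `orientation`, `element_seq` (see [make_truth_insertions()]); rows to
#'   implant on this haplotype.
#' @param cfg [erv_config()] (supplies `tsd_length` and `flank_bp`).
#' @return Named character vector: the occupied haplotype.
#' @export
implant_insertions <- function(reference, truth, cfg = erv_config()) {
  hap <- reference
  if (!nrow(truth)) return(hap)
  if (any(truth$breakpoint < cfg$flank_bp |
          truth$breakpoint + cfg$tsd_length + cfg$flank_bp >
            nchar(reference[truth$chrom])))
    stop("breakpoint within ", cfg$flank_bp, " bp of a chromosome end")
  t5 <- cfg$tsd_length
  # apply right-to-left per chromosome so earlier breakpoints stay valid
  truth <- truth[order(truth$chrom, -truth$breakpoint), , drop = FALSE]
  for (i in seq_len(nrow(truth))) {
    ch <- truth$chrom[i]; b <- truth$breakpoint[i]
    el <- truth$element_seq[i]
    if (truth$orientation[i] == "-") el <- revcomp(el)
    s <- hap[[ch]]
    hap[[ch]] <- paste0(substr(s, 1L, b + t5), el,
                        substr(s, b + 1L, b + t5),
                        substr(s, b + t5 + 1L, nchar(s)))
  }
  hap
}

#' Simulate diploid genotypes for a cohort
#'
#' Per sample and locus, the insertion-allele copy number is drawn
#' `Binomial(2, f)` with `f` the insertion frequency in the sample's
#' population (Hardy-Weinberg sampling).
#'
#' @param truth Truth set from [make_truth_insertions()] (with
#'   `freq_<population>` columns).
#' @param samples `data.frame` with columns `sample_id`, `population`.
#' @param seed Optional integer seed.
#' @return List with `samples` (as given) and `genotypes`: an integer
#'   matrix (loci x samples) of insertion-allele copies in `{0, 1, 2}`.
#' @export
simulate_cohort <- function(truth, samples, seed = NULL) {
  fcols <- paste0("freq_", samples$population)
  missing <- setdiff(unique(fcols), names(truth))
  if (length(missing)) stop("no frequency column for population(s): ",
                            paste(sub("^freq_", "", missing), collapse = ", "))
  with_seed(seed, {
    g <- matrix(0L, nrow = nrow(truth), ncol = nrow(samples),
                dimnames = list(truth$locus_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      f <- truth[[fcols[j]]]
      if (any(f < 0 | f > 1)) stop("frequency outside [0,1]")
      g[, j] <- stats::rbinom(nrow(truth), 2L, f)
    }
    list(samples = samples, genotypes = g)
  })
}

#' Simulate paired-end reads from a haplotype pair
#'
#' Fragments are placed uniformly over each haplotype (each haplotype
#' receives `coverage * length / (2 * read_len)` pairs, i.e. `coverage` is
#' per-haplotype depth), with Normal fragment lengths, FR orientation
#' (mate 1 forward from the fragment start, mate 2 reverse-complemented from
#' the fragment end) and independent per-base substitution errors.
#'
#' @param haplotype_pair List of two named character vectors (the two
#'   haplotypes of a diploid sample).
#' @param coverage Per-haplotype sequencing depth (> 0).
#' @param read_len Read length.
#' @param frag_mean,frag_sd Fragment length distribution (must satisfy
#'   `frag_mean > read_len`).
#' @param base_error Per-base substitution error rate.
#' @param seed Optional integer seed.
#' @param fastq_prefix If non-NULL, FASTQ files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written (mate names suffixed `/1`, `/2`).
#' @return `data.frame` with columns `qname`, `seq1`, `seq2` (and,
#'   for reference, `hap`, `chrom`, `frag_start`, `frag_len`).
#' @export
simulate_reads <- function(haplotype_pair, coverage, read_len = 100L,
                           frag_mean = 400, frag_sd = 50, base_error = 0.001,
                           seed = NULL, fastq_prefix = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  if (frag_mean <= read_len) stop("frag_mean must exceed read_len")
  with_seed(seed, {
    out <- list()
    for (h in 1:2) {
      hap <- haplotype_pair[[h]]
      for (ch in names(hap)) {
        L <- nchar(hap[[ch]])
        n <- round(coverage * L / (2 * read_len))
        if (n == 0) next
        fl <- pmin(pmax(round(stats::rnorm(n, frag_mean, frag_sd)),
                        read_len), L)
        st <- floor(stats::runif(n, 0, L - fl + 1))  # 0-based fragment start
        frag <- substring(hap[[ch]], st + 1L, st + fl)
        r1 <- substr(frag, 1L, read_len)
        r2 <- revcomp(substring(frag, fl - read_len + 1L, fl))
        out[[length(out) + 1L]] <- data.frame(
          hap = h, chrom = ch, frag_start = as.integer(st),
          frag_len = as.integer(fl), seq1 = r1, seq2 = r2,
          stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, out)
    reads$qname <- sprintf("frag%06d", seq_len(nrow(reads)))
    if (base_error > 0) {
      reads$seq1 <- add_base_errors(reads$seq1, base_error)
      reads$seq2 <- add_base_errors(reads$seq2, base_error)
    }
    reads <- reads[, c("qname", "seq1", "seq2", "hap", "chrom",
                       "frag_start", "frag_len")]
    if (!is.null(fastq_prefix)) {
      write_fastq(stats::setNames(reads$seq1, paste0(reads$qname, "/1")),
                  paste0(fastq_prefix, "_1.fastq"))
      write_fastq(stats::setNames(reads$seq2, paste0(reads$qname, "/2")),
                  paste0(fastq_prefix, "_2.fastq"))
    }
    reads
  })
}

add_base_errors <- function(seqs, rate) {
  n_err <- stats::rpois(length(seqs), rate * nchar(seqs))
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample(length(s), min(n_err[i], length(s)))
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

write_fastq <- function(records, path) {
  qual <- vapply(nchar(records), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(records)), unname(records),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Synthetic ERV consensus sequences
#'
#' Generates a deterministic synthetic stand-in for the ERV lineage's
#' consensus: a 457-bp LTR with the canonical `TG...CA` termini, and an
#' internal proviral segment carrying non-overlapping gag, pol, and env open
#' reading frames (ATG-initiated, stop-free, stop-terminated). These are
#' synthetic sequences for testing the pipeline machinery, not curated
#' repeat-library entries.
#'
#' @param seed Integer seed (fixed default so every session sees the same
#'   consensus).
#' @param ltr_length LTR length (default 457).
#' @param gene_lengths_aa Named integer vector of ORF lengths (amino acids,
#'   excluding the stop) for gag, pol, env.
#' @param utr_lengths Lengths of the 5' UTR, the two inter-ORF spacers, and
#'   the 3' UTR of the internal segment.
#' @return List with `ltr`, `internal`, `provirus` (LTR+internal+LTR),
#'   and `genes`: a `data.frame` of 1-based start/end (stop codon included)
#'   of each gene on the provirus.
#' @export
synthetic_erv_consensus <- function(seed = 99L, ltr_length = 457L,
                                    gene_lengths_aa = c(gag = 550L, pol = 1150L,
                                                        env = 580L),
                                    utr_lengths = c(450L, 30L, 30L, 300L)) {
  with_seed(seed, {
    ltr <- paste0("TG", random_dna(ltr_length - 4L), "CA")
    orf <- function(aa) {
      codons <- sense_codons()
      codons <- setdiff(codons, "ATG")  # avoid nested starts dominating
      body <- sample(codons, aa - 1L, replace = TRUE)
      paste0("ATG", paste(body, collapse = ""), "TAA")
    }
    genes <- lapply(gene_lengths_aa, orf)
    internal <- paste0(random_dna(utr_lengths[1]), genes$gag,
                       random_dna(utr_lengths[2]), genes$pol,
                       random_dna(utr_lengths[3]), genes$env,
                       random_dna(utr_lengths[4]))
    pv <- paste0(ltr, internal, ltr)
    gstart <- nchar(ltr) + cumsum(c(utr_lengths[1] + 1L,
      nchar(genes$gag) + utr_lengths[2],
      nchar(genes$pol) + utr_lengths[3])) +
      c(0L, 0L, 0L)
    gdf <- data.frame(gene = names(gene_lengths_aa),
                      start = as.integer(gstart),
                      end = as.integer(gstart + nchar(unlist(genes)) - 1L),
                      stringsAsFactors = FALSE)
    list(ltr = ltr, internal = internal, provirus = pv, genes = gdf)
  })
}

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Write an insertion truth set as TSV
#'
#' @param truth Truth `data.frame` from [make_truth_insertions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
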