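#' Count insertions with a gene model within each window size
#'
#' An insertion counts for window `w` if any gene interval, expanded by
#' `w` kb on both sides, contains its breakpoint; window 0 is strict
#' overlap (intronic/exonic). Counts are non-decreasing in window size.
#'
#' @param insertions `data.frame` with `chrom` and `pos` (0-based
#'   breakpoint).
#' @param genes Interval `data.frame` (`chrom`, `start`, `end`, 0-based
#'   half-open), gene intervals merged per gene.
#' @param windows_kb Numeric vector of window sizes in kb.
#' @return `data.frame`: `window_kb`, `n_with_gene`, `n_total`.
#' @export
gene_window_counts <- function(insertions, genes,
                               windows_kb = c(0, 5, 10, 25, 50, 100)) {
  n <- nrow(insertions)
  if (n == 0 || nrow(genes) == 0) {
    return(data.frame(window_kb = windows_kb,
                      n_with_gene = 0L, n_total = n))
  }
  ins <- GenomicRanges::GRanges(insertions$chrom,
                                IRanges::IRanges(insertions$pos + 1L,
                                                 insertions$pos + 1L))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  counts <- vapply(windows_kb, function(w) {
    gw <- suppressWarnings(g + as.integer(w * 1000))
    # insertions on chromosomes absent from the gene set count as gene-free
    sum(suppressWarnings(IRanges::overlapsAny(ins, gw)))
  }, numeric(1))
  data.frame(window_kb = windows_kb, n_with_gene = as.integer(counts),
             n_total = n)
}

#' Randomly shuffle insertion positions genome-wide
#'
#' Each insertion is independently relocated to a uniform position: the
#' chromosome is drawn proportional to its length and the position uniform
#' along it. The insertion count is preserved.
#'
#' @param insertions `data.frame` with `chrom`/`pos` (only its row count is
#'   used), or an integer count.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param seed Optional integer seed.
#' @param per_chromosome If TRUE, per-chromosome insertion counts are
#'   preserved and shuffling is within chromosomes.
#' @return `data.frame` with `chrom`, `pos`.
#' @export
shuffle_insertions <- function(insertions, chrom_lengths, seed = NULL,
                               per_chromosome = FALSE) {
  n <- if (is.data.frame(insertions)) nrow(insertions) else as.integer(insertions)
  with_seed(seed, {
    if (per_chromosome && is.data.frame(insertions)) {
      chrom <- insertions$chrom
    } else {
      chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                      prob = chrom_lengths)
    }
    pos <- floor(stats::runif(n, 0, chrom_lengths[chrom]))
    data.frame(chrom = chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' One-sided depletion p-value from a permutation null
#'
#' `p = #\{permuted <= observed\} / n_perm`. A p of zero is reported with a
#' `label` attribute `"< 1/n_perm"` since the permutation resolution is
#' exhausted.
#'
#' @param observed Observed count of insertions with a nearby gene.
#' @param permuted_counts Vector of counts from permuted insertion sets.
#' @return Numeric p in `[0, 1]` with attribute `label` (a printable
#'   string, e.g. `"< 0.001"` when no permutation was as small).
#' @export
depletion_pvalue <- function(observed, permuted_counts) {
  stopifnot(length(permuted_counts) > 0)
  n <- length(permuted_counts)
  p <- sum(permuted_counts <= observed) / n
  attr(p, "label") <- if (p == 0) paste0("< ", format(1 / n)) else format(p)
  p
}

#' Permutation test for depletion of insertions near genes
#'
#' For each window size, the observed number of insertions with a gene
#' within the window is compared with the counts from `n_perm` random
#' genome-wide shuffles of the insertion positions; the one-sided p-value
#' is the fraction of permuted sets with a count less than or equal to the
#' observed one.
#'
#' @param insertions `data.frame` with `chrom`, `pos`.
#' @param genes Gene interval `data.frame` (0-based half-open).
#' @param chrom_lengths Named numeric vector.
#' @param windows_kb Window sizes (kb).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List: `table` (`data.frame` with `window_kb`, `observed`,
#'   `mean_permuted`, `p`, `p_label`) and `permuted` (matrix n_perm x
#'   windows of permuted counts, for audit).
#' @export
gene_depletion_test <- function(insertions, genes, chrom_lengths,
                                windows_kb = c(0, 5, 10, 25, 50, 100),
                                n_perm = 1000L, seed = NULL) {
  obs <- gene_window_counts(insertions, genes, windows_kb)
  n <- nrow(insertions)
  # precompute merged expanded intervals per window/chromosome once, then
  # test all n_perm * n shuffled positions with findInterval (the slow
  # GRanges path above is kept for the observed counts as a cross-check)
  merged <- lapply(windows_kb, function(w) {
    gw <- genes
    gw$start <- gw$start - as.integer(w * 1000)
    gw$end <- gw$end + as.integer(w * 1000)
    lapply(split(gw, gw$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      list(starts = BiocGenerics::start(ir) - 1L, ends = BiocGenerics::end(ir))
    })
  })
  perm <- with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n_perm * n, replace = TRUE,
                    prob = chrom_lengths)
    pos <- floor(stats::runif(n_perm * n, 0, chrom_lengths[chrom]))
    pid <- rep(seq_len(n_perm), each = n)
    m <- matrix(0L, nrow = n_perm, ncol = length(windows_kb))
    for (j in seq_along(windows_kb)) {
      hit <- logical(n_perm * n)
      for (ch in names(merged[[j]])) {
        sel <- chrom == ch
        if (!any(sel)) next
        iv <- merged[[j]][[ch]]
        ix <- findInterval(pos[sel], iv$starts)
        hit[sel] <- ix > 0L & pos[sel] < iv$ends[pmax(ix, 1L)]
      }
      cnt <- tabulate(pid[hit], nbins = n_perm)
      m[, j] <- as.integer(cnt)
    }
    m
  })
  colnames(perm) <- paste0("w", windows_kb)
  ps <- lapply(seq_along(windows_kb), function(j)
    depletion_pvalue(obs$n_with_gene[j], perm[, j]))
  list(table = data.frame(
    window_kb = windows_kb,
    observed = obs$n_with_gene,
    mean_permuted = colMeans(perm),
    p = vapply(ps, as.numeric, numeric(1)),
    p_label = vapply(ps, function(p) attr(p, "label"), character(1)),
    stringsAsFactors = FALSE), permuted = perm)
}
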