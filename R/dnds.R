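# Nei-Gojobori (1986) dN/dS with pathway-averaged difference counting and
# Jukes-Cantor correction. Site fractions are computed per codon position
# from the 3 single-base neighbors (neighbors that create a stop codon are
# excluded and the fraction renormalized, so every position contributes one
# site and S + N = 3 per codon); differences between codon pairs are
# averaged over all minimal mutational pathways that avoid stop codons.

codon_table_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

codon_aa <- function(codon) unname(genetic_code()[codon])

# synonymous site count of one codon (sum of per-position syn fractions)
syn_sites_codon <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    cur <- substr(codon, p, p)
    nb <- vapply(setdiff(bases, cur), function(b) {
      x <- codon; substr(x, p, p) <- b; x
    }, character(1))
    nb_aa <- gc[nb]
    valid <- nb_aa != "*"
    if (!any(valid)) next  # all neighbors are stops: position contributes 0
    s <- s + sum(nb_aa[valid] == aa) / sum(valid)
  }
  s
}

# pathway-averaged (syn, nonsyn) difference counts between two sense codons
codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- all_perms(pos)
  acc <- matrix(0, nrow = 0, ncol = 2)
  for (ord in perms) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && nxt != c2) { valid <- FALSE; break }
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) acc <- rbind(acc, c(sd, nd))
  }
  if (!nrow(acc)) {
    # every pathway passes through a stop codon; fall back to counting over
    # all pathways (degenerate case, not reachable for sense-codon pairs
    # one or two steps apart)
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      acc <- rbind(acc, c(sd, nd))
    }
  }
  c(sd = mean(acc[, 1]), nd = mean(acc[, 2]))
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# cached lookup tables over the 61 sense codons
codon_tables <- function() {
  if (!is.null(codon_table_env$S)) return(as.list(codon_table_env))
  sense <- sense_codons()
  S <- vapply(sense, syn_sites_codon, numeric(1))
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- codon_path_diffs(sense[i], sense[j])
      sd[i, j] <- d["sd"]; nd[i, j] <- d["nd"]
    }
  }
  codon_table_env$S <- S
  codon_table_env$sd <- sd
  codon_table_env$nd <- nd
  codon_table_env$sense <- sense
  as.list(codon_table_env)
}

split_codons <- function(seq) {
  L <- nchar(seq)
  if (L %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, L, 3), seq(3, L, 3))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)  # correction undefined
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori dN/dS between two coding sequences
#'
#' Synonymous/nonsynonymous site counts are averaged over the two sequences
#' (per-position synonymous fractions from the single-base neighbors, stop
#' neighbors excluded with renormalization). Differences are resolved by
#' averaging over all minimal mutational pathways between each codon pair,
#' skipping pathways through stop codons. Proportions are Jukes-Cantor
#' corrected: `d = -(3/4) ln(1 - (4/3) p)`. A codon-bootstrap Z test of
#' dN = dS is available.
#'
#' @param codon_seq_a,codon_seq_b In-frame coding sequences of equal length
#'   (no internal stop codons).
#' @param bootstrap Number of codon bootstrap resamples for the Z test of
#'   strict neutrality (0 to skip).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `ng86`: `Sd`, `Nd` (pathway-averaged difference
#'   counts), `S`, `N` (site counts, `S + N = 3 * codons`), `pS`, `pN`,
#'   `dS`, `dN` (NA with `dS_undefined`/`dN_undefined` flags when p >= 3/4),
#'   `ratio` (dN/dS; NA when undefined or dS = 0), and when bootstrapped
#'   `Z`, `p_value` (two-sided normal).
#' @examples
#' r <- ng86_dnds("TTTGGG", "TTAGGG")
#' c(r$Sd, r$Nd)
#' @export
ng86_dnds <- function(codon_seq_a, codon_seq_b, bootstrap = 0L, seed = NULL) {
  if (nchar(codon_seq_a) != nchar(codon_seq_b))
    stop("sequences must have equal length")
  ca <- split_codons(toupper(codon_seq_a))
  cb <- split_codons(toupper(codon_seq_b))
  tab <- codon_tables()
  if (any(!ca %in% tab$sense) || any(!cb %in% tab$sense))
    stop("internal stop codon (or ambiguous base) in input")
  Sa <- tab$S[ca]; Sb <- tab$S[cb]
  S <- (sum(Sa) + sum(Sb)) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, tab$sense), match(cb, tab$sense))
  sd_i <- tab$sd[idx]
  nd_i <- tab$nd[idx]
  Sd <- sum(sd_i); Nd <- sum(nd_i)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  out <- list(Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
              dS = dS, dN = dN,
              dS_undefined = !is.na(pS) && pS >= 3 / 4,
              dN_undefined = !is.na(pN) && pN >= 3 / 4,
              ratio = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_)
  if (bootstrap > 0) {
    nc <- length(ca)
    stat <- function(ix) {
      s <- (sum(Sa[ix]) + sum(Sb[ix])) / 2
      n <- 3 * length(ix) - s
      ds <- jc_correct(if (s > 0) sum(sd_i[ix]) / s else NA_real_)
      dn <- jc_correct(if (n > 0) sum(nd_i[ix]) / n else NA_real_)
      dn - ds
    }
    boots <- with_seed(seed, {
      vapply(seq_len(bootstrap),
             function(i) stat(sample.int(nc, nc, replace = TRUE)),
             numeric(1))
    })
    se <- stats::sd(boots, na.rm = TRUE)
    z <- if (!is.na(dN) && !is.na(dS) && !is.na(se) && se > 0)
      (dN - dS) / se else NA_real_
    out$Z <- z
    out$p_value <- if (!is.na(z)) 2 * stats::pnorm(-abs(z)) else NA_real_
  }
  structure(out, class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf("Nei-Gojobori: Sd=%.3f Nd=%.3f S=%.2f N=%.2f\n",
              x$Sd, x$Nd, x$S, x$N))
  cat(sprintf("  pS=%.4f pN=%.4f dS=%s dN=%s dN/dS=%s\n",
              x$pS, x$pN, format(x$dS), format(x$dN), format(x$ratio)))
  if (!is.null(x$Z)) cat(sprintf("  Z=%.3f p=%.4f (codon bootstrap)\n",
                                 x$Z, x$p_value))
  invisible(x)
}

#' Average pairwise dN/dS over a set of coding sequences
#'
#' Mean of pairwise dN/dS ratios over pairs where both dS and dN are
#' defined and dS > 0; excluded pairs are reported.
#'
#' @param seqs Named character vector of equal-length in-frame sequences.
#' @return List: `mean_ratio`, `pairs` (`data.frame` with per-pair values),
#'   `excluded` (pair labels with undefined or zero dS).
#' @export
average_dnds <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2)
  ids <- names(seqs)
  rows <- list(); excluded <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- ng86_dnds(seqs[[i]], seqs[[j]])
      lbl <- paste(ids[i], ids[j], sep = ":")
      rows[[lbl]] <- data.frame(a = ids[i], b = ids[j], dN = r$dN, dS = r$dS,
                                ratio = r$ratio, stringsAsFactors = FALSE)
      if (is.na(r$ratio)) excluded <- c(excluded, lbl)
    }
  }
  pairs <- do.call(rbind, rows)
  list(mean_ratio = mean(pairs$ratio, na.rm = TRUE), pairs = pairs,
       excluded = excluded)
}
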