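# Independent brute-force oracle for Nei-Gojobori counting, written against
# the method definition rather than the package implementation: synonymous
# site fractions by explicit neighbor enumeration, pathway averages by
# explicit enumeration of substitution orderings.

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)

oracle_neighbors <- function(codon, pos) {
  cur <- substr(codon, pos, pos)
  out <- character(0)
  for (b in c("A", "C", "G", "T")) {
    if (b == cur) next
    x <- codon
    substr(x, pos, pos) <- b
    out <- c(out, x)
  }
  out
}

oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    nb <- oracle_neighbors(codon, pos)
    aa <- oracle_code[nb]
    ok <- aa != "*"
    if (sum(ok) == 0) next
    total <- total + sum(aa[ok] == oracle_code[codon]) / sum(ok)
  }
  total
}

# all orderings of a small vector, written out by hand
oracle_orderings <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  if (n == 2) return(list(v, v[c(2, 1)]))
  list(v[c(1, 2, 3)], v[c(1, 3, 2)], v[c(2, 1, 3)],
       v[c(2, 3, 1)], v[c(3, 1, 2)], v[c(3, 2, 1)])
}

oracle_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- list()
  for (ord in oracle_orderings(pos)) {
    cur <- c1
    sd <- 0; nd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_code[nxt] == "*" && nxt != c2) { blocked <- TRUE; break }
      if (oracle_code[cur] == oracle_code[nxt]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) paths[[length(paths) + 1L]] <- c(sd, nd)
  }
  if (!length(paths)) return(c(NA, NA))
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i)
    oracle_pair_diffs(ca[i], cb[i]), numeric(2)))
  list(S = S, N = N, Sd = d[1], Nd = d[2])
}
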