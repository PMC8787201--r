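# Independent oracles, deliberately implemented differently from the package.

# per-pair energy lookup by name, no matrices
oracle_pair_energy <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key, "CG" = 6.37, "AU" = 4.25, "GU" = 2.12, "AC" = 2.12, 0)
}

# duplex energy by explicit position-by-position summation
oracle_duplex_dG <- function(mirna, site) {
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  stopifnot(length(m) == length(s))
  L <- length(m)
  -sum(vapply(seq_len(L), function(i) oracle_pair_energy(s[i], m[L + 1 - i]), 0))
}

oracle_dGm <- function(mirna) {
  m <- strsplit(mirna, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  -sum(vapply(m, function(b) oracle_pair_energy(b, comp[[b]]), 0))
}

# brute-force window scan: re-derive every site from scratch
oracle_scan <- function(mirna, txseq, threshold) {
  lm <- nchar(mirna)
  w <- nchar(txseq) - lm + 1
  if (w < 1) return(data.frame(start = integer(), dG = numeric(),
                               ratio = numeric()))
  dgm <- abs(oracle_dGm(mirna))
  rows <- lapply(seq_len(w), function(s) {
    dg <- oracle_duplex_dG(mirna, substr(txseq, s, s + lm - 1))
    ratio <- 100 * abs(dg) / dgm
    if (ratio >= threshold - 1e-9) data.frame(start = s, dG = dg, ratio = ratio)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(start = integer(), dG = numeric(),
                               ratio = numeric()) else out
}

# regex-based GCC run oracle
oracle_gcc_run <- function(seq) {
  m <- gregexpr("(?:GCC)+", seq)[[1]]
  if (m[1] == -1) return(list(start = NA, run_length = 0))
  len <- attr(m, "match.length")
  best <- which.max(len)  # leftmost maximum
  list(start = m[best], run_length = len[best])
}

# exhaustive tolerant-run oracle over all (start, end) triplet windows
oracle_tolerant_run <- function(seq, max_bad) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  is_gcc <- function(p) p + 2 <= n && ch[p] == "G" && ch[p + 1] == "C" && ch[p + 2] == "C"
  best <- 0
  for (p in seq_len(max(n - 2, 0))) {
    if (!is_gcc(p)) next
    q <- p
    while (q + 2 <= n) {
      ntrip <- (q - p) / 3 + 1
      bad <- ntrip - sum(vapply(seq(p, q, by = 3), is_gcc, TRUE))
      if (is_gcc(q) && bad <= max_bad) best <- max(best, 3 * ntrip)
      q <- q + 3
    }
  }
  best
}

random_rna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "U")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
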