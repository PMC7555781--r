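# Independent brute-force oracles.  These deliberately use different
# algorithms from the package internals: substring-shift identities for
# SSRs, per-position character scans for mapping, and direct probability
# enumeration for the exact test.

# SSR oracle: a 12-nt window is a period-p repeat iff its first 12-p
# characters equal its last 12-p characters shifted by p.
brute_ssr <- function(s) {
  n <- nchar(s)
  if (n < 12L) return(FALSE)
  for (j in seq_len(n - 11L)) {
    w <- substr(s, j, j + 11L)
    for (p in 1:3) {
      if (substr(w, 1L, 12L - p) == substr(w, p + 1L, 12L)) return(TRUE)
    }
  }
  FALSE
}

# Exhaustive per-position Hamming scan of 20-nt tags against a set of
# sequences.  Returns a data.frame (tag, seqname, pos0, mm) for mm <= max_mm.
brute_hamming_scan <- function(tags, seqs, max_mm = 1L) {
  out <- list()
  for (sn in names(seqs)) {
    chars <- strsplit(seqs[[sn]], "")[[1]]
    npos <- length(chars) - 19L
    if (npos < 1L) next
    M <- vapply(seq_len(npos), function(p) chars[p:(p + 19L)],
                character(20L))
    for (ti in seq_along(tags)) {
      tv <- strsplit(tags[ti], "")[[1]]
      mm <- colSums(M != tv)
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          tag = ti, seqname = sn, pos0 = hit - 1L, mm = mm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag = integer(0), seqname = character(0),
                      pos0 = integer(0), mm = integer(0)))
  }
  do.call(rbind, out)
}

# Conditional binomial oracle for the dispersion-0 exact test: both
# conditions scaled to the geometric-mean library size, pooled, and the
# two-sided p-value obtained by summing binomial(t, 1/2) probabilities no
# larger than the observed outcome's.
brute_exact_binom <- function(rna, pare, rna_sizes, pare_sizes) {
  ref <- exp(mean(log(c(rna_sizes, pare_sizes))))
  a <- round(sum(rna * ref / rna_sizes))
  b <- round(sum(pare * ref / pare_sizes))
  t <- a + b
  if (t == 0) return(1)
  pr <- choose(t, 0:t) / 2^t
  sum(pr[pr <= pr[a + 1] * (1 + 1e-12)])
}

# Textbook covariance-formula R^2.
brute_r2 <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  (sxy / sqrt(sxx * syy))^2
}

random_20mers <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
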