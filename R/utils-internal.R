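# Internal helpers shared across modules.

# Derive a stage-specific RNG seed from the user seed; stays well below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 19999999L) * 100L + as.integer(stage)
}

# sample() treats a length-1 numeric first argument as 1:x; these wrappers
# avoid that pitfall for index vectors and integer ranges.
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Random DNA of length n (equal base frequencies), as a single string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a DNAStringSet or named character vector to named character.
as_seq_vector <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else {
    out <- as.character(x)
    names(out) <- names(x)
  }
  if (is.null(names(out)) || anyNA(names(out))) {
    stop("sequences must be named")
  }
  out
}

# utf8 code matrix (nchar x n) for equal-length sequences.
seq_int_matrix <- function(seqs, width) {
  if (length(seqs) == 0L) {
    return(matrix(integer(0), nrow = width, ncol = 0L))
  }
  codes <- utf8ToInt(paste(seqs, collapse = ""))
  if (length(codes) != width * length(seqs)) {
    stop("sequences must all have width ", width)
  }
  matrix(codes, nrow = width)
}

# 2-bit encode k-mers starting at every position of an utf8 code vector.
# Codes containing non-ACGT get values >= 4^k and therefore never collide
# with clean k-mers.
.BASE_CODE <- local({
  z <- rep(4L, 256L)
  z[utf8ToInt("A") + 1L] <- 0L
  z[utf8ToInt("C") + 1L] <- 1L
  z[utf8ToInt("G") + 1L] <- 2L
  z[utf8ToInt("T") + 1L] <- 3L
  z
})

encode_kmers <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0))
  b <- .BASE_CODE[codes + 1L]
  acc <- numeric(n)
  for (i in seq_len(k)) {
    acc <- acc + b[i:(i + n - 1L)] * 5^(k - i)
  }
  acc
}

TAG_WIDTH <- 20L
SEED_K <- 10L

# Split-seed index over subject sequences for Hamming <= 1 lookup of 20-mers:
# any 20-mer matching with at most one mismatch matches one 10-mer half
# exactly.  Subjects may have arbitrary length >= 20.
kmer_index <- function(subjects) {
  subjects <- as_seq_vector(subjects)
  codes <- lapply(subjects, utf8ToInt)
  tabs <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    L <- length(codes[[i]])
    npos <- L - TAG_WIDTH + 1L
    if (npos < 1L) {
      tabs[[i]] <- data.table::data.table(
        subject = integer(0), pos0 = integer(0), seed = numeric(0),
        half = integer(0))
      next
    }
    km <- encode_kmers(codes[[i]], SEED_K)
    pos0 <- 0:(npos - 1L)
    tabs[[i]] <- data.table::data.table(
      subject = i,
      pos0 = c(pos0, pos0),
      seed = c(km[pos0 + 1L], km[pos0 + 1L + SEED_K]),
      half = rep(1:2, each = npos))
  }
  tab <- data.table::rbindlist(tabs)
  tab <- tab[seed < 5^SEED_K]  # halves containing non-ACGT are unindexable
  data.table::setkey(tab, seed)
  lens <- vapply(codes, length, integer(1))
  structure(list(table = tab, codes = unlist(codes, use.names = FALSE),
                 offsets = cumsum(c(0L, lens[-length(lens)])),
                 lens = lens, names = names(subjects)),
            class = "kmer_index")
}

# Index over a contig set plus its reverse complement (for locus counting
# on both strands).
both_strand_index <- function(seqs) {
  seqs <- as_seq_vector(seqs)
  both <- c(seqs, revcomp(seqs))
  names(both) <- c(names(seqs), paste0(names(seqs), "_rc"))
  kmer_index(both)
}

# All (query, subject, pos0) with Hamming distance <= max_mismatch between
# the 20-nt query and subject[pos0 .. pos0+19] (0-based).  Queries are
# 20-nt character strings; returns a data.table (query, subject, pos0, mm).
hamming_hits <- function(queries, index, max_mismatch = 1L) {
  stopifnot(inherits(index, "kmer_index"))
  empty <- data.table::data.table(
    query = integer(0), subject = integer(0), pos0 = integer(0),
    mm = integer(0))
  if (length(queries) == 0L || nrow(index$table) == 0L) return(empty)
  qm <- seq_int_matrix(queries, TAG_WIDTH)
  qb <- matrix(.BASE_CODE[qm + 1L], nrow = TAG_WIDTH)
  pow <- 5^(SEED_K - seq_len(SEED_K))
  seed1 <- colSums(qb[1:SEED_K, , drop = FALSE] * pow)
  seed2 <- colSums(qb[(SEED_K + 1L):TAG_WIDTH, , drop = FALSE] * pow)
  qtab <- data.table::data.table(
    query = rep(seq_along(queries), 2L),
    seed = c(seed1, seed2),
    qhalf = rep(1:2, each = length(queries)))
  qtab <- qtab[seed < 5^SEED_K]
  # candidate positions share an exact half at the matching half offset
  cand <- index$table[qtab, on = c("seed", half = "qhalf"),
                      allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0L) return(empty)
  cand <- unique(cand[, list(query, subject, pos0)])
  # verify full Hamming distance against the concatenated subject codes
  start <- index$offsets[cand$subject] + cand$pos0
  idx <- rep(start, each = TAG_WIDTH) + seq_len(TAG_WIDTH)
  cand[, mm := .colSums(index$codes[idx] != qm[, cand$query, drop = FALSE],
                        TAG_WIDTH, nrow(cand))]
  cand <- cand[mm <= max_mismatch]
  data.table::setorder(cand, query, subject, pos0)
  cand[]
}
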