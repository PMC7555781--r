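# Read standardization and filtering: adapter trimming to 20-nt tags,
# simple-sequence-repeat removal, genomic multi-hit and mitochondrial
# filters, and 1-mismatch mapping onto cDNAs.

#' Detect a 12-nt simple sequence repeat
#'
#' A sequence is flagged when some 12-nt window is a perfect period-1,
#' period-2 or period-3 repeat (w[i] == w[i+p] for all valid i).
#' Equivalently: the shifted self-comparison at lag p contains a run of at
#' least 12 - p consecutive matches.
#'
#' @param sequence character vector of nucleotide strings.
#' @return logical vector; sequences shorter than 12 nt are FALSE.
#' @export
detect_ssr <- function(sequence) {
  out <- logical(length(sequence))
  lens <- nchar(sequence)
  # batch equal-length sequences: a period-p SSR is a run of >= 12 - p
  # consecutive matches in the lag-p self-comparison
  for (L in unique(lens)) {
    if (L < 12L) next
    sel <- which(lens == L)
    M <- seq_int_matrix(sequence[sel], L)
    flag <- logical(length(sel))
    for (p in 1:3) {
      eq <- M[seq_len(L - p), , drop = FALSE] ==
        M[(p + 1L):L, , drop = FALSE]
      k <- 12L - p
      nwin <- (L - p) - k + 1L
      acc <- eq[seq_len(nwin), , drop = FALSE]
      for (j in seq_len(k - 1L)) {
        acc <- acc & eq[j + seq_len(nwin), , drop = FALSE]
      }
      flag <- flag | colSums(acc) > 0L
    }
    out[sel] <- flag
  }
  out
}

#' Trim raw reads to 20-nt tags
#'
#' Removes the 3' adapter at its first (leftmost) exact occurrence, allowing
#' a truncated adapter at the read end with a minimum overlap of 3 nt.
#' Reads shorter than 20 nt after trimming are discarded; longer reads are
#' truncated to their first 20 nt.  Reads containing characters outside
#' ACGTN are discarded with a warning.  Identical sequences are collapsed
#' with summed counts.
#'
#' @param reads character vector of reads (5' to 3'), or a data frame with
#'   columns sequence and count.
#' @param adapter 3' adapter sequence, or NULL to skip trimming.
#' @param min_overlap minimum adapter-prefix overlap at the read end.
#' @return data frame: sequence (20 nt), count; attribute
#'   \code{trim_log} with discard tallies.
#' @export
trim_reads <- function(reads, adapter = NULL, min_overlap = 3L) {
  if (is.data.frame(reads)) {
    dt <- data.table::data.table(sequence = as.character(reads$sequence),
                                 count = as.integer(reads$count))
  } else {
    dt <- data.table::data.table(sequence = as.character(reads), count = 1L)
  }
  dt <- dt[, list(count = sum(count)), by = "sequence"]
  bad <- grepl("[^ACGTN]", dt$sequence)
  n_bad <- sum(dt$count[bad])
  if (n_bad > 0) {
    warning(n_bad, " read(s) with characters outside ACGTN discarded")
    dt <- dt[!bad]
  }
  trim_one <- function(s) {
    if (is.null(adapter)) return(s)
    n <- nchar(s)
    alen <- nchar(adapter)
    for (j in seq_len(n)) {
      k <- min(alen, n - j + 1L)
      if (k < min_overlap) break
      if (substr(s, j, j + k - 1L) == substr(adapter, 1L, k)) {
        return(substr(s, 1L, j - 1L))
      }
    }
    s
  }
  trimmed <- vapply(dt$sequence, trim_one, character(1), USE.NAMES = FALSE)
  short <- nchar(trimmed) < TAG_WIDTH
  n_short <- sum(dt$count[short])
  out <- data.table::data.table(
    sequence = substr(trimmed[!short], 1L, TAG_WIDTH),
    count = dt$count[!short])
  out <- out[, list(count = sum(count)), by = "sequence"]
  data.table::setorder(out, sequence)
  out <- as.data.frame(out)
  attr(out, "trim_log") <- c(discarded_bad_chars = n_bad,
                             discarded_short = n_short)
  out
}

#' Filter tags against the genome
#'
#' Applies, in order: (1) simple-sequence-repeat removal
#' (\code{\link{detect_ssr}}); (2) removal of tags hitting more than
#' \code{max_hits} genomic loci at up to one mismatch, both strands;
#' (3) removal of tags matching the mitochondrial sequence exactly (either
#' strand).  Each stage's retained set is a subset of the previous one.
#'
#' @param tags data frame: sequence, count (20-nt tags).
#' @param genome named character vector or DNAStringSet of nuclear contigs,
#'   or a prebuilt both-strand index from \code{\link{genome_index}} (reuse
#'   it when filtering several libraries against the same genome).
#' @param mito mitochondrial sequence (single contig or
#'   \code{\link{genome_index}}), or NULL to skip.
#' @param max_hits maximum allowed genomic loci at <= 1 mismatch.
#' @return filtered tag data frame; attribute \code{filter_log} with
#'   per-stage retained tag-type and read counts.
#' @export
filter_tags <- function(tags, genome, mito = NULL, max_hits = 20L) {
  if (missing(genome) || is.null(genome)) {
    stop("a genome is required for the multi-hit filter")
  }
  log <- list()
  tally <- function(t) c(types = nrow(t), reads = sum(t$count))
  log$input <- tally(tags)
  tags <- tags[!detect_ssr(tags$sequence), , drop = FALSE]
  log$after_ssr <- tally(tags)
  if (!inherits(genome, "kmer_index")) genome <- genome_index(genome)
  if (nrow(tags) > 0L) {
    hits <- hamming_hits(tags$sequence, genome, max_mismatch = 1L)
    nhits <- tabulate(hits$query, nbins = nrow(tags))
    tags <- tags[nhits <= max_hits, , drop = FALSE]
  }
  log$after_multihit <- tally(tags)
  if (!is.null(mito) && nrow(tags) > 0L) {
    if (!inherits(mito, "kmer_index")) {
      if (is.character(mito) && is.null(names(mito))) {
        names(mito) <- "chrM"
      }
      mito <- genome_index(mito)
    }
    mhits <- hamming_hits(tags$sequence, mito, max_mismatch = 0L)
    tags <- tags[!seq_len(nrow(tags)) %in% mhits$query, , drop = FALSE]
  }
  log$after_mito <- tally(tags)
  rownames(tags) <- NULL
  attr(tags, "filter_log") <- do.call(rbind, log)
  tags
}

#' Prebuilt sequence indexes for repeated mapping
#'
#' \code{genome_index} indexes a contig set together with its reverse
#' complement (for strand-aware locus counting); \code{cdna_index} indexes
#' cDNA sequences on the transcript strand only.  Both return an index
#' reusable across libraries in \code{\link{filter_tags}} and
#' \code{\link{map_tags}}.
#'
#' @param seqs named character vector or DNAStringSet.
#' @return an opaque index object.
#' @export
genome_index <- function(seqs) {
  both_strand_index(seqs)
}

#' @rdname genome_index
#' @export
cdna_index <- function(seqs) {
  seqs <- as_seq_vector(seqs)
  if (any(nchar(seqs) < TAG_WIDTH)) {
    stop("all cDNA sequences must be at least 20 nt")
  }
  kmer_index(seqs)
}

#' Map tags to cDNAs with up to one mismatch
#'
#' A tag is assigned to every (transcript, position) whose 20-nt cDNA
#' substring is within Hamming distance 1; a tag hitting several isoforms
#' contributes its full count to each.  Reads-per-million are computed from
#' the total count of tags with at least one cDNA hit (each distinct read
#' counted once regardless of isoform multiplicity).
#'
#' @param tags filtered tag data frame (sequence, count).
#' @param cdna named character vector or DNAStringSet of cDNA sequences, or
#'   a prebuilt \code{\link{cdna_index}}.
#' @param library_id,library_type,replicate library metadata recorded in the
#'   table; \code{library_type} is "PARE" or "CPARE".
#' @return TagTable data frame: library_id, library_type, replicate,
#'   transcript_id, position (0-based 5'-end coordinate), raw_count, rpm;
#'   attributes \code{total_mapped_reads} and \code{unmapped_reads}.
#' @export
map_tags <- function(tags, cdna, library_id = "lib",
                     library_type = c("PARE", "CPARE"), replicate = 1L) {
  library_type <- match.arg(library_type)
  idx <- if (inherits(cdna, "kmer_index")) cdna else cdna_index(cdna)
  hits <- hamming_hits(tags$sequence, idx, max_mismatch = 1L)
  mapped <- unique(hits$query)
  total <- sum(tags$count[mapped])
  unmapped <- sum(tags$count) - total
  rec <- data.table::data.table(
    transcript_id = idx$names[hits$subject],
    position = hits$pos0,
    raw_count = tags$count[hits$query])
  rec <- rec[, list(raw_count = sum(raw_count)),
             by = c("transcript_id", "position")]
  data.table::setorder(rec, transcript_id, position)
  out <- data.frame(
    library_id = library_id,
    library_type = library_type,
    replicate = as.integer(replicate),
    as.data.frame(rec),
    stringsAsFactors = FALSE)
  out$rpm <- out$raw_count * 1e6 / total
  attr(out, "total_mapped_reads") <- total
  attr(out, "unmapped_reads") <- unmapped
  class(out) <- c("tag_table", "data.frame")
  out
}

#' Preprocess one raw tag library end-to-end
#'
#' Convenience wrapper: \code{\link{trim_reads}} then
#' \code{\link{filter_tags}} then \code{\link{map_tags}}.
#'
#' @inheritParams trim_reads
#' @inheritParams filter_tags
#' @inheritParams map_tags
#' @return list: \code{table} (the TagTable), \code{filtered_tags} (the
#'   retained tag multiset, used for window projection), \code{trim_log},
#'   \code{filter_log}.
#' @export
preprocess_library <- function(reads, cdna, genome, mito = NULL,
                               adapter = NULL, library_id = "lib",
                               library_type = c("PARE", "CPARE"),
                               replicate = 1L, max_hits = 20L) {
  library_type <- match.arg(library_type)
  tags <- trim_reads(reads, adapter)
  filt <- filter_tags(tags, genome, mito, max_hits = max_hits)
  tab <- map_tags(filt, cdna, library_id = library_id,
                  library_type = library_type, replicate = replicate)
  list(table = tab, filtered_tags = filt,
       trim_log = attr(tags, "trim_log"),
       filter_log = attr(filt, "filter_log"))
}
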