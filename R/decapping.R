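# Cap-window construction (+/- 200 nt around the TSS), projection of tag
# libraries into windows, empirical cap inference from C-PARE, and decap
# calling where the degradome Max-seq coincides with the cap.

WINDOW_FLANK <- 200L

#' Build +/- 200-nt transcription-start-site windows
#'
#' Each window concatenates 200 nt of genomic sequence upstream of the TSS
#' (on the transcript strand; reverse-complemented for minus-strand
#' transcripts) with the first 200 nt of the cDNA.  Offset 0 is the
#' annotated first transcribed nucleotide; full windows span offsets
#' -200..+199.  Windows with insufficient upstream sequence are truncated
#' and flagged.
#'
#' @param annotation annotation data frame.
#' @param genome named character vector or DNAStringSet of contigs.
#' @return data frame: transcript_id, sequence, upstream_len, truncated.
#' @export
build_windows <- function(annotation, genome) {
  genome <- as_seq_vector(genome)
  miss <- setdiff(annotation$chrom, names(genome))
  if (length(miss)) {
    stop("contig '", miss[1], "' missing from the genome")
  }
  chrs <- genome[annotation$chrom]
  tss <- annotation$tss
  plus <- annotation$strand == "+"
  up_len <- ifelse(plus,
                   pmin(WINDOW_FLANK, tss - 1L),
                   pmin(WINDOW_FLANK, nchar(chrs) - tss))
  upstream <- ifelse(plus,
                     substr(chrs, tss - up_len, tss - 1L),
                     substr(chrs, tss + 1L, tss + up_len))
  first <- ifelse(plus,
                  substr(chrs, tss, tss + WINDOW_FLANK - 1L),
                  substr(chrs, tss - WINDOW_FLANK + 1L, tss))
  if (any(!plus)) {
    upstream[!plus] <- revcomp(upstream[!plus])
    first[!plus] <- revcomp(first[!plus])
  }
  seqs <- paste0(upstream, first)
  data.frame(transcript_id = annotation$transcript_id,
             sequence = seqs,
             upstream_len = up_len,
             truncated = up_len < WINDOW_FLANK,
             stringsAsFactors = FALSE)
}

#' Index the window sequences for repeated projection
#'
#' @param windows window data frame from \code{\link{build_windows}}.
#' @return an opaque index object for \code{\link{project_tags_to_window}}.
#' @export
window_index <- function(windows) {
  kmer_index(stats::setNames(windows$sequence, windows$transcript_id))
}

#' Project tags into TSS windows
#'
#' A tag is assigned to every window offset where its 20-mer matches the
#' window sequence with at most one mismatch.  Offsets are relative to the
#' annotated TSS (offset 0 = first transcribed nucleotide).
#' Reads-per-million use the total count of tags with at least one window
#' hit as denominator.
#'
#' @param tags filtered tag data frame (sequence, count).
#' @param windows window data frame from \code{\link{build_windows}}.
#' @param library_id,library_type,replicate library metadata.
#' @param index prebuilt \code{\link{window_index}} for these windows
#'   (rebuilt when NULL).
#' @return window table data frame: library_id, library_type, replicate,
#'   transcript_id, offset, raw_count, rpm; attribute
#'   \code{total_mapped_reads}.
#' @export
project_tags_to_window <- function(tags, windows, library_id = "lib",
                                   library_type = c("CPARE", "PARE"),
                                   replicate = 1L, index = NULL) {
  library_type <- match.arg(library_type)
  idx <- if (is.null(index)) window_index(windows) else index
  hits <- hamming_hits(tags$sequence, idx, max_mismatch = 1L)
  total <- sum(tags$count[unique(hits$query)])
  rec <- data.table::data.table(
    transcript_id = windows$transcript_id[hits$subject],
    offset = hits$pos0 - windows$upstream_len[hits$subject],
    raw_count = tags$count[hits$query])
  rec <- rec[, list(raw_count = sum(raw_count)),
             by = c("transcript_id", "offset")]
  data.table::setorder(rec, transcript_id, offset)
  out <- data.frame(
    library_id = library_id,
    library_type = library_type,
    replicate = as.integer(replicate),
    as.data.frame(rec),
    stringsAsFactors = FALSE)
  out$rpm <- out$raw_count * 1e6 / total
  attr(out, "total_mapped_reads") <- total
  class(out) <- c("window_table", "data.frame")
  out
}

# Per-transcript in-window totals and Max-seq offsets of a window table.
window_max_stats <- function(wtable) {
  dt <- data.table::as.data.table(wtable)
  if (nrow(dt) == 0L) {
    return(data.frame(transcript_id = character(0), total = numeric(0),
                      max_offset = integer(0), max_rpm = numeric(0),
                      ratio = numeric(0)))
  }
  data.table::setorder(dt, transcript_id, -rpm, offset)
  tot <- dt[, list(total = sum(rpm)), by = "transcript_id"]
  top <- dt[, .SD[1], by = "transcript_id"]
  out <- merge(tot, top, by = "transcript_id")
  data.frame(transcript_id = out$transcript_id, total = out$total,
             max_offset = as.integer(out$offset), max_rpm = out$rpm,
             ratio = out$rpm / out$total, stringsAsFactors = FALSE)
}

# Shared three-filter cascade on a pair of replicate window tables.
window_filter_cascade <- function(w1, w2, rpm_min, ratio_min,
                                  per_replicate) {
  s1 <- window_max_stats(w1)
  s2 <- window_max_stats(w2)
  m <- merge(s1, s2, by = "transcript_id", suffixes = c("_r1", "_r2"))
  cascade <- data.frame(filter = "input", survivors = nrow(m))
  m <- m[m$max_offset_r1 == m$max_offset_r2, , drop = FALSE]
  cascade <- rbind(cascade,
                   data.frame(filter = "F1_same_position",
                              survivors = nrow(m)))
  pass <- function(x1, x2, thr) {
    if (per_replicate) x1 > thr & x2 > thr else (x1 + x2) / 2 > thr
  }
  m <- m[pass(m$max_rpm_r1, m$max_rpm_r2, rpm_min), , drop = FALSE]
  cascade <- rbind(cascade,
                   data.frame(filter = "F2_rpm", survivors = nrow(m)))
  m <- m[pass(m$ratio_r1, m$ratio_r2, ratio_min), , drop = FALSE]
  cascade <- rbind(cascade,
                   data.frame(filter = "F3_ratio", survivors = nrow(m)))
  m <- m[order(m$transcript_id), , drop = FALSE]
  rownames(m) <- NULL
  list(stats = m, cascade = cascade)
}

#' Infer empirical cap positions from C-PARE window profiles
#'
#' Three filters on the replicate pair: (F1) identical C-PARE Max-seq
#' offsets; (F2) Max-seq abundance above \code{rpm_min}; (F3) Max-seq /
#' in-window total ratio above \code{ratio_min}.  F2/F3 use replicate
#' means unless \code{per_replicate = TRUE}.
#'
#' @param w1,w2 replicate C-PARE window tables
#'   (see \code{\link{project_tags_to_window}}).
#' @param rpm_min,ratio_min thresholds (strict; defaults 10 RPM and 0.2).
#' @param per_replicate require both replicates to pass F2/F3 individually.
#' @return list: \code{calls} (data frame: transcript_id, cap_offset,
#'   max_rpm_r1/r2, ratio_r1/r2) and \code{cascade}.
#' @export
infer_cap_position <- function(w1, w2, rpm_min = 10, ratio_min = 0.2,
                               per_replicate = FALSE) {
  res <- window_filter_cascade(w1, w2, rpm_min, ratio_min, per_replicate)
  m <- res$stats
  calls <- data.frame(
    transcript_id = m$transcript_id,
    cap_offset = m$max_offset_r1,
    max_rpm_r1 = m$max_rpm_r1, max_rpm_r2 = m$max_rpm_r2,
    ratio_r1 = m$ratio_r1, ratio_r2 = m$ratio_r2,
    stringsAsFactors = FALSE)
  list(calls = calls, cascade = res$cascade)
}

#' Call decapped transcripts
#'
#' The replicate PARE window profiles are filtered with the same three
#' filters as cap inference; a transcript is decapped when it has both an
#' inferred cap position and a filtered PARE window Max-seq, and the two
#' offsets are equal.
#'
#' @param cap_calls calls from \code{\link{infer_cap_position}}.
#' @param pare_w1,pare_w2 replicate PARE window tables.
#' @inheritParams infer_cap_position
#' @return list: \code{calls} (data frame: transcript_id, offset,
#'   cpare_max_rpm_r1/r2, pare_max_rpm_r1/r2), \code{pare_cascade} and
#'   \code{pare_max} (the filtered PARE window maxima).
#' @export
call_decapped <- function(cap_calls, pare_w1, pare_w2, rpm_min = 10,
                          ratio_min = 0.2, per_replicate = FALSE) {
  res <- window_filter_cascade(pare_w1, pare_w2, rpm_min, ratio_min,
                               per_replicate)
  pm <- res$stats
  m <- merge(cap_calls, pm, by = "transcript_id")
  m <- m[m$cap_offset == m$max_offset_r1, , drop = FALSE]
  calls <- data.frame(
    transcript_id = m$transcript_id,
    offset = m$cap_offset,
    cpare_max_rpm_r1 = m$max_rpm_r1.x, cpare_max_rpm_r2 = m$max_rpm_r2.x,
    pare_max_rpm_r1 = m$max_rpm_r1.y, pare_max_rpm_r2 = m$max_rpm_r2.y,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, pare_cascade = res$cascade, pare_max = pm)
}

#' Cap-offset distribution around the annotated TSS
#'
#' Histogram of inferred cap offsets over the -200..+199 window plus the
#' two headline summaries: the fraction of caps exactly at the annotated
#' 5' end (offset 0) and the fraction within 50 nt of it.
#'
#' @param cap_calls calls from \code{\link{infer_cap_position}}.
#' @return list: \code{histogram} (data frame: offset, count; sums to the
#'   number of calls), \code{frac_at_annotated} and \code{frac_within_50}.
#' @export
offset_distribution <- function(cap_calls) {
  off <- cap_calls$cap_offset
  offsets <- (-WINDOW_FLANK):(WINDOW_FLANK - 1L)
  hist <- data.frame(
    offset = offsets,
    count = as.integer(table(factor(off, levels = offsets))))
  list(histogram = hist,
       frac_at_annotated = if (length(off)) mean(off == 0) else NA_real_,
       frac_within_50 = if (length(off)) mean(abs(off) <= 50) else NA_real_)
}
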