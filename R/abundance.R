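# Per-transcript decay profiles and the DPKM / FPKM normalized abundances.

#' Build a decay profile (D-plot vector) for one transcript
#'
#' Aggregates a TagTable's records for one transcript into a per-position
#' normalized-abundance map and its sum (SOA, the sum of PARE-sequence
#' abundances on the transcript).
#'
#' @param table a TagTable (see \code{\link{map_tags}}).
#' @param transcript_id transcript to profile.
#' @param length cDNA length in nt; looked up from the table's records when
#'   omitted (required for empty profiles).
#' @return object of class \code{decay_profile}: list with transcript_id,
#'   replicate, positions, rpm, soa, length.
#' @export
build_decay_profile <- function(table, transcript_id, length = NULL) {
  rec <- table[table$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(rec) == 0L && is.null(length)) {
    stop("transcript '", transcript_id,
         "' has no records; supply its length explicitly")
  }
  if (nrow(rec) == 0L) {
    agg <- data.frame(position = integer(0), rpm = numeric(0),
                      raw_count = integer(0))
  } else {
    agg <- stats::aggregate(cbind(rpm, raw_count) ~ position, data = rec,
                            FUN = sum)
    agg <- agg[order(agg$position), , drop = FALSE]
  }
  structure(list(
    transcript_id = transcript_id,
    replicate = if (nrow(rec) > 0L) rec$replicate[1] else NA_integer_,
    positions = as.integer(agg$position),
    rpm = as.numeric(agg$rpm),
    raw_count = as.integer(agg$raw_count),
    soa = sum(agg$rpm),
    length = if (is.null(length)) NA_integer_ else as.integer(length)),
    class = "decay_profile")
}

#' @export
print.decay_profile <- function(x, ...) {
  cat("Decay profile for", x$transcript_id,
      sprintf("(replicate %s)\n", x$replicate))
  cat(sprintf("  %d occupied positions, SOA = %.3f RPM\n",
              length(x$positions), x$soa))
  invisible(x)
}

#' Decay reads per kilobase per million (DPKM)
#'
#' DPKM = raw tag count on the cDNA x 10^9 / (cDNA length x total mapped
#' reads); computed from raw counts with explicit length/total
#' normalization (equivalently SOA in RPM divided by length in kb).
#'
#' @param count raw tag-count sum on the cDNA (vectorized).
#' @param length cDNA length in nt (> 0).
#' @param total total mapped reads in the library (> 0).
#' @return DPKM value(s).
#' @export
compute_dpkm <- function(count, length, total) {
  if (any(length <= 0)) stop("cDNA length must be positive")
  if (any(total <= 0)) stop("total mapped reads must be positive")
  count * 1e9 / (length * total)
}

#' Fragments per kilobase per million (FPKM)
#'
#' Same normalization as \code{\link{compute_dpkm}}, applied to RNA-seq
#' transcript counts.
#'
#' @inheritParams compute_dpkm
#' @param count RNA-seq fragment count for the transcript.
#' @export
compute_fpkm <- function(count, length, total) {
  compute_dpkm(count, length, total)
}

#' Per-transcript abundance table (FPKM and DPKM, two replicates each)
#'
#' Tabulates raw counts and normalized abundances for every annotated
#' transcript: RNA-seq counts and FPKM per replicate, PARE tag-count sums
#' and DPKM per replicate.  Transcripts without mapped PARE tags get
#' DPKM 0.
#'
#' @param pare_tables list of two PARE TagTables (replicates 1 and 2).
#' @param rnaseq data frame: transcript_id, rep1, rep2 (RNA-seq counts).
#' @param annotation annotation data frame with transcript_id and length.
#' @return data frame: transcript_id, length, rna_count_r1/r2,
#'   pare_count_r1/r2, fpkm_r1/r2, dpkm_r1/r2; attributes
#'   \code{rna_totals} and \code{pare_totals}.
#' @export
abundance_table <- function(pare_tables, rnaseq, annotation) {
  stopifnot(length(pare_tables) == 2L)
  ann <- annotation[, c("transcript_id", "length")]
  pare_counts <- lapply(pare_tables, function(tab) {
    dt <- data.table::as.data.table(tab)
    agg <- dt[, list(count = sum(raw_count)), by = "transcript_id"]
    cnt <- agg$count[match(ann$transcript_id, agg$transcript_id)]
    ifelse(is.na(cnt), 0L, cnt)
  })
  pare_totals <- vapply(pare_tables, function(tab) {
    as.numeric(attr(tab, "total_mapped_reads"))
  }, numeric(1))
  i <- match(ann$transcript_id, rnaseq$transcript_id)
  rna <- cbind(rnaseq$rep1[i], rnaseq$rep2[i])
  rna[is.na(rna)] <- 0L
  rna_totals <- colSums(rna)
  out <- data.frame(
    transcript_id = ann$transcript_id,
    length = ann$length,
    rna_count_r1 = rna[, 1], rna_count_r2 = rna[, 2],
    pare_count_r1 = pare_counts[[1]], pare_count_r2 = pare_counts[[2]],
    fpkm_r1 = compute_fpkm(rna[, 1], ann$length, rna_totals[1]),
    fpkm_r2 = compute_fpkm(rna[, 2], ann$length, rna_totals[2]),
    dpkm_r1 = compute_dpkm(pare_counts[[1]], ann$length, pare_totals[1]),
    dpkm_r2 = compute_dpkm(pare_counts[[2]], ann$length, pare_totals[2]),
    stringsAsFactors = FALSE)
  attr(out, "rna_totals") <- as.numeric(rna_totals)
  attr(out, "pare_totals") <- pare_totals
  out
}
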