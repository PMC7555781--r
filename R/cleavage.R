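# Endonucleolytic cleavage calling: the Max-seq four-filter cascade and
# the cleavage-position percentile distribution.

#' Most abundant tag position (Max-seq) of a decay profile
#'
#' Returns the position with maximal normalized abundance; ties are broken
#' toward the smallest coordinate (5'-most).
#'
#' @param profile a \code{decay_profile}
#'   (see \code{\link{build_decay_profile}}).
#' @return list: transcript_id, position, abundance (rpm), ratio
#'   (abundance / SOA); NULL for an empty profile.
#' @export
find_max_seq <- function(profile) {
  stopifnot(inherits(profile, "decay_profile"))
  if (length(profile$positions) == 0L) return(NULL)
  i <- order(-profile$rpm, profile$positions)[1]
  list(transcript_id = profile$transcript_id,
       position = profile$positions[i],
       abundance = profile$rpm[i],
       ratio = profile$rpm[i] / profile$soa)
}

# Per-transcript SOA / Max-seq summary of a whole TagTable.
max_seq_stats <- function(table) {
  dt <- data.table::as.data.table(table)
  if (nrow(dt) == 0L) {
    return(data.frame(transcript_id = character(0), soa = numeric(0),
                      max_pos = integer(0), max_rpm = numeric(0),
                      ratio = numeric(0)))
  }
  agg <- dt[, list(rpm = sum(rpm)), by = c("transcript_id", "position")]
  data.table::setorder(agg, transcript_id, -rpm, position)
  soa <- agg[, list(soa = sum(rpm)), by = "transcript_id"]
  top <- agg[, .SD[1], by = "transcript_id"]
  out <- merge(soa, top, by = "transcript_id")
  data.frame(transcript_id = out$transcript_id, soa = out$soa,
             max_pos = as.integer(out$position), max_rpm = out$rpm,
             ratio = out$rpm / out$soa, stringsAsFactors = FALSE)
}

#' Call endonucleolytically cleaved transcripts (four-filter cascade)
#'
#' Filters, applied in order on transcripts present in both replicates:
#' \enumerate{
#'   \item F1 -- identical Max-seq position in the two replicates;
#'   \item F2 -- SOA above \code{soa_min};
#'   \item F3 -- Max-seq abundance above \code{max_min};
#'   \item F4 -- Max-seq / SOA ratio above \code{ratio_min}.
#' }
#' F2-F4 use the mean of the two replicates by default, or require both
#' replicates to pass when \code{per_replicate = TRUE}.  Survivor counts
#' per filter are logged.
#'
#' @param table1,table2 replicate PARE TagTables.
#' @param annotation annotation data frame (for cDNA lengths / percentiles).
#' @param soa_min,max_min,ratio_min filter thresholds (strict inequalities);
#'   defaults 50 RPM, 10 RPM and 0.2.
#' @param per_replicate apply F2-F4 per replicate instead of to the mean.
#' @return list: \code{calls} (data frame: transcript_id, position, length,
#'   soa_r1, soa_r2, max_rpm_r1, max_rpm_r2, ratio_r1, ratio_r2,
#'   percentile) and \code{cascade} (data frame: filter, survivors).
#' @export
call_endonucleolytic <- function(table1, table2, annotation,
                                 soa_min = 50, max_min = 10,
                                 ratio_min = 0.2, per_replicate = FALSE) {
  s1 <- max_seq_stats(table1)
  s2 <- max_seq_stats(table2)
  m <- merge(s1, s2, by = "transcript_id", suffixes = c("_r1", "_r2"))
  cascade <- data.frame(filter = character(0), survivors = integer(0))
  note <- function(name, n) {
    rbind(cascade, data.frame(filter = name, survivors = n))
  }
  cascade <- note("input", nrow(m))
  m <- m[m$max_pos_r1 == m$max_pos_r2, , drop = FALSE]
  cascade <- note("F1_same_position", nrow(m))
  pass <- function(x1, x2, thr) {
    if (per_replicate) x1 > thr & x2 > thr else (x1 + x2) / 2 > thr
  }
  m <- m[pass(m$soa_r1, m$soa_r2, soa_min), , drop = FALSE]
  cascade <- note("F2_soa", nrow(m))
  m <- m[pass(m$max_rpm_r1, m$max_rpm_r2, max_min), , drop = FALSE]
  cascade <- note("F3_max_abundance", nrow(m))
  m <- m[pass(m$ratio_r1, m$ratio_r2, ratio_min), , drop = FALSE]
  cascade <- note("F4_ratio", nrow(m))
  len <- annotation$length[match(m$transcript_id, annotation$transcript_id)]
  calls <- data.frame(
    transcript_id = m$transcript_id,
    position = m$max_pos_r1,
    length = len,
    soa_r1 = m$soa_r1, soa_r2 = m$soa_r2,
    max_rpm_r1 = m$max_rpm_r1, max_rpm_r2 = m$max_rpm_r2,
    ratio_r1 = m$ratio_r1, ratio_r2 = m$ratio_r2,
    percentile = cleavage_percentile(m$max_pos_r1, len),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$transcript_id), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, cascade = cascade)
}

# Percentile bin (1..100) of a 0-based position on a cDNA of given length.
cleavage_percentile <- function(position, length) {
  b <- ceiling(100 * (position + 1) / length)
  pmin(pmax(as.integer(b), 1L), 100L)
}

#' Cleavage-position percentile distribution
#'
#' Counts calls per percentile of cDNA length (bin b holds calls with
#' ceiling(100 x (position + 1) / length) = b); bin counts sum to the
#' number of calls.
#'
#' @param calls calls data frame from \code{\link{call_endonucleolytic}}.
#' @return data frame: bin (1..100), count.
#' @export
percentile_distribution <- function(calls) {
  bins <- cleavage_percentile(calls$position, calls$length)
  data.frame(bin = 1:100, count = tabulate(bins, nbins = 100L))
}
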