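# Readers and writers for the standard formats at the package boundary.
# Internally everything is 0-based half-open; GTF is 1-based inclusive.

#' Write a transcript annotation as GTF
#'
#' Emits transcript, exon and CDS features (single-exon transcripts).  The
#' CDS feature encodes the 5'UTR/CDS/3'UTR partition so that
#' \code{\link{read_annotation_gtf}} can reconstruct the cDNA-coordinate
#' boundaries.
#'
#' @param annotation annotation data frame
#'   (see \code{\link{generate_transcriptome}}).
#' @param path output GTF path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  ann <- annotation
  feat <- function(type, start, end) {
    GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(start = start, end = end),
      strand = ann$strand,
      type = type,
      gene_id = ann$gene_id,
      transcript_id = ann$transcript_id)
  }
  # CDS in genomic coordinates from the cDNA-coordinate partition
  cds_gstart <- ifelse(ann$strand == "+",
                       ann$start + ann$utr5_end,
                       ann$end - ann$cds_end + 1L)
  cds_gend <- ifelse(ann$strand == "+",
                     ann$start + ann$cds_end - 1L,
                     ann$end - ann$utr5_end)
  gr <- c(feat("transcript", ann$start, ann$end),
          feat("exon", ann$start, ann$end),
          feat("CDS", cds_gstart, cds_gend))
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr),
                 match(gr$type, c("transcript", "exon", "CDS")))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a transcript annotation from GTF
#'
#' Expects single-exon transcripts with transcript (or exon) and optional
#' CDS features carrying \code{gene_id}/\code{transcript_id} attributes.
#'
#' @param path GTF path.
#' @return annotation data frame with the columns produced by
#'   \code{\link{generate_transcriptome}}.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  tx <- gr[gr$type %in% "transcript"]
  if (length(tx) == 0L) {
    tx <- gr[gr$type %in% "exon"]
  }
  if (length(tx) == 0L) stop("no transcript or exon features in ", path)
  strand <- as.character(GenomicRanges::strand(tx))
  if (any(strand == "*")) stop("unstranded transcript features in ", path)
  start <- GenomicRanges::start(tx)
  end <- GenomicRanges::end(tx)
  len <- end - start + 1L
  ann <- data.frame(
    transcript_id = tx$transcript_id,
    gene_id = if (!is.null(tx$gene_id)) tx$gene_id else tx$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end),
    length = len,
    utr5_end = 0L,
    cds_end = len,
    stringsAsFactors = FALSE)
  cds <- gr[gr$type %in% "CDS"]
  if (length(cds) > 0L) {
    i <- match(cds$transcript_id, ann$transcript_id)
    ok <- !is.na(i)
    cds <- cds[ok]; i <- i[ok]
    plus <- ann$strand[i] == "+"
    ann$utr5_end[i] <- ifelse(plus,
                              GenomicRanges::start(cds) - ann$start[i],
                              ann$end[i] - GenomicRanges::end(cds))
    ann$cds_end[i] <- ifelse(plus,
                             GenomicRanges::end(cds) - ann$start[i] + 1L,
                             ann$end[i] - GenomicRanges::start(cds) + 1L)
  }
  rownames(ann) <- NULL
  ann
}

#' Read raw tag reads
#'
#' Accepts FASTQ (one record per read) or a 2-column TSV (sequence, count).
#'
#' @param path input path; format inferred from the extension unless given.
#' @param format "auto", "fastq" or "tsv".
#' @return data frame: sequence, count (identical sequences collapsed).
#' @export
read_tag_library <- function(path, format = c("auto", "fastq", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "tsv"
  }
  if (format == "fastq") {
    reads <- Biostrings::readDNAStringSet(path, format = "fastq")
    dt <- data.table::data.table(sequence = as.character(reads))
    dt <- dt[, list(count = .N), by = "sequence"]
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            colClasses = list(character = 1))
    data.table::setnames(dt, 1:2, c("sequence", "count"))
    dt <- dt[, list(count = sum(as.integer(count))), by = "sequence"]
  }
  data.table::setorder(dt, sequence)
  as.data.frame(dt)
}

#' Write a tag library
#'
#' @param tags data frame: sequence, count.
#' @param path output path.
#' @param format "tsv" writes the collapsed 2-column table; "fastq" expands
#'   counts into individual reads with dummy quality "I" per base.
#' @export
write_tag_library <- function(tags, path, format = c("tsv", "fastq")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(tags[, c("sequence", "count")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    seqs <- rep(tags$sequence, tags$count)
    ids <- sprintf("read%08d", seq_along(seqs))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Write a TagTable as TSV
#'
#' Columns: library_id, library_type, replicate, transcript_id, position,
#' raw_count, rpm.  The total mapped read count is carried in a
#' \code{# total_mapped_reads=} comment line so the table round-trips.
#'
#' @param table a tag table from \code{\link{map_tags}} (or a window table).
#' @param path output path.
#' @export
write_tag_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_mapped_reads=%d",
                     attr(table, "total_mapped_reads")), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TagTable written by \code{\link{write_tag_table}}
#'
#' @param path TSV path.
#' @return the tag table data frame with its \code{total_mapped_reads}
#'   attribute restored.
#' @export
read_tag_table <- function(path) {
  first <- readLines(path, n = 1L)
  total <- NA_integer_
  if (grepl("^# total_mapped_reads=", first)) {
    total <- as.integer(sub("^# total_mapped_reads=", "", first))
  }
  dt <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(dt, "total_mapped_reads") <- total
  dt
}

#' Read a two-replicate RNA-seq count table
#'
#' @param path TSV with columns transcript_id, rep1, rep2.
#' @return data frame.
#' @export
read_rnaseq_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
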