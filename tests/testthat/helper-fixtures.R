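# Shared fixtures, computed lazily and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete synthetic experiment + pipeline run (30 transcripts,
# 6e4 reads per library): enough planted structure to exercise every stage.
small_config <- function(seed = 7) {
  sim_config(n_transcripts = 30L, length_range = c(500L, 900L),
             background_decay_tags = 2000, seed = seed)
}

small_run <- function() {
  cached("small_run", run_degradome(simulate_degradome(small_config())))
}

small_sim <- function() small_run()$sim

# Minimal hand-built tag table (already normalized records).
toy_tag_table <- function(records, total, replicate = 1L,
                          type = "PARE") {
  out <- data.frame(library_id = "toy", library_type = type,
                    replicate = replicate,
                    transcript_id = records$transcript_id,
                    position = records$position,
                    raw_count = records$raw_count,
                    stringsAsFactors = FALSE)
  out$rpm <- out$raw_count * 1e6 / total
  attr(out, "total_mapped_reads") <- total
  class(out) <- c("tag_table", "data.frame")
  out
}

# Minimal hand-built window table.
toy_window_table <- function(transcript_id, offset, rpm, replicate = 1L,
                             type = "CPARE") {
  out <- data.frame(library_id = "toy", library_type = type,
                    replicate = replicate, transcript_id = transcript_id,
                    offset = offset, raw_count = round(rpm),
                    rpm = rpm, stringsAsFactors = FALSE)
  attr(out, "total_mapped_reads") <- 1e6
  class(out) <- c("window_table", "data.frame")
  out
}

# Abundance table wrapper from raw count vectors (for stability tests).
toy_abundance <- function(rna1, rna2, pare1, pare2, length = 1000L,
                          rna_totals = NULL, pare_totals = NULL) {
  n <- length(rna1)
  if (is.null(rna_totals)) rna_totals <- c(sum(rna1), sum(rna2))
  if (is.null(pare_totals)) pare_totals <- c(sum(pare1), sum(pare2))
  len <- rep(length, n)[seq_len(n)]
  out <- data.frame(
    transcript_id = sprintf("T%03d", seq_len(n)),
    length = len,
    rna_count_r1 = rna1, rna_count_r2 = rna2,
    pare_count_r1 = pare1, pare_count_r2 = pare2,
    fpkm_r1 = rna1 * 1e9 / (len * rna_totals[1]),
    fpkm_r2 = rna2 * 1e9 / (len * rna_totals[2]),
    dpkm_r1 = pare1 * 1e9 / (len * pare_totals[1]),
    dpkm_r2 = pare2 * 1e9 / (len * pare_totals[2]),
    stringsAsFactors = FALSE)
  attr(out, "rna_totals") <- as.numeric(rna_totals)
  attr(out, "pare_totals") <- as.numeric(pare_totals)
  out
}

# Tag table built directly from a simulation's true per-cell counts
# (bypasses read mapping; used to test callers in isolation).
tag_table_from_truth <- function(lib, replicate = 1L) {
  cc <- attr(lib, "cell_counts")
  cc <- cc[cc$position >= 0, , drop = FALSE]
  agg <- stats::aggregate(count ~ transcript_id + position, data = cc,
                          FUN = sum)
  toy_tag_table(data.frame(transcript_id = agg$transcript_id,
                           position = agg$position,
                           raw_count = agg$count),
                total = sum(agg$count), replicate = replicate)
}
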