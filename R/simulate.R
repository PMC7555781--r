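#' Simulation configuration for synthetic degradome libraries
#'
#' Defines the conditions of a synthetic degradome experiment: a random
#' single-exon transcriptome, RNA-seq counts with negative-binomial replicate
#' noise, and PARE / C-PARE tag libraries with planted decay structure
#' (stable/unstable classes, endonucleolytic cleavage peaks, decap peaks at
#' the cap position).  The seed fully determines every downstream output.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param length_range integer length-2 vector, min/max cDNA length in nt.
#'   The minimum must be at least 500 so every transcript accommodates the
#'   +200-nt cap window.
#' @param tss_upstream_pad nt of genomic sequence guaranteed upstream of each
#'   TSS on the transcript strand.
#' @param frac_stable,frac_unstable proportions of transcripts planted as
#'   stable (RNA-seq excess) and unstable (PARE excess); the remainder is
#'   balanced ("neither").
#' @param frac_cleaved proportion with a planted endonucleolytic cleavage
#'   peak (drawn from the non-stable transcripts).
#' @param frac_decapped proportion with a planted decap peak at the cap
#'   position (disjoint from the cleaved set).
#' @param background_decay_tags expected background tags per transcript (RPM
#'   scale); used to derive \code{library_size} when that is \code{NULL}.
#' @param peak_fraction fraction of a cleaved (or decapped) transcript's PARE
#'   tags concentrated at the planted site.
#' @param cap_jitter_sd standard deviation (nt) of the integer jitter of
#'   C-PARE tag starts around the planted cap position.
#' @param nb_dispersion negative-binomial dispersion of RNA-seq replicate
#'   counts; 0 gives Poisson counts.
#' @param library_size total reads per replicate library (all library types);
#'   default \code{n_transcripts * background_decay_tags}.
#' @param effect_log2 planted |log2(RNA-seq : PARE)| ratio for the stable and
#'   unstable classes.
#' @param expr_sdlog sdlog of the log-normal per-transcript expression draw.
#' @param cap_offset_range integer range from which each transcript's true
#'   cap offset (relative to the annotated TSS) is drawn; default exactly 0.
#' @param seed integer seed; identical seeds give byte-identical outputs.
#'
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_transcripts = 500L,
                       length_range = c(500L, 1500L),
                       tss_upstream_pad = 300L,
                       frac_stable = 0.2,
                       frac_unstable = 0.2,
                       frac_cleaved = 0.1,
                       frac_decapped = 0.1,
                       background_decay_tags = 2000,
                       peak_fraction = 0.4,
                       cap_jitter_sd = 0,
                       nb_dispersion = 0.05,
                       library_size = NULL,
                       effect_log2 = 4,
                       expr_sdlog = 0.5,
                       cap_offset_range = c(0L, 0L),
                       seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    length_range = as.integer(length_range),
    tss_upstream_pad = as.integer(tss_upstream_pad),
    frac_stable = frac_stable, frac_unstable = frac_unstable,
    frac_cleaved = frac_cleaved, frac_decapped = frac_decapped,
    background_decay_tags = background_decay_tags,
    peak_fraction = peak_fraction,
    cap_jitter_sd = cap_jitter_sd,
    nb_dispersion = nb_dispersion,
    library_size = if (is.null(library_size)) {
      as.integer(round(n_transcripts * background_decay_tags))
    } else as.integer(library_size),
    effect_log2 = effect_log2,
    expr_sdlog = expr_sdlog,
    cap_offset_range = as.integer(cap_offset_range),
    seed = as.integer(seed))
  fr <- c(cfg$frac_stable, cfg$frac_unstable, cfg$frac_cleaved,
          cfg$frac_decapped)
  if (any(fr < 0 | fr > 1)) stop("class fractions must lie in [0, 1]")
  if (cfg$frac_stable + cfg$frac_unstable > 1) {
    stop("frac_stable + frac_unstable must not exceed 1")
  }
  if (cfg$length_range[1] < 500L) {
    stop("length_range minimum must be >= 500 nt to accommodate the ",
         "+200-nt cap window")
  }
  if (cfg$length_range[1] > cfg$length_range[2]) {
    stop("length_range must be increasing")
  }
  if (cfg$n_transcripts < 1L) stop("n_transcripts must be positive")
  if (cfg$peak_fraction < 0 || cfg$peak_fraction > 1) {
    stop("peak_fraction must lie in [0, 1]")
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random transcriptome with SSR-free cDNAs
#'
#' Lays out single-exon transcripts on random chromosomes (both strands,
#' equal base frequencies) with at least \code{tss_upstream_pad} nt of
#' genomic sequence upstream of every TSS.  cDNA sequences are regenerated
#' until free of 12-nt period-1/2/3 simple sequence repeats, so no planted
#' tag is lost to the SSR read filter.  A random mitochondrial contig
#' ("chrM") is included for the mitochondrial read filter.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with elements \code{genome} (named character vector of
#'   contig sequences, including \code{chrM}), \code{annotation} (data frame:
#'   transcript_id, gene_id, chrom, strand, start, end, tss, length,
#'   utr5_end, cds_end) and \code{cdna} (named character vector).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_transcripts
  pad <- max(config$tss_upstream_pad, 300L)
  lens <- sample_range(config$length_range[1], config$length_range[2], n)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  # SSR-free cDNA sequences (transcript orientation)
  cdna <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- random_dna(lens[i])
      if (!detect_ssr(s)) break
    }
    cdna[i] <- s
  }
  per_chr <- 50L
  chrom_of <- ceiling(seq_len(n) / per_chr)
  tid <- sprintf("TX%04d", seq_len(n))
  names(cdna) <- tid
  ann <- data.frame(
    transcript_id = tid,
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = sprintf("chr%d", chrom_of),
    strand = strands,
    start = NA_integer_, end = NA_integer_, tss = NA_integer_,
    length = lens,
    utr5_end = pmax(0L, floor(lens * 0.15)),
    cds_end = floor(lens * 0.80),
    stringsAsFactors = FALSE)
  loci <- cdna
  minus <- strands == "-"
  if (any(minus)) loci[minus] <- revcomp(cdna[minus])
  genome <- character(0)
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    k <- length(idx)
    padseq <- random_dna(2L * k * pad)
    pstart <- seq(1L, by = pad, length.out = 2L * k)
    pads <- substring(padseq, pstart, pstart + pad - 1L)
    segs <- character(3L * k)
    segs[seq(1L, by = 3L, length.out = k)] <- pads[seq(1L, 2L * k, 2L)]
    segs[seq(2L, by = 3L, length.out = k)] <- loci[idx]
    segs[seq(3L, by = 3L, length.out = k)] <- pads[seq(2L, 2L * k, 2L)]
    offs <- cumsum(c(0L, (2L * pad + lens[idx])[-k]))
    ann$start[idx] <- offs + pad + 1L
    ann$end[idx] <- offs + pad + lens[idx]
    genome[ch] <- paste(segs, collapse = "")
  }
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  genome["chrM"] <- random_dna(16569L)
  list(genome = genome, annotation = ann, cdna = cdna)
}

#' Assign per-transcript ground truth
#'
#' Draws expression levels and plants the stability classes, cleavage sites
#' and decap signals defined by the configuration.  Cleaved transcripts are
#' drawn from the non-stable classes and their sites lie at least 25 nt
#' downstream of the cap and 25 nt from the 3' end; decapped transcripts are
#' disjoint from the cleaved set.
#'
#' @param annotation the annotation data frame from
#'   \code{\link{generate_transcriptome}}.
#' @param config a \code{\link{sim_config}}.
#' @return data frame: transcript_id, stability_class, expression,
#'   decay_factor, cleavage_pos (0-based cDNA coordinate or NA), cap_offset,
#'   is_decapped.
#' @export
assign_ground_truth <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 2L))
  n <- nrow(annotation)
  cls <- rep("neither", n)
  ord <- sample.int(n)
  n_st <- round(config$frac_stable * n)
  n_un <- round(config$frac_unstable * n)
  if (n_st > 0) cls[ord[seq_len(n_st)]] <- "stable"
  if (n_un > 0) cls[ord[n_st + seq_len(n_un)]] <- "unstable"
  expression <- stats::rlnorm(n, meanlog = 0, sdlog = config$expr_sdlog)
  decay <- c(stable = 2^(-config$effect_log2),
             unstable = 2^(config$effect_log2),
             neither = 1)[cls]
  cap_offset <- sample_range(config$cap_offset_range[1],
                             config$cap_offset_range[2], n)
  cleavage_pos <- rep(NA_integer_, n)
  non_stable <- which(cls != "stable")
  n_cl <- min(round(config$frac_cleaved * n), length(non_stable))
  cleaved <- if (n_cl > 0) sample_from(non_stable, n_cl) else integer(0)
  for (i in cleaved) {
    lo <- max(25L, cap_offset[i] + 25L)
    hi <- annotation$length[i] - 25L
    cleavage_pos[i] <- sample_range(lo, hi, 1L)
  }
  is_decapped <- rep(FALSE, n)
  pool <- setdiff(seq_len(n), cleaved)
  n_dc <- min(round(config$frac_decapped * n), length(pool))
  if (n_dc > 0) is_decapped[sample_from(pool, n_dc)] <- TRUE
  data.frame(
    transcript_id = annotation$transcript_id,
    stability_class = cls,
    expression = expression,
    decay_factor = unname(decay),
    cleavage_pos = cleavage_pos,
    cap_offset = cap_offset,
    is_decapped = is_decapped,
    stringsAsFactors = FALSE)
}

#' Simulate RNA-seq transcript counts (two replicates)
#'
#' Counts are negative-binomial with per-transcript mean proportional to the
#' expression level (library scaled to \code{library_size} expected reads)
#' and common dispersion \code{nb_dispersion}; dispersion 0 gives Poisson
#' counts.  Each replicate is an independent draw from the same expectations.
#'
#' @param truth ground-truth data frame from \code{\link{assign_ground_truth}}.
#' @param config a \code{\link{sim_config}}.
#' @return data frame: transcript_id, rep1, rep2.
#' @export
simulate_rnaseq <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 3L))
  mu <- config$library_size * truth$expression / sum(truth$expression)
  draw <- function() {
    if (config$nb_dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
  }
  data.frame(transcript_id = truth$transcript_id,
             rep1 = draw(), rep2 = draw(),
             stringsAsFactors = FALSE)
}

# Expected per-cell tag weights for one PARE library.  Cells are
# (transcript, start position) pairs; positions are cDNA coordinates, with
# negative values denoting starts upstream of the TSS (decap peaks when the
# planted cap lies upstream).
pare_cell_weights <- function(truth, transcriptome, config) {
  ann <- transcriptome$annotation
  n <- nrow(ann)
  w_tx <- truth$expression * truth$decay_factor
  npos <- ann$length - TAG_WIDTH + 1L
  n_peaks <- as.integer(!is.na(truth$cleavage_pos)) +
    as.integer(truth$is_decapped)
  pf <- config$peak_fraction * n_peaks
  if (any(pf > 1)) stop("peak fractions exceed 1")
  bad <- which(!is.na(truth$cleavage_pos) &
                 truth$cleavage_pos > ann$length - TAG_WIDTH)
  bad <- c(bad, which(truth$is_decapped &
                        truth$cap_offset > ann$length - TAG_WIDTH))
  if (length(bad)) {
    stop("planted peak within 20 nt of the 3' end of ",
         ann$transcript_id[bad[1]])
  }
  bg <- data.frame(
    tx = rep.int(seq_len(n), npos),
    pos = sequence(npos) - 1L,
    w = rep.int(w_tx * (1 - pf) / npos, npos))
  cl <- which(!is.na(truth$cleavage_pos))
  dc <- which(truth$is_decapped)
  peaks <- data.frame(
    tx = c(cl, dc),
    pos = c(truth$cleavage_pos[cl], truth$cap_offset[dc]),
    w = w_tx[c(cl, dc)] * config$peak_fraction)
  rbind(bg, peaks)
}

# 20-nt tag sequence for transcript index tx at (possibly negative)
# position pos, reading genomic sequence upstream of the TSS when needed.
tag_sequences <- function(tx, pos, transcriptome) {
  ann <- transcriptome$annotation
  cdna <- transcriptome$cdna
  out <- character(length(tx))
  neg <- pos < 0L
  if (any(!neg)) {
    i <- which(!neg)
    out[i] <- substr(cdna[ann$transcript_id[tx[i]]],
                     pos[i] + 1L, pos[i] + TAG_WIDTH)
  }
  if (any(neg)) {
    win <- build_windows(ann, transcriptome$genome)
    for (j in which(neg)) {
      k <- match(ann$transcript_id[tx[j]], win$transcript_id)
      wstart <- win$upstream_len[k] + pos[j] + 1L
      if (wstart < 1L) stop("tag start beyond available upstream sequence")
      out[j] <- substr(win$sequence[k], wstart, wstart + TAG_WIDTH - 1L)
    }
  }
  out
}

# One multinomial library draw over weighted cells; returns a tag library
# (data frame: sequence, count) plus the true per-cell counts as attributes.
draw_tag_library <- function(cells, transcriptome, library_size) {
  counts <- as.integer(stats::rmultinom(1L, library_size,
                                        cells$w / sum(cells$w)))
  keep <- counts > 0L
  cells <- cells[keep, , drop = FALSE]
  counts <- counts[keep]
  seqs <- tag_sequences(cells$tx, cells$pos, transcriptome)
  lib <- data.table::data.table(sequence = seqs, count = counts)
  lib <- lib[, list(count = sum(count)), by = "sequence"]
  data.table::setorder(lib, sequence)
  out <- as.data.frame(lib)
  attr(out, "cell_counts") <- data.frame(
    transcript_id = transcriptome$annotation$transcript_id[cells$tx],
    position = cells$pos, count = counts, stringsAsFactors = FALSE)
  out
}

#' Simulate PARE tag libraries (two replicates)
#'
#' Background decay tags start uniformly over each transcript's valid
#' positions; planted cleavage and decap peaks each concentrate
#' \code{peak_fraction} of the transcript's tags at their site.  Tags are
#' the 20-nt cDNA substring at the start position; replicates are
#' independent multinomial draws of \code{library_size} reads from the same
#' expectations, so per-transcript counts sum exactly to the library draw.
#'
#' @inheritParams simulate_rnaseq
#' @param transcriptome output of \code{\link{generate_transcriptome}}.
#' @return list of two tag libraries (data frames: sequence, count).
#' @export
simulate_pare <- function(truth, transcriptome, config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- pare_cell_weights(truth, transcriptome, config)
  out <- vector("list", 2L)
  for (r in 1:2) {
    set.seed(stage_seed(config$seed, 3L + r))
    out[[r]] <- draw_tag_library(cells, transcriptome, config$library_size)
  }
  names(out) <- c("rep1", "rep2")
  out
}

#' Simulate C-PARE (capped 5' end) tag libraries (two replicates)
#'
#' Every transcript's capped-end tags start at its planted cap position plus
#' integer jitter distributed as round(Normal(0, cap_jitter_sd)); with
#' jitter 0 all tags of a transcript share a single start.  Per-transcript
#' abundance is proportional to expression.
#'
#' @inheritParams simulate_pare
#' @return list of two tag libraries (data frames: sequence, count).
#' @export
simulate_cpare <- function(truth, transcriptome, config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- transcriptome$annotation
  sd <- config$cap_jitter_sd
  if (sd == 0) {
    offs <- list(k = 0L, p = 1)
  } else {
    span <- max(1L, ceiling(4 * sd))
    k <- (-span):span
    p <- stats::pnorm(k + 0.5, sd = sd) - stats::pnorm(k - 0.5, sd = sd)
    offs <- list(k = k, p = p / sum(p))
  }
  n <- nrow(ann)
  tx <- rep(seq_len(n), each = length(offs$k))
  pos <- rep(truth$cap_offset, each = length(offs$k)) +
    rep(offs$k, times = n)
  w <- rep(truth$expression, each = length(offs$k)) *
    rep(offs$p, times = n)
  # keep cells that fit on the available sequence
  ok <- pos >= -config$tss_upstream_pad & pos <= ann$length[tx] - TAG_WIDTH
  cells <- data.frame(tx = tx[ok], pos = as.integer(pos[ok]), w = w[ok])
  out <- vector("list", 2L)
  for (r in 1:2) {
    set.seed(stage_seed(config$seed, 5L + r))
    out[[r]] <- draw_tag_library(cells, transcriptome, config$library_size)
  }
  names(out) <- c("rep1", "rep2")
  out
}

#' Simulate a full synthetic degradome experiment
#'
#' Runs \code{\link{generate_transcriptome}},
#' \code{\link{assign_ground_truth}}, \code{\link{simulate_rnaseq}},
#' \code{\link{simulate_pare}} and \code{\link{simulate_cpare}} under one
#' configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: config, transcriptome, truth, rnaseq, pare (2 libraries),
#'   cpare (2 libraries); class \code{degradome_sim}.
#' @export
simulate_degradome <- function(config = sim_config()) {
  tr <- generate_transcriptome(config)
  truth <- assign_ground_truth(tr$annotation, config)
  out <- list(
    config = config,
    transcriptome = tr,
    truth = truth,
    rnaseq = simulate_rnaseq(truth, config),
    pare = simulate_pare(truth, tr, config),
    cpare = simulate_cpare(truth, tr, config))
  class(out) <- "degradome_sim"
  out
}

#' Write a simulated experiment to disk
#'
#' Emits genome FASTA, cDNA FASTA, GTF annotation, tag libraries (2-column
#' TSV or FASTQ with dummy qualities), RNA-seq counts TSV and the
#' ground-truth TSV sidecar.  All outputs are plain text and byte-stable
#' under a fixed seed.
#'
#' @param sim output of \code{\link{simulate_degradome}}.
#' @param outdir output directory (created if needed).
#' @param tag_format "tsv" (sequence, count) or "fastq" (one record per
#'   read, quality "I" x 20).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir, tag_format = c("tsv", "fastq")) {
  tag_format <- match.arg(tag_format)
  stopifnot(inherits(sim, "degradome_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(x) file.path(outdir, x)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$transcriptome$genome), p("genome.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$transcriptome$cdna), p("cdna.fa"))
  write_annotation_gtf(sim$transcriptome$annotation, p("annotation.gtf"))
  files <- c(files, p(c("genome.fa", "cdna.fa", "annotation.gtf")))
  for (lib in c("pare", "cpare")) {
    for (r in 1:2) {
      f <- p(sprintf("%s_rep%d.%s", lib, r,
                     if (tag_format == "tsv") "tsv" else "fastq"))
      write_tag_library(sim[[lib]][[r]], f, format = tag_format)
      files <- c(files, f)
    }
  }
  utils::write.table(sim$rnaseq, p("rnaseq_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, p("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, p(c("rnaseq_counts.tsv", "ground_truth.tsv")))
  invisible(files)
}
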