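random_dna_local <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("adapter trimming follows the 20-nt tag rules", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert25 <- "ACGTACGGTTCAGGCATAACGGTCA"
  insert18 <- "ACGTACGGTTCAGGCATA"
  # long insert: adapter removed, read truncated to its first 20 nt
  tags <- trim_reads(paste0(insert25, adapter), adapter)
  expect_equal(tags$sequence, substr(insert25, 1, 20))
  expect_equal(tags$count, 1L)
  # insert shorter than 20 nt after trimming is discarded
  expect_equal(nrow(trim_reads(paste0(insert18, adapter), adapter)), 0L)
  # identical reads collapse with summed counts
  two <- trim_reads(rep(insert25, 2), adapter)
  expect_equal(two$count, 2L)
  # partial adapter at the read end needs >= 3 nt overlap
  part <- trim_reads(paste0(insert25, substr(adapter, 1, 4)), adapter)
  expect_equal(part$sequence, substr(insert25, 1, 20))
  tooshort <- trim_reads(paste0(insert25, substr(adapter, 1, 2)), adapter)
  expect_equal(nchar(tooshort$sequence), 20L)
  expect_equal(tooshort$sequence, substr(insert25, 1, 20))
  # leftmost adapter occurrence wins
  double <- paste0(insert25, adapter, "CCCCC", adapter)
  expect_equal(trim_reads(double, adapter)$sequence, substr(insert25, 1, 20))
  # non-ACGTN characters discard the read with a warning
  expect_warning(bad <- trim_reads(c("ACGTXCGGTTCAGGCATAACGGTCA", insert25),
                                   adapter),
                 "ACGTN")
  expect_equal(nrow(bad), 1L)
  # empty input is fine
  expect_equal(nrow(trim_reads(character(0), adapter)), 0L)
})

test_that("SSR detection matches the stated period rules and the oracle", {
  expect_true(detect_ssr("AAAAAAAAAAAAGCGTACGT"))    # period 1
  expect_true(detect_ssr("ACACACACACACGTGTCCAA"))    # period 2
  expect_true(detect_ssr("GGCAGCAGCAGCAGCTTAAC"))    # period 3
  expect_false(detect_ssr("ACGTACGTACGTACGTACGT"))   # period 4 only
  expect_false(detect_ssr("AAAAAAAAAAAGCGTACGTT"))   # run of 11 only
  expect_false(detect_ssr("ACGTACGTACG"))            # < 12 nt
  # vectorized agreement with the substring-shift oracle
  seqs <- random_20mers(2000, seed = 42)
  # enrich with repeat-prone sequences
  set.seed(43)
  enriched <- vapply(1:500, function(i) {
    unit <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                         replace = TRUE), collapse = "")
    core <- strrep(unit, ceiling(sample(8:14, 1) / nchar(unit)))
    s <- paste0(random_dna_local(sample(0:6, 1)), core,
                random_dna_local(6))
    substr(paste0(s, strrep("A", 20)), 1, 20)
  }, character(1))
  all_seqs <- c(seqs, enriched)
  expect_identical(detect_ssr(all_seqs),
                   vapply(all_seqs, brute_ssr, logical(1),
                          USE.NAMES = FALSE))
  # variable lengths
  longs <- c(paste0(strrep("AT", 6), random_20mers(1, 1)),
             substr(random_20mers(1, 2), 1, 15))
  expect_identical(detect_ssr(longs),
                   vapply(longs, brute_ssr, logical(1), USE.NAMES = FALSE))
})

test_that("filter cascade removes SSR, multi-hit and mitochondrial tags", {
  set.seed(21)
  uniq <- random_20mers(3, seed = 77)
  multi <- random_20mers(1, seed = 78)
  ssr_tag <- "ACACACACACACGTGTCCAA"
  # genome: unique tags once, the multi-hit tag 25 times
  genome <- c(chr1 = paste0(
    paste(uniq, collapse = random_dna_local(30)),
    paste(rep(multi, 25), collapse = random_dna_local(10))))
  mito <- c(chrM = paste0(random_dna_local(50), uniq[3],
                          random_dna_local(50)))
  tags <- data.frame(
    sequence = c(uniq, multi, ssr_tag),
    count = c(10L, 20L, 30L, 40L, 50L))
  out <- filter_tags(tags, genome, mito)
  # SSR and multi-hit and mito-exact tags gone; the rest retained
  expect_setequal(out$sequence, uniq[1:2])
  log <- attr(out, "filter_log")
  expect_equal(unname(log[, "types"]), c(5L, 4L, 3L, 2L))
  # monotone cascade
  expect_true(all(diff(log[, "reads"]) <= 0))
  # one mismatch to the mito contig is NOT removed (0-mismatch filter)
  near_mito <- mutate_at(uniq[3], 10,
                         setdiff(c("A", "C", "G", "T"),
                                 substr(uniq[3], 10, 10))[1])
  out2 <- filter_tags(data.frame(sequence = near_mito, count = 1L),
                      genome, mito)
  expect_equal(nrow(out2), 1L)
  # reverse-complement mito match is removed
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(uniq[3])))
  out3 <- filter_tags(data.frame(sequence = rc, count = 1L), genome, mito)
  expect_equal(nrow(out3), 0L)
})

test_that("multi-hit counting includes 1-mismatch loci on both strands", {
  tag <- random_20mers(1, seed = 99)
  # plant 11 exact copies + 10 one-mismatch variants: 21 loci > 20
  set.seed(100)
  variants <- vapply(1:10, function(i) {
    mutate_at(tag, sample(20, 1), sample(c("A", "C", "G", "T"), 1))
  }, character(1))
  filler <- function() random_dna_local(12)
  genome <- c(chr1 = paste0(
    paste(c(rep(tag, 11), variants), collapse = filler()), filler()))
  # every variant is within Hamming distance 1 of the tag, so the tag has
  # at least 21 loci and must be discarded
  hits1 <- filter_tags(data.frame(sequence = tag, count = 1L), genome)
  expect_equal(nrow(hits1), 0L)
  # with only 11 exact copies the tag survives
  genome11 <- c(chr1 = paste0(paste(rep(tag, 11), collapse = filler()),
                              filler()))
  hits2 <- filter_tags(data.frame(sequence = tag, count = 1L), genome11)
  expect_equal(nrow(hits2), 1L)
})

test_that("cDNA mapping matches the exhaustive Hamming oracle", {
  cfg <- sim_config(n_transcripts = 10L, length_range = c(500L, 600L),
                    seed = 13)
  tr <- generate_transcriptome(cfg)
  cdna <- tr$cdna
  set.seed(14)
  exact <- substr(cdna[[1]], 41, 60)           # position 40, 0-based
  onemm <- mutate_at(substr(cdna[[2]], 101, 120), 5, "N")
  twomm <- mutate_at(mutate_at(substr(cdna[[3]], 201, 220), 3, "A"), 9, "A")
  twomm_ok <- sum(strsplit(twomm, "")[[1]] !=
                    strsplit(substr(cdna[[3]], 201, 220), "")[[1]]) == 2
  random <- random_20mers(20, seed = 15)
  tags <- data.frame(sequence = c(exact, onemm, twomm, random),
                     count = rep(1L, 23))
  tab <- map_tags(tags, cdna)
  expect_true(any(tab$transcript_id == names(cdna)[1] &
                    tab$position == 40L))
  expect_true(any(tab$transcript_id == names(cdna)[2] &
                    tab$position == 100L))
  if (twomm_ok) {
    expect_false(any(tab$transcript_id == names(cdna)[3] &
                       tab$position == 200L))
  }
  # full agreement with the brute-force scan
  oracle <- brute_hamming_scan(tags$sequence, cdna, max_mm = 1L)
  got <- paste(tab$transcript_id, tab$position)
  want <- unique(paste(oracle$seqname, oracle$pos0))
  expect_setequal(got, want)
})

test_that("RPM normalization uses reads with at least one cDNA hit", {
  cdna <- c(T1 = paste0(random_20mers(1, 31), random_20mers(1, 32),
                        random_20mers(1, 33)))
  tags <- data.frame(
    sequence = c(substr(cdna, 1, 20), substr(cdna, 21, 40),
                 random_20mers(1, 34)),
    count = c(100L, 900L, 500L))  # the third does not map
  tab <- map_tags(tags, cdna)
  expect_equal(attr(tab, "total_mapped_reads"), 1000L)
  expect_equal(attr(tab, "unmapped_reads"), 500L)
  expect_equal(tab$rpm[tab$position == 0], 100 * 1e6 / 1000)
  expect_equal(sum(tab$rpm), 1e6)
  # a tag hitting two isoforms contributes full counts to each but is
  # counted once in the denominator
  cdna2 <- c(A = cdna[[1]], B = paste0(substr(cdna[[1]], 1, 40),
                                       random_20mers(1, 35)))
  tab2 <- map_tags(data.frame(sequence = substr(cdna[[1]], 1, 20),
                              count = 10L), cdna2)
  expect_equal(nrow(tab2), 2L)
  expect_equal(attr(tab2, "total_mapped_reads"), 10L)
  expect_equal(tab2$raw_count, c(10L, 10L))
})

test_that("window projection agrees with cDNA mapping on shared offsets", {
  sim <- small_sim()
  tr <- sim$transcriptome
  tags <- trim_reads(sim$pare$rep1)
  tags <- filter_tags(tags, tr$genome[names(tr$genome) != "chrM"],
                      tr$genome["chrM"])
  win <- build_windows(tr$annotation, tr$genome)
  wt <- project_tags_to_window(tags, win, library_type = "PARE")
  tt <- map_tags(tags, tr$cdna)
  w_sub <- wt[wt$offset >= 0 & wt$offset <= 180, ]
  t_sub <- tt[tt$position <= 180, ]
  expect_setequal(paste(w_sub$transcript_id, w_sub$offset, w_sub$raw_count),
                  paste(t_sub$transcript_id, t_sub$position,
                        t_sub$raw_count))
})
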