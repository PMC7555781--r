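test_that("TSS windows concatenate upstream sequence with the cDNA start", {
  up <- paste(rep("ACGTA", 60), collapse = "")       # 300 nt
  cdna_plus <- random_20mers(25, seed = 61)          # 500 nt
  body_plus <- paste(cdna_plus, collapse = "")
  genome <- c(chr1 = paste0(up, body_plus, strrep("T", 40)))
  ann <- data.frame(transcript_id = "P", gene_id = "G", chrom = "chr1",
                    strand = "+", start = 301L, end = 800L, tss = 301L,
                    length = 500L, utr5_end = 100L, cds_end = 400L,
                    stringsAsFactors = FALSE)
  win <- build_windows(ann, genome)
  expect_equal(win$upstream_len, 200L)
  expect_false(win$truncated)
  expect_equal(nchar(win$sequence), 400L)
  expect_equal(substr(win$sequence, 1, 200), substr(up, 101, 300))
  expect_equal(substr(win$sequence, 201, 400), substr(body_plus, 1, 200))
  # minus strand: window reads on the transcript strand
  genome2 <- c(chr2 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome[["chr1"]]))))
  clen <- nchar(genome2)
  ann2 <- data.frame(transcript_id = "M", gene_id = "G", chrom = "chr2",
                     strand = "-", start = clen - 800L + 1L,
                     end = clen - 301L + 1L, tss = clen - 301L + 1L,
                     length = 500L, utr5_end = 100L, cds_end = 400L,
                     stringsAsFactors = FALSE)
  win2 <- build_windows(ann2, genome2)
  expect_equal(win2$sequence, win$sequence)
  # a TSS 50 nt from the contig edge gives a truncated, flagged window
  ann3 <- ann
  ann3$start <- 51L; ann3$end <- 550L; ann3$tss <- 51L
  win3 <- build_windows(ann3, genome)
  expect_true(win3$truncated)
  expect_equal(win3$upstream_len, 50L)
  ann4 <- ann
  ann4$chrom <- "chrX"
  expect_error(build_windows(ann4, genome), "missing")
})

test_that("window offsets are TSS-anchored and RPM uses in-window hits", {
  up <- random_20mers(15, seed = 62)                 # 300 nt upstream
  body <- random_20mers(25, seed = 63)               # 500 nt cDNA
  genome <- c(chr1 = paste0(paste(up, collapse = ""),
                            paste(body, collapse = "")))
  ann <- data.frame(transcript_id = "P", gene_id = "G", chrom = "chr1",
                    strand = "+", start = 301L, end = 800L, tss = 301L,
                    length = 500L, utr5_end = 100L, cds_end = 400L,
                    stringsAsFactors = FALSE)
  win <- build_windows(ann, genome)
  tags <- data.frame(
    sequence = c(body[1],                      # offset 0
                 up[15],                       # offset -20
                 substr(genome, 291, 310),     # straddles the TSS: -10
                 random_20mers(1, 64)),        # no window hit
    count = c(5L, 3L, 2L, 90L))
  wt <- project_tags_to_window(tags, win, library_type = "CPARE")
  expect_equal(attr(wt, "total_mapped_reads"), 10L)
  expect_setequal(wt$offset, c(0L, -20L, -10L))
  expect_equal(wt$raw_count[wt$offset == 0L], 5L)
  expect_equal(wt$rpm[wt$offset == -20L], 3 * 1e6 / 10)
  expect_equal(sum(wt$rpm), 1e6)
  # prebuilt index gives identical results
  wt2 <- project_tags_to_window(tags, win, library_type = "CPARE",
                                index = window_index(win))
  expect_identical(wt, wt2)
})

test_that("cap inference applies the three filters on replicate pairs", {
  # counts are RPM directly (total 1e6 in the toy builder):
  #   C1 passes (max 200 at offset 0, ratio 0.8)
  #   C2 fails F1 (maxima at different offsets)
  #   C3 fails F2 (max 8 <= 10)
  #   C4 fails F3 (ratio exactly 0.2, strict threshold)
  w <- function(r, c2off) toy_window_table(
    transcript_id = c("C1", "C1", "C2", "C2", "C3",
                      "C4", "C4", "C4", "C4", "C4"),
    offset = c(0L, 30L, c2off, 90L, -5L, 10L, 20L, 30L, 40L, 50L),
    rpm = c(200, 50, 100, 80, 8, 19, 19, 19, 19, 19), replicate = r)
  res <- infer_cap_position(w(1L, 60L), w(2L, 61L))
  expect_equal(res$cascade$survivors, c(4L, 3L, 2L, 1L))
  expect_equal(res$calls$transcript_id, "C1")
  expect_equal(res$calls$cap_offset, 0L)
  # per-replicate mode: one replicate below a threshold now fails even
  # though the replicate mean passes
  wa <- toy_window_table("C1", c(0L, 30L), c(8, 5), replicate = 1L)
  wb <- toy_window_table("C1", c(0L, 30L), c(60, 20), replicate = 2L)
  expect_equal(nrow(infer_cap_position(wa, wb)$calls), 1L)  # mean 34 > 10
  expect_equal(nrow(infer_cap_position(wa, wb,
                                       per_replicate = TRUE)$calls),
               0L)  # replicate-1 max 8 <= 10
  wa2 <- toy_window_table("C1", c(0L, 30L), c(40, 5), replicate = 1L)
  expect_equal(nrow(infer_cap_position(wa2, wb,
                                       per_replicate = TRUE)$calls), 1L)
})

test_that("decap calls require the PARE Max-seq at the inferred cap", {
  cap_calls <- data.frame(
    transcript_id = c("A", "B", "C"),
    cap_offset = c(0L, 5L, -3L),
    max_rpm_r1 = c(100, 100, 100), max_rpm_r2 = c(100, 100, 100),
    ratio_r1 = c(0.9, 0.9, 0.9), ratio_r2 = c(0.9, 0.9, 0.9),
    stringsAsFactors = FALSE)
  # PARE windows: A peaks at the cap (decapped), B peaks elsewhere,
  # C fails the PARE abundance filter
  pw <- function(r) toy_window_table(
    transcript_id = c("A", "A", "B", "B", "C"),
    offset = c(0L, 100L, 40L, 5L, -3L),
    rpm = c(80, 15, 90, 20, 6), replicate = r)
  res <- call_decapped(cap_calls, pw(1L), pw(2L))
  expect_equal(res$calls$transcript_id, "A")
  expect_equal(res$calls$offset, 0L)
  expect_equal(res$calls$cpare_max_rpm_r1, 100)
  expect_equal(res$calls$pare_max_rpm_r1, 80)
  # B survived the PARE cascade but at the wrong offset
  expect_true("B" %in% res$pare_max$transcript_id)
  expect_false("C" %in% res$pare_max$transcript_id)
})

test_that("offset distribution reports the headline cap statistics", {
  calls <- data.frame(transcript_id = sprintf("T%d", 1:8),
                      cap_offset = c(0L, 0L, 3L, -50L, 51L, 199L, -200L,
                                     25L))
  od <- offset_distribution(calls)
  expect_equal(sum(od$histogram$count), 8L)
  expect_equal(od$histogram$offset, -200L:199L)
  expect_equal(od$histogram$count[od$histogram$offset == 0L], 2L)
  expect_equal(od$frac_at_annotated, 2 / 8)
  # within 50 nt inclusive: 0,0,3,-50,25 -> 5/8
  expect_equal(od$frac_within_50, 5 / 8)
  empty <- offset_distribution(calls[0, , drop = FALSE])
  expect_true(is.na(empty$frac_at_annotated))
})

test_that("planted caps and decapping are recovered on the small run", {
  run <- small_run()
  truth <- run$sim$truth
  cap <- run$cap$calls
  i <- match(truth$transcript_id, cap$transcript_id)
  found <- !is.na(i)
  # every inferred cap sits at its planted offset
  expect_true(all(cap$cap_offset[i[found]] == truth$cap_offset[found]))
  # decap calls recover the planted decapped transcripts; planted-stable
  # transcripts are excluded because their 16-fold-depleted degradome
  # signal legitimately fails the 10-RPM window filter
  planted_dc <- truth$transcript_id[truth$is_decapped &
                                      truth$stability_class != "stable"]
  expect_gt(length(planted_dc), 0L)
  expect_true(all(run$decap$calls$transcript_id %in%
                    truth$transcript_id))
  recall <- mean(planted_dc %in% run$decap$calls$transcript_id)
  expect_gte(recall, 0.9)
})
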