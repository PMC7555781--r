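# End-to-end orchestration on a synthetic experiment, recovery evaluation
# against the planted ground truth, and deterministic TSV export.

#' Run the full degradome pipeline on a simulated experiment
#'
#' Preprocesses the simulated PARE and C-PARE libraries (trimming, SSR /
#' multi-hit / mitochondrial filters, 1-mismatch cDNA mapping), computes
#' abundance and stability classifications, calls endonucleolytic cleavage
#' sites, infers cap positions and calls decapped transcripts, and builds
#' the run summary.
#'
#' @param sim a \code{degradome_sim} from \code{\link{simulate_degradome}},
#'   or a \code{\link{sim_config}} (simulated on the fly).
#' @param fdr_max,lfc_min,abundance_min stability filter thresholds.
#' @param soa_min,max_min cleavage cascade thresholds (RPM).
#' @param rpm_min cap/decap Max-seq abundance threshold (RPM).
#' @param ratio_min Max-seq ratio threshold (cleavage F4 and window F3).
#' @param dispersion common NB dispersion for the exact test; NULL to
#'   estimate from the replicates.
#' @return object of class \code{degradome_run}: the simulation plus
#'   tag tables, window tables, abundance, stability, cleavage, cap,
#'   decap and summary components.
#' @export
run_degradome <- function(sim,
                          fdr_max = 0.01, lfc_min = 2.5, abundance_min = 1,
                          soa_min = 50, max_min = 10, rpm_min = 10,
                          ratio_min = 0.2, dispersion = NULL) {
  if (inherits(sim, "sim_config")) sim <- simulate_degradome(sim)
  stopifnot(inherits(sim, "degradome_sim"))
  tr <- sim$transcriptome
  gidx <- genome_index(tr$genome[names(tr$genome) != "chrM"])
  midx <- genome_index(tr$genome["chrM"])
  cidx <- cdna_index(tr$cdna)
  pre <- function(lib, type, r) {
    preprocess_library(lib, cdna = cidx, genome = gidx, mito = midx,
                       library_id = sprintf("%s_rep%d", type, r),
                       library_type = type, replicate = r)
  }
  pare <- list(pre(sim$pare$rep1, "PARE", 1L),
               pre(sim$pare$rep2, "PARE", 2L))
  cpare_tags <- lapply(1:2, function(r) {
    tags <- trim_reads(sim$cpare[[r]])
    filter_tags(tags, gidx, midx)
  })
  windows <- build_windows(tr$annotation, tr$genome)
  widx <- window_index(windows)
  wproj <- function(tags, type, r) {
    project_tags_to_window(tags, windows,
                           library_id = sprintf("%s_rep%d_win", type, r),
                           library_type = type, replicate = r,
                           index = widx)
  }
  cpare_w <- list(wproj(cpare_tags[[1]], "CPARE", 1L),
                  wproj(cpare_tags[[2]], "CPARE", 2L))
  pare_w <- list(wproj(pare[[1]]$filtered_tags, "PARE", 1L),
                 wproj(pare[[2]]$filtered_tags, "PARE", 2L))
  ab <- abundance_table(list(pare[[1]]$table, pare[[2]]$table),
                        sim$rnaseq, tr$annotation)
  test <- stability_test(ab, dispersion = dispersion)
  stab <- classify_stability(test, ab, fdr_max = fdr_max,
                             lfc_min = lfc_min,
                             abundance_min = abundance_min)
  cleav <- call_endonucleolytic(pare[[1]]$table, pare[[2]]$table,
                                tr$annotation, soa_min = soa_min,
                                max_min = max_min, ratio_min = ratio_min)
  cap <- infer_cap_position(cpare_w[[1]], cpare_w[[2]],
                            rpm_min = rpm_min, ratio_min = ratio_min)
  decap <- call_decapped(cap$calls, pare_w[[1]], pare_w[[2]],
                         rpm_min = rpm_min, ratio_min = ratio_min)
  out <- list(
    sim = sim,
    windows = windows,
    pare_tables = list(pare[[1]]$table, pare[[2]]$table),
    pare_logs = list(pare[[1]]$filter_log, pare[[2]]$filter_log),
    cpare_windows = cpare_w,
    pare_windows = pare_w,
    abundance = ab,
    stability = stab,
    cleavage = cleav,
    cap = cap,
    decap = decap,
    summary = summary_tables(stab, cleav$calls, cap$calls, decap$calls))
  class(out) <- "degradome_run"
  out
}

#' @export
print.degradome_run <- function(x, ...) {
  s <- x$summary
  cat("Degradome pipeline run\n")
  cat(sprintf("  transcripts:        %d\n", s$stability$n_transcripts))
  cat(sprintf("  stable / unstable:  %d / %d\n",
              s$stability$n_stable, s$stability$n_unstable))
  cat(sprintf("  cleavage calls:     %d\n", s$cleavage$n_calls))
  cat(sprintf("  cap positions:      %d\n", s$cap$n_calls))
  cat(sprintf("  decapped calls:     %d\n", s$decap$n_calls))
  invisible(x)
}

#' @export
summary.degradome_run <- function(object, ...) {
  object$summary
}

#' Evaluate a run against the planted ground truth
#'
#' Compares the pipeline's calls with the simulation's ground-truth labels.
#'
#' @param run a \code{degradome_run}.
#' @return list: sensitivity_stable, sensitivity_unstable, class_swaps
#'   (planted stable called unstable or vice versa),
#'   null_nonneither_rate (fraction of planted-neither transcripts
#'   classified), cleavage_recall, cleavage_exact (recalled at the exact
#'   planted position), cleavage_fpr (calls among transcripts without a
#'   planted site), decap_recall, decap_fp_cleavage_only (decap calls among
#'   cleavage-only transcripts).
#' @export
evaluate_recovery <- function(run) {
  stopifnot(inherits(run, "degradome_run"))
  truth <- run$sim$truth
  stab <- run$stability
  cls <- stab$class[match(truth$transcript_id, stab$transcript_id)]
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- function(class) {
    planted <- truth$stability_class == class
    rate(sum(planted & cls == class), sum(planted))
  }
  swaps <- sum((truth$stability_class == "stable" & cls == "unstable") |
                 (truth$stability_class == "unstable" & cls == "stable"))
  planted_cl <- !is.na(truth$cleavage_pos)
  calls <- run$cleavage$calls
  hit <- truth$transcript_id[planted_cl] %in% calls$transcript_id
  pos_ok <- calls$position[match(truth$transcript_id[planted_cl],
                                 calls$transcript_id)] ==
    truth$cleavage_pos[planted_cl]
  planted_dc <- truth$is_decapped
  # a planted decap peak is itself a dominant 5'-end signal, so only
  # transcripts without any planted peak count toward false positives
  no_peak <- !planted_cl & !planted_dc
  fp_cl <- sum(calls$transcript_id %in% truth$transcript_id[no_peak])
  dc <- run$decap$calls
  dc_hit <- truth$transcript_id[planted_dc] %in% dc$transcript_id
  cl_only <- planted_cl & !planted_dc
  list(
    sensitivity_stable = sens("stable"),
    sensitivity_unstable = sens("unstable"),
    class_swaps = swaps,
    null_nonneither_rate = rate(
      sum(truth$stability_class == "neither" & cls != "neither"),
      sum(truth$stability_class == "neither")),
    cleavage_recall = rate(sum(hit), sum(planted_cl)),
    cleavage_exact = rate(sum(pos_ok, na.rm = TRUE), sum(planted_cl)),
    cleavage_fpr = rate(fp_cl, sum(no_peak)),
    decap_recall = rate(sum(dc_hit), sum(planted_dc)),
    decap_fp_cleavage_only = rate(
      sum(dc$transcript_id %in% truth$transcript_id[cl_only]),
      sum(cl_only)))
}

#' Write a run's outputs as deterministic TSV/JSON files
#'
#' @param run a \code{degradome_run}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_degradome <- function(run, outdir) {
  stopifnot(inherits(run, "degradome_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(outdir, x)
  wt <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p(f)
  }
  files <- c(
    write_tag_table(run$pare_tables[[1]], p("pare_rep1_tags.tsv")),
    write_tag_table(run$pare_tables[[2]], p("pare_rep2_tags.tsv")),
    wt(run$abundance, "abundance.tsv"),
    wt(run$stability, "stability.tsv"),
    wt(run$cleavage$calls, "cleavage_calls.tsv"),
    wt(run$cleavage$cascade, "cleavage_cascade.tsv"),
    wt(percentile_distribution(run$cleavage$calls),
       "cleavage_percentiles.tsv"),
    wt(run$cap$calls, "cap_calls.tsv"),
    wt(run$cap$cascade, "cap_cascade.tsv"),
    wt(offset_distribution(run$cap$calls)$histogram,
       "cap_offset_histogram.tsv"),
    wt(run$decap$calls, "decap_calls.tsv"))
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(files, p("summary.json")))
}
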