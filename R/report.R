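# Descriptive outputs: D-plot data and figures, replicate correlation,
# and machine-readable run summaries.  Every figure has a TSV twin so the
# numbers behind a plot are testable without parsing images.

#' Assemble D-plot data for one transcript
#'
#' A D-plot shows the normalized abundance of degradome tags versus their
#' position on the cDNA, with the 5'UTR/CDS/3'UTR partition and the
#' Max-seq marked.
#'
#' @param profile a \code{decay_profile}.
#' @param annotation_row one-row annotation data frame for the transcript.
#' @param coverage optional companion RNA-seq coverage series (numeric
#'   vector along the cDNA).
#' @return list of class \code{dplot_data}: transcript_id, series (data
#'   frame: position, rpm), regions (utr5_end, cds_end, length), max_seq
#'   (from \code{\link{find_max_seq}}; NULL when empty), coverage.
#' @export
dplot_data <- function(profile, annotation_row, coverage = NULL) {
  stopifnot(inherits(profile, "decay_profile"),
            annotation_row$transcript_id == profile$transcript_id)
  structure(list(
    transcript_id = profile$transcript_id,
    series = data.frame(position = profile$positions, rpm = profile$rpm),
    regions = list(utr5_end = annotation_row$utr5_end,
                   cds_end = annotation_row$cds_end,
                   length = annotation_row$length),
    max_seq = find_max_seq(profile),
    coverage = coverage), class = "dplot_data")
}

#' Render a D-plot and write its TSV twin
#'
#' Writes \code{<file>.tsv} (position, rpm series; byte-stable for equal
#' inputs) and, when \code{file} ends in .png or .svg, the rendered figure.
#' An empty profile yields an empty series and an annotated empty plot.
#'
#' @inheritParams dplot_data
#' @param file output path stem or figure path (.png/.svg); NULL renders to
#'   the active device only.
#' @return the \code{dplot_data}, invisibly.
#' @export
make_dplot <- function(profile, annotation_row, coverage = NULL,
                       file = NULL) {
  d <- dplot_data(profile, annotation_row, coverage)
  if (!is.null(file)) {
    stem <- sub("\\.(png|svg)$", "", file)
    utils::write.table(d$series, paste0(stem, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ext <- tolower(sub(".*\\.", "", file))
    if (ext == "png") {
      grDevices::png(file, width = 900, height = 450)
      on.exit(grDevices::dev.off())
    } else if (ext == "svg") {
      grDevices::svg(file, width = 9, height = 4.5)
      on.exit(grDevices::dev.off())
    }
  }
  if (is.null(file) || grepl("\\.(png|svg)$", file)) {
    L <- d$regions$length
    plot(NA, xlim = c(0, L), ylim = c(0, max(d$series$rpm, 1)),
         xlab = "cDNA position (nt)", ylab = "abundance (RPM)",
         main = paste("D-plot:", d$transcript_id))
    graphics::rect(0, 0, d$regions$utr5_end, -0.02, col = "grey70")
    graphics::abline(v = c(d$regions$utr5_end, d$regions$cds_end),
                     lty = 3, col = "grey50")
    if (nrow(d$series) > 0) {
      graphics::segments(d$series$position, 0, d$series$position,
                         d$series$rpm)
    }
    if (!is.null(d$max_seq)) {
      graphics::points(d$max_seq$position, d$max_seq$abundance, pch = 8,
                       col = "red")
    }
    if (!is.null(coverage)) {
      graphics::lines(seq_along(coverage) - 1L,
                      coverage * max(d$series$rpm, 1) / max(coverage, 1),
                      col = "grey60")
    }
  }
  invisible(d)
}

#' Squared Pearson correlation between replicates
#'
#' Computes R^2 between paired replicate values, optionally after a
#' log10(x + 1) transform (the scale used for abundance scatter plots).
#'
#' @param rep1,rep2 paired numeric vectors (length >= 2).
#' @param log_transform apply log10(x + 1) first.
#' @return squared Pearson correlation coefficient.
#' @export
replicate_correlation <- function(rep1, rep2, log_transform = TRUE) {
  stopifnot(length(rep1) == length(rep2), length(rep1) >= 2L)
  if (log_transform) {
    rep1 <- log10(rep1 + 1)
    rep2 <- log10(rep2 + 1)
  }
  if (stats::sd(rep1) == 0 || stats::sd(rep2) == 0) {
    stop("replicate correlation undefined: zero variance")
  }
  stats::cor(rep1, rep2)^2
}

pct <- function(num, den) {
  if (is.na(den) || den == 0) NA_real_ else 100 * num / den
}

#' Summarize a full run
#'
#' Headline counts and cross-tabulations of the pipeline outputs:
#' stability classes, cleavage calls, cap calls, decap calls, and the
#' overlap of cleaved / decapped transcripts with the stability classes.
#' Missing sections (NULL inputs) are reported as absent; percentages with
#' zero denominators are NA.
#'
#' @param stability classification data frame from
#'   \code{\link{classify_stability}}, or NULL.
#' @param cleavage_calls calls data frame from
#'   \code{\link{call_endonucleolytic}}, or NULL.
#' @param cap_calls calls data frame from \code{\link{infer_cap_position}},
#'   or NULL.
#' @param decap_calls calls data frame from \code{\link{call_decapped}},
#'   or NULL.
#' @return a nested list (JSON-serializable) of counts and percentages.
#' @export
summary_tables <- function(stability = NULL, cleavage_calls = NULL,
                           cap_calls = NULL, decap_calls = NULL) {
  out <- list()
  cls <- function(ids) {
    if (is.null(stability)) return(NULL)
    stability$class[match(ids, stability$transcript_id)]
  }
  if (!is.null(stability)) {
    tab <- table(factor(stability$class,
                        levels = c("stable", "unstable", "neither")))
    out$stability <- list(n_transcripts = nrow(stability),
                          n_stable = unname(tab["stable"]),
                          n_unstable = unname(tab["unstable"]),
                          n_neither = unname(tab["neither"]))
  } else {
    out$stability <- list(absent = TRUE)
  }
  if (!is.null(cleavage_calls)) {
    k <- cls(cleavage_calls$transcript_id)
    out$cleavage <- list(
      n_calls = nrow(cleavage_calls),
      n_unstable = if (is.null(k)) NA else sum(k == "unstable"),
      n_stable = if (is.null(k)) NA else sum(k == "stable"),
      pct_unstable = if (is.null(k)) NA else
        pct(sum(k == "unstable"), nrow(cleavage_calls)))
  } else {
    out$cleavage <- list(absent = TRUE)
  }
  if (!is.null(cap_calls)) {
    dist <- offset_distribution(cap_calls)
    out$cap <- list(n_calls = nrow(cap_calls),
                    frac_at_annotated = dist$frac_at_annotated,
                    frac_within_50 = dist$frac_within_50)
  } else {
    out$cap <- list(absent = TRUE)
  }
  if (!is.null(decap_calls)) {
    k <- cls(decap_calls$transcript_id)
    out$decap <- list(
      n_calls = nrow(decap_calls),
      n_unstable = if (is.null(k)) NA else sum(k == "unstable"),
      n_stable = if (is.null(k)) NA else sum(k == "stable"),
      pct_unstable = if (is.null(k)) NA else
        pct(sum(k == "unstable"), nrow(decap_calls)),
      pct_stable = if (is.null(k)) NA else
        pct(sum(k == "stable"), nrow(decap_calls)))
  } else {
    out$decap <- list(absent = TRUE)
  }
  out
}
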