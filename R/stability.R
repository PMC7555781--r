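# Stable / unstable classification: exact negative-binomial count test
# comparing RNA-seq to degradome counts, BH false-discovery control, and
# the abundance / significance / fold-change filter triple.

#' Exact conditional count test for RNA-seq vs degradome abundance
#'
#' Two-sided test for a difference in relative abundance between the two
#' assays under a negative-binomial model with a common dispersion.  Counts
#' are equalized to the geometric mean of the supplied library sizes and
#' pooled across replicates; conditional on the pooled total, the first
#' condition's count follows a symmetric beta-binomial (dispersion > 0) or
#' binomial(total, 1/2) (dispersion 0) null, and the p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param rna_counts,pare_counts integer count vectors, one element per
#'   replicate.
#' @param rna_libsizes,pare_libsizes (effective) library sizes, same length
#'   as the count vectors.
#' @param dispersion common negative-binomial dispersion (>= 0) of a single
#'   replicate; the pooled count over n replicates uses dispersion / n.
#' @return two-sided p-value in (0, 1]; all-zero counts give 1.
#' @export
exact_count_test <- function(rna_counts, pare_counts,
                             rna_libsizes, pare_libsizes,
                             dispersion = 0) {
  stopifnot(length(rna_counts) == length(rna_libsizes),
            length(pare_counts) == length(pare_libsizes),
            all(rna_libsizes > 0), all(pare_libsizes > 0),
            dispersion >= 0)
  ref <- exp(mean(log(c(rna_libsizes, pare_libsizes))))
  a <- round(sum(rna_counts * ref / rna_libsizes))
  b <- round(sum(pare_counts * ref / pare_libsizes))
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  if (dispersion == 0) {
    logp <- stats::dbinom(k, t, 0.5, log = TRUE)
  } else {
    # conditional law of one NB count given the sum of two iid NB counts
    # (negative hypergeometric); free of the common mean
    s <- mean(c(length(rna_counts), length(pare_counts))) / dispersion
    logp <- lchoose(k + s - 1, k) + lchoose(t - k + s - 1, t - k)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  obs <- logp[a + 1L]
  p <- sum(exp(logp[logp <= obs + 1e-8]))
  min(1, p)
}

#' Method-of-moments common dispersion
#'
#' Estimates a single negative-binomial dispersion shared across transcripts
#' from replicate count matrices: counts are scaled to a common library
#' size, and the per-transcript moment estimate (var - mean) / mean^2 is
#' averaged over sufficiently expressed transcripts.
#'
#' @param counts matrix (transcripts x replicates) of one condition's
#'   counts; or a list of such matrices pooled over conditions.
#' @param libsizes library sizes per replicate (or list matching
#'   \code{counts}).
#' @param min_mean minimum scaled mean for a transcript to contribute.
#' @return non-negative dispersion estimate.
#' @export
estimate_dispersion <- function(counts, libsizes, min_mean = 5) {
  if (!is.list(counts)) {
    counts <- list(counts)
    libsizes <- list(libsizes)
  }
  ests <- unlist(lapply(seq_along(counts), function(i) {
    cm <- as.matrix(counts[[i]])
    ls <- libsizes[[i]]
    ref <- exp(mean(log(ls)))
    sc <- sweep(cm, 2, ref / ls, `*`)
    m <- rowMeans(sc)
    v <- apply(sc, 1, stats::var)
    keep <- m >= min_mean
    ((v - m) / m^2)[keep]
  }))
  if (length(ests) == 0L) return(0)
  max(0, mean(ests))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard BH step-up false-discovery-rate values.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return FDR values, same length and order as the input.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

# Effective library sizes: library sizes rescaled by a median-of-log-ratios
# composition factor between the pooled RNA-seq and pooled degradome
# counts, so that the typical transcript has fold change 0.  This plays the
# role of the differential package's normalization factors; under a
# balanced null it reduces to plain library-size equalization.
effective_libsizes <- function(ab) {
  rna_tot <- attr(ab, "rna_totals")
  pare_tot <- attr(ab, "pare_totals")
  r <- ab$rna_count_r1 + ab$rna_count_r2
  p <- ab$pare_count_r1 + ab$pare_count_r2
  ok <- r > 0 & p > 0
  s <- if (any(ok)) {
    stats::median(log2((r[ok] / sum(rna_tot)) / (p[ok] / sum(pare_tot))))
  } else 0
  list(rna = rna_tot * 2^(s / 2), pare = pare_tot * 2^(-s / 2),
       composition_log2 = s)
}

#' Exact count test across all transcripts
#'
#' Runs \code{\link{exact_count_test}} for every transcript of an abundance
#' table, with effective library sizes (library sizes rescaled by the
#' median log-ratio between assays so the typical transcript is balanced)
#' and a common dispersion estimated from the replicates unless supplied.
#'
#' @param ab abundance table from \code{\link{abundance_table}}.
#' @param dispersion common dispersion; NULL to estimate by
#'   \code{\link{estimate_dispersion}} pooled over both assays.
#' @return data frame: transcript_id, log2fc (log2 FPKM/DPKM on effective
#'   library sizes, 0.5 pseudo-count only when one pooled count is zero),
#'   pvalue, fdr; attributes \code{dispersion}, \code{effective_libsizes},
#'   \code{pseudo_count_used} (logical vector).
#' @export
stability_test <- function(ab, dispersion = NULL) {
  eff <- effective_libsizes(ab)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(
      list(as.matrix(ab[, c("rna_count_r1", "rna_count_r2")]),
           as.matrix(ab[, c("pare_count_r1", "pare_count_r2")])),
      list(attr(ab, "rna_totals"), attr(ab, "pare_totals")))
  }
  n <- nrow(ab)
  pv <- numeric(n)
  for (i in seq_len(n)) {
    pv[i] <- exact_count_test(
      c(ab$rna_count_r1[i], ab$rna_count_r2[i]),
      c(ab$pare_count_r1[i], ab$pare_count_r2[i]),
      eff$rna, eff$pare, dispersion)
  }
  r <- ab$rna_count_r1 + ab$rna_count_r2
  p <- ab$pare_count_r1 + ab$pare_count_r2
  pseudo <- xor(r == 0, p == 0)
  rr <- ifelse(pseudo & r == 0, 0.5, r)
  pp <- ifelse(pseudo & p == 0, 0.5, p)
  log2fc <- ifelse(r == 0 & p == 0, 0,
                   log2((rr / sum(eff$rna)) / (pp / sum(eff$pare))))
  out <- data.frame(transcript_id = ab$transcript_id,
                    log2fc = log2fc, pvalue = pv, fdr = adjust_fdr(pv),
                    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  attr(out, "effective_libsizes") <- eff
  attr(out, "pseudo_count_used") <- pseudo
  out
}

#' Classify transcripts as stable, unstable or neither
#'
#' Applies the three filters: abundance (mean FPKM or mean DPKM at least
#' \code{abundance_min}), significance (FDR below \code{fdr_max}) and fold
#' change (|log2 FPKM/DPKM| above \code{lfc_min}).  A transcript with
#' log2fc above +lfc_min is stable (RNA-seq excess over decay products);
#' below -lfc_min, unstable.
#'
#' @param test results of \code{\link{stability_test}}.
#' @param ab matching abundance table (for the abundance filter).
#' @param fdr_max FDR threshold (default 0.01).
#' @param lfc_min |log2 fold change| threshold (default 2.5).
#' @param abundance_min minimum mean FPKM or DPKM (default 1).
#' @return data frame: transcript_id, log2fc, pvalue, fdr,
#'   passes_abundance, class; attribute \code{class_counts}.
#' @export
classify_stability <- function(test, ab, fdr_max = 0.01, lfc_min = 2.5,
                               abundance_min = 1) {
  i <- match(test$transcript_id, ab$transcript_id)
  mean_fpkm <- (ab$fpkm_r1[i] + ab$fpkm_r2[i]) / 2
  mean_dpkm <- (ab$dpkm_r1[i] + ab$dpkm_r2[i]) / 2
  passes <- mean_fpkm >= abundance_min | mean_dpkm >= abundance_min
  cls <- rep("neither", nrow(test))
  sig <- passes & test$fdr < fdr_max
  cls[sig & test$log2fc > lfc_min] <- "stable"
  cls[sig & test$log2fc < -lfc_min] <- "unstable"
  out <- data.frame(test,
                    passes_abundance = passes,
                    class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "class_counts") <- table(factor(cls, levels = c(
    "stable", "unstable", "neither")))
  for (a in c("dispersion", "effective_libsizes", "pseudo_count_used")) {
    if (!is.null(attr(test, a))) attr(out, a) <- attr(test, a)
  }
  out
}
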