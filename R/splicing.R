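# Compartment-differential splicing screen: a nucleo-cytoplasmic splicing
# index on gene-normalized exon signal, a per-exon interaction F-test, BH
# FDR control, and pairing of flagged transcripts with miRNA targets.

#' Nucleo-cytoplasmic splicing index per exon
#'
#' The gene-level signal of a transcript is the mean of its exon signals;
#' exon and gene signals are averaged across replicates within each
#' compartment, and the splicing index of an exon is
#' `log2((exon/gene)_nuclear / (exon/gene)_cytoplasmic)`.  The index is
#' antisymmetric under swapping compartment labels and invariant to global
#' rescaling of the signals.  Exons with a zero denominator are undefined
#' (`NA`); single-exon transcripts are excluded with a warning.
#'
#' @param x an [ExonExperiment] with both compartments present.
#' @return data.frame with columns `transcript_id`, `exon_id`, `si`.
#' @export
splicingIndex <- function(x) {
  comp <- .check_both_compartments(x)
  s <- signalMatrix(x)
  tx <- transcriptIds(x)
  single <- names(which(table(tx) < 2L))
  if (length(single)) {
    warning(length(single),
            " single-exon transcript(s) excluded from the splicing index")
    keep <- !tx %in% single
    s <- s[keep, , drop = FALSE]
    x <- x[keep, ]
    tx <- tx[keep]
  }
  eN <- rowMeans(s[, comp == "nuclear", drop = FALSE])
  eC <- rowMeans(s[, comp == "cytoplasmic", drop = FALSE])
  gN <- ave(eN, tx)          # per-transcript mean of replicate-averaged exons
  gC <- ave(eC, tx)
  rN <- ifelse(gN == 0, NA_real_, eN / gN)
  rC <- ifelse(gC == 0, NA_real_, eC / gC)
  si <- ifelse(is.na(rN) | is.na(rC) | rC == 0 | rN == 0,
               NA_real_, log2(rN / rC))
  data.frame(transcript_id = tx, exon_id = exonIds(x), si = si,
             row.names = NULL)
}

#' Per-exon compartment-by-exon interaction test
#'
#' For each transcript, fits a two-way fixed-effects model on
#' `log2(signal + 1)` with factors exon and compartment; per-exon baseline
#' differences are absorbed by the exon main effect, and the reported
#' p-value is the F-test of the exon x compartment interaction restricted
#' to the single-exon-vs-rest contrast for the exon under test (does this
#' exon's compartment difference depart from the transcript's?).  In the
#' degenerate
#' noiseless case with no interaction the F statistic is 0/0; such
#' undefined p-values are reported as 1 (no evidence of differential
#' splicing).  Transcripts with fewer than two exons or without residual
#' degrees of freedom are skipped with a warning.
#'
#' @param x an [ExonExperiment] with >= 2 replicates per compartment.
#' @return data.frame with columns `transcript_id`, `exon_id`, `p`.
#' @export
exonInteractionTest <- function(x) {
  comp <- .check_both_compartments(x)
  if (any(tabulate(factor(comp, .COMPARTMENTS), 2L) < 2L))
    stop("at least two replicates per compartment are required")
  s <- signalMatrix(x)
  y <- log2(s + 1)
  tx <- transcriptIds(x)
  ex <- exonIds(x)
  skipped <- character()
  res <- lapply(unique(tx), function(t) {
    rows <- which(tx == t)
    if (length(rows) < 2L) {
      skipped <<- c(skipped, t)
      return(NULL)
    }
    yt <- y[rows, , drop = FALSE]
    nSamp <- ncol(yt)
    J <- length(rows)
    if (J * nSamp - (J + 2L) < 1L) {
      skipped <<- c(skipped, t)
      return(NULL)
    }
    long_y <- as.vector(yt)                         # column-major: exon fast
    long_comp <- factor(rep(comp, each = J), .COMPARTMENTS)
    exonF <- factor(rep(seq_len(J), times = nSamp))
    p <- vapply(seq_len(J), function(k) {
      this <- factor(exonF == k, c(FALSE, TRUE))
      fit <- lm(long_y ~ exonF + long_comp + this:long_comp)
      # essentially-perfect fits (noiseless data) warn in anova; the
      # degenerate cases are handled explicitly below
      an <- suppressWarnings(anova(fit))
      iRow <- which(grepl(":", rownames(an)))[1L]
      # numerically zero interaction (noiseless degenerate fit): no evidence
      if (an[iRow, "Sum Sq"] < 1e-10 * max(sum(an[, "Sum Sq"]), 1))
        return(1)
      pv <- an[iRow, "Pr(>F)"]
      if (is.na(pv)) pv <- 1                        # 0/0 F: no evidence
      pv
    }, numeric(1L))
    data.frame(transcript_id = t, exon_id = ex[rows], p = p)
  })
  if (length(skipped))
    warning(length(skipped), " transcript(s) skipped (too few exons or no ",
            "residual degrees of freedom)")
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), exon_id = character(),
                      p = numeric())
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment with monotonicity enforcement, stable under input
#' reordering; q-values never fall below the raw p-values.  Thin validated
#' wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in [0, 1] (`NA` allowed,
#'   propagated).
#' @return numeric vector of q-values, same order as the input.
#' @export
bhFdr <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Splicing screen: index, interaction test, FDR and flags
#'
#' Combines [splicingIndex()], [exonInteractionTest()] and [bhFdr()], and
#' flags each exon whose q-value is below `fdrAlpha` and whose
#' gene-normalized compartment ratio exceeds `siThreshold` in either
#' direction.  With `scale = "linear"` (default) the fold criterion is
#' `max(2^si, 2^-si) > siThreshold`; with `scale = "log2"` it is
#' `|si| > siThreshold`.
#'
#' @param x an [ExonExperiment].
#' @param fdrAlpha FDR level (default 0.01).
#' @param siThreshold splicing-index threshold (default 2).
#' @param scale `"linear"` (default) or `"log2"` interpretation of
#'   `siThreshold`.
#' @return data.frame with columns `transcript_id`, `exon_id`, `si`, `p`,
#'   `q`, `flagged`.
#' @export
splicingScreen <- function(x, fdrAlpha = 0.01, siThreshold = 2,
                           scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  si <- splicingIndex(x)
  pv <- suppressWarnings(exonInteractionTest(x))
  out <- merge(si, pv, by = c("transcript_id", "exon_id"), sort = FALSE)
  out$q <- bhFdr(out$p)
  fold <- if (scale == "linear") pmax(2^out$si, 2^-out$si) else abs(out$si)
  out$flagged <- !is.na(out$si) & !is.na(out$q) &
    out$q < fdrAlpha & fold > siThreshold
  out
}

#' Transcripts flagged as differentially spliced
#'
#' A transcript is flagged when at least one of its exons passes both the
#' FDR and the splicing-index criterion (recomputed from the table, so the
#' thresholds can differ from those used in [splicingScreen()]).
#'
#' @param results data.frame from [splicingScreen()] (columns
#'   `transcript_id`, `si`, `q`).
#' @inheritParams splicingScreen
#' @return character vector of flagged transcript ids.
#' @export
flagSpliced <- function(results, fdrAlpha = 0.01, siThreshold = 2,
                        scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  fold <- if (scale == "linear") pmax(2^results$si, 2^-results$si)
          else abs(results$si)
  hit <- !is.na(results$si) & !is.na(results$q) &
    results$q < fdrAlpha & fold > siThreshold
  unique(results$transcript_id[hit])
}

#' Pair flagged transcripts with their targeting miRNAs
#'
#' Crosses the flagged transcript set with a gene-to-miRNA target map (from
#' [targetsOfEnriched()] or an external list), one row per (miRNA,
#' transcript) pairing.
#'
#' @param flagged character vector of flagged transcript ids.
#' @param targetMap named list mapping gene/transcript ids to character
#'   vectors of targeting miRNA names.
#' @return data.frame with columns `mirna`, `transcript`.
#' @export
pairWithMirna <- function(flagged, targetMap) {
  flagged <- intersect(flagged, names(targetMap))
  rows <- lapply(flagged, function(t)
    data.frame(mirna = targetMap[[t]], transcript = t))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(mirna = character(),
                                      transcript = character())
  rownames(out) <- NULL
  out
}
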