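# Three compartment-enrichment calling methods for nuclear/cytoplasmic
# fractionation expression matrices:
#   raw nuclear-percentage thresholding (no normalization),
#   in-sample signal-rank separation, and
#   quantile normalization + empirical-Bayes moderated t.

.check_both_compartments <- function(x) {
  comp <- compartments(x)
  if (!all(.COMPARTMENTS %in% comp))
    stop("both nuclear and cytoplasmic samples are required")
  comp
}

#' Remove probes with low signal in all samples
#'
#' Retains probes with raw signal at or above `floor` in at least one sample;
#' a probe is dropped only when it is below the floor everywhere.  Row order
#' is preserved and an empty result is allowed.
#'
#' @param x a [CompartmentExperiment].
#' @param floor raw-signal floor (default 30).
#' @return A [CompartmentExperiment] with the retained probes.
#' @export
filterLowSignal <- function(x, floor = 30) {
  stopifnot(is(x, "CompartmentExperiment"), floor > 0)
  keep <- apply(signalMatrix(x) >= floor, 1L, any)
  x[keep, ]
}

#' Per-compartment replicate-mean signals
#'
#' @param x a [CompartmentExperiment] with both compartments present.
#' @return matrix with columns `mean_nuclear`, `mean_cytoplasmic`.
#' @export
compartmentMeans <- function(x) {
  comp <- .check_both_compartments(x)
  s <- signalMatrix(x)
  cbind(mean_nuclear = rowMeans(s[, comp == "nuclear", drop = FALSE]),
        mean_cytoplasmic = rowMeans(s[, comp == "cytoplasmic", drop = FALSE]))
}

#' Nuclear percentage of expression
#'
#' Raw signals are first averaged across replicates within each compartment;
#' the nuclear percentage is then 100 * nuclear / (nuclear + cytoplasmic).
#' A probe expressed in only one compartment gets 100 or 0; a probe with both
#' compartment means zero is undefined (`NA`) and is never called enriched.
#' The percentage is invariant to global rescaling of the matrix.
#'
#' @param x a [CompartmentExperiment] with both compartments present.
#' @return named numeric vector of percentages in [0, 100] (`NA` when
#'   undefined).
#' @export
nuclearPercentage <- function(x) {
  m <- compartmentMeans(x)
  tot <- m[, 1L] + m[, 2L]
  pct <- ifelse(tot == 0, NA_real_, 100 * m[, 1L] / tot)
  setNames(pct, rownames(m))
}

#' Call nuclear enrichment from nuclear percentages
#'
#' Strictly-greater comparison against the threshold; undefined (`NA`)
#' percentages are never enriched.  A percentage of exactly the threshold is
#' not a call.
#'
#' @param pct numeric vector of nuclear percentages (see
#'   [nuclearPercentage()]).
#' @param threshold percent, in [0, 100] (default 70).
#' @return named logical vector.
#' @export
callNuclearPercentage <- function(pct, threshold = 70) {
  stopifnot(threshold >= 0, threshold <= 100)
  call <- !is.na(pct) & pct > threshold
  setNames(call, names(pct))
}

#' In-sample rank scores relative to the sample median
#'
#' Within each sample, probes are sorted in descending signal order and given
#' ordinal positions 1..N (ties receive the average position).  The score of
#' a probe is the median position minus its position, so a larger signal
#' yields a larger score, the median probe scores 0 (odd N), and any strictly
#' monotone within-sample transform of the signals leaves the scores
#' unchanged.
#'
#' @param x a [CompartmentExperiment].
#' @param units `"rank"` (default; ordinal-position scores) or `"signal"`
#'   (raw distance from the in-sample median signal).
#' @return probe x sample numeric matrix of scores.
#' @export
rankScores <- function(x, units = c("rank", "signal")) {
  units <- match.arg(units)
  s <- signalMatrix(x)
  if (nrow(s) < 1L) stop("at least one probe is required")
  out <- s
  for (j in seq_len(ncol(s))) {
    if (units == "rank") {
      pos <- rank(-s[, j], ties.method = "average")
      out[, j] <- (nrow(s) + 1) / 2 - pos
    } else {
      out[, j] <- s[, j] - median(s[, j])
    }
  }
  out
}

#' Call enrichment by full rank separation between compartments
#'
#' A probe is called enriched in the chosen compartment when every sample of
#' that compartment scores strictly higher than every sample of the other
#' (min over enriched-compartment scores > max over the other's scores).
#' Ties never produce a call.
#'
#' @param scores probe x sample score matrix from [rankScores()].
#' @param compartment character vector of per-sample compartments (column
#'   order of `scores`).
#' @param direction compartment to call enrichment for (default
#'   `"nuclear"`).
#' @return named logical vector.
#' @export
callRankSeparation <- function(scores, compartment, direction = "nuclear") {
  stopifnot(ncol(scores) == length(compartment),
            direction %in% .COMPARTMENTS)
  if (!all(.COMPARTMENTS %in% compartment))
    stop("both nuclear and cytoplasmic samples are required")
  hi <- scores[, compartment == direction, drop = FALSE]
  lo <- scores[, compartment != direction, drop = FALSE]
  call <- apply(hi, 1L, min) > apply(lo, 1L, max)
  setNames(call, rownames(scores))
}

#' Quantile normalization across samples
#'
#' Makes every sample's empirical signal distribution equal to the mean of
#' the sorted sample distributions while preserving within-sample ordering
#' (ties map to the tie-mean of the reference values).  Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x a [CompartmentExperiment] with at least two samples.
#' @return A [CompartmentExperiment] with the normalized `"signal"` assay.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "CompartmentExperiment"))
  if (ncol(x) < 2L) stop("at least two samples are required")
  s <- signalMatrix(x)
  norm <- limma::normalizeQuantiles(s, ties = TRUE)
  dimnames(norm) <- dimnames(s)
  assay(x, "signal") <- norm
  x
}

#' Moment-matched inverse-chi-square variance prior
#'
#' Fits the prior degrees of freedom `d0` and prior variance `s02` of a
#' scaled inverse-chi-square distribution to the observed per-probe sample
#' variances by matching the first two moments of their marginal (scaled F)
#' distribution: `E[s2] = s02 d0/(d0-2)` and
#' `Var[s2]/E[s2]^2 = 2 (d + d0 - 2) / (d (d0 - 4))`.  When the observed
#' variance of `s2` does not exceed pure chi-square sampling scatter the
#' prior is degenerate (`d0 = Inf`, complete shrinkage to the mean).
#'
#' @param s2 numeric vector of per-probe sample variances.
#' @param df residual degrees of freedom of each `s2`.
#' @return list with elements `d0` and `s02`.
#' @export
fitVariancePrior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  m1 <- mean(s2)
  v <- var(s2)
  if (!is.finite(v) || m1 <= 0) return(list(d0 = Inf, s02 = max(m1, 0)))
  R <- v / m1^2
  if (R * df <= 2) return(list(d0 = Inf, s02 = m1))
  d0 <- (4 * R * df + 2 * df - 4) / (R * df - 2)   # algebra gives d0 > 2
  list(d0 = d0, s02 = m1 * (d0 - 2) / d0)
}

#' Moderated two-group t-test between compartments
#'
#' Per-probe nuclear-vs-cytoplasmic comparison on log2 signals with
#' empirical-Bayes variance shrinkage: the posterior variance is
#' `(d0 s02 + d s2) / (d0 + d)` with the prior `(d0, s02)` fit by moment
#' matching ([fitVariancePrior()]); the statistic is referred to a t
#' distribution with `d0 + d` degrees of freedom, two-sided, with
#' Benjamini-Hochberg adjusted q-values.  Intended to be applied after
#' [quantileNormalize()].  With `prior = list(d0 = 0)` the statistic reduces
#' to the ordinary pooled two-sample t-test.
#'
#' @param x a [CompartmentExperiment] with >= 2 replicates per compartment.
#' @param log2transform log2(signal + offset) first (default TRUE).
#' @param offset additive offset guarding zeros (default 1).
#' @param prior optional list with `d0` (and `s02` unless `d0` is 0)
#'   overriding the fitted prior.
#' @return data.frame with columns `probe_id`, `t`, `p`, `q`.
#' @export
moderatedT <- function(x, log2transform = TRUE, offset = 1, prior = NULL) {
  comp <- .check_both_compartments(x)
  s <- signalMatrix(x)
  y <- if (log2transform) log2(s + offset) else s
  g1 <- comp == "nuclear"
  g2 <- comp == "cytoplasmic"
  n1 <- sum(g1); n2 <- sum(g2)
  d <- n1 + n2 - 2L
  if (n1 < 2L || n2 < 2L || d < 1L)
    stop("at least two replicates per compartment are required ",
         "(zero residual degrees of freedom)")
  m1 <- rowMeans(y[, g1, drop = FALSE])
  m2 <- rowMeans(y[, g2, drop = FALSE])
  ss <- rowSums((y[, g1, drop = FALSE] - m1)^2) +
        rowSums((y[, g2, drop = FALSE] - m2)^2)
  s2 <- ss / d
  if (is.null(prior)) prior <- fitVariancePrior(s2, d)
  d0 <- prior$d0
  if (identical(d0, 0) || identical(d0, 0L)) {
    post <- s2
    dfTotal <- d
  } else if (is.infinite(d0)) {
    post <- rep(prior$s02, length(s2))
    dfTotal <- Inf
  } else {
    post <- (d0 * prior$s02 + d * s2) / (d0 + d)
    dfTotal <- d0 + d
  }
  se <- sqrt(post * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- 2 * pt(-abs(t), df = dfTotal)
  data.frame(probe_id = rownames(s), t = t, p = p,
             q = p.adjust(p, method = "BH"), row.names = NULL)
}

#' Combined per-probe enrichment table
#'
#' Applies the low-signal filter and all three calling methods and returns
#' one row per retained probe with the columns written by the `enrich`
#' pipeline stage: `probe_id`, `mean_nuclear`, `mean_cytoplasmic`,
#' `nuclear_pct`, `method2_call`, `method1_t`, `method1_p`, `method1_q`,
#' `method3_call`.
#'
#' @param x a [CompartmentExperiment].
#' @param config an [analysisConfig()] list.
#' @return data.frame, one row per probe retained by the signal floor.
#' @export
enrichmentTable <- function(x, config = analysisConfig()) {
  xf <- filterLowSignal(x, config$signal_floor)
  if (nrow(xf) == 0L)
    return(data.frame(probe_id = character(), mean_nuclear = numeric(),
                      mean_cytoplasmic = numeric(), nuclear_pct = numeric(),
                      method2_call = logical(), method1_t = numeric(),
                      method1_p = numeric(), method1_q = numeric(),
                      method3_call = logical()))
  means <- compartmentMeans(xf)
  pct <- nuclearPercentage(xf)
  m2 <- callRankSeparation(rankScores(xf), compartments(xf))
  m1 <- moderatedT(quantileNormalize(xf))
  data.frame(probe_id = rownames(xf),
             mean_nuclear = means[, "mean_nuclear"],
             mean_cytoplasmic = means[, "mean_cytoplasmic"],
             nuclear_pct = pct,
             method2_call = m2,
             method1_t = m1$t, method1_p = m1$p, method1_q = m1$q,
             method3_call = callNuclearPercentage(
               pct, config$nuclear_pct_threshold),
             row.names = NULL)
}
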