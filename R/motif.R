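# k-mer motif discovery among nucleus-enriched mature miRNAs, exact
# motif-by-enrichment association testing, and GA-box (MAZ consensus,
# GnAGn) element scanning.

.as_seq_chars <- function(seqs) {
  if (is(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else {
    out <- setNames(toupper(as.character(seqs)), names(seqs))
  }
  if (is.null(names(out)) && length(out))
    names(out) <- paste0("seq", seq_along(out))
  out
}

#' Per-sequence k-mer support counts
#'
#' Counts, for every k-mer occurring at least once, the number of sequences
#' that contain it (presence, not occurrences: multiple copies in one
#' sequence count once).  Sequences shorter than `k` contribute nothing.
#' The counts are invariant to sequence order.
#'
#' @param seqs character vector or [Biostrings::XStringSet] of RNA/DNA
#'   sequences.
#' @param k k-mer length in nucleotides (>= 1).
#' @return named integer vector of support counts, sorted by decreasing
#'   support then lexicographically.
#' @export
kmerSupport <- function(seqs, k) {
  stopifnot(k >= 1)
  seqs <- .as_seq_chars(seqs)
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  tab <- table(unlist(per_seq, use.names = FALSE))
  if (!length(tab)) return(setNames(integer(), character()))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Find recurrent k-mer motifs in an enriched sequence set
#'
#' Enumerates all k-mers and keeps those supported by at least
#' `ceiling(minSupportFrac * n)` of the `n` sequences, sorted by support
#' (descending) then lexicographically.  The divergent members (sequences
#' lacking the top motif) can be listed with [divergentMembers()].
#'
#' @param seqs enriched mature sequences (character or
#'   [Biostrings::XStringSet]).
#' @param k motif length (default 4).
#' @param minSupportFrac minimum supporting fraction in (0, 1]
#'   (default 0.75).
#' @return data.frame with columns `motif`, `support`, `n`; zero rows when
#'   the input is empty or no k-mer reaches the support threshold.
#' @export
findRecurrentMotif <- function(seqs, k = 4, minSupportFrac = 0.75) {
  stopifnot(minSupportFrac > 0, minSupportFrac <= 1)
  seqs <- .as_seq_chars(seqs)
  n <- length(seqs)
  supp <- kmerSupport(seqs, k)
  keep <- supp >= ceiling(minSupportFrac * n)
  data.frame(motif = names(supp)[keep], support = unname(supp[keep]),
             n = rep(n, sum(keep)))
}

#' Sequences lacking a motif
#'
#' @param seqs sequences (character or [Biostrings::XStringSet]).
#' @param motif exact motif string.
#' @return character vector of the names of sequences that do not contain
#'   the motif.
#' @export
divergentMembers <- function(seqs, motif) {
  seqs <- .as_seq_chars(seqs)
  names(seqs)[!grepl(motif, seqs, fixed = TRUE)]
}

#' Motif-by-enrichment contingency table
#'
#' Counts motif presence (exact substring) in an enriched and a background
#' group of sequences.  The groups must be disjoint by name.
#'
#' @param enriched,background sequence sets (character or
#'   [Biostrings::XStringSet]); names must not overlap.
#' @param motif exact motif string.
#' @return A [MotifContingency].
#' @export
motifContingency <- function(enriched, background, motif) {
  enriched <- .as_seq_chars(enriched)
  background <- .as_seq_chars(background)
  shared <- intersect(names(enriched), names(background))
  if (length(shared))
    stop("groups overlap by name: ", paste(head(shared, 5L), collapse = ", "))
  inE <- grepl(motif, enriched, fixed = TRUE)
  inB <- grepl(motif, background, fixed = TRUE)
  MotifContingency(sum(inE), sum(!inE), sum(inB), sum(!inB), motif = motif)
}

.logsumexp <- function(lx) {
  if (!length(lx)) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Fisher's exact test for a 2x2 table, computed in log space
#'
#' Exact hypergeometric tail probability with all margins fixed.  The
#' one-sided (`"greater"`) p-value sums the point probabilities of all
#' tables at least as extreme in the enrichment direction (top-left cell at
#' least as large); the two-sided p-value sums all tables whose point
#' probability does not exceed the observed one (up to a 1e-7 relative
#' tolerance).  Point probabilities are accumulated in log space for
#' numerical stability.
#'
#' @param x a [MotifContingency] or a 2x2 numeric matrix with non-negative
#'   integer cells (rows: groups; columns: motif present/absent).
#' @param alternative `"greater"` (default, enrichment direction) or
#'   `"two.sided"`.
#' @return the exact p-value, a number in (0, 1].
#' @examples
#' fisherExact(MotifContingency(12, 1, 0, 30))  # 8.48e-10
#' @export
fisherExact <- function(x, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  m <- if (is(x, "MotifContingency")) as.matrix(x) else as.matrix(x)
  if (!identical(dim(m), c(2L, 2L))) stop("a 2x2 table is required")
  if (any(m < 0)) stop("cells must be non-negative")
  if (any(m != round(m))) stop("cells must be integers")
  a <- m[1L, 1L]; b <- m[1L, 2L]; cc <- m[2L, 1L]; d <- m[2L, 2L]
  r1 <- a + b; r2 <- cc + d; K <- a + cc; N <- r1 + r2
  if (K == 0 || K == N || r1 == 0 || r2 == 0) return(1)
  av <- max(0, K - r2):min(K, r1)          # support of the top-left cell
  lp <- lchoose(r1, av) + lchoose(r2, K - av) - lchoose(N, K)
  if (alternative == "greater") {
    ls <- .logsumexp(lp[av >= a])
  } else {
    lobs <- lp[av == a]
    ls <- .logsumexp(lp[lp <= lobs + log1p(1e-7)])
  }
  min(1, exp(ls))
}

#' Scan a sequence for MAZ GA-box consensus elements (GnAGn)
#'
#' Reports every occurrence of the GA-box consensus `G^n A G^n` with arm
#' length `n` in `[nMin, nMax]`.  Per A-center, only the maximal applicable
#' arm is reported (maximal munch; a `G3AG3` is not additionally reported as
#' the nested `G2AG2`), unless `nested = TRUE`.  Overlapping centers are all
#' reported.  `U` and `T` are treated identically (the element consists of
#' G and A only).  Coordinates are 0-based.
#'
#' @param seqs sequences (character vector or [Biostrings::XStringSet]).
#' @param nMin,nMax arm-length range (defaults 2 and 6).
#' @param nested also report all nested shorter arms per center
#'   (default FALSE).
#' @return data.frame with columns `name`, `start` (0-based offset), `n`
#'   (arm length) and `matched` (the matched substring, of length 2n+1).
#' @examples
#' mazScan("GGGAGGG")  # one hit, n = 3, start = 0
#' @export
mazScan <- function(seqs, nMin = 2, nMax = 6, nested = FALSE) {
  stopifnot(nMin >= 1, nMin <= nMax)
  seqs <- .as_seq_chars(seqs)
  res <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    ch <- strsplit(s, "")[[1L]]
    L <- length(ch)
    if (L < 2 * nMin + 1)
      return(NULL)
    isG <- ch == "G"
    gl <- integer(L)   # length of G-run ending at i
    for (i in seq_len(L)) gl[i] <- if (isG[i]) (if (i > 1L) gl[i - 1L] else 0L) + 1L else 0L
    gr <- integer(L)   # length of G-run starting at i
    for (i in rev(seq_len(L))) gr[i] <- if (isG[i]) (if (i < L) gr[i + 1L] else 0L) + 1L else 0L
    centers <- which(ch == "A")
    rows <- lapply(centers, function(i) {
      left <- if (i > 1L) gl[i - 1L] else 0L
      right <- if (i < L) gr[i + 1L] else 0L
      nn <- min(left, right, nMax)
      if (nn < nMin) return(NULL)
      ns <- if (nested) seq.int(nMin, nn) else nn
      data.frame(name = nm, start = i - 1L - ns, n = as.integer(ns),
                 matched = substring(s, i - ns, i + ns))
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(name = character(), start = integer(), n = integer(),
                      matched = character())
  rownames(out) <- NULL
  out
}

#' Scan sequences for an exact element
#'
#' Plain substring scan (e.g. for the hexanucleotide nuclear-import element
#' of the miR-29b type, "AGUGUU").  `U` and `T` are interchangeable.
#'
#' @param seqs sequences (character vector or [Biostrings::XStringSet]).
#' @param element exact element string.
#' @return data.frame with columns `name` and `start` (0-based offset), one
#'   row per occurrence.
#' @export
scanElement <- function(seqs, element) {
  seqs <- .as_seq_chars(seqs)
  norm <- function(s) chartr("T", "U", toupper(s))
  element <- norm(element)
  w <- nchar(element)
  res <- lapply(names(seqs), function(nm) {
    s <- norm(seqs[[nm]])
    n <- nchar(s)
    if (n < w) return(NULL)
    # windowed comparison so that overlapping occurrences are all reported
    starts <- which(substring(s, seq_len(n - w + 1L),
                              seq_len(n - w + 1L) + w - 1L) == element) - 1L
    if (!length(starts)) return(NULL)
    data.frame(name = nm, start = as.integer(starts))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(name = character(), start = integer())
  rownames(out) <- NULL
  out
}
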