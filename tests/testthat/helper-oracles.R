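# Independent brute-force oracles used to verify the package's scanners and
# exact test.  These are deliberately naive reimplementations (plain loops,
# full enumeration) that share no code with the implementations they check.

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

rc_rna_oracle <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# one-sided / two-sided Fisher p by full enumeration over the table support
# using the hypergeometric point mass from stats::dhyper
oracle_fisher <- function(m, alternative = "greater") {
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  K <- a + cc; r1 <- a + b; r2 <- cc + d
  if (K == 0 || K == r1 + r2 || r1 == 0 || r2 == 0) return(1)
  av <- max(0, K - r2):min(K, r1)
  probs <- dhyper(av, r1, r2, K)
  if (alternative == "greater") sum(probs[av >= a])
  else sum(probs[probs <= probs[av == a] * (1 + 1e-7)])
}

# GA-box scan by sliding a window of every width over the sequence, keeping
# the maximal arm per A-center
oracle_maz <- function(s, nMin = 2, nMax = 6) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  hits <- NULL
  for (i in seq_len(L)) {
    if (ch[i] != "A") next
    best <- 0
    for (n in nMin:nMax) {
      lo <- i - n; hi <- i + n
      if (lo < 1 || hi > L) next
      win <- ch[lo:hi]
      ok <- all(win[seq_len(n)] == "G") && all(win[n + 1 + seq_len(n)] == "G")
      if (ok) best <- n
    }
    if (best >= nMin)
      hits <- rbind(hits, data.frame(start = i - 1 - best, n = best,
                                     matched = substr(s, i - best, i + best)))
  }
  if (is.null(hits)) data.frame(start = integer(), n = integer(),
                                matched = character())
  else hits
}

# seed-site scan by testing every UTR offset for the 6mer core and then
# classifying from the flanking bases
oracle_seed_sites <- function(utr, mature) {
  core <- rc_rna_oracle(substr(mature, 2, 7))
  m8 <- rc_rna_oracle(substr(mature, 8, 8))
  L <- nchar(utr)
  out <- NULL
  for (s1 in seq_len(L - 5)) {
    if (substr(utr, s1, s1 + 5) != core) next
    hasM8 <- s1 > 1 && substr(utr, s1 - 1, s1 - 1) == m8
    hasA1 <- s1 + 6 <= L && substr(utr, s1 + 6, s1 + 6) == "A"
    type <- if (hasM8 && hasA1) "8mer" else if (hasM8) "7mer-m8"
            else if (hasA1) "7mer-A1" else "6mer"
    start <- if (hasM8) s1 - 2 else s1 - 1
    out <- rbind(out, data.frame(site_type = type, start = start))
  }
  if (is.null(out)) data.frame(site_type = character(), start = integer())
  else out
}

# quantile normalization reference: replace each column by the mean of the
# sorted columns, mapped back through the column's order (tie-free inputs)
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# rank scores by explicit descending sort
oracle_rank_scores <- function(v) {
  ord <- order(v, decreasing = TRUE)
  pos <- integer(length(v))
  pos[ord] <- seq_along(v)
  (length(v) + 1) / 2 - pos
}

# k-mer presence counts by direct substring search
oracle_kmer_support <- function(seqs, k) {
  all_kmers <- unique(unlist(lapply(seqs, function(s) {
    if (nchar(s) < k) return(character())
    vapply(seq_len(nchar(s) - k + 1),
           function(i) substr(s, i, i + k - 1), character(1))
  })))
  counts <- vapply(all_kmers, function(km)
    sum(vapply(seqs, function(s) grepl(km, s, fixed = TRUE), logical(1))),
    integer(1))
  sort(counts, decreasing = TRUE)
}

make_ce <- function(signal, reps = ncol(signal) / 2) {
  if (is.null(rownames(signal)))
    rownames(signal) <- paste0("p", seq_len(nrow(signal)))
  CompartmentExperiment(signal,
                        compartment = rep(c("nuclear", "cytoplasmic"),
                                          each = reps),
                        replicate = rep(seq_len(reps), 2))
}
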