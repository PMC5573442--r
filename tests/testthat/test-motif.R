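test_that("k-mer support counts presence once per sequence", {
  expect_equal(kmerSupport("GAGG", 4), c(GAGG = 1L))
  expect_equal(kmerSupport("GAGGAGG", 4),
               c(AGGA = 1L, GAGG = 1L, GGAG = 1L))  # two GAGG copies, one seq
  expect_equal(unname(kmerSupport(c("AC", "A"), 2)), 1L)  # short seqs skipped
  set.seed(14)
  seqs <- vapply(1:20, function(i) random_rna(20), character(1))
  expect_equal(kmerSupport(seqs, 4),
               oracle_kmer_support(seqs, 4)[names(kmerSupport(seqs, 4))])
  # order invariance
  expect_equal(sort(kmerSupport(rev(seqs), 4)), sort(kmerSupport(seqs, 4)))
})

test_that("recurrent-motif search finds a planted motif and its divergents", {
  sim <- simulateMirnaSet(seed = 23)
  found <- findRecurrentMotif(sim$enriched, k = 4, minSupportFrac = 0.75)
  expect_equal(found$motif[1], "GAGG")
  expect_equal(found$support[1], 12L)
  expect_equal(found$n[1], 13L)
  div <- divergentMembers(sim$enriched, "GAGG")
  expect_length(div, 1L)
  expect_setequal(div, setdiff(names(sim$enriched),
                               sim$truth$carriers_enriched))
  # no universal k-mer at full support in a generic random set
  set.seed(15)
  rand <- vapply(1:10, function(i) random_rna(20), character(1))
  expect_equal(nrow(findRecurrentMotif(rand, 4, minSupportFrac = 1)), 0L)
  expect_equal(nrow(findRecurrentMotif(character(), 4)), 0L)
})

test_that("contingency tables count carriers per group and reject overlap", {
  sim <- simulateMirnaSet(seed = 23)
  ct <- motifContingency(sim$enriched, sim$background, "GAGG")
  expect_equal(as.vector(as.matrix(ct)), c(12L, 0L, 1L, 30L))
  swapped <- motifContingency(sim$background, sim$enriched, "GAGG")
  expect_equal(as.matrix(swapped), as.matrix(ct)[2:1, ], ignore_attr = TRUE)
  empty <- motifContingency(character(), character(), "GAGG")
  expect_equal(as.vector(as.matrix(empty)), rep(0L, 4))
  expect_error(motifContingency(c(x = "GAGG"), c(x = "AAAA"), "GAGG"),
               "overlap")
})

test_that("log-space Fisher test matches exact enumeration", {
  # headline table: 12/13 carriers among enriched, 0/30 in background
  p <- fisherExact(MotifContingency(12, 1, 0, 30), "greater")
  expect_equal(p, 31 / choose(43, 13), tolerance = 1e-12)
  expect_lt(p, 1e-4)
  expect_equal(fisherExact(MotifContingency(0, 5, 0, 5)), 1)
  expect_equal(fisherExact(MotifContingency(2, 1, 1, 2), "greater"),
               oracle_fisher(matrix(c(2, 1, 1, 2), 2), "greater"),
               tolerance = 1e-12)
  expect_equal(fisherExact(MotifContingency(2, 1, 1, 2), "two.sided"),
               oracle_fisher(matrix(c(2, 1, 1, 2), 2), "two.sided"),
               tolerance = 1e-12)
  expect_error(fisherExact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  # agreement with stats::fisher.test on random tables, both alternatives
  set.seed(16)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisherExact(m, "greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisherExact(m, "two.sided"),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("one-sided p never decreases when motif-negative cells grow", {
  for (add in c(1, 3, 10)) {
    p0 <- fisherExact(MotifContingency(5, 2, 1, 6), "greater")
    p1 <- fisherExact(MotifContingency(5, 2 + add, 1, 6 + add), "greater")
    expect_gte(p1, p0)
    expect_equal(p1,
                 oracle_fisher(matrix(c(5, 1, 2 + add, 6 + add), 2),
                               "greater"),
                 tolerance = 1e-12)
  }
})

test_that("GA-box scan reports maximal arms per A-center", {
  expect_equal(mazScan("GGGAGGG")[, c("start", "n", "matched")],
               data.frame(start = 0L, n = 3L, matched = "GGGAGGG"))
  expect_equal(mazScan("GGAGG")[, c("start", "n", "matched")],
               data.frame(start = 0L, n = 2L, matched = "GGAGG"))
  expect_equal(nrow(mazScan("ACGUACGUACGU")), 0L)
  # maximal munch: a G3AG3 is not additionally reported as G2AG2 ...
  hits <- mazScan("UUGGGAGGGUU")
  expect_equal(hits$n, 3L)
  # ... unless nested reporting is requested
  nested <- mazScan("UUGGGAGGGUU", nested = TRUE)
  expect_equal(sort(nested$n), 2:3)
  # arm capped at nMax even in longer runs
  capped <- mazScan(paste0(strrep("G", 8), "A", strrep("G", 8)), nMax = 6)
  expect_equal(capped$n, 6L)
  # U/T equivalence
  expect_equal(mazScan("UUGGAGGUU")$n, mazScan("TTGGAGGTT")$n)
})

test_that("every GA-box hit contains all nested shorter boxes", {
  set.seed(17)
  for (i in 1:50) {
    s <- paste(sample(c("G", "A", "C", "U"), 120, replace = TRUE,
                      prob = c(0.5, 0.25, 0.125, 0.125)), collapse = "")
    hits <- mazScan(s)
    for (r in seq_len(nrow(hits))) {
      n <- hits$n[r]
      expect_equal(nchar(hits$matched[r]), 2 * n + 1)
      for (m in 2:n)
        expect_true(grepl(paste0(strrep("G", m), "A", strrep("G", m)),
                          hits$matched[r], fixed = TRUE))
    }
  }
})

test_that("GA-box scan matches the brute-force oracle on G-rich sequences", {
  set.seed(18)
  for (i in 1:100) {
    s <- paste(sample(c("G", "A", "C", "U"), 200, replace = TRUE,
                      prob = c(0.45, 0.3, 0.125, 0.125)), collapse = "")
    got <- mazScan(s)[, c("start", "n", "matched")]
    ref <- oracle_maz(s)
    rownames(got) <- rownames(ref) <- NULL
    expect_equal(got, ref)
  }
})

test_that("element scan finds overlapping exact occurrences", {
  hits <- scanElement(c(x = "AGUGUUAGUGUU"), "AGUGUU")
  expect_equal(hits$start, c(0L, 6L))
  expect_equal(nrow(scanElement(c(x = "ACGU"), "AGUGUU")), 0L)
  # T/U interchangeable in both sequence and element
  expect_equal(scanElement(c(x = "AGTGTT"), "AGUGUU")$start, 0L)
  # overlapping occurrences are all reported
  expect_equal(scanElement(c(x = "AAAA"), "AAA")$start, c(0L, 1L))
})

test_that("the planted motif dominates and stays significant across seeds", {
  top_ok <- p_ok <- logical(200)
  for (s in 1:200) {
    sim <- simulateMirnaSet(seed = 4000 + s)
    found <- findRecurrentMotif(sim$enriched, k = 4, minSupportFrac = 0.5)
    top_ok[s] <- nrow(found) > 0 && found$motif[1] == "GAGG"
    ct <- motifContingency(sim$enriched, sim$background, "GAGG")
    p_ok[s] <- fisherExact(ct, "greater") < 1e-4
  }
  expect_gte(mean(top_ok), 0.99)
  expect_gte(mean(p_ok), 0.95)
})
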