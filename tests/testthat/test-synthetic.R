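test_that("all generators are deterministic under a fixed seed", {
  ms <- simulateMirnaSet(seed = 3)
  e1 <- simulateExpression(nProbes = 40, nEnriched = 4, seed = 9)
  e2 <- simulateExpression(nProbes = 40, nEnriched = 4, seed = 9)
  expect_identical(signalMatrix(e1$experiment), signalMatrix(e2$experiment))
  expect_identical(e1$truth, e2$truth)
  expect_identical(as.character(simulateMirnaSet(seed = 3)$enriched),
                   as.character(ms$enriched))
  expect_identical(as.character(simulatePremir(elementN = 2, seed = 4)),
                   as.character(simulatePremir(elementN = 2, seed = 4)))
  r1 <- simulateRipDataset(nGenes = 12, nAgo1 = 1, nAgo2 = 2, nShared = 3,
                           mirnas = ms$enriched, seed = 5)
  r2 <- simulateRipDataset(nGenes = 12, nAgo1 = 1, nAgo2 = 2, nShared = 3,
                           mirnas = ms$enriched, seed = 5)
  expect_identical(r1$ago1, r2$ago1)
  expect_identical(as.character(r1$utrs), as.character(r2$utrs))
  x1 <- simulateExonTable(nTranscripts = 5, nSpliced = 1, seed = 6)
  x2 <- simulateExonTable(nTranscripts = 5, nSpliced = 1, seed = 6)
  expect_identical(signalMatrix(x1$experiment), signalMatrix(x2$experiment))
})

test_that("noiseless expression recovers the planted fraction in closed form", {
  sim <- simulateExpression(nProbes = 30, nEnriched = 5,
                            enrichedNuclearFrac = 0.9, noiseCV = 0,
                            seed = 11)
  pct <- nuclearPercentage(sim$experiment)
  expect_equal(unname(pct[sim$truth$enriched_probe_ids]), rep(90, 5))
})

test_that("with no planted probes the percentage method makes no calls", {
  sim <- simulateExpression(nProbes = 200, nEnriched = 0, seed = 12)
  expect_length(sim$truth$enriched_probe_ids, 0L)
  xf <- filterLowSignal(sim$experiment)
  calls <- callNuclearPercentage(nuclearPercentage(xf), 70)
  expect_false(any(calls))
})

test_that("expression generator rejects impossible fractions", {
  expect_error(simulateExpression(nProbes = 5, nEnriched = 1,
                                  enrichedNuclearFrac = c(0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(simulateExpression(nProbes = 5, nEnriched = 6), "nEnriched")
})

test_that("miRNA set generator honours carrier prevalences", {
  all_in <- simulateMirnaSet(nEnriched = 5, nBackground = 0,
                             prevalenceEnriched = 1, seed = 21)
  expect_true(all(grepl("GAGG", as.character(all_in$enriched), fixed = TRUE)))

  none <- simulateMirnaSet(nEnriched = 0, nBackground = 25,
                           prevalenceBackground = 0, seed = 22)
  expect_false(any(grepl("GAGG", as.character(none$background),
                         fixed = TRUE)))

  def <- simulateMirnaSet(seed = 23)
  ct <- motifContingency(def$enriched, def$background, "GAGG")
  expect_equal(as.vector(as.matrix(ct)), c(12L, 0L, 1L, 30L))
  expect_error(simulateMirnaSet(motif = "GAGGAGGAGGAGGAGGAGG",
                                lengthRange = c(18, 24)), "longer")
})

test_that("miRNA truth is recomputed honestly after generation", {
  sim <- simulateMirnaSet(seed = 31)
  carriers <- names(sim$enriched)[grepl("GAGG",
                                        as.character(sim$enriched),
                                        fixed = TRUE)]
  expect_setequal(sim$truth$carriers_enriched, carriers)
})

test_that("precursor hairpins have complementary arms and planted GA-boxes", {
  hp <- simulatePremir(armLen = 30, loopLen = 10, elementN = 3, seed = 41)
  s <- as.character(hp)[[1]]
  expect_equal(nchar(s), 70L)
  arm5 <- substr(s, 1, 30)
  arm3 <- substr(s, 41, 70)
  expect_equal(arm3, rc_rna_oracle(arm5))
  hits <- mazScan(hp)
  expect_gte(max(hits$n), 3)

  free <- simulatePremir(elementN = NULL, seed = 42)
  expect_equal(nrow(mazScan(free)), 0L)
  expect_error(simulatePremir(armLen = 5, elementN = 3), "longer than")
})

test_that("RIP generator plants recoverable target structure", {
  ms <- simulateMirnaSet(nEnriched = 3, nBackground = 0, seed = 51)
  rip <- simulateRipDataset(nGenes = 20, nAgo1 = 2, nAgo2 = 3, nShared = 5,
                            mirnas = ms$enriched, seed = 52)
  # planted targets pass the count floor in their pull-down, others fail it
  expect_true(all(rowSums(rip$ago1)[c(rip$truth$targets_ago1,
                                      rip$truth$shared)] >= 10))
  others <- setdiff(rownames(rip$ago1),
                    c(rip$truth$targets_ago1, rip$truth$shared))
  expect_true(all(rowSums(rip$ago1)[others] < 10))
  # every planted target carries a seed site for some supplied miRNA
  for (g in c(rip$truth$targets_ago1, rip$truth$targets_ago2,
              rip$truth$shared)) {
    n_sites <- sum(vapply(as.character(ms$enriched), function(m)
      nrow(seedSites(as.character(rip$utrs[[g]]), m)), integer(1)))
    expect_gt(n_sites, 0)
  }
  # degenerate and invalid designs
  r0 <- simulateRipDataset(nGenes = 10, nAgo1 = 2, nAgo2 = 2, nShared = 0,
                           mirnas = ms$enriched, seed = 53)
  expect_length(r0$truth$shared, 0L)
  expect_error(simulateRipDataset(nGenes = 5, nAgo1 = 3, nAgo2 = 3,
                                  nShared = 0, mirnas = ms$enriched),
               "exceed")
})

test_that("noiseless exon tables give exact closed-form splicing indices", {
  sim <- simulateExonTable(nTranscripts = 6, nSpliced = 3, siMagnitude = 4,
                           noiseCV = 0, seed = 61)
  si <- splicingIndex(sim$experiment)
  planted <- merge(sim$truth$spliced, si)
  expect_equal(planted$si, rep(2, 3))
  # non-planted exons of unspliced transcripts track their gene exactly
  un <- si[!si$transcript_id %in% sim$truth$spliced$transcript_id, ]
  expect_equal(un$si, rep(0, nrow(un)))
})
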