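# Synthetic-data generators with recorded ground truth.  Each generator
# emulates the statistical structure one pipeline stage assumes, so that
# every stage is testable offline; `truth` components are recomputed by
# scanning after generation ("honest truth"), so chance motif or site
# occurrences are included.

.MAX_REJECT <- 10000L

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)   # unit mean
}

.runif_range <- function(n, range) {
  range <- rep(range, length.out = 2L)
  if (any(range < 0) || any(range > 1))
    stop("fractions must lie in [0, 1]")
  if (range[1L] > range[2L]) stop("invalid fraction range")
  if (range[1L] == range[2L]) rep(range[1L], n)
  else runif(n, range[1L], range[2L])
}

.random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len[(i - 1L) %% length(len) + 1L],
                 replace = TRUE), collapse = ""),
    character(1L))
}

#' Simulate a compartment-fractionated expression matrix
#'
#' Emulates triplicate nuclear/cytoplasmic microarray signals for `nProbes`
#' probes of which `nEnriched` are planted as nucleus-enriched.  Each probe
#' draws a total abundance from a log-normal (meanlog 7, sdlog 1.5 in
#' natural-log raw units, so a realistic minority of probes falls below the
#' signal floor of 30); enriched probes split it so the nuclear fraction
#' lies in `enrichedNuclearFrac`, background probes use a fraction from
#' `backgroundNuclearFrac`; each replicate signal gets multiplicative
#' log-normal noise with coefficient of variation `noiseCV`.  Because an
#' enriched set is by construction detected on the array, planted probes are
#' redrawn (rejection, capped) until their expected nuclear replicate signal
#' reaches `detectFloor`.
#'
#' @param nProbes number of probes (default 847).
#' @param nEnriched number of planted nucleus-enriched probes (default 13;
#'   must not exceed `nProbes`).
#' @param reps replicates per compartment (default 3).
#' @param enrichedNuclearFrac nuclear-fraction interval for planted probes
#'   (default `c(0.75, 0.95)`; a single value gives that exact fraction).
#' @param backgroundNuclearFrac nuclear-fraction interval for background
#'   probes (default `c(0.2, 0.6)`).
#' @param noiseCV per-replicate multiplicative noise CV (default 0.1; 0
#'   gives noiseless closed-form signals).
#' @param detectFloor detection floor for planted probes, raw units
#'   (default 30).
#' @param meanlog,sdlog parameters of the total-abundance log-normal.
#' @param seed integer seed (optional).
#' @return list with elements `experiment` (a [CompartmentExperiment]) and
#'   `truth` (list with `enriched_probe_ids`, `nuclear_frac`, `seed`).
#' @export
simulateExpression <- function(nProbes = 847, nEnriched = 13, reps = 3,
                               enrichedNuclearFrac = c(0.75, 0.95),
                               backgroundNuclearFrac = c(0.2, 0.6),
                               noiseCV = 0.1, detectFloor = 30,
                               meanlog = 7, sdlog = 1.5, seed = NULL) {
  stopifnot(nEnriched <= nProbes, noiseCV >= 0, reps >= 1)
  .with_seed(seed, {
    probes <- sprintf("probe%04d", seq_len(nProbes))
    enriched <- if (nEnriched > 0) sample(probes, nEnriched) else character()
    isE <- probes %in% enriched
    total <- rlnorm(nProbes, meanlog, sdlog)
    frac <- numeric(nProbes)
    frac[!isE] <- .runif_range(sum(!isE), backgroundNuclearFrac)
    frac[isE] <- .runif_range(sum(isE), enrichedNuclearFrac)
    # planted probes must be detectable: expected nuclear signal >= floor
    for (i in which(isE)) {
      tries <- 0L
      while (total[i] * frac[i] < detectFloor) {
        tries <- tries + 1L
        if (tries > .MAX_REJECT)
          stop("could not draw a detectable planted probe")
        total[i] <- rlnorm(1L, meanlog, sdlog)
      }
    }
    nuc <- total * frac
    cyt <- total * (1 - frac)
    nSamp <- 2L * reps
    signal <- matrix(0, nProbes, nSamp)
    compartment <- rep(.COMPARTMENTS, each = reps)
    replicate <- rep(seq_len(reps), times = 2L)
    for (j in seq_len(nSamp)) {
      base <- if (compartment[j] == "nuclear") nuc else cyt
      signal[, j] <- base * .lognoise(nProbes, noiseCV)
    }
    rownames(signal) <- probes
    colnames(signal) <- paste0(ifelse(compartment == "nuclear", "N", "C"),
                               replicate)
    ce <- CompartmentExperiment(signal, compartment, replicate)
    list(experiment = ce,
         truth = list(enriched_probe_ids = sort(enriched),
                      nuclear_frac = setNames(frac, probes),
                      seed = seed))
  })
}

.insert_motif <- function(seq, motif) {
  L <- nchar(seq)
  k <- nchar(motif)
  pos <- sample.int(L - k + 1L, 1L)
  paste0(substr(seq, 1L, pos - 1L), motif, substr(seq, pos + k, L))
}

.rna_without <- function(len, motif) {
  for (i in seq_len(.MAX_REJECT)) {
    s <- .random_rna(1L, len)
    if (!grepl(motif, s, fixed = TRUE)) return(s)
  }
  stop("rejection sampling failed after ", .MAX_REJECT, " attempts")
}

#' Simulate mature miRNA sequence sets with a planted motif
#'
#' Generates an enriched and a background set of random mature sequences
#' (uniform base composition, lengths uniform in `lengthRange`).  In each
#' group, a designated fraction of sequences (rounded count) carries the
#' motif inserted at a random position; the remaining sequences are
#' rejection-sampled to be motif-free.  The default design mirrors a
#' 13-vs-30 comparison in which 12 of 13 enriched sequences carry the motif
#' and none of the 30 background sequences do; the genome-wide motif
#' prevalence among human miRNA (about 25%) is available by setting
#' `prevalenceBackground = 0.25`.  Truth is recomputed by scanning after
#' generation, so chance second copies in carriers are counted honestly.
#'
#' @param nEnriched,nBackground group sizes (defaults 13 and 30).
#' @param motif motif to plant (default `"GAGG"`).
#' @param prevalenceEnriched,prevalenceBackground carrier fractions in
#'   [0, 1] (defaults 12/13 and 0).
#' @param lengthRange mature length range in nt (default `c(18, 24)`).
#' @param seed integer seed (optional).
#' @return list with `enriched` and `background`
#'   ([Biostrings::RNAStringSet]s) and `truth` (list with `motif`,
#'   `carriers_enriched`, `carriers_background`, `seed`).
#' @export
simulateMirnaSet <- function(nEnriched = 13, nBackground = 30,
                             motif = "GAGG", prevalenceEnriched = 12 / 13,
                             prevalenceBackground = 0,
                             lengthRange = c(18, 24), seed = NULL) {
  stopifnot(prevalenceEnriched >= 0, prevalenceEnriched <= 1,
            prevalenceBackground >= 0, prevalenceBackground <= 1)
  motif <- chartr("T", "U", toupper(motif))
  if (nchar(motif) > lengthRange[1L])
    stop("motif longer than the minimum mature length")
  .with_seed(seed, {
    gen_group <- function(n, prevalence, prefix) {
      if (n == 0L) return(RNAStringSet())
      lens <- sample(seq(lengthRange[1L], lengthRange[2L]), n, replace = TRUE)
      nCarry <- round(prevalence * n)
      carry <- seq_len(n) <= nCarry          # order randomized by naming only
      seqs <- vapply(seq_len(n), function(i) {
        if (carry[i]) .insert_motif(.random_rna(1L, lens[i]), motif)
        else .rna_without(lens[i], motif)
      }, character(1L))
      out <- RNAStringSet(seqs)
      names(out) <- sprintf("%s%02d", prefix, seq_len(n))
      out
    }
    enriched <- gen_group(nEnriched, prevalenceEnriched, "nucmir")
    background <- gen_group(nBackground, prevalenceBackground, "cytmir")
    list(enriched = enriched, background = background,
         truth = list(
           motif = motif,
           carriers_enriched = divergent_complement(enriched, motif),
           carriers_background = divergent_complement(background, motif),
           seed = seed))
  })
}

# names of sequences containing the motif (complement of divergentMembers)
divergent_complement <- function(seqs, motif) {
  setdiff(names(seqs), divergentMembers(seqs, motif))
}

#' Simulate a precursor-miRNA hairpin
#'
#' Builds a hairpin-like RNA of a random 5' arm, a random loop, and the
#' reverse complement of the arm, optionally planting a GA-box element
#' `G^n A G^n` in the 5' arm.  With `elementN = NULL` the hairpin is
#' rejection-sampled to contain no GA-box in the scanned arm range.  The
#' defaults give a 70 nt hairpin, within the 80 nt span used for synthetic
#' EMSA-style oligos.
#'
#' @param armLen arm length in nt (default 30).
#' @param loopLen loop length in nt (default 10).
#' @param elementN GA-box arm length to plant (integer in `[nMin, nMax]`),
#'   or `NULL` for a GA-box-free hairpin.
#' @param nMin,nMax GA-box range used for the element-free guarantee
#'   (defaults 2 and 6).
#' @param name sequence name (default `"premir"`).
#' @param seed integer seed (optional).
#' @return a single-element named [Biostrings::RNAStringSet].
#' @export
simulatePremir <- function(armLen = 30, loopLen = 10, elementN = NULL,
                           nMin = 2, nMax = 6, name = "premir",
                           seed = NULL) {
  if (!is.null(elementN) && 2 * elementN + 1 > armLen)
    stop("GA-box element longer than the arm")
  .with_seed(seed, {
    for (i in seq_len(.MAX_REJECT)) {
      arm <- .random_rna(1L, armLen)
      if (!is.null(elementN)) {
        el <- paste0(strrep("G", elementN), "A", strrep("G", elementN))
        arm <- .insert_motif(arm, el)
      }
      loop <- .random_rna(1L, loopLen)
      hairpin <- paste0(arm, loop, .rc_rna(arm))
      hits <- mazScan(hairpin, nMin, nMax)
      ok <- if (is.null(elementN)) nrow(hits) == 0L else nrow(hits) > 0L
      if (ok) {
        out <- RNAStringSet(hairpin)
        names(out) <- name
        return(out)
      }
    }
    stop("rejection sampling failed after ", .MAX_REJECT, " attempts")
  })
}

#' Simulate an Ago1/Ago2 RIP-seq dataset with planted targets
#'
#' Generates two gene x sample read-count tables (one per pull-down), a set
#' of synthetic 3'UTRs, and the planted target structure: `nAgo1` genes
#' unique to the Ago1 pull-down, `nAgo2` unique to Ago2, and `nShared`
#' present in both.  Planted targets receive negative-binomial counts
#' (mean 50, dispersion 0.3, redrawn until the pull-down total reaches
#' `countFloor`) in the corresponding pull-down(s) and carry a perfect 8mer
#' seed site for one designated nucleus-enriched miRNA in their UTR;
#' non-targets receive low counts (total below `countFloor`; mean 2) and a
#' UTR rejection-sampled to be free of seed sites for all supplied miRNAs.
#'
#' @param nGenes total number of genes (default 60).
#' @param nAgo1,nAgo2,nShared planted target-set sizes (defaults 10, 15,
#'   20; their sum must not exceed `nGenes`).
#' @param utrLen UTR length in nt (default 300).
#' @param mirnas named mature sequences of the nucleus-enriched miRNAs
#'   whose sites are planted (character or [Biostrings::RNAStringSet]).
#' @param reps samples per pull-down (default 2).
#' @param countFloor the read-count floor the analysis will apply
#'   (default 10).
#' @param meanTarget,meanBackground negative-binomial means (defaults 50
#'   and 2).
#' @param dispersion negative-binomial dispersion (default 0.3).
#' @param seed integer seed (optional).
#' @return list with `ago1`, `ago2` (integer count matrices), `utrs`
#'   ([Biostrings::RNAStringSet]) and `truth` (list with `targets_ago1`,
#'   `targets_ago2`, `shared`, `target_map`, `seed`).
#' @export
simulateRipDataset <- function(nGenes = 60, nAgo1 = 10, nAgo2 = 15,
                               nShared = 20, utrLen = 300, mirnas,
                               reps = 2, countFloor = 10, meanTarget = 50,
                               meanBackground = 2, dispersion = 0.3,
                               seed = NULL) {
  if (nAgo1 + nAgo2 + nShared > nGenes)
    stop("planted sets exceed the number of genes")
  mirnas <- .as_seq_chars(mirnas)
  if (!length(mirnas)) stop("at least one enriched miRNA is required")
  .with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(nGenes))
    idx <- sample(genes, nAgo1 + nAgo2 + nShared)
    only1 <- idx[seq_len(nAgo1)]
    only2 <- idx[nAgo1 + seq_len(nAgo2)]
    both <- idx[nAgo1 + nAgo2 + seq_len(nShared)]
    targets <- c(only1, only2, both)
    size <- 1 / dispersion

    draw_high <- function() {
      for (i in seq_len(.MAX_REJECT)) {
        cts <- rnbinom(reps, mu = meanTarget, size = size)
        if (sum(cts) >= countFloor) return(cts)
      }
      stop("rejection sampling failed for target counts")
    }
    draw_low <- function() {
      for (i in seq_len(.MAX_REJECT)) {
        cts <- rnbinom(reps, mu = meanBackground, size = size)
        if (sum(cts) < countFloor) return(cts)
      }
      stop("rejection sampling failed for background counts")
    }
    mk_counts <- function(high) {
      m <- matrix(0L, nGenes, reps, dimnames = list(genes, NULL))
      for (g in genes)
        m[g, ] <- as.integer(if (g %in% high) draw_high() else draw_low())
      m
    }
    ago1 <- mk_counts(c(only1, both))
    ago2 <- mk_counts(c(only2, both))
    colnames(ago1) <- paste0("ago1_r", seq_len(reps))
    colnames(ago2) <- paste0("ago2_r", seq_len(reps))

    # UTRs: targets carry a perfect 8mer site for one designated miRNA;
    # non-targets are free of any seed-core match for every supplied miRNA
    cores <- vapply(mirnas, function(m) .rc_rna(substr(m, 2L, 7L)),
                    character(1L))
    utr_free <- function() {
      for (i in seq_len(.MAX_REJECT)) {
        u <- .random_rna(1L, utrLen)
        if (!any(vapply(cores, grepl, logical(1L), x = u, fixed = TRUE)))
          return(u)
      }
      stop("rejection sampling failed for site-free UTRs")
    }
    designated <- setNames(sample(names(mirnas), length(targets),
                                  replace = TRUE), targets)
    utrs <- vapply(genes, function(g) {
      u <- utr_free()
      if (g %in% targets) {
        m <- mirnas[[designated[[g]]]]
        site <- paste0(.rc_rna(substr(m, 2L, 8L)), "A")   # perfect 8mer
        u <- .insert_motif(u, site)
      }
      u
    }, character(1L))
    utrSet <- RNAStringSet(utrs)
    names(utrSet) <- genes

    # honest truth: recompute the gene -> miRNA map by scanning
    target_map <- targetsOfEnriched(
      matrix(1L, length(genes), 1L, dimnames = list(genes, "x")),
      mirnas, utrSet)
    list(ago1 = ago1, ago2 = ago2, utrs = utrSet,
         truth = list(targets_ago1 = sort(only1), targets_ago2 = sort(only2),
                      shared = sort(both), target_map = target_map,
                      seed = seed))
  })
}

#' Simulate an exon-level signal table with planted differential splicing
#'
#' Generates an exon x sample table for `nTranscripts` transcripts of
#' `exonsPerTranscript` exons each, in `reps` replicates per compartment.
#' Cytoplasmic exon signals are log-normal baselines; for `nSpliced`
#' transcripts one exon is planted so that its measured splicing index (on
#' gene-normalized, replicate-averaged signal, gene = mean of exons) equals
#' exactly `log2(siMagnitude)` in the noiseless limit, solving
#' `x = m b S_-k / (S - m b)` for the nuclear exon value so that the
#' gene-mean renormalization is accounted for.  Multiplicative log-normal
#' noise with CV `noiseCV` is applied per cell.
#'
#' @param nTranscripts number of transcripts (default 40).
#' @param exonsPerTranscript exons per transcript (default 6).
#' @param nSpliced number of transcripts with one planted differential exon
#'   (default 6).
#' @param siMagnitude planted linear fold of the gene-normalized exon ratio
#'   (default 4, i.e. splicing index 2 on the log2 scale).
#' @param reps replicates per compartment (default 3).
#' @param noiseCV per-cell multiplicative noise CV (default 0.1).
#' @param meanlog,sdlog baseline exon-signal log-normal parameters.
#' @param seed integer seed (optional).
#' @return list with `experiment` (an [ExonExperiment]) and `truth` (list
#'   with `spliced` data.frame of planted (transcript_id, exon_id) pairs
#'   and `seed`).
#' @export
simulateExonTable <- function(nTranscripts = 40, exonsPerTranscript = 6,
                              nSpliced = 6, siMagnitude = 4, reps = 3,
                              noiseCV = 0.1, meanlog = 6, sdlog = 0.5,
                              seed = NULL) {
  stopifnot(nSpliced <= nTranscripts, exonsPerTranscript >= 2, noiseCV >= 0)
  .with_seed(seed, {
    txs <- sprintf("tx%03d", seq_len(nTranscripts))
    spliced_tx <- if (nSpliced > 0) sample(txs, nSpliced) else character()
    J <- exonsPerTranscript
    exon_id <- rep(sprintf("e%02d", seq_len(J)), nTranscripts)
    transcript_id <- rep(txs, each = J)
    nuc <- cyt <- numeric(nTranscripts * J)
    planted <- data.frame(transcript_id = character(), exon_id = character())
    for (t in seq_len(nTranscripts)) {
      rows <- (t - 1L) * J + seq_len(J)
      for (i in seq_len(.MAX_REJECT)) {
        b <- rlnorm(J, meanlog, sdlog)
        k <- sample.int(J, 1L)
        S <- sum(b)
        if (!txs[t] %in% spliced_tx || S - siMagnitude * b[k] > 0) break
        if (i == .MAX_REJECT) stop("could not place the planted exon")
      }
      cyt[rows] <- b
      nb <- b
      if (txs[t] %in% spliced_tx) {
        nb[k] <- siMagnitude * b[k] * (S - b[k]) / (S - siMagnitude * b[k])
        planted <- rbind(planted,
                         data.frame(transcript_id = txs[t],
                                    exon_id = sprintf("e%02d", k)))
      }
      nuc[rows] <- nb
    }
    nSamp <- 2L * reps
    compartment <- rep(.COMPARTMENTS, each = reps)
    replicate <- rep(seq_len(reps), times = 2L)
    signal <- matrix(0, nTranscripts * J, nSamp)
    for (j in seq_len(nSamp)) {
      base <- if (compartment[j] == "nuclear") nuc else cyt
      signal[, j] <- base * .lognoise(length(base), noiseCV)
    }
    colnames(signal) <- paste0(ifelse(compartment == "nuclear", "N", "C"),
                               replicate)
    ee <- ExonExperiment(signal, transcript_id, exon_id,
                         compartment, replicate)
    list(experiment = ee,
         truth = list(spliced = planted, seed = seed))
  })
}
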