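# Downstream RIP-seq computation: read-count filtering, canonical seed-site
# scanning of 3'UTRs for nucleus-enriched miRNAs, and Ago1/Ago2 target-set
# partitioning.

.SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

.check_rna <- function(s, what) {
  ch <- unique(strsplit(s, "")[[1L]])
  bad <- setdiff(ch, c("A", "C", "G", "U"))
  if (length(bad))
    stop("non-RNA character(s) in ", what, ": ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

.rc_rna <- function(s) {
  as.character(reverseComplement(RNAStringSet(s))[[1L]])
}

#' Remove genes with low total read count
#'
#' Retains genes whose total count across the table's samples is at least
#' `floor` (the floor applies to the per-pulldown total, not per sample).
#' Idempotent, and monotone in `floor` (a larger floor retains a subset).
#'
#' @param counts integer gene x sample count matrix (gene rownames), or a
#'   `SummarizedExperiment` whose first assay is one.
#' @param floor read-count floor (default 10); genes with total below it are
#'   dropped.
#' @return the filtered object, same type as the input.
#' @export
filterCounts <- function(counts, floor = 10) {
  stopifnot(floor >= 0)
  m <- if (is(counts, "SummarizedExperiment")) assay(counts) else counts
  keep <- rowSums(m) >= floor
  counts[keep, , drop = FALSE]
}

#' Scan a 3'UTR for canonical miRNA seed sites
#'
#' Finds matches of the reverse complement of miRNA positions 2-7 (the 6mer
#' core) in the UTR and classifies each locus by the two canonical
#' extensions: a match to position 8 (the UTR base immediately 5' of the
#' core pairing miRNA position 8) and an adenosine opposite position 1 (the
#' UTR base immediately 3' of the core being `A`).  Both present: `8mer`;
#' position-8 match only: `7mer-m8`; A only: `7mer-A1`; neither: `6mer`.
#' Only the single strongest class per locus is reported.  Wobble (G:U)
#' pairing in the seed is not considered.  Coordinates are 0-based offsets
#' of the reported span (span length 8, 7, 7 and 6 respectively).
#'
#' @param utr RNA string (character or [Biostrings::RNAString]-compatible).
#' @param mature mature miRNA RNA string, length >= 8.
#' @return data.frame with columns `site_type` (one of `8mer`, `7mer-m8`,
#'   `7mer-A1`, `6mer`), `start` (0-based) and `width`.
#' @examples
#' # plant a perfect 8mer for a miRNA in a UTR:
#' mir <- "UGAGGUAGUAGGUUGUAUAGUU"          # let-7a
#' site <- "CUACCUCA"                       # rc(positions 2-8) + A
#' seedSites(paste0("AAAA", site, "AAAA"), mir)
#' @export
seedSites <- function(utr, mature) {
  utr <- toupper(as.character(utr))
  mature <- toupper(as.character(mature))
  .check_rna(utr, "UTR")
  .check_rna(mature, "mature miRNA")
  if (nchar(mature) < 8L) stop("mature miRNA must be at least 8 nt")
  core <- .rc_rna(substr(mature, 2L, 7L))             # rc of positions 2-7
  m8 <- .rc_rna(substr(mature, 8L, 8L))               # UTR base pairing m8
  hits <- matchPattern(core, Biostrings::RNAString(utr))
  starts1 <- BiocGenerics::start(hits)                # 1-based core starts
  if (!length(starts1))
    return(data.frame(site_type = character(), start = integer(),
                      width = integer()))
  L <- nchar(utr)
  rows <- lapply(starts1, function(s1) {
    hasM8 <- s1 > 1L && substr(utr, s1 - 1L, s1 - 1L) == m8
    hasA1 <- s1 + 6L <= L && substr(utr, s1 + 6L, s1 + 6L) == "A"
    if (hasM8 && hasA1)
      data.frame(site_type = "8mer", start = s1 - 2L, width = 8L)
    else if (hasM8)
      data.frame(site_type = "7mer-m8", start = s1 - 2L, width = 7L)
    else if (hasA1)
      data.frame(site_type = "7mer-A1", start = s1 - 1L, width = 7L)
    else
      data.frame(site_type = "6mer", start = s1 - 1L, width = 6L)
  })
  out <- do.call(rbind, rows)
  out$site_type <- factor(out$site_type, levels = .SITE_TYPES)
  out[order(out$start), , drop = FALSE]
}

#' Map filtered RIP genes to the nucleus-enriched miRNAs that target them
#'
#' For every gene in an (already count-filtered) RIP table, scans its 3'UTR
#' for seed sites of each nucleus-enriched miRNA; a gene is retained when at
#' least one site for at least one enriched miRNA is found.  Genes without a
#' UTR sequence are skipped with a single warning reporting the number of
#' skips.
#'
#' @param counts filtered count matrix (gene rownames) or
#'   `SummarizedExperiment`; see [filterCounts()].
#' @param mirnas named mature sequences of the nucleus-enriched miRNAs
#'   (character vector or [Biostrings::RNAStringSet]).
#' @param utrs named 3'UTR sequences (character vector or
#'   [Biostrings::RNAStringSet]).
#' @return named list mapping each retained gene to the character vector of
#'   miRNA names with at least one seed site in its UTR.
#' @export
targetsOfEnriched <- function(counts, mirnas, utrs) {
  m <- if (is(counts, "SummarizedExperiment")) assay(counts) else counts
  genes <- rownames(m)
  mirnas <- .as_seq_chars(mirnas)
  utrs <- .as_seq_chars(utrs)
  absent <- setdiff(genes, names(utrs))
  if (length(absent)) {
    warning(length(absent), " gene(s) without a UTR sequence were skipped")
    genes <- setdiff(genes, absent)
  }
  out <- lapply(genes, function(g) {
    hit <- vapply(mirnas, function(mir) nrow(seedSites(utrs[[g]], mir)) > 0L,
                  logical(1L))
    names(mirnas)[hit]
  })
  names(out) <- genes
  out[lengths(out) > 0L]
}

#' Partition two pull-down target sets
#'
#' Splits the Ago1 and Ago2 target gene sets into genes unique to each
#' pull-down and genes detected in both.  The three sets are pairwise
#' disjoint and their union is the union of the inputs.
#'
#' @param ago1,ago2 character vectors of target gene ids.
#' @return named list with elements `unique_ago1`, `unique_ago2`, `shared`.
#' @examples
#' partitionTargets(c("a", "b"), c("b", "c"))
#' @export
partitionTargets <- function(ago1, ago2) {
  ago1 <- unique(as.character(ago1))
  ago2 <- unique(as.character(ago2))
  list(unique_ago1 = setdiff(ago1, ago2),
       unique_ago2 = setdiff(ago2, ago1),
       shared = intersect(ago1, ago2))
}
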