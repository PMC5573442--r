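# Readers/writers for the plain-text formats used throughout: expression and
# count TSVs with a sample-metadata sidecar, exon TSVs, FASTA sequence sets,
# and a flat YAML-style analysis configuration.

.CONFIG_KEYS <- c("signal_floor", "nuclear_pct_threshold", "count_floor",
                  "fdr_alpha", "si_threshold", "motif_k",
                  "maz_n_min", "maz_n_max", "rng_seed")

#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline, with the study defaults:
#' probes are dropped when their raw signal is below `signal_floor` (30 raw
#' units) in every sample; a miRNA is called nucleus-enriched when its nuclear
#' percentage exceeds `nuclear_pct_threshold` (70, strict); RIP-seq genes with
#' total read count below `count_floor` (10) are removed; the splicing screen
#' flags exons at `fdr_alpha` (0.01) with linear fold beyond `si_threshold`
#' (2); motif discovery enumerates `motif_k`-mers (4 nt); the GA-box scanner
#' considers arm lengths `maz_n_min` to `maz_n_max` (2 to 6).
#'
#' @param signal_floor low-signal floor, raw units (> 0).
#' @param nuclear_pct_threshold nuclear-percentage call threshold, percent.
#' @param count_floor RIP read-count floor, reads (> 0).
#' @param fdr_alpha FDR level for the splicing screen, in (0, 1).
#' @param si_threshold splicing-index linear fold threshold (> 0).
#' @param motif_k motif length, nucleotides (> 0).
#' @param maz_n_min,maz_n_max GA-box arm-length range (`maz_n_min` <=
#'   `maz_n_max`, both > 0).
#' @param rng_seed integer seed used by [runPipeline()] simulation stages.
#' @return A validated list of class `"AnalysisConfig"`.
#' @export
analysisConfig <- function(signal_floor = 30, nuclear_pct_threshold = 70,
                           count_floor = 10, fdr_alpha = 0.01,
                           si_threshold = 2, motif_k = 4,
                           maz_n_min = 2, maz_n_max = 6, rng_seed = 1L) {
  cfg <- list(signal_floor = signal_floor,
              nuclear_pct_threshold = nuclear_pct_threshold,
              count_floor = count_floor, fdr_alpha = fdr_alpha,
              si_threshold = si_threshold, motif_k = as.integer(motif_k),
              maz_n_min = as.integer(maz_n_min),
              maz_n_max = as.integer(maz_n_max),
              rng_seed = as.integer(rng_seed))
  num <- c("signal_floor", "nuclear_pct_threshold", "count_floor",
           "fdr_alpha", "si_threshold", "motif_k", "maz_n_min", "maz_n_max")
  for (k in num) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("config: '", k, "' must be a single positive number")
  }
  if (cfg$fdr_alpha >= 1) stop("config: 'fdr_alpha' must be in (0, 1)")
  if (cfg$nuclear_pct_threshold > 100)
    stop("config: 'nuclear_pct_threshold' must be in [0, 100]")
  if (cfg$maz_n_min > cfg$maz_n_max)
    stop("config: 'maz_n_min' must not exceed 'maz_n_max'")
  structure(cfg, class = "AnalysisConfig")
}

#' Read an analysis configuration file
#'
#' Parses a flat `key: value` text file (YAML-compatible subset).  Unknown
#' keys are an error so that mistyped threshold names are caught.
#'
#' @param path path to the configuration file.
#' @return An `"AnalysisConfig"` list (see [analysisConfig()]).
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain key: value pairs")
  unknown <- setdiff(names(vals), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysisConfig, vals)
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig:\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

.read_tsv_matrix <- function(path, what = "signal") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("expected an id column plus at least one sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated ", names(df)[1L], " id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1L]))
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop("non-numeric or negative ", what, " at row '", ids[bad[1L]],
           "', column '", colnames(m)[j], "'")
    m[, j] <- v
  }
  m
}

.read_sample_meta <- function(path, samples) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "compartment", "replicate")
  if (!all(need %in% names(meta)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing))
    stop("missing compartment annotation for sample(s): ",
         paste(missing, collapse = ", "))
  meta[match(samples, meta$sample_id), , drop = FALSE]
}

#' Read a compartment-labelled expression matrix
#'
#' Reads a tab-separated signal table (first column: probe id; header: sample
#' ids; cells: non-negative raw signals) together with a sidecar metadata TSV
#' with columns `sample_id`, `compartment` (`nuclear`/`cytoplasmic`) and
#' `replicate`.
#'
#' @param path path to the signal TSV.
#' @param metaPath path to the sample-metadata sidecar TSV; defaults to
#'   `<path>.meta.tsv`.
#' @return A [CompartmentExperiment].
#' @seealso [writeExpressionTSV()] for the inverse operation.
#' @export
readExpressionTSV <- function(path, metaPath = paste0(path, ".meta.tsv")) {
  m <- .read_tsv_matrix(path, "signal")
  if (!file.exists(metaPath))
    stop("missing compartment annotation sidecar: ", metaPath)
  meta <- .read_sample_meta(metaPath, colnames(m))
  CompartmentExperiment(m, meta$compartment, meta$replicate)
}

#' Write a compartment-labelled expression matrix
#'
#' @param x a [CompartmentExperiment].
#' @param path output signal TSV path.
#' @param metaPath output sidecar metadata path.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(x, path, metaPath = paste0(path, ".meta.tsv")) {
  .write_matrix_tsv(signalMatrix(x), "probe_id", path)
  meta <- data.frame(sample_id = colnames(x),
                     compartment = compartments(x),
                     replicate = replicates(x))
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, idCol, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exon-level signal table
#'
#' Expects columns `transcript_id`, `exon_id`, then one column per sample,
#' plus the same metadata sidecar format as [readExpressionTSV()].
#'
#' @inheritParams readExpressionTSV
#' @return An [ExonExperiment].
#' @export
readExonTSV <- function(path, metaPath = paste0(path, ".meta.tsv")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "exon_id") %in% names(df)))
    stop("exon table needs 'transcript_id' and 'exon_id' columns")
  samples <- setdiff(names(df), c("transcript_id", "exon_id"))
  m <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("exon signals must be non-negative numbers")
  if (!file.exists(metaPath))
    stop("missing compartment annotation sidecar: ", metaPath)
  meta <- .read_sample_meta(metaPath, samples)
  ExonExperiment(m, df$transcript_id, df$exon_id,
                 meta$compartment, meta$replicate)
}

#' Write an exon-level signal table
#'
#' @param x an [ExonExperiment].
#' @inheritParams writeExpressionTSV
#' @return `path`, invisibly.
#' @export
writeExonTSV <- function(x, path, metaPath = paste0(path, ".meta.tsv")) {
  df <- data.frame(transcript_id = transcriptIds(x), exon_id = exonIds(x),
                   signalMatrix(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(x),
                     compartment = compartments(x),
                     replicate = replicates(x))
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample read-count table
#'
#' @param path path to a TSV whose first column is the gene id and remaining
#'   columns are non-negative integer read counts.
#' @return An integer matrix with gene rownames.
#' @export
readCountsTSV <- function(path) {
  m <- .read_tsv_matrix(path, "count")
  if (any(m != round(m))) stop("read counts must be integers")
  storage.mode(m) <- "integer"
  m
}

#' Write a gene x sample read-count table
#'
#' @param m integer matrix with gene rownames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCountsTSV <- function(m, path) .write_matrix_tsv(m, "gene_id", path)

.IUPAC <- strsplit("ACGTURYSWKMBDHVN", "")[[1L]]

#' Read a FASTA file of miRNA or UTR sequences
#'
#' Sequences are upper-cased and normalized to the requested alphabet
#' (`T` and `U` are interchangeable on input).  Any character outside the
#' IUPAC nucleotide codes, or an empty record, is an error.
#'
#' @param path FASTA file path.
#' @param alphabet `"RNA"` (default) or `"DNA"`.
#' @return An [Biostrings::RNAStringSet] or [Biostrings::DNAStringSet].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "gatg"), f)
#' readMirnaFasta(f)            # "GAUG"
#' @export
readMirnaFasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  raw <- readBStringSet(path)
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    stop("empty record(s): ", paste(names(raw)[!nzchar(seqs)], collapse = ", "))
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% .IUPAC), TRUE)
  if (any(bad))
    stop("non-IUPAC character(s) in record(s): ",
         paste(names(raw)[bad], collapse = ", "))
  if (alphabet == "RNA") {
    out <- RNAStringSet(chartr("T", "U", seqs))
  } else {
    out <- DNAStringSet(chartr("U", "T", seqs))
  }
  names(out) <- names(raw)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::XStringSet] (or named character vector).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeMirnaFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- RNAStringSet(chartr("T", "U", toupper(seqs)))
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Reference nuclear percentages of the most nucleus-enriched miRNAs
#'
#' The bundled reference table of microarray "Nuclear % expression" values for
#' the 13 mature human miRNAs with the highest nuclear share of total
#' (nuclear + cytoplasmic) signal measured in fractionated SH-SY5Y
#' neuroblastoma cells, with their conservation status.  All 13 exceed the
#' strict 70% enrichment threshold; see [callNuclearPercentage()].
#'
#' @return data.frame with columns `mirna`, `nuclear_pct`, `conserved`.
#' @examples
#' ref <- nuclearMirnaReference()
#' sum(callNuclearPercentage(ref$nuclear_pct, threshold = 70))  # 13
#' @export
nuclearMirnaReference <- function() {
  read.delim(system.file("extdata", "nuclear_mirna_pct.tsv",
                         package = "nucmiR"),
             stringsAsFactors = FALSE)
}
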