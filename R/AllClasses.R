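#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.COMPARTMENTS <- c("nuclear", "cytoplasmic")

#' CompartmentExperiment: compartment-labelled expression signals
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container holding a
#' probe x sample matrix of non-negative raw signals (assay `"signal"`)
#' together with per-sample compartment metadata: `compartment` (one of
#' `"nuclear"` or `"cytoplasmic"`) and `replicate` (positive integer).  The
#' (compartment, replicate) pairs must be unique and probe ids (rownames)
#' must be unique.
#'
#' @param signal numeric matrix of non-negative raw signals, probes in rows
#'   (rownames are probe ids), samples in columns.
#' @param compartment character vector, one of `"nuclear"`/`"cytoplasmic"`
#'   per sample.
#' @param replicate positive integer vector, replicate index per sample.
#' @param rowData optional `DataFrame` of per-probe annotation.
#'
#' @return A `CompartmentExperiment` object.
#' @examples
#' m <- matrix(c(90, 10, 80, 20, 85, 15), nrow = 1,
#'             dimnames = list("p1", NULL))
#' ce <- CompartmentExperiment(m,
#'   compartment = rep(c("nuclear", "cytoplasmic"), 3),
#'   replicate   = rep(1:3, each = 2)[order(rep(1:3, each = 2))])
#' nuclearPercentage(ce)
#' @aliases CompartmentExperiment-class
#' @export
CompartmentExperiment <- function(signal, compartment, replicate,
                                  rowData = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(colnames(signal)))
    colnames(signal) <- paste0(substr(compartment, 1, 1), replicate)
  cd <- DataFrame(compartment = as.character(compartment),
                  replicate = as.integer(replicate),
                  row.names = colnames(signal))
  se <- SummarizedExperiment(assays = list(signal = signal), colData = cd)
  if (!is.null(rowData)) rowData(se) <- rowData
  new("CompartmentExperiment", se)
}

setClass("CompartmentExperiment", contains = "SummarizedExperiment")

.validCompartmentExperiment <- function(object) {
  msg <- character()
  if (!"signal" %in% assayNames(object))
    msg <- c(msg, "assay 'signal' is required")
  else {
    s <- assay(object, "signal")
    if (any(!is.finite(s)))
      msg <- c(msg, "signals must be finite numbers")
    else if (any(s < 0))
      msg <- c(msg, "signals must be non-negative")
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "probe ids (rownames) are required")
  else if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated probe ids")
  cd <- colData(object)
  if (!all(c("compartment", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'compartment' and 'replicate'")
  else {
    if (!all(cd$compartment %in% .COMPARTMENTS))
      msg <- c(msg, "compartment must be 'nuclear' or 'cytoplasmic'")
    if (!is.integer(cd$replicate) || any(is.na(cd$replicate)) ||
        any(cd$replicate < 1L))
      msg <- c(msg, "replicate must be a positive integer")
    if (anyDuplicated(paste(cd$compartment, cd$replicate)))
      msg <- c(msg, "(compartment, replicate) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CompartmentExperiment", .validCompartmentExperiment)

#' ExonExperiment: exon-level compartment-labelled signals
#'
#' A [CompartmentExperiment] whose rows are exons: `rowData` carries
#' `transcript_id` and `exon_id`, each exon belongs to exactly one transcript,
#' and rownames are `transcript_id:exon_id`.
#'
#' @param signal numeric matrix of non-negative exon signals (exons x samples).
#' @param transcript_id,exon_id character vectors of length `nrow(signal)`.
#' @inheritParams CompartmentExperiment
#' @return An `ExonExperiment` object.
#' @aliases ExonExperiment-class
#' @export
ExonExperiment <- function(signal, transcript_id, exon_id,
                           compartment, replicate) {
  signal <- as.matrix(signal)
  rownames(signal) <- paste(transcript_id, exon_id, sep = ":")
  ce <- CompartmentExperiment(signal, compartment, replicate,
                              rowData = DataFrame(
                                transcript_id = as.character(transcript_id),
                                exon_id = as.character(exon_id)))
  new("ExonExperiment", ce)
}

setClass("ExonExperiment", contains = "CompartmentExperiment")

setValidity("ExonExperiment", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("transcript_id", "exon_id") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'transcript_id' and 'exon_id'")
  else if (anyDuplicated(paste(rd$transcript_id, rd$exon_id)))
    msg <- c(msg, "duplicated (transcript_id, exon_id) pairs")
  if (length(msg)) msg else TRUE
})

#' MotifContingency: 2x2 motif-by-enrichment contingency table
#'
#' Counts of motif-positive/-negative sequences in an enriched and a
#' background (depleted) group, the input of [fisherExact()].
#'
#' @param a motif-positive enriched count.
#' @param b motif-negative enriched count.
#' @param c motif-positive background count.
#' @param d motif-negative background count.
#' @param motif optional motif string the counts refer to.
#' @return A `MotifContingency` object.
#' @examples
#' fisherExact(MotifContingency(12, 1, 0, 30))
#' @aliases MotifContingency-class
#' @export
MotifContingency <- function(a, b, c, d, motif = NA_character_) {
  new("MotifContingency", a = as.integer(a), b = as.integer(b),
      c = as.integer(c), d = as.integer(d), motif = as.character(motif))
}

setClass("MotifContingency",
         representation(a = "integer", b = "integer",
                        c = "integer", d = "integer", motif = "character"))

setValidity("MotifContingency", function(object) {
  cells <- c(object@a, object@b, object@c, object@d)
  if (any(is.na(cells))) return("cells must not be NA")
  if (any(cells < 0L)) return("cells must be non-negative")
  TRUE
})

#' @describeIn MotifContingency coerce to a base 2x2 matrix
#'   (rows: enriched/background, columns: motif+/motif-).
#' @param x a `MotifContingency`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "MotifContingency", function(x, ...) {
  matrix(c(x@a, x@c, x@b, x@d), nrow = 2,
         dimnames = list(group = c("enriched", "background"),
                         motif = c("present", "absent")))
})

setMethod("show", "MotifContingency", function(object) {
  cat("MotifContingency",
      if (!is.na(object@motif)) paste0("(motif ", object@motif, ")"), "\n")
  print(as.matrix(object))
})

setMethod("show", "CompartmentExperiment", function(object) {
  callNextMethod()
  cd <- colData(object)
  cat("compartments:",
      paste(sprintf("%s (%d)", .COMPARTMENTS,
                    tabulate(factor(cd$compartment, .COMPARTMENTS), 2L)),
            collapse = ", "), "\n")
})
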