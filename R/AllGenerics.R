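#' Sample compartment labels
#'
#' @param x a [CompartmentExperiment].
#' @return character vector of per-sample compartments.
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname compartments
#' @export
setMethod("compartments", "CompartmentExperiment",
          function(x) colData(x)$compartment)

#' Sample replicate indices
#'
#' @param x a [CompartmentExperiment].
#' @return integer vector of per-sample replicate indices.
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname replicates
#' @export
setMethod("replicates", "CompartmentExperiment",
          function(x) colData(x)$replicate)

#' Raw signal matrix
#'
#' @param x a [CompartmentExperiment].
#' @return the probe x sample matrix of the `"signal"` assay.
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "CompartmentExperiment",
          function(x) assay(x, "signal"))

#' Transcript and exon identifiers of an ExonExperiment
#'
#' @param x an [ExonExperiment].
#' @return character vector of per-row transcript (or exon) ids.
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname transcriptIds
#' @export
setMethod("transcriptIds", "ExonExperiment",
          function(x) rowData(x)$transcript_id)

#' @rdname transcriptIds
#' @export
setGeneric("exonIds", function(x) standardGeneric("exonIds"))

#' @rdname transcriptIds
#' @export
setMethod("exonIds", "ExonExperiment", function(x) rowData(x)$exon_id)
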