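#' @include AllClasses.R
NULL

#' Accessors for pipeline result objects
#'
#' Small accessor generics for the S4 containers: candidate accessions and
#' per-source counts of a [FamilyScreen-class]; nodes, edges and degrees of
#' a [CoannotationGraph-class] (plus the hub families removed by pruning);
#' ids, members and the full annotation table of a
#' [TransportClusterSet-class]; TPM sums, relative abundances and the
#' abundant set of a [ClusterAbundance-class].
#'
#' @param x the object.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("candidateAccessions", function(x) standardGeneric("candidateAccessions"))

#' @rdname accessors
#' @export
setGeneric("sourceCounts", function(x) standardGeneric("sourceCounts"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("graphDegree", function(x) standardGeneric("graphDegree"))

#' @rdname accessors
#' @export
setGeneric("removedFamilies", function(x) standardGeneric("removedFamilies"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("clusterTpm", function(x) standardGeneric("clusterTpm"))

#' @rdname accessors
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @rdname accessors
#' @export
setGeneric("abundantSet", function(x) standardGeneric("abundantSet"))

#' TPM normalisation
#'
#' @param x a counts matrix (ORFs x samples) or a
#'   \linkS4class{SummarizedExperiment} with a \code{"counts"} assay and a
#'   \code{length} column in its rowData.
#' @param ... passed to methods; the matrix method takes \code{lengths}.
#' @return Same shape as the input; see [tpmNormalize,matrix-method].
#' @export
setGeneric("tpmNormalize", function(x, ...) standardGeneric("tpmNormalize"))
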