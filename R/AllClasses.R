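#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
NULL

#' FamilyScreen: result of a transporter text screen
#'
#' Holds the candidate accessions selected by [screenFamilies()] together
#' with the per-source-database candidate counts and the screen
#' configuration that produced them.
#'
#' @slot candidates sorted character vector of candidate accessions.
#' @slot counts named integer vector, candidates per source database.
#' @slot terms character vector of screen terms used.
#' @slot mode matching mode, \code{"substring"} or \code{"word"}.
#' @aliases FamilyScreen
#' @exportClass FamilyScreen
setClass("FamilyScreen",
    slots = c(candidates = "character", counts = "integer",
              terms = "character", mode = "character"))

setValidity("FamilyScreen", function(object) {
    msg <- character()
    if (anyDuplicated(object@candidates))
        msg <- c(msg, "duplicated candidate accessions")
    if (is.unsorted(object@candidates))
        msg <- c(msg, "candidates must be sorted")
    if (is.null(names(object@counts)) && length(object@counts))
        msg <- c(msg, "counts must be named by source database")
    if (length(msg)) msg else TRUE
})

#' CoannotationGraph: family co-annotation graph
#'
#' An undirected graph over candidate transporter families. An edge links
#' two families whenever both annotate the same reviewed cross-reference
#' entry or the same operon; each edge carries the identifiers of every
#' supporting record as provenance. Hub families removed by [pruneHubs()]
#' are retained in the \code{removed} slot.
#'
#' @slot nodes character vector of family accessions (the candidates).
#' @slot edges data.frame with columns \code{from}, \code{to}
#'   (lexicographically ordered, no self edges).
#' @slot provenance CharacterList parallel to the edge rows; supporting
#'   cross-reference entry and operon identifiers.
#' @slot removed accessions pruned as hubs (empty before pruning).
#' @aliases CoannotationGraph
#' @exportClass CoannotationGraph
setClass("CoannotationGraph",
    slots = c(nodes = "character", edges = "data.frame",
              provenance = "CharacterList", removed = "character"))

setValidity("CoannotationGraph", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to") %in% names(e)))
        return("edges must have columns 'from' and 'to'")
    if (nrow(e)) {
        if (any(e$from == e$to)) msg <- c(msg, "self edges are not allowed")
        if (any(e$from > e$to)) msg <- c(msg, "edges must satisfy from < to")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edges reference accessions outside the node set")
        if (anyDuplicated(paste(e$from, e$to)))
            msg <- c(msg, "duplicated edges")
    }
    if (length(object@provenance) != nrow(e))
        msg <- c(msg, "provenance must be parallel to the edge rows")
    if (length(intersect(object@nodes, object@removed)))
        msg <- c(msg, "removed accessions must not remain in the node set")
    if (length(msg)) msg else TRUE
})

#' TransportClusterSet: transport clusters and their annotation
#'
#' A set of transport clusters, each a group of protein families jointly
#' representing one membrane transporter (all subunits). Produced by
#' [clusterFamilies()] as the connected components of a pruned
#' co-annotation graph; annotation columns (substrate category, transport
#' class, secretion type, TCDB class) are filled in by
#' [annotateClusters()] and [classifyTransportClass()].
#'
#' @slot clusters a [S4Vectors::DataFrame] with at least columns
#'   \code{cluster_id}, \code{members} (a CharacterList), \code{n_members}
#'   and \code{n_edges}.
#' @aliases TransportClusterSet
#' @exportClass TransportClusterSet
setClass("TransportClusterSet", slots = c(clusters = "DataFrame"))

setValidity("TransportClusterSet", function(object) {
    cl <- object@clusters
    req <- c("cluster_id", "members", "n_members")
    if (!all(req %in% colnames(cl)))
        return(paste("missing columns:",
                     paste(setdiff(req, colnames(cl)), collapse = ", ")))
    msg <- character()
    if (anyDuplicated(cl$cluster_id)) msg <- c(msg, "duplicated cluster ids")
    members <- unlist(cl$members, use.names = FALSE)
    if (anyDuplicated(members))
        msg <- c(msg, "clusters must be disjoint (a family in two clusters)")
    if (!all(lengths(cl$members) == cl$n_members))
        msg <- c(msg, "n_members inconsistent with members")
    if (any(cl$n_members < 1L)) msg <- c(msg, "empty cluster")
    if ("category" %in% colnames(cl)) {
        bad <- setdiff(cl$category, c(substrateCategories(), "unannotated"))
        if (length(bad))
            msg <- c(msg, paste("unknown category:", paste(bad, collapse = ", ")))
    }
    if ("transport_class" %in% colnames(cl)) {
        bad <- setdiff(stats::na.omit(cl$transport_class), transportClasses())
        if (length(bad))
            msg <- c(msg, paste("unknown transport class:",
                                paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' ClusterAbundance: per-cluster TPM abundance
#'
#' Cluster-by-sample TPM sums, the per-sample relative abundances (each
#' column summing to 1 where the sample has any transporter signal), and
#' the set of clusters exceeding the relative-abundance threshold in at
#' least one sample.
#'
#' @slot entries numeric matrix, cluster x sample TPM sums.
#' @slot relative numeric matrix, columns are fractions of the sample's
#'   total transporter TPM.
#' @slot abundant cluster ids whose relative abundance strictly exceeds
#'   \code{threshold} in at least one sample.
#' @slot threshold the relative-abundance cutoff (default 0.005).
#' @slot dataset dataset tag, e.g. \code{"MG"} or \code{"MT"}.
#' @aliases ClusterAbundance
#' @exportClass ClusterAbundance
setClass("ClusterAbundance",
    slots = c(entries = "matrix", relative = "matrix", abundant = "character",
              threshold = "numeric", dataset = "character"))

setValidity("ClusterAbundance", function(object) {
    msg <- character()
    if (!identical(dim(object@entries), dim(object@relative)))
        msg <- c(msg, "entries and relative must have identical dimensions")
    if (any(object@entries < 0)) msg <- c(msg, "negative abundance")
    if (!all(object@abundant %in% rownames(object@entries)))
        msg <- c(msg, "abundant set outside the cluster ids")
    tot <- colSums(object@entries)
    ok <- tot <= 0 | abs(colSums(object@relative) - 1) < 1e-9
    if (!all(ok)) msg <- c(msg, "relative columns must sum to 1")
    if (length(msg)) msg else TRUE
})
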