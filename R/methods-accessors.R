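#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("candidateAccessions", "FamilyScreen", function(x) x@candidates)

#' @rdname accessors
setMethod("sourceCounts", "FamilyScreen", function(x) x@counts)

setMethod("show", "FamilyScreen", function(object) {
    cat("FamilyScreen with", length(object@candidates), "candidate families\n")
    cat("  terms:", paste(object@terms, collapse = ", "),
        sprintf("(%s match)\n", object@mode))
    if (length(object@counts)) {
        cat("  per source:",
            paste(sprintf("%s=%d", names(object@counts), object@counts),
                  collapse = ", "), "\n")
    }
})

#' @rdname accessors
setMethod("graphNodes", "CoannotationGraph", function(x) x@nodes)

#' @rdname accessors
setMethod("graphEdges", "CoannotationGraph", function(x) x@edges)

#' @rdname accessors
setMethod("removedFamilies", "CoannotationGraph", function(x) x@removed)

#' @rdname accessors
setMethod("graphDegree", "CoannotationGraph", function(x) {
    deg <- setNames(integer(length(x@nodes)), x@nodes)
    if (nrow(x@edges)) {
        tab <- table(c(x@edges$from, x@edges$to))
        deg[names(tab)] <- as.integer(tab)
    }
    deg
})

setMethod("show", "CoannotationGraph", function(object) {
    cat("CoannotationGraph:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges")
    if (length(object@removed))
        cat(",", length(object@removed), "hub(s) removed")
    cat("\n")
})

#' @rdname accessors
setMethod("clusterIds", "TransportClusterSet", function(x) x@clusters$cluster_id)

#' @rdname accessors
setMethod("clusterMembers", "TransportClusterSet", function(x) {
    setNames(x@clusters$members, x@clusters$cluster_id)
})

#' @rdname accessors
setMethod("clusterTable", "TransportClusterSet", function(x) x@clusters)

setMethod("length", "TransportClusterSet", function(x) nrow(x@clusters))

setMethod("show", "TransportClusterSet", function(object) {
    cl <- object@clusters
    cat("TransportClusterSet with", nrow(cl), "clusters (",
        sum(cl$n_members), "families )\n")
    if ("category" %in% colnames(cl)) {
        cat("  annotated:", sum(!cl$excluded), "| excluded:",
            sum(cl$excluded), "\n")
    }
    if ("transport_class" %in% colnames(cl)) {
        tab <- table(cl$transport_class)
        cat("  classes:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
})

#' @rdname accessors
setMethod("clusterTpm", "ClusterAbundance", function(x) x@entries)

#' @rdname accessors
setMethod("relativeAbundance", "ClusterAbundance", function(x) x@relative)

#' @rdname accessors
setMethod("abundantSet", "ClusterAbundance", function(x) x@abundant)

setMethod("show", "ClusterAbundance", function(object) {
    cat(sprintf("ClusterAbundance [%s]: %d clusters x %d samples\n",
                object@dataset, nrow(object@entries), ncol(object@entries)))
    cat(sprintf("  abundant (> %.2f%% in >=1 sample): %d clusters\n",
                100 * object@threshold, length(object@abundant)))
})
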