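#' @include AllClasses.R
NULL

## Accept accession sets as a CharacterList/list or comma-separated strings
## (the on-disk TSV form); always returns a list of character vectors.
.accessionList <- function(x) {
    if (is.list(x) || inherits(x, "CharacterList"))
        return(lapply(x, as.character))
    lapply(strsplit(as.character(x), ","), trimws)
}

#' Build the family co-annotation graph
#'
#' Every reviewed cross-reference entry and every operon that carries two
#' or more candidate families contributes an edge for each unordered pair
#' of those families. Families on the same record that are not candidates
#' are ignored; unreviewed cross-reference entries contribute nothing.
#' Each edge records the identifiers of all supporting records as
#' provenance, but an edge counts once towards a family's degree no matter
#' how many records support it.
#'
#' @param candidates character vector of candidate family accessions
#'   (non-empty), e.g. from [screenFamilies()].
#' @param xrefs data.frame of cross-reference entries with columns
#'   \code{entry_id}, \code{reviewed} (logical) and \code{accessions}
#'   (comma-separated string or list of accessions). May be \code{NULL}.
#' @param operons data.frame with columns \code{operon_id} and
#'   \code{accessions}. May be \code{NULL}.
#' @param families optional family table; accessions appearing in records
#'   but absent from it trigger a warning and are skipped.
#' @return A [CoannotationGraph-class] whose nodes are the candidates.
#' @examples
#' xr <- data.frame(entry_id = "UP1", reviewed = TRUE, accessions = "A,B,C")
#' g <- buildCoannotationGraph(c("A", "B", "C"), xrefs = xr)
#' graphEdges(g)
#' @export
buildCoannotationGraph <- function(candidates, xrefs = NULL, operons = NULL,
                                   families = NULL) {
    candidates <- sort(unique(as.character(candidates)))
    if (length(candidates) == 0L)
        stop("candidate set is empty")

    ids <- character()
    accs <- list()
    if (!is.null(xrefs) && nrow(xrefs)) {
        lst <- .accessionList(xrefs$accessions)
        keep <- as.logical(xrefs$reviewed)
        ids <- c(ids, as.character(xrefs$entry_id)[keep])
        accs <- c(accs, lst[keep])
        seen <- unlist(lst, use.names = FALSE)
    } else {
        seen <- character()
    }
    if (!is.null(operons) && nrow(operons)) {
        lst <- .accessionList(operons$accessions)
        ids <- c(ids, as.character(operons$operon_id))
        accs <- c(accs, lst)
        seen <- c(seen, unlist(lst, use.names = FALSE))
    }
    if (!is.null(families)) {
        unknown <- setdiff(unique(seen), families$accession)
        if (length(unknown))
            warning("skipping accessions absent from the family table: ",
                    paste(utils::head(unknown, 5L), collapse = ", "),
                    if (length(unknown) > 5L) ", ...")
        known <- unique(families$accession)
        accs <- lapply(accs, intersect, known)
    }

    from <- to <- prov <- character()
    for (i in seq_along(accs)) {
        m <- sort(unique(intersect(accs[[i]], candidates)))
        if (length(m) >= 2L) {
            p <- utils::combn(m, 2L)
            from <- c(from, p[1L, ])
            to <- c(to, p[2L, ])
            prov <- c(prov, rep(ids[i], ncol(p)))
        }
    }

    if (length(from)) {
        key <- paste(from, to, sep = "\r")
        byEdge <- split(prov, key)
        uKey <- sort(names(byEdge))
        parts <- strsplit(uKey, "\r", fixed = TRUE)
        edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                            to = vapply(parts, `[`, "", 2L),
                            stringsAsFactors = FALSE)
        provenance <- CharacterList(lapply(byEdge[uKey], unique))
        names(provenance) <- NULL
    } else {
        edges <- data.frame(from = character(), to = character())
        provenance <- CharacterList()
    }
    new("CoannotationGraph", nodes = candidates, edges = edges,
        provenance = provenance, removed = character())
}

#' Prune hub families from a co-annotation graph
#'
#' Generic protein families (e.g. ubiquitous ATP-binding domains) annotate
#' diverse proteins and accumulate many co-annotation partners, which would
#' inflate transport clusters. Every node whose degree in the \emph{input}
#' graph exceeds \code{maxDegree} distinct neighbours is removed together
#' with all incident edges. Removal decisions are a single pass on input
#' degrees: a node whose degree only drops below the cutoff because another
#' hub was removed is still pruned, and surviving nodes with degree exactly
#' \code{maxDegree} are kept.
#'
#' @param graph a [CoannotationGraph-class].
#' @param maxDegree maximum allowed number of distinct neighbours
#'   (default 6).
#' @return The pruned [CoannotationGraph-class]; the removed accessions are
#'   available via [removedFamilies()].
#' @export
pruneHubs <- function(graph, maxDegree = 6L) {
    stopifnot(is(graph, "CoannotationGraph"), maxDegree >= 0L)
    deg <- graphDegree(graph)
    removed <- sort(names(deg)[deg > maxDegree])
    e <- graph@edges
    keep <- !(e$from %in% removed) & !(e$to %in% removed)
    new("CoannotationGraph",
        nodes = setdiff(graph@nodes, removed),
        edges = e[keep, , drop = FALSE],
        provenance = graph@provenance[keep],
        removed = sort(union(graph@removed, removed)))
}

#' Cluster families into transport clusters
#'
#' Transport clusters are the connected components of the (pruned)
#' co-annotation graph, plus one singleton cluster per candidate family
#' that carries no edge. Pruned hub families are excluded. Cluster ids are
#' deterministic: clusters are ordered by their lexicographically smallest
#' member accession and labelled \code{TC00001, TC00002, ...}, so the
#' partition is invariant to record order up to relabelling.
#'
#' @param graph a [CoannotationGraph-class], typically after [pruneHubs()].
#' @param candidates the candidate accession set; graph nodes must be a
#'   subset of the candidates plus the pruned set.
#' @return A [TransportClusterSet-class]; its union of members equals the
#'   candidates minus the pruned hubs.
#' @export
clusterFamilies <- function(graph, candidates = graphNodes(graph)) {
    stopifnot(is(graph, "CoannotationGraph"))
    candidates <- sort(unique(as.character(candidates)))
    if (!all(graph@nodes %in% union(candidates, graph@removed)))
        stop("graph nodes must be a subset of candidates plus pruned hubs")
    units <- sort(union(graph@nodes, setdiff(candidates, graph@removed)))

    e <- graph@edges
    if (nrow(e)) {
        g <- igraph::graph_from_data_frame(
            e, directed = FALSE, vertices = data.frame(name = units))
        memb <- igraph::components(g)$membership
        members <- split(names(memb), memb)
    } else {
        members <- as.list(units)
    }
    members <- lapply(members, function(m) sort(as.character(m)))
    ord <- order(vapply(members, `[`, "", 1L))
    members <- members[ord]

    nEdges <- integer(length(members))
    if (nrow(e)) {
        owner <- setNames(rep(seq_along(members), lengths(members)),
                          unlist(members, use.names = FALSE))
        tab <- table(owner[e$from])
        nEdges[as.integer(names(tab))] <- as.integer(tab)
    }

    cl <- DataFrame(
        cluster_id = sprintf("TC%05d", seq_along(members)),
        members = CharacterList(members),
        n_members = lengths(members),
        n_edges = nEdges)
    new("TransportClusterSet", clusters = cl)
}
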