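#' @include AllClasses.R
NULL

#' Run the full transporter trait pipeline
#'
#' Convenience wrapper chaining the stages on a reference bundle (family
#' metadata, cross-references, operons, annotation hints — e.g. the output
#' of [simulateReference()]) and a community bundle (ORF catalogue plus MG
#' and MT \linkS4class{SummarizedExperiment}s — e.g. the output of
#' [simulateCommunity()]): text screen, co-annotation graph, hub pruning,
#' connected-component clustering, substrate and transport-class
#' annotation, TPM normalisation, ORF-to-cluster mapping, per-cluster
#' abundance with the abundant-transporter filter, contig LCA voting with
#' propagation, and taxon-by-category aggregation.
#'
#' @param ref list with \code{families}, \code{xrefs}, \code{operons} and
#'   optionally \code{roles}, \code{goMap}.
#' @param community list with \code{orfs} and \code{mg}/\code{mt}
#'   SummarizedExperiments carrying a \code{counts} assay.
#' @param overrides optional curated override table.
#' @param terms screen terms, default [defaultScreenTerms()].
#' @param maxDegree hub-pruning cutoff, default 6.
#' @param threshold abundant-transporter cutoff, default 0.005.
#' @param rank taxon rank for aggregation, default \code{"order"}.
#' @return List with the intermediate objects: \code{screen},
#'   \code{graph}, \code{pruned}, \code{clusters}, \code{mapping},
#'   \code{tpm} (per dataset), \code{abundance} (per dataset),
#'   \code{abundant} (union), \code{orfPaths} and \code{tensor}
#'   (per dataset).
#' @export
runTransporterPipeline <- function(ref, community, overrides = NULL,
                                   terms = defaultScreenTerms(),
                                   maxDegree = 6L, threshold = 0.005,
                                   rank = "order") {
    scr <- screenFamilies(ref$families, terms = terms)
    g <- buildCoannotationGraph(candidateAccessions(scr), ref$xrefs,
                                ref$operons)
    pg <- pruneHubs(g, maxDegree)
    cl <- clusterFamilies(pg, candidateAccessions(scr))
    cl <- annotateClusters(cl, ref$roles, ref$goMap, overrides)
    cl <- classifyTransportClass(cl, ref$families, overrides)

    mapping <- mapOrfsToClusters(community$orfs, cl)
    contigs <- voteAllContigs(community$orfs)
    paths <- propagateTaxonomy(community$orfs, contigs)

    out <- list(screen = scr, graph = g, pruned = pg, clusters = cl,
                mapping = mapping, orfPaths = paths,
                tpm = list(), abundance = list(), tensor = list())
    for (tag in c("MG", "MT")) {
        se <- community[[tolower(tag)]]
        if (is.null(se)) next
        se <- tpmNormalize(se)
        tpm <- SummarizedExperiment::assay(se, "tpm")
        out$tpm[[tag]] <- tpm
        out$abundance[[tag]] <- clusterAbundance(tpm, mapping, threshold,
                                                 dataset = tag)
        out$tensor[[tag]] <- aggregateByTaxon(tpm, mapping, cl, paths,
                                              rank = rank)
    }
    out$abundant <- do.call(abundantUnion, unname(out$abundance))
    out
}
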