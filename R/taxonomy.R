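#' @include AllClasses.R
NULL

#' Split and join semicolon-delimited taxonomy paths
#'
#' Lineages are stored as semicolon-delimited rank labels, from domain
#' downwards with no gaps; an empty string is an unclassified path.
#'
#' @param x character vector of semicolon-delimited paths.
#' @return \code{splitTaxonomyPath}: a list of character vectors;
#'   \code{joinTaxonomyPath}: a character vector.
#' @export
splitTaxonomyPath <- function(x) {
    out <- strsplit(as.character(x), ";", fixed = TRUE)
    lapply(out, function(p) {
        p <- trimws(p)
        p[nzchar(p)]
    })
}

#' @rdname splitTaxonomyPath
#' @param paths a list of character vectors (ranked labels).
#' @export
joinTaxonomyPath <- function(paths) {
    vapply(paths, paste, "", collapse = ";")
}

#' Vote a contig's lowest-common-ancestor taxonomy from its ORFs
#'
#' Descends rank by rank. At each rank, among the ORFs whose path is
#' consistent with the lineage voted so far \emph{and} classified at that
#' rank, the label supported by a fraction strictly greater than
#' \code{majorityFraction} is kept; the vote stops at the first rank
#' without such a label. An exactly 50\% split therefore truncates the
#' path. All-empty input yields the empty (unclassified) path.
#'
#' @param orfPaths character vector of semicolon paths, or a list of rank
#'   label vectors; empty paths are allowed.
#' @param majorityFraction required support fraction, in [0.5, 1);
#'   default 0.5 (strict majority).
#' @return A single semicolon-delimited path (possibly \code{""}).
#' @examples
#' voteContigTaxonomy(c("Bacteria;Proteobacteria", "Bacteria;Bacteroidetes"))
#' @export
voteContigTaxonomy <- function(orfPaths, majorityFraction = 0.5) {
    stopifnot(majorityFraction >= 0.5, majorityFraction < 1)
    paths <- if (is.list(orfPaths)) orfPaths else splitTaxonomyPath(orfPaths)
    if (length(paths) == 0L) return("")
    voted <- character()
    consistent <- rep(TRUE, length(paths))
    depth <- lengths(paths)
    repeat {
        r <- length(voted) + 1L
        atRank <- consistent & depth >= r
        if (!any(atRank)) break
        labels <- vapply(paths[atRank], `[`, "", r)
        tab <- table(labels)
        frac <- tab / sum(tab)
        winner <- names(frac)[frac > majorityFraction]
        if (length(winner) != 1L) break
        voted <- c(voted, winner)
        consistent[atRank] <- labels == winner
    }
    paste(voted, collapse = ";")
}

#' Vote taxonomy for every contig in an ORF table
#'
#' @param orfs data.frame with columns \code{orf_id}, \code{contig_id} and
#'   \code{taxonomy} (semicolon paths; empty string for unclassified).
#' @param majorityFraction see [voteContigTaxonomy()].
#' @return Named character vector contig id -> voted path.
#' @export
voteAllContigs <- function(orfs, majorityFraction = 0.5) {
    byContig <- split(as.character(orfs$taxonomy), orfs$contig_id)
    vapply(byContig, voteContigTaxonomy,
           majorityFraction = majorityFraction, FUN.VALUE = "")
}

#' Propagate voted contig taxonomy back to ORFs
#'
#' Every ORF receives its contig's voted path, overriding its own
#' assignment; an empty contig path leaves the ORF unclassified.
#'
#' @param orfs ORF table with \code{orf_id} and \code{contig_id}.
#' @param contigPaths named vector from [voteAllContigs()].
#' @return Named character vector ORF id -> path.
#' @export
propagateTaxonomy <- function(orfs, contigPaths) {
    orphan <- setdiff(unique(orfs$contig_id), names(contigPaths))
    if (length(orphan))
        stop("contig(s) without a voted path: ",
             paste(utils::head(orphan, 5L), collapse = ", "))
    setNames(unname(contigPaths[as.character(orfs$contig_id)]),
             orfs$orf_id)
}

#' Domain-level grouping of taxonomy paths
#'
#' Groups lineages into Archaea, Bacteria (excluding Cyanobacteria),
#' Cyanobacteria (identified by phylum label), Picoeukaryota (the
#' Eukaryota domain in this size fraction), Viruses, and Unclassified.
#' The groups partition all paths, so the Bacteria and Cyanobacteria
#' groups together equal the unsubtracted Bacteria domain total.
#'
#' @param paths character vector of semicolon paths.
#' @return Character vector of group labels.
#' @export
domainGroup <- function(paths) {
    split <- splitTaxonomyPath(paths)
    vapply(split, function(p) {
        if (length(p) == 0L) return("Unclassified")
        switch(p[1L],
            Archaea = "Archaea",
            Viruses = "Viruses",
            Eukaryota = "Picoeukaryota",
            Bacteria = if (length(p) >= 2L && p[2L] == "Cyanobacteria")
                "Cyanobacteria" else "Bacteria",
            "Unclassified")
    }, "")
}

.rankLabel <- function(paths, rank) {
    r <- match(rank, taxonomicRanks())
    if (is.na(r)) stop("unknown rank: ", rank)
    split <- splitTaxonomyPath(paths)
    vapply(split, function(p) {
        if (length(p) >= r) p[r] else "Unclassified"
    }, "")
}

#' Aggregate transporter abundance by taxon and substrate category
#'
#' Builds the taxon x category x sample tensor: each cell sums the TPM of
#' the ORFs whose propagated taxonomy carries the given label at
#' \code{rank} and whose transport cluster has the given substrate
#' category. ORFs unclassified at the rank are kept in a dedicated
#' \code{"Unclassified"} taxon so that the tensor conserves the total
#' cluster abundance per category and sample. With
#' \code{grouping = TRUE} the taxa are the domain groups of
#' [domainGroup()], i.e. cyanobacterial abundance is reported separately
#' and thereby subtracted from the Bacteria fraction.
#'
#' @param tpm TPM matrix (ORFs x samples).
#' @param mapping ORF-to-cluster vector from [mapOrfsToClusters()].
#' @param clusters annotated [TransportClusterSet-class].
#' @param orfPaths named ORF-to-path vector from [propagateTaxonomy()].
#' @param rank taxonomic rank for the taxon axis, default \code{"order"}.
#' @param grouping if TRUE use domain groups instead of rank labels.
#' @return 3-d array with dimnames (taxon, category, sample); categories
#'   are always the nine substrate categories.
#' @export
aggregateByTaxon <- function(tpm, mapping, clusters, orfPaths,
                             rank = "order", grouping = FALSE) {
    stopifnot(is(clusters, "TransportClusterSet"))
    cl <- clusters@clusters
    if (is.null(cl$category))
        stop("clusters must be annotated (run annotateClusters)")
    cl2cat <- setNames(cl$category, cl$cluster_id)

    orfIds <- names(mapping)
    cat <- unname(cl2cat[mapping])
    paths <- unname(orfPaths[orfIds])
    taxon <- if (grouping) domainGroup(paths) else .rankLabel(paths, rank)

    cats <- substrateCategories()
    taxa <- sort(unique(taxon))
    samples <- colnames(tpm)
    tensor <- array(0, dim = c(length(taxa), length(cats), length(samples)),
                    dimnames = list(taxon = taxa, category = cats,
                                    sample = samples))
    key <- paste(taxon, cat, sep = "\r")
    sums <- rowsum(tpm[orfIds, , drop = FALSE], group = key)
    parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
    for (i in seq_len(nrow(sums))) {
        t <- parts[[i]][1L]
        c <- parts[[i]][2L]
        if (c %in% cats) tensor[t, c, ] <- sums[i, ]
    }
    tensor
}

#' Per-taxon substrate composition from a tensor
#'
#' Normalises each taxon's category profile to sum to 1 within each
#' sample; samples where the taxon is absent give NA rows.
#'
#' @param tensor output of [aggregateByTaxon()].
#' @return Array of the same shape holding compositions.
#' @export
tensorComposition <- function(tensor) {
    tot <- apply(tensor, c(1L, 3L), sum)
    out <- tensor
    for (s in seq_len(dim(tensor)[3L])) {
        t <- tot[, s]
        out[, , s] <- sweep(tensor[, , s, drop = FALSE][, , 1L], 1L,
                            ifelse(t > 0, t, NA_real_), `/`)
    }
    out
}

#' Taxon richness per substrate category
#'
#' For each category and sample, counts the taxa whose abundance exceeds
#' \code{minAbundance}; also returns the mean count over samples per
#' category.
#'
#' @param tensor output of [aggregateByTaxon()].
#' @param minAbundance TPM floor (strictly exceeded), default 0.
#' @return List with \code{perSample} (category x sample counts) and
#'   \code{mean} (named numeric).
#' @export
taxonRichnessPerCategory <- function(tensor, minAbundance = 0) {
    perSample <- apply(tensor > minAbundance, c(2L, 3L), sum)
    list(perSample = perSample, mean = rowMeans(perSample))
}

#' Importer richness per taxon with a visibility mask
#'
#' Counts, per taxon and sample, the distinct importer clusters with
#' positive abundance. A taxon's count is only reported (visible) in a
#' sample when its total transporter abundance is greater than or equal to
#' the across-taxa 90\% quantile (linear-interpolation sample quantile) in
#' that sample \emph{and} strictly more than \code{minReads} raw reads of
#' that taxon map to the abundant transporter set.
#'
#' @param tpm TPM matrix (ORFs x samples).
#' @param counts raw count matrix, same shape as \code{tpm}.
#' @param mapping,clusters,orfPaths,rank as in [aggregateByTaxon()].
#' @param abundant character vector of abundant cluster ids (see
#'   [abundantUnion()]); used for the read-support mask. Defaults to all
#'   mapped clusters.
#' @param quantileProb visibility quantile, default 0.9.
#' @param minReads read-support cutoff (strict), default 500.
#' @return List with matrices \code{richness}, \code{visible} (logical),
#'   \code{totals} (taxon total TPM) and \code{reads} (taxon reads on the
#'   abundant set), all taxon x sample.
#' @export
importerRichnessPerTaxon <- function(tpm, counts, mapping, clusters,
                                     orfPaths, rank = "order",
                                     abundant = NULL, quantileProb = 0.9,
                                     minReads = 500) {
    stopifnot(is(clusters, "TransportClusterSet"))
    cl <- clusters@clusters
    if (is.null(cl$transport_class))
        stop("clusters must be classified (run classifyTransportClass)")
    importers <- cl$cluster_id[cl$transport_class == "importer"]
    if (is.null(abundant)) abundant <- sort(unique(mapping))

    orfIds <- names(mapping)
    taxon <- .rankLabel(unname(orfPaths[orfIds]), rank)
    taxa <- sort(unique(taxon))
    samples <- colnames(tpm)

    ## importer cluster presence per (taxon, cluster, sample)
    imp <- mapping %in% importers
    richness <- matrix(0L, length(taxa), length(samples),
                       dimnames = list(taxa, samples))
    if (any(imp)) {
        key <- paste(taxon[imp], mapping[imp], sep = "\r")
        sums <- rowsum(tpm[orfIds[imp], , drop = FALSE], group = key)
        kTaxon <- vapply(strsplit(rownames(sums), "\r", fixed = TRUE),
                         `[`, "", 1L)
        pres <- sums > 0
        for (t in taxa) {
            rows <- kTaxon == t
            if (any(rows))
                richness[t, ] <- colSums(pres[rows, , drop = FALSE])
        }
    }

    totals <- rowsum(tpm[orfIds, , drop = FALSE], group = taxon)
    totals <- totals[taxa, , drop = FALSE]
    onAbundant <- mapping %in% abundant
    reads <- matrix(0, length(taxa), length(samples),
                    dimnames = list(taxa, samples))
    if (any(onAbundant)) {
        r <- rowsum(counts[orfIds[onAbundant], , drop = FALSE],
                    group = taxon[onAbundant])
        reads[rownames(r), ] <- r
    }

    visible <- matrix(FALSE, length(taxa), length(samples),
                      dimnames = list(taxa, samples))
    for (s in seq_along(samples)) {
        q <- stats::quantile(totals[, s], probs = quantileProb, type = 7,
                             names = FALSE)
        visible[, s] <- totals[, s] >= q & reads[, s] > minReads
    }
    list(richness = richness, visible = visible, totals = totals,
         reads = reads)
}
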