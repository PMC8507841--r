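# Independent oracles used by the property and recovery tests. These are
# deliberately written with different algorithms than the package code.

# Union-find with path compression; returns the canonical partition.
ufPartition <- function(nodes, edgeFrom, edgeTo) {
    parent <- setNames(nodes, nodes)
    find <- function(x) {
        while (parent[[x]] != x) {
            parent[[x]] <<- parent[[parent[[x]]]]
            x <- parent[[x]]
        }
        x
    }
    for (i in seq_along(edgeFrom)) {
        ra <- find(edgeFrom[i])
        rb <- find(edgeTo[i])
        if (ra != rb) parent[[ra]] <- rb
    }
    canonicalPartition(unname(split(nodes, vapply(nodes, find, ""))))
}

# Canonical form of a partition: sorted members, blocks ordered by their
# smallest member, labels dropped.
canonicalPartition <- function(blocks) {
    blocks <- lapply(blocks, function(b) sort(as.character(b)))
    unname(blocks[order(vapply(blocks, `[`, "", 1L))])
}

# Brute-force co-annotation edge oracle: double loop over every reviewed
# xref record and every operon, and every ordered pair on it.
bruteEdges <- function(candidates, xrefs, operons) {
    recs <- list()
    if (!is.null(xrefs) && nrow(xrefs)) {
        for (i in which(as.logical(xrefs$reviewed)))
            recs[[length(recs) + 1L]] <-
                strsplit(xrefs$accessions[i], ",")[[1L]]
    }
    if (!is.null(operons) && nrow(operons)) {
        for (i in seq_len(nrow(operons)))
            recs[[length(recs) + 1L]] <-
                strsplit(operons$accessions[i], ",")[[1L]]
    }
    edges <- character()
    for (r in recs) {
        r <- intersect(unique(trimws(r)), candidates)
        for (a in r) for (b in r)
            if (a < b) edges <- c(edges, paste(a, b))
    }
    sort(unique(edges))
}

edgeKeys <- function(graph) {
    e <- graphEdges(graph)
    sort(paste(e$from, e$to))
}

# Exhaustive permutation enumeration by the insertion method (independent
# of the package's selection recursion).
insPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    p <- insPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(pos) {
        if (pos == 1L) cbind(n, p)
        else if (pos == n) cbind(p, n)
        else cbind(p[, seq_len(pos - 1L), drop = FALSE], n,
                   p[, pos:(n - 1L), drop = FALSE])
    }))
}

oracleSpearman <- function(x, y) {
    rx <- rank(x)
    ry <- rank(y)
    rho <- cor(rx, ry)
    P <- insPerms(length(x))
    rhos <- apply(P, 1L, function(idx) cor(rx, ry[idx]))
    list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# Cluster specs covering all nine substrate categories and all five
# transport classes, so community profiles always find a planted cluster.
coveringClusterSpecs <- function() {
    cats <- substrateCategories()
    specs <- lapply(seq_along(cats), function(i) {
        clusterSpec(sprintf("PC%02d", i), 1L + i %% 3L, cats[i], "importer")
    })
    c(specs, list(
        clusterSpec("PC20", 2L, "cation", "metal"),
        clusterSpec("PC21", 3L, "anion", "exporter_toxin"),
        clusterSpec("PC22", 2L, "carbohydrate", "exporter_utility"),
        clusterSpec("PC23", 1L, "urea", "other")))
}

# Random cross-reference/operon record sets for graph property tests.
randomRecordSet <- function(seed, nFam = NULL) {
    set.seed(seed)
    if (is.null(nFam)) nFam <- sample(5:30, 1L)
    fams <- sprintf("F%02d", seq_len(nFam))
    nX <- sample(3:15, 1L)
    xrefs <- do.call(rbind, lapply(seq_len(nX), function(i) {
        data.frame(entry_id = sprintf("E%03d", i),
                   reviewed = runif(1) < 0.8,
                   accessions = paste(sample(fams, sample(2:4, 1L)),
                                      collapse = ","),
                   stringsAsFactors = FALSE)
    }))
    nO <- sample(0:5, 1L)
    operons <- if (nO > 0) do.call(rbind, lapply(seq_len(nO), function(i) {
        data.frame(operon_id = sprintf("O%03d", i),
                   accessions = paste(sample(fams, sample(2:3, 1L)),
                                      collapse = ","),
                   stringsAsFactors = FALSE)
    })) else NULL
    list(fams = fams, xrefs = xrefs, operons = operons)
}

# Small three-taxon community used by several end-to-end tests.
threeTaxonSpecs <- function() {
    list(
        taxonSpec("Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales",
                  peakDay = 100, peakWidth = 25, amplitude = 1,
                  c(cation = 0.5, amino_acids_peptides_ammonium = 0.27,
                    carbohydrate = 0.23)),
        taxonSpec("Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales",
                  peakDay = 160, peakWidth = 25, amplitude = 1,
                  c(carbohydrate = 0.4, phosphonate = 0.3, anion = 0.3)),
        taxonSpec("Bacteria;Proteobacteria;Gammaproteobacteria;Cellvibrionales",
                  peakDay = 220, peakWidth = 30, amplitude = 1,
                  c(anion = 0.4, amino_acids_peptides_ammonium = 0.6)))
}
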