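xr <- function(id, accs, reviewed = TRUE) {
    data.frame(entry_id = id, reviewed = reviewed,
               accessions = accs, stringsAsFactors = FALSE)
}
op <- function(id, accs) {
    data.frame(operon_id = id, accessions = accs, stringsAsFactors = FALSE)
}

test_that("every pair on a record becomes an edge; non-candidates and unreviewed entries do not", {
    g <- buildCoannotationGraph(c("A", "B", "C"), xrefs = xr("E1", "A,B,C"))
    expect_identical(edgeKeys(g), c("A B", "A C", "B C"))
    expect_identical(graphDegree(g), c(A = 2L, B = 2L, C = 2L))

    g2 <- buildCoannotationGraph(c("A", "B", "C", "D"),
                                 xrefs = rbind(xr("E1", "A,B"),
                                               xr("E2", "B,C")),
                                 operons = op("O1", "C,D"))
    expect_identical(edgeKeys(g2), c("A B", "B C", "C D"))
    expect_identical(graphDegree(g2), c(A = 1L, B = 2L, C = 2L, D = 1L))

    # unreviewed evidence and non-candidate families contribute nothing
    g3 <- buildCoannotationGraph(c("A", "B"),
                                 xrefs = rbind(xr("E1", "A,B", FALSE),
                                               xr("E2", "A,Z")))
    expect_identical(nrow(graphEdges(g3)), 0L)
})

test_that("edge provenance lists every supporting record and degree counts neighbours once", {
    g <- buildCoannotationGraph(c("A", "B"),
                                xrefs = rbind(xr("E1", "A,B"),
                                              xr("E2", "A,B")),
                                operons = op("O1", "A,B"))
    expect_identical(nrow(graphEdges(g)), 1L)
    expect_setequal(g@provenance[[1L]], c("E1", "E2", "O1"))
    expect_identical(graphDegree(g), c(A = 1L, B = 1L))
})

test_that("accessions missing from the family table warn and are skipped", {
    families <- data.frame(accession = c("A", "B"), source_db = "PFAM",
                           name = "x", description = "transport")
    expect_warning(
        g <- buildCoannotationGraph(c("A", "B"), xrefs = xr("E1", "A,B,GHOST"),
                                    families = families),
        "GHOST")
    expect_identical(edgeKeys(g), "A B")
})

test_that("edge sets match a brute-force double loop on 100 random record tables", {
    for (seed in 1:100) {
        rs <- randomRecordSet(seed)
        cand <- sort(sample(rs$fams, max(2L, round(0.8 * length(rs$fams)))))
        g <- buildCoannotationGraph(cand, rs$xrefs, rs$operons)
        expect_identical(edgeKeys(g),
                         bruteEdges(cand, rs$xrefs, rs$operons))
    }
})

test_that("hub pruning removes degree > 6 in a single pass on input degrees", {
    star <- function(nLeaves) {
        leaves <- sprintf("L%d", seq_len(nLeaves))
        buildCoannotationGraph(c("HUB", leaves), xrefs = do.call(rbind,
            lapply(leaves, function(l) xr(paste0("E", l),
                                          paste("HUB", l, sep = ",")))))
    }
    p7 <- pruneHubs(star(7))
    expect_identical(removedFamilies(p7), "HUB")
    expect_identical(nrow(graphEdges(p7)), 0L)
    expect_identical(length(graphNodes(p7)), 7L)

    p6 <- pruneHubs(star(6))
    expect_identical(removedFamilies(p6), character(0))
    expect_identical(nrow(graphEdges(p6)), 6L)

    # two hubs sharing leaves, input degrees 8 and 7: both go in one pass
    # even though removing the first would drop the second below the cutoff
    leaves <- sprintf("L%d", 1:6)
    recs <- rbind(
        do.call(rbind, lapply(leaves, function(l)
            xr(paste0("A", l), paste("H1", l, sep = ",")))),
        do.call(rbind, lapply(leaves, function(l)
            xr(paste0("B", l), paste("H2", l, sep = ",")))),
        xr("AB", "H1,H2"), xr("AX", "H1,X1"))
    g <- buildCoannotationGraph(c("H1", "H2", "X1", leaves), xrefs = recs)
    expect_identical(graphDegree(g)[c("H1", "H2")], c(H1 = 8L, H2 = 7L))
    pg <- pruneHubs(g)
    expect_identical(removedFamilies(pg), c("H1", "H2"))
})

test_that("clusters are components plus singletons and match a union-find oracle", {
    # no edges: all singletons
    g0 <- buildCoannotationGraph(c("A", "B", "C"))
    cl0 <- clusterFamilies(g0, c("A", "B", "C"))
    expect_identical(unname(lengths(clusterMembers(cl0))),
                     c(1L, 1L, 1L))

    g1 <- buildCoannotationGraph(c("A", "B", "C", "D", "E", "F"),
                                 xrefs = rbind(xr("E1", "A,B"),
                                               xr("E2", "B,C"),
                                               xr("E3", "D,E")))
    cl1 <- clusterFamilies(g1)
    expect_identical(canonicalPartition(clusterMembers(cl1)),
                     list(c("A", "B", "C"), c("D", "E"), "F"))

    for (seed in 101:130) {
        rs <- randomRecordSet(seed, nFam = sample(5:50, 1L))
        g <- buildCoannotationGraph(rs$fams, rs$xrefs, rs$operons)
        pg <- pruneHubs(g)
        cl <- clusterFamilies(pg, rs$fams)
        e <- graphEdges(pg)
        expect_identical(canonicalPartition(clusterMembers(cl)),
                         ufPartition(graphNodes(pg), e$from, e$to))
        # partition property over the full candidate set
        expect_setequal(unlist(clusterMembers(cl)),
                        setdiff(rs$fams, removedFamilies(pg)))
    }
})

test_that("record order only relabels clusters and lowering maxDegree never grows the largest cluster", {
    rs <- randomRecordSet(7, nFam = 25)
    g <- buildCoannotationGraph(rs$fams, rs$xrefs, rs$operons)
    cl <- clusterFamilies(pruneHubs(g), rs$fams)

    set.seed(1)
    shuf <- rs$xrefs[sample(nrow(rs$xrefs)), ]
    g2 <- buildCoannotationGraph(rs$fams, shuf, rs$operons)
    cl2 <- clusterFamilies(pruneHubs(g2), rs$fams)
    expect_identical(canonicalPartition(clusterMembers(cl)),
                     canonicalPartition(clusterMembers(cl2)))

    largest <- vapply(6:0, function(d) {
        max(lengths(clusterMembers(
            clusterFamilies(pruneHubs(g, d), rs$fams))))
    }, integer(1))
    expect_true(all(diff(largest) <= 0))
})

test_that("screen + cluster recovers the planted partition and removes exactly the hubs", {
    ref <- simulateReference(randomClusterSpecs(30, seed = 4),
                             nDecoyFamilies = 15, nHubs = 2, hubDegree = 8,
                             seed = 4)
    scr <- screenFamilies(ref$families)
    g <- buildCoannotationGraph(candidateAccessions(scr), ref$xrefs,
                                ref$operons)
    pg <- pruneHubs(g)
    expect_identical(removedFamilies(pg), ref$truth$hubFamilies)
    cl <- clusterFamilies(pg, candidateAccessions(scr))
    expect_identical(canonicalPartition(clusterMembers(cl)),
                     canonicalPartition(ref$truth$trueClusters))
})
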