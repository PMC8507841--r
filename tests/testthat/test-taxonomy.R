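test_that("contig voting descends by strict majority and stops without one", {
    full <- "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales"
    expect_identical(voteContigTaxonomy(rep(full, 3)), full)

    expect_identical(
        voteContigTaxonomy(c("Bacteria;Proteobacteria",
                             "Bacteria;Bacteroidetes")),
        "Bacteria")

    paths <- c(rep("Bacteria;P;C;OrderX", 8), rep("Bacteria;P;C;OrderY", 2))
    expect_identical(voteContigTaxonomy(paths), "Bacteria;P;C;OrderX")

    expect_identical(voteContigTaxonomy(c("", "", "")), "")
    expect_identical(voteContigTaxonomy("Bacteria;P"), "Bacteria;P")
})

test_that("unclassified ORFs do not dilute the vote at deeper ranks", {
    # only the ORFs classified at a rank (and consistent so far) count
    paths <- c("Bacteria", "Bacteria", "Bacteria;P;C;OrderX",
               "Bacteria;P;C;OrderX", "Bacteria;P;C;OrderY")
    expect_identical(voteContigTaxonomy(paths), "Bacteria;P;C;OrderX")
})

test_that("voted paths are always a prefix of some input path", {
    set.seed(12)
    labels <- list(c("Bacteria", "Archaea", "Eukaryota"),
                   c("P1", "P2"), c("C1", "C2"), c("O1", "O2", "O3"))
    for (rep in 1:50) {
        n <- sample(1:8, 1)
        paths <- vapply(seq_len(n), function(i) {
            depth <- sample(0:4, 1)
            paste(vapply(seq_len(depth),
                         function(r) sample(labels[[r]], 1), ""),
                  collapse = ";")
        }, "")
        v <- voteContigTaxonomy(paths)
        if (nzchar(v)) {
            pref <- vapply(paths, startsWith, TRUE, prefix = v)
            expect_true(any(pref))
        } else {
            succeed()
        }
    }
})

test_that("contig taxonomy propagates to every ORF, overriding its own hit", {
    orfs <- data.frame(orf_id = c("o1", "o2", "o3"),
                       contig_id = c("c1", "c1", "c2"),
                       taxonomy = c("Bacteria;P;C;OrderX",
                                    "Archaea;Z",          # conflicting hit
                                    ""))
    voted <- voteAllContigs(orfs)
    expect_identical(unname(voted["c2"]), "")   # vote of one empty path
    paths <- propagateTaxonomy(orfs, voted)
    expect_identical(unname(paths["o2"]), unname(voted["c1"]))
    expect_identical(unname(paths["o3"]), "")

    expect_error(propagateTaxonomy(orfs, voted["c1"]), "without a voted path")
})

mkTensorInput <- function() {
    tpm <- matrix(c(100, 200, 300, 400,
                    50, 60, 70, 80), 2, 4, byrow = TRUE,
                  dimnames = list(c("o1", "o2"), sprintf("s%d", 1:4)))
    cl <- clusterFamilies(buildCoannotationGraph(c("PF00001", "TIGR00001")))
    cl <- annotateClusters(cl, overrides = data.frame(
        id = c("PF00001", "TIGR00001"), category = c("cation", "urea")))
    tab <- clusterTable(cl)
    clOf <- setNames(rep(tab$cluster_id, tab$n_members), unlist(tab$members))
    mapping <- c(o1 = unname(clOf["PF00001"]), o2 = unname(clOf["TIGR00001"]))
    paths <- c(o1 = "Bacteria;P;C;OrderX", o2 = "Bacteria;Cyanobacteria;C;OrderZ")
    list(tpm = tpm, cl = cl, mapping = mapping, paths = paths)
}

test_that("the taxon tensor conserves abundance and supports domain grouping", {
    x <- mkTensorInput()
    tns <- aggregateByTaxon(x$tpm, x$mapping, x$cl, x$paths, rank = "order")
    expect_identical(dimnames(tns)[[1]], c("OrderX", "OrderZ"))
    expect_equal(tns["OrderX", "cation", ], x$tpm["o1", ])
    expect_equal(tns["OrderZ", "urea", ], x$tpm["o2", ])
    # conservation: taxon sums equal the mapped ORF totals per sample
    expect_equal(apply(tns, 3, sum), colSums(x$tpm))

    grp <- aggregateByTaxon(x$tpm, x$mapping, x$cl, x$paths, grouping = TRUE)
    expect_setequal(dimnames(grp)[[1]], c("Bacteria", "Cyanobacteria"))
    # Bacteria group + Cyanobacteria group = unsubtracted Bacteria domain
    unsub <- apply(tns, 3, sum)
    expect_equal(apply(grp["Bacteria", , , drop = FALSE], 3, sum) +
                 apply(grp["Cyanobacteria", , , drop = FALSE], 3, sum),
                 unsub)
})

test_that("domain grouping partitions all lineages", {
    paths <- c("Archaea;X", "Bacteria;Proteobacteria",
               "Bacteria;Cyanobacteria;Syn", "Eukaryota;Chlorophyta",
               "Viruses;Caudovirales", "", "SomethingElse;Y")
    expect_identical(domainGroup(paths),
                     c("Archaea", "Bacteria", "Cyanobacteria",
                       "Picoeukaryota", "Viruses", "Unclassified",
                       "Unclassified"))
})

test_that("taxon richness per category equals a brute-force count", {
    set.seed(3)
    tns <- array(rexp(5 * 9 * 4) * rbinom(180, 1, 0.5),
                 dim = c(5, 9, 4),
                 dimnames = list(sprintf("T%d", 1:5), substrateCategories(),
                                 sprintf("s%d", 1:4)))
    r <- taxonRichnessPerCategory(tns, minAbundance = 0.1)
    for (c in substrateCategories()) {
        for (s in 1:4) {
            expect_identical(r$perSample[c, s],
                             sum(tns[, c, s] > 0.1))
        }
    }
    expect_equal(r$mean, rowMeans(r$perSample))
    none <- taxonRichnessPerCategory(tns, minAbundance = max(tns))
    expect_true(all(none$perSample == 0))
})

test_that("importer richness masks taxa below the 90% quantile or with <=500 reads", {
    x <- mkTensorInput()
    tab <- clusterTable(x$cl)
    tab$transport_class <- c("importer", "importer")
    cl <- new("TransportClusterSet", clusters = tab)
    counts <- matrix(600, 2, 4, dimnames = dimnames(x$tpm))

    # single taxon: always its own quantile, visible when reads suffice
    one <- importerRichnessPerTaxon(
        x$tpm["o1", , drop = FALSE], counts["o1", , drop = FALSE],
        x$mapping["o1"], cl, x$paths, minReads = 0)
    expect_true(all(one$visible))
    expect_true(all(one$richness == 1))

    # 499 mapped reads: masked regardless of the quantile
    c499 <- counts
    c499["o1", ] <- 499
    r <- importerRichnessPerTaxon(
        x$tpm["o1", , drop = FALSE], c499["o1", , drop = FALSE],
        x$mapping["o1"], cl, x$paths)
    expect_false(any(r$visible))

    # ten taxa with distinct totals: visibility matches the quantile oracle
    set.seed(9)
    tpm10 <- matrix(sample(1:1000, 10), 10, 1,
                    dimnames = list(sprintf("o%02d", 1:10), "s1"))
    counts10 <- matrix(1000, 10, 1, dimnames = dimnames(tpm10))
    paths10 <- setNames(sprintf("Bacteria;P;C;Order%02d", 1:10),
                        rownames(tpm10))
    map10 <- setNames(rep(clusterIds(cl)[1], 10), rownames(tpm10))
    r10 <- importerRichnessPerTaxon(tpm10, counts10, map10, cl, paths10)
    q <- quantile(r10$totals[, 1], 0.9, type = 7)
    expect_identical(unname(r10$visible[, 1]),
                     unname(r10$totals[, 1] >= q))
})
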