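test_that("the reference generator is deterministic and validates its inputs", {
    specs <- randomClusterSpecs(8, seed = 6)
    a <- simulateReference(specs, nDecoyFamilies = 5, nHubs = 1,
                           hubDegree = 7, seed = 13)
    b <- simulateReference(specs, nDecoyFamilies = 5, nHubs = 1,
                           hubDegree = 7, seed = 13)
    expect_identical(a, b)

    expect_error(simulateReference(list()), "no cluster specs")
    expect_error(simulateReference(specs, nDecoyFamilies = -1),
                 "non-negative")
    expect_error(simulateReference(specs, nHubs = 1, hubDegree = 6),
                 ">= 7")
    expect_error(simulateReference(c(specs, specs)), "duplicate")
    expect_error(clusterSpec("X", 0, "cation"), "positive")
})

test_that("planted clusters of sizes (1,2,3) yield six families wired exactly within clusters", {
    specs <- list(clusterSpec("C1", 1, "cation"),
                  clusterSpec("C2", 2, "urea"),
                  clusterSpec("C3", 3, "anion"))
    ref <- simulateReference(specs, seed = 1)
    expect_identical(nrow(ref$families), 6L)
    expect_identical(lengths(ref$truth$trueClusters),
                     c(C1 = 1L, C2 = 2L, C3 = 3L))

    # every record links members of exactly one planted cluster, except the
    # unreviewed cross-cluster noise, which must contribute no edges
    fam2cl <- ref$truth$familyToCluster
    recs <- c(strsplit(ref$xrefs$accessions[ref$xrefs$reviewed], ","),
              strsplit(ref$operons$accessions, ","))
    for (r in recs)
        expect_identical(length(unique(fam2cl[r])), 1L)

    # transporter descriptions carry a screen keyword; decoys never do
    ref2 <- simulateReference(specs, nDecoyFamilies = 12, seed = 2)
    scr <- screenFamilies(ref2$families)
    expect_identical(candidateAccessions(scr), ref2$truth$trueCandidates)
    expect_length(intersect(candidateAccessions(scr),
                            ref2$truth$decoyFamilies), 0)
})

test_that("hub families get the requested number of distinct partners", {
    ref <- simulateReference(randomClusterSpecs(10, seed = 3), nHubs = 1,
                             hubDegree = 7, seed = 7)
    hub <- ref$truth$hubFamilies
    expect_length(hub, 1)
    recs <- strsplit(ref$xrefs$accessions[ref$xrefs$reviewed], ",")
    partners <- unique(unlist(lapply(recs, function(r) {
        if (hub %in% r) setdiff(r, hub) else character(0)
    })))
    expect_gte(length(partners), 7)
})

test_that("community counts are multinomial draws of the requested depth", {
    specs <- list(clusterSpec("C1", 2, "cation"))
    ref <- simulateReference(specs, seed = 1)
    taxa <- list(taxonSpec("Bacteria;P;C;OrderA", 150, 30, 1,
                           c(cation = 1)))
    spec <- communitySpec(taxa, nSamplesMg = 4, nSamplesMt = 2,
                          mgDays = c(80, 150, 220, 300), mtDays = c(150, 220),
                          depth = 1000, decoyFraction = 0)
    comm <- simulateCommunity(spec, ref$truth, seed = 3)
    counts <- SummarizedExperiment::assay(comm$mg, "counts")
    expect_identical(unname(colSums(counts)), rep(1000, 4))
    # single taxon, single category: everything lands on its ORFs
    expect_true(all(rownames(counts) %in% names(comm$orfToCluster)))

    same <- simulateCommunity(spec, ref$truth, seed = 3)
    expect_identical(SummarizedExperiment::assay(same$mg, "counts"), counts)

    expect_error(communitySpec(list()), "empty")
    expect_error(communitySpec(taxa, decoyFraction = 1), "decoyFraction")
})

test_that("Gaussian peaks order the counts: each taxon dominates near its own peak", {
    specs <- list(clusterSpec("C1", 1, "cation"),
                  clusterSpec("C2", 1, "urea"))
    ref <- simulateReference(specs, seed = 1)
    taxa <- list(taxonSpec("Bacteria;P;C;OrderA", 100, 20, 1, c(cation = 1)),
                 taxonSpec("Bacteria;P;C;OrderB", 250, 20, 1, c(urea = 1)))
    spec <- communitySpec(taxa, nSamplesMg = 2, nSamplesMt = 2,
                          mgDays = c(100, 250), mtDays = c(100, 250),
                          depth = 2000, decoyFraction = 0)
    for (seed in 1:20) {
        comm <- simulateCommunity(spec, ref$truth, seed = seed)
        counts <- SummarizedExperiment::assay(comm$mg, "counts")
        byTaxon <- rowsum(counts, comm$orfToTaxon[rownames(counts)])
        expect_gt(byTaxon["OrderA", 1], byTaxon["OrderA", 2])
        expect_gt(byTaxon["OrderB", 2], byTaxon["OrderB", 1])
    }
})

test_that("planted substrate profiles are recovered within multinomial error", {
    ref <- simulateReference(coveringClusterSpecs(), nDecoyFamilies = 10,
                             seed = 5)
    profile <- c(cation = 0.5, amino_acids_peptides_ammonium = 0.27,
                 carbohydrate = 0.23)
    taxa <- list(taxonSpec("Bacteria;P;C;OrderA", 150, 40, 1, profile))
    spec <- communitySpec(taxa, nSamplesMg = 6, nSamplesMt = 2,
                          mgDays = seq(100, 200, 20), mtDays = c(100, 120),
                          depth = 1e5, decoyFraction = 0.1)
    comm <- simulateCommunity(spec, ref$truth, seed = 11)
    res <- runTransporterPipeline(ref, comm)
    tns <- res$tensor$MG
    pooled <- apply(tns["OrderA", , ], 1, sum)
    est <- pooled / sum(pooled)
    full <- setNames(numeric(9), substrateCategories())
    full[names(profile)] <- profile
    expect_lt(max(abs(est - full)), 0.03)
})

test_that("environment variables track their linked taxon monotonically", {
    specs <- list(clusterSpec("C1", 1, "cation"), clusterSpec("C2", 1, "urea"))
    ref <- simulateReference(specs, seed = 1)
    taxa <- list(taxonSpec("Bacteria;P;C;OrderA", 120, 30, 1, c(cation = 1)),
                 taxonSpec("Bacteria;P;C;OrderB", 260, 30, 1, c(urea = 1)))
    spec <- communitySpec(taxa, nSamplesMg = 12, nSamplesMt = 2,
                          mgDays = round(seq(60, 340, length.out = 12)),
                          mtDays = c(100, 200), depth = 1e4,
                          envLink = list(
                              temperature = list(taxon = "OrderA", sign = 1),
                              no3 = list(taxon = "OrderA", sign = -1)),
                          envNoiseSd = 0.01)
    comm <- simulateCommunity(spec, ref$truth, seed = 2)
    counts <- SummarizedExperiment::assay(comm$mg, "counts")
    shareA <- colSums(counts[comm$orfToTaxon[rownames(counts)] == "OrderA",
                             , drop = FALSE]) / colSums(counts)
    expect_gt(cor(comm$env$temperature, shareA, method = "spearman"), 0.8)
    expect_lt(cor(comm$env$no3, shareA, method = "spearman"), -0.8)
})
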