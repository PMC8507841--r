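#' @include AllClasses.R
NULL

#' Specification of one planted transport cluster
#'
#' @param clusterId unique identifier of the planted cluster.
#' @param nFamilies number of protein families (subunits), >= 1.
#' @param substrateCategory one of [substrateCategories()].
#' @param transportClass one of [transportClasses()].
#' @param secretionType secretion type for toxin exporters; one of
#'   [secretionTypes()], drawn later if NA.
#' @return A validated list of class \code{ClusterSpec}.
#' @export
clusterSpec <- function(clusterId, nFamilies, substrateCategory,
                        transportClass = "importer",
                        secretionType = NA_character_) {
    if (!is.numeric(nFamilies) || nFamilies < 1)
        stop("nFamilies must be a positive integer")
    substrateCategory <- match.arg(substrateCategory, substrateCategories())
    transportClass <- match.arg(transportClass, transportClasses())
    if (!is.na(secretionType))
        secretionType <- match.arg(secretionType, secretionTypes())
    structure(list(clusterId = as.character(clusterId),
                   nFamilies = as.integer(nFamilies),
                   substrateCategory = substrateCategory,
                   transportClass = transportClass,
                   secretionType = secretionType),
              class = "ClusterSpec")
}

#' Draw random cluster specifications
#'
#' Convenience generator of \code{n} planted cluster specs with sizes
#' uniform on 1..\code{maxFamilies} and categories/classes sampled from
#' the closed vocabularies (importers weighted highest, matching the
#' predominance of importers among annotated transporters).
#'
#' @param n number of clusters.
#' @param maxFamilies maximal subunit count, default 4.
#' @param seed optional RNG seed.
#' @return List of \code{ClusterSpec}.
#' @export
randomClusterSpecs <- function(n, maxFamilies = 4L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    sizes <- sample.int(maxFamilies, n, replace = TRUE)
    cats <- sample(substrateCategories(), n, replace = TRUE)
    classes <- sample(transportClasses(), n, replace = TRUE,
                      prob = c(0.5, 0.15, 0.15, 0.1, 0.1))
    lapply(seq_len(n), function(i) {
        clusterSpec(sprintf("PC%03d", i), sizes[i], cats[i], classes[i])
    })
}

## Deterministic description text carrying (a) a transporter screen
## keyword, (b) the class keyword the classifier keys on, and (c) for
## toxin exporters the secretion-type token.
.descriptionFor <- function(class, category, secretion, j) {
    catTxt <- gsub("_", " ", category)
    roman <- c(T1 = "I", T2 = "II", T3 = "III", T5 = "V", T6 = "VI",
               other = "unclassified")
    switch(class,
        importer = sprintf(
            "%s uptake transporter, substrate-binding subunit %d",
            catTxt, j),
        exporter_utility = sprintf(
            "%s export system permease, efflux component %d", catTxt, j),
        exporter_toxin = sprintf(
            "toxin secretion transport protein %d, type %s secretion system",
            j, roman[[secretion]]),
        metal = sprintf(
            "cobalt-zinc-cadmium metal ion efflux transporter subunit %d", j),
        other = sprintf(
            "uncharacterised membrane transport protein %d", j))
}

.decoyDescriptions <- c(
    "ribosomal protein, large subunit",
    "transcription initiation factor sigma",
    "DNA gyrase subunit B",
    "two-component histidine kinase sensor",
    "chaperonin GroEL homolog",
    "cell division protein FtsZ",
    "glyceraldehyde-3-phosphate dehydrogenase",
    "tRNA ligase, class II")

#' Simulate a reference protein-family database with planted clusters
#'
#' Generates the family metadata, reviewed cross-reference entries and
#' operons that the screening and clustering stages consume, with known
#' ground truth. Each planted multi-family cluster is wired as a chain of
#' co-annotations (alternating cross-reference and operon records), so its
#' members form one connected component and share no record with any other
#' cluster. Hub families emulate generic domains (e.g. a ubiquitous
#' ATP-binding cassette): each is co-annotated with \code{hubDegree}
#' distinct partner families drawn across clusters so it exceeds the
#' degree-6 pruning cutoff. Decoy families carry descriptions free of any
#' screen keyword. When at least two clusters exist, two \emph{unreviewed}
#' cross-cluster entries are emitted as negative evidence that the
#' reviewed-only filter must ignore. TIGRFAM-role and GO hint tables
#' consistent with the planted substrate categories are returned so
#' annotation recovery can be tested.
#'
#' @param clusterSpecs list of [clusterSpec()].
#' @param nDecoyFamilies number of non-transporter families, default 0.
#' @param nHubs number of hub families, default 0.
#' @param hubDegree co-annotation partners per hub, >= 7 so hubs exceed
#'   the pruning cutoff.
#' @param seed RNG seed.
#' @return List with \code{families}, \code{xrefs}, \code{operons},
#'   \code{roles}, \code{goMap} (data.frames) and \code{truth}, a list
#'   carrying \code{trueClusters} (partition of the transporter families
#'   minus hubs), \code{hubFamilies}, \code{trueCandidates} (all
#'   transporter accessions incl. hubs), \code{decoyFamilies},
#'   \code{familyToCluster} and \code{clusterInfo} (per-cluster category,
#'   class, secretion type).
#' @export
simulateReference <- function(clusterSpecs, nDecoyFamilies = 0L,
                              nHubs = 0L, hubDegree = 7L, seed = 1L) {
    if (length(clusterSpecs) == 0L) stop("no cluster specs")
    if (nDecoyFamilies < 0L || nHubs < 0L)
        stop("counts must be non-negative")
    if (nHubs > 0L && hubDegree < 7L)
        stop("hubDegree must be >= 7 so hubs exceed the pruning cutoff")
    ids <- vapply(clusterSpecs, `[[`, "", "clusterId")
    if (anyDuplicated(ids)) stop("duplicate cluster ids in specs")
    set.seed(seed)

    nextAcc <- local({
        counters <- c(TIGRFAM = 0L, COG = 0L, PFAM = 0L)
        function(db) {
            counters[db] <<- counters[db] + 1L
            switch(db,
                TIGRFAM = sprintf("TIGR%05d", counters[db]),
                COG = sprintf("COG%04d", counters[db]),
                PFAM = sprintf("PF%05d", counters[db]))
        }
    })

    fam <- list()
    trueClusters <- list()
    info <- list()
    for (spec in clusterSpecs) {
        k <- spec$nFamilies
        dbs <- c("TIGRFAM", rep(c("COG", "PFAM"), length.out = max(0L, k - 1L)))
        secretion <- spec$secretionType
        if (spec$transportClass == "exporter_toxin" && is.na(secretion))
            secretion <- sample(setdiff(secretionTypes(), "other"), 1L)
        members <- character(k)
        for (j in seq_len(k)) {
            acc <- nextAcc(dbs[j])
            members[j] <- acc
            fam[[length(fam) + 1L]] <- data.frame(
                accession = acc, source_db = dbs[j],
                name = sprintf("%s_%s", tolower(spec$clusterId), letters[j]),
                description = .descriptionFor(spec$transportClass,
                                              spec$substrateCategory,
                                              secretion, j),
                stringsAsFactors = FALSE)
        }
        trueClusters[[spec$clusterId]] <- sort(members)
        info[[length(info) + 1L]] <- data.frame(
            cluster_id = spec$clusterId,
            substrate_category = spec$substrateCategory,
            transport_class = spec$transportClass,
            secretion_type = if (spec$transportClass == "exporter_toxin")
                secretion else NA_character_,
            n_families = k, stringsAsFactors = FALSE)
    }

    hubs <- character(nHubs)
    for (h in seq_len(nHubs)) {
        acc <- nextAcc("PFAM")
        hubs[h] <- acc
        fam[[length(fam) + 1L]] <- data.frame(
            accession = acc, source_db = "PFAM",
            name = sprintf("hub_%d", h),
            description = "ATP-binding cassette domain, generic transport energiser",
            stringsAsFactors = FALSE)
    }

    decoys <- character(nDecoyFamilies)
    for (d in seq_len(nDecoyFamilies)) {
        db <- c("PFAM", "TIGRFAM", "COG")[(d - 1L) %% 3L + 1L]
        acc <- nextAcc(db)
        decoys[d] <- acc
        fam[[length(fam) + 1L]] <- data.frame(
            accession = acc, source_db = db,
            name = sprintf("dec_%d", d),
            description = paste(.decoyDescriptions[(d - 1L) %%
                length(.decoyDescriptions) + 1L], d),
            stringsAsFactors = FALSE)
    }
    families <- do.call(rbind, fam)
    if (anyDuplicated(families$accession))
        stop("generation error: duplicate accessions")

    ## chain links within clusters: odd links via reviewed xrefs, even via
    ## operons, so both evidence channels are exercised
    xrefRows <- list()
    operonRows <- list()
    nx <- 0L
    no <- 0L
    for (cid in names(trueClusters)) {
        m <- trueClusters[[cid]]
        if (length(m) < 2L) next
        for (j in seq_len(length(m) - 1L)) {
            pair <- paste(m[j], m[j + 1L], sep = ",")
            if (j %% 2L == 1L) {
                nx <- nx + 1L
                xrefRows[[length(xrefRows) + 1L]] <- data.frame(
                    entry_id = sprintf("UP%06d", nx), reviewed = TRUE,
                    accessions = pair, stringsAsFactors = FALSE)
            } else {
                no <- no + 1L
                operonRows[[length(operonRows) + 1L]] <- data.frame(
                    operon_id = sprintf("OPR%05d", no),
                    accessions = pair, stringsAsFactors = FALSE)
            }
        }
    }

    allMembers <- unlist(trueClusters, use.names = FALSE)
    for (h in hubs) {
        partners <- sample(allMembers, min(hubDegree, length(allMembers)))
        if (length(partners) < hubDegree)
            stop("not enough planted families for the requested hub degree")
        for (p in partners) {
            nx <- nx + 1L
            xrefRows[[length(xrefRows) + 1L]] <- data.frame(
                entry_id = sprintf("UP%06d", nx), reviewed = TRUE,
                accessions = paste(h, p, sep = ","),
                stringsAsFactors = FALSE)
        }
    }

    ## unreviewed cross-cluster noise: must contribute no edges
    if (length(trueClusters) >= 2L) {
        for (i in 1:2) {
            pick <- sample(names(trueClusters), 2L)
            nx <- nx + 1L
            xrefRows[[length(xrefRows) + 1L]] <- data.frame(
                entry_id = sprintf("UP%06d", nx), reviewed = FALSE,
                accessions = paste(trueClusters[[pick[1L]]][1L],
                                   trueClusters[[pick[2L]]][1L], sep = ","),
                stringsAsFactors = FALSE)
        }
    }

    xrefs <- if (length(xrefRows)) do.call(rbind, xrefRows) else
        data.frame(entry_id = character(), reviewed = logical(),
                   accessions = character())
    operons <- if (length(operonRows)) do.call(rbind, operonRows) else
        data.frame(operon_id = character(), accessions = character())

    clusterInfo <- do.call(rbind, info)
    catOf <- setNames(clusterInfo$substrate_category, clusterInfo$cluster_id)
    fam2cl <- setNames(rep(names(trueClusters), lengths(trueClusters)),
                       unlist(trueClusters, use.names = FALSE))
    isTigr <- setNames(families$source_db == "TIGRFAM", families$accession)
    memberAcc <- names(fam2cl)
    roles <- data.frame(
        accession = memberAcc[isTigr[memberAcc]],
        category = unname(catOf[fam2cl[memberAcc[isTigr[memberAcc]]]]),
        stringsAsFactors = FALSE)
    goMap <- data.frame(
        accession = memberAcc,
        category = unname(catOf[fam2cl[memberAcc]]),
        stringsAsFactors = FALSE)

    truth <- list(
        trueClusters = trueClusters,
        hubFamilies = sort(hubs),
        trueCandidates = sort(c(allMembers, hubs)),
        decoyFamilies = sort(decoys),
        familyToCluster = fam2cl,
        clusterInfo = clusterInfo)
    list(families = families, xrefs = xrefs, operons = operons,
         roles = roles, goMap = goMap, truth = truth)
}
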