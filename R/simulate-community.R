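#' @include AllClasses.R
NULL

#' Specification of one planted taxon
#'
#' A taxon's seasonal trajectory is a Gaussian bump in day-of-year:
#' expected relative abundance proportional to
#' \code{amplitude * exp(-(day - peakDay)^2 / (2 * peakWidth^2))}
#' (computed on circular day-of-year distance so multi-year panels reuse
#' the seasonal cycle). Its transporter repertoire is split across the
#' nine substrate categories by a fixed profile, encoding the observation
#' that per-taxon substrate specificity stays stable while total abundance
#' rises and falls.
#'
#' @param taxonPath semicolon lineage down to rank order (>= 4 labels).
#' @param peakDay day of year of the abundance peak.
#' @param peakWidth s.d. of the Gaussian peak, in days (> 0).
#' @param amplitude positive peak height.
#' @param substrateProfile named non-negative vector over (a subset of)
#'   [substrateCategories()], summing to 1 within 1e-9.
#' @return A validated list of class \code{TaxonSpec}.
#' @export
taxonSpec <- function(taxonPath, peakDay, peakWidth, amplitude = 1,
                      substrateProfile) {
    parts <- splitTaxonomyPath(taxonPath)[[1L]]
    if (length(parts) < 4L)
        stop("taxonPath must reach rank order (4 labels)")
    if (peakWidth <= 0) stop("peakWidth must be positive")
    if (amplitude <= 0) stop("amplitude must be positive")
    bad <- setdiff(names(substrateProfile), substrateCategories())
    if (length(bad))
        stop("unknown categories in substrateProfile: ",
             paste(bad, collapse = ", "))
    if (any(substrateProfile < 0))
        stop("substrateProfile entries must be non-negative")
    if (abs(sum(substrateProfile) - 1) > 1e-9)
        stop("substrateProfile must sum to 1")
    profile <- setNames(numeric(length(substrateCategories())),
                        substrateCategories())
    profile[names(substrateProfile)] <- substrateProfile
    structure(list(taxonPath = paste(parts, collapse = ";"),
                   order = parts[4L], peakDay = peakDay,
                   peakWidth = peakWidth, amplitude = amplitude,
                   profile = profile),
              class = "TaxonSpec")
}

#' Specification of a simulated community and sampling design
#'
#' Defaults emulate a temperate coastal time series: 33 metagenome (MG)
#' samples roughly biweekly from early spring to early winter, 25
#' metatranscriptome (MT) samples monthly over a longer span, four of
#' which fall on MG sampling dates so gene-abundance/expression coupling
#' can be assessed on matched dates.
#'
#' @param taxa list of [taxonSpec()]; order labels must be unique.
#' @param nSamplesMg,nSamplesMt panel sizes.
#' @param mgDays,mtDays sampling days (numeric, day 1 = Jan 1 of year 1;
#'   values beyond 365 wrap seasonally). Defaults are derived from the
#'   panel sizes with four shared MG/MT dates.
#' @param depth expected reads per sample (multinomial draw size).
#' @param orfsPerClusterPerTaxon ORFs generated per (taxon, cluster).
#' @param orfLengthRange bp interval for uniform ORF lengths; lengths vary
#'   so TPM differs from the raw count proportion.
#' @param decoyFraction fraction of ORFs that are non-transporter decoys,
#'   in [0, 1).
#' @param envLink named list mapping an environmental variable name to
#'   \code{list(taxon = <order label>, sign = +1/-1)}.
#' @param envNoiseSd s.d. of the noise added to linked env variables.
#' @param mtExpressionMultiplier optional named per-taxon expression
#'   multiplier applied to the MT composition (default 1 for all).
#' @param orfsPerContig ORFs per contig in the synthetic assembly.
#' @return A validated list of class \code{CommunitySpec}.
#' @export
communitySpec <- function(taxa, nSamplesMg = 33L, nSamplesMt = 25L,
                          mgDays = NULL, mtDays = NULL, depth = 1e5,
                          orfsPerClusterPerTaxon = 2L,
                          orfLengthRange = c(300L, 3000L),
                          decoyFraction = 0.1, envLink = list(),
                          envNoiseSd = 0.1,
                          mtExpressionMultiplier = NULL,
                          orfsPerContig = 3L) {
    if (length(taxa) == 0L) stop("taxa list is empty")
    if (!all(vapply(taxa, inherits, TRUE, "TaxonSpec")))
        stop("taxa must be a list of taxonSpec() objects")
    orders <- vapply(taxa, `[[`, "", "order")
    if (anyDuplicated(orders)) stop("taxon order labels must be unique")
    if (depth <= 0) stop("depth must be positive")
    if (decoyFraction < 0 || decoyFraction >= 1)
        stop("decoyFraction must be in [0, 1)")
    if (is.null(mgDays))
        mgDays <- round(seq(60, 355, length.out = nSamplesMg))
    if (is.null(mtDays)) {
        nShared <- min(4L, nSamplesMt, length(mgDays))
        sharedIdx <- unique(pmax(1L, round(
            seq(0.3, 0.9, length.out = nShared) * length(mgDays))))
        monthly <- round(seq(160, by = 30, length.out = 3L * nSamplesMt))
        monthly <- setdiff(monthly, mgDays[sharedIdx])
        mtDays <- sort(c(mgDays[sharedIdx],
                         monthly[seq_len(nSamplesMt - length(sharedIdx))]))
    }
    names(envLink) <- as.character(names(envLink))
    structure(list(taxa = taxa, orders = orders,
                   mgDays = mgDays[seq_len(min(nSamplesMg, length(mgDays)))],
                   mtDays = mtDays[seq_len(min(nSamplesMt, length(mtDays)))],
                   depth = depth,
                   orfsPerClusterPerTaxon = as.integer(orfsPerClusterPerTaxon),
                   orfLengthRange = as.integer(orfLengthRange),
                   decoyFraction = decoyFraction, envLink = envLink,
                   envNoiseSd = envNoiseSd,
                   mtExpressionMultiplier = mtExpressionMultiplier,
                   orfsPerContig = as.integer(orfsPerContig)),
              class = "CommunitySpec")
}

## Circular day-of-year distance keeps multi-year panels seasonal.
.gaussWeight <- function(day, peakDay, peakWidth, amplitude) {
    d <- ((day - peakDay + 182.5) %% 365) - 182.5
    amplitude * exp(-d^2 / (2 * peakWidth^2))
}

#' Simulate MG/MT count matrices for a planted community
#'
#' Builds a synthetic ORF catalogue on contigs (every taxon contributes
#' \code{orfsPerClusterPerTaxon} ORFs to each planted cluster of every
#' category in its substrate profile, plus decoy ORFs hitting
#' non-transporter families), then draws one multinomial read sample of
#' size \code{depth} per sampling date. The expected TPM share of taxon t
#' in a sample is its normalised Gaussian weight at that day, split across
#' substrate categories by its profile; per-ORF read probabilities are the
#' intended TPM shares multiplied by ORF length, so TPM normalisation
#' recovers the planted composition. MT counts are drawn independently
#' from the same composition (optionally rescaled per taxon by the
#' expression multiplier). Environmental variables linked to a taxon track
#' that taxon's trajectory (scaled to [0, 1], signed) plus Gaussian noise;
#' unlinked variables are pure noise.
#'
#' @param spec a [communitySpec()].
#' @param truth ground truth from [simulateReference()].
#' @param seed RNG seed.
#' @return List with \code{orfs} (data.frame: orf_id, contig_id, length,
#'   families, taxonomy), \code{mg}/\code{mt}
#'   (\linkS4class{SummarizedExperiment}s with a \code{counts} assay),
#'   \code{samples}, \code{env},
#'   \code{expectedCompositionMG}/\code{expectedCompositionMT}
#'   (taxon x category x sample arrays of expected relative abundance),
#'   \code{orfToCluster} and \code{orfToTaxon}.
#' @export
simulateCommunity <- function(spec, truth, seed = 1L) {
    stopifnot(inherits(spec, "CommunitySpec"))
    set.seed(seed)
    cats <- substrateCategories()
    info <- truth$clusterInfo
    clustersByCat <- split(info$cluster_id,
                           factor(info$substrate_category, cats))

    ## ORF catalogue -----------------------------------------------------
    rows <- list()
    mass <- numeric()        # intended TPM share within (taxon); sums to 1
    orfTaxon <- character()
    orfCluster <- character()
    n <- 0L
    for (tx in spec$taxa) {
        useCats <- names(tx$profile)[tx$profile > 0]
        for (cc in useCats) {
            cl <- clustersByCat[[cc]]
            if (length(cl) == 0L)
                stop("no planted cluster for category '", cc, "'")
            for (k in cl) {
                members <- truth$trueClusters[[k]]
                for (j in seq_len(spec$orfsPerClusterPerTaxon)) {
                    n <- n + 1L
                    rows[[n]] <- data.frame(
                        orf_id = sprintf("ORF%06d", n),
                        length = sample(spec$orfLengthRange[1L]:
                                        spec$orfLengthRange[2L], 1L),
                        families = sample(members, 1L),
                        taxonomy = tx$taxonPath,
                        stringsAsFactors = FALSE)
                    mass <- c(mass, tx$profile[[cc]] /
                              (length(cl) * spec$orfsPerClusterPerTaxon))
                    orfTaxon <- c(orfTaxon, tx$order)
                    orfCluster <- c(orfCluster, k)
                }
            }
        }
    }
    orfs <- do.call(rbind, rows)
    nT <- nrow(orfs)

    nD <- round(spec$decoyFraction / (1 - spec$decoyFraction) * nT)
    if (nD > 0L) {
        if (length(truth$decoyFamilies) == 0L)
            stop("decoyFraction > 0 but the reference has no decoy families")
        dTaxa <- spec$taxa[((seq_len(nD) - 1L) %% length(spec$taxa)) + 1L]
        decoyDf <- data.frame(
            orf_id = sprintf("ORF%06d", nT + seq_len(nD)),
            length = sample(spec$orfLengthRange[1L]:spec$orfLengthRange[2L],
                            nD, replace = TRUE),
            families = sample(truth$decoyFamilies, nD, replace = TRUE),
            taxonomy = vapply(dTaxa, `[[`, "", "taxonPath"),
            stringsAsFactors = FALSE)
        orfs <- rbind(orfs, decoyDf)
        orfTaxon <- c(orfTaxon, vapply(dTaxa, `[[`, "", "order"))
        orfCluster <- c(orfCluster, rep(NA_character_, nD))
    }

    ## contigs: chunk each taxon's ORFs (transporter and decoy separately)
    contig <- character(nrow(orfs))
    isDecoy <- c(rep(FALSE, nT), rep(TRUE, max(0L, nD)))
    for (t in unique(orfTaxon)) {
        for (dec in c(FALSE, TRUE)) {
            idx <- which(orfTaxon == t & isDecoy == dec)
            if (length(idx) == 0L) next
            chunk <- ceiling(seq_along(idx) / spec$orfsPerContig)
            contig[idx] <- sprintf("CTG_%s%s_%04d", t,
                                   if (dec) "_dec" else "", chunk)
        }
    }
    orfs$contig_id <- contig
    orfs <- orfs[, c("orf_id", "contig_id", "length", "families",
                     "taxonomy")]

    ## per-taxon seasonal weights ---------------------------------------
    weightsAt <- function(days, mult = NULL) {
        w <- vapply(spec$taxa, function(tx) {
            m <- if (is.null(mult)) 1 else
                if (tx$order %in% names(mult)) mult[[tx$order]] else 1
            m * .gaussWeight(days, tx$peakDay, tx$peakWidth, tx$amplitude)
        }, numeric(length(days)))
        w <- matrix(w, nrow = length(days))
        colnames(w) <- spec$orders
        w + 1e-12                              # numeric floor, winter samples
    }

    drawCounts <- function(days, ids, mult = NULL) {
        w <- weightsAt(days, mult)
        share <- w / rowSums(w)
        counts <- matrix(0L, nrow(orfs), length(days),
                         dimnames = list(orfs$orf_id, ids))
        expComp <- array(0, dim = c(length(spec$orders), length(cats),
                                    length(days)),
                         dimnames = list(taxon = sort(spec$orders),
                                         category = cats, sample = ids))
        tMass <- if (nD > 0L) 1 - spec$decoyFraction else 1
        for (s in seq_along(days)) {
            m <- mass * share[s, orfTaxon[seq_len(nT)]] * tMass
            if (nD > 0L) m <- c(m, rep(spec$decoyFraction / nD, nD))
            prob <- m * orfs$length
            counts[, s] <- stats::rmultinom(1L, size = spec$depth,
                                            prob = prob)
            for (tx in spec$taxa)
                expComp[tx$order, , s] <- share[s, tx$order] * tx$profile
        }
        list(counts = counts, expComp = expComp)
    }

    mgIds <- sprintf("MG_%02d", seq_along(spec$mgDays))
    mtIds <- sprintf("MT_%02d", seq_along(spec$mtDays))
    mg <- drawCounts(spec$mgDays, mgIds)
    mt <- drawCounts(spec$mtDays, mtIds, spec$mtExpressionMultiplier)

    rd <- DataFrame(contig_id = orfs$contig_id, length = orfs$length,
                    families = orfs$families, taxonomy = orfs$taxonomy,
                    row.names = orfs$orf_id)
    makeSe <- function(counts, ids, days, tag) {
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts), rowData = rd,
            colData = DataFrame(sample_id = ids, date = days,
                                dataset = tag, row.names = ids))
    }
    samples <- data.frame(
        sample_id = c(mgIds, mtIds),
        date = c(spec$mgDays, spec$mtDays),
        dataset = rep(c("MG", "MT"), c(length(mgIds), length(mtIds))),
        stringsAsFactors = FALSE)

    ## environment table (measured on the MG panel) ----------------------
    envVars <- c("temperature", "salinity", "chla", "doc", "nh4", "no3",
                 "po4", "sio4", "tot_n")
    wMg <- weightsAt(spec$mgDays)
    shareMg <- wMg / rowSums(wMg)
    env <- data.frame(row.names = mgIds)
    for (v in envVars) {
        if (v %in% names(spec$envLink)) {
            link <- spec$envLink[[v]]
            tr <- shareMg[, link$taxon]
            rng <- range(tr)
            z <- if (diff(rng) > 0) (tr - rng[1L]) / diff(rng) else
                rep(0.5, length(tr))
            env[[v]] <- link$sign * z +
                stats::rnorm(length(tr), 0, spec$envNoiseSd)
        } else {
            env[[v]] <- stats::rnorm(length(mgIds))
        }
    }

    list(orfs = orfs,
         mg = makeSe(mg$counts, mgIds, spec$mgDays, "MG"),
         mt = makeSe(mt$counts, mtIds, spec$mtDays, "MT"),
         samples = samples, env = env,
         expectedCompositionMG = mg$expComp,
         expectedCompositionMT = mt$expComp,
         orfToCluster = setNames(orfCluster, orfs$orf_id)[
             !is.na(orfCluster)],
         orfToTaxon = setNames(orfTaxon, orfs$orf_id))
}
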