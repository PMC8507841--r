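#' @include AllGenerics.R
NULL

#' @describeIn tpmNormalize TPM-normalise a counts matrix. For each sample
#'   (column), counts are divided by the ORF length in bp to give a
#'   per-base rate, and rates are rescaled so the column sums to one
#'   million: \code{tpm(i,s) = 1e6 * (c(i,s)/L(i)) / sum_j (c(j,s)/L(j))}.
#'   Columns with zero depth stay all-zero with a warning. Rescaling all
#'   counts of a sample by a constant leaves its TPM column unchanged.
#' @param lengths numeric vector of ORF lengths in bp, named by ORF id or
#'   parallel to the rows.
#' @export
setMethod("tpmNormalize", "matrix", function(x, lengths, ...) {
    if (!is.null(names(lengths)) && !is.null(rownames(x))) {
        if (!all(rownames(x) %in% names(lengths)))
            stop("missing length for ORF(s): ",
                 paste(utils::head(setdiff(rownames(x), names(lengths)), 5L),
                       collapse = ", "))
        lengths <- lengths[rownames(x)]
    }
    if (length(lengths) != nrow(x))
        stop("lengths must be parallel to the rows of the count matrix")
    if (anyNA(lengths) || any(lengths <= 0))
        stop("ORF lengths must be positive and non-missing")
    if (any(x < 0)) stop("negative counts")

    rate <- x / lengths
    tot <- colSums(rate)
    if (any(tot == 0))
        warning("zero-depth sample(s): ",
                paste(colnames(x)[tot == 0], collapse = ", "))
    scale <- ifelse(tot > 0, 1e6 / tot, 0)
    sweep(rate, 2L, scale, `*`)
})

#' @describeIn tpmNormalize Uses the \code{"counts"} assay and the
#'   \code{length} rowData column, and stores the result as a \code{"tpm"}
#'   assay on the returned object.
#' @export
setMethod("tpmNormalize", "SummarizedExperiment", function(x, ...) {
    len <- SummarizedExperiment::rowData(x)$length
    if (is.null(len)) stop("rowData must carry a 'length' column")
    tpm <- tpmNormalize(SummarizedExperiment::assay(x, "counts"),
                        lengths = as.numeric(len))
    SummarizedExperiment::assay(x, "tpm") <- tpm
    x
})

## Source-database priority used when an ORF hits families in several
## clusters: TIGRFAM > COG > PFAM, then lexicographic accession.
.sourcePriority <- function(accession) {
    p <- rep(3L, length(accession))
    p[startsWith(accession, "TIGR")] <- 1L
    p[startsWith(accession, "COG")] <- 2L
    p
}

#' Map ORFs to transport clusters
#'
#' An ORF maps to a cluster when at least one of its family hits belongs to
#' a non-excluded (annotated) cluster. Each ORF maps to exactly one
#' cluster so no TPM mass is double-counted: when hits fall in several
#' clusters, the hit with the highest source priority wins (TIGRFAM > COG >
#' PFAM, ties broken by lexicographic accession). ORFs whose only hits lie
#' in excluded clusters, or with no transporter hits at all, are unmapped.
#'
#' @param orfs data.frame with columns \code{orf_id} and \code{families}
#'   (comma-separated string or list of family accessions).
#' @param clusters an annotated [TransportClusterSet-class] (the
#'   \code{excluded} column must be present).
#' @return Named character vector: ORF id to cluster id, mapped ORFs only.
#' @export
mapOrfsToClusters <- function(orfs, clusters) {
    stopifnot(is(clusters, "TransportClusterSet"))
    cl <- clusters@clusters
    if (is.null(cl$excluded))
        stop("clusters must be annotated before mapping (run annotateClusters)")
    keep <- !cl$excluded
    fam2cl <- setNames(rep(cl$cluster_id[keep], cl$n_members[keep]),
                       unlist(cl$members[keep], use.names = FALSE))

    hits <- .accessionList(orfs$families)
    out <- character(nrow(orfs))
    for (i in seq_along(hits)) {
        h <- intersect(hits[[i]], names(fam2cl))
        if (length(h) == 0L) next
        h <- h[order(.sourcePriority(h), h)]
        out[i] <- fam2cl[[h[1L]]]
    }
    mapped <- nzchar(out)
    setNames(out[mapped], orfs$orf_id[mapped])
}

#' Per-cluster abundance and the abundant-transporter filter
#'
#' Sums ORF-level TPM into cluster-by-sample abundances, computes each
#' cluster's share of the sample's total transporter TPM, and flags
#' clusters whose relative abundance \emph{strictly} exceeds
#' \code{threshold} (default 0.5\%) in at least one sample. The relative
#' denominator is per dataset: compute MG and MT abundances separately and
#' combine their abundant sets with [abundantUnion()].
#'
#' @param tpm TPM matrix (ORFs x samples) with ORF ids as rownames.
#' @param mapping named ORF-to-cluster vector from [mapOrfsToClusters()].
#' @param threshold relative-abundance cutoff, default 0.005.
#' @param dataset dataset tag stored on the result, e.g. \code{"MG"}.
#' @return A [ClusterAbundance-class].
#' @export
clusterAbundance <- function(tpm, mapping, threshold = 0.005,
                             dataset = "MG") {
    if (length(mapping) == 0L) stop("empty ORF-to-cluster mapping")
    missing <- setdiff(names(mapping), rownames(tpm))
    if (length(missing))
        stop("mapped ORFs absent from the TPM matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    sub <- tpm[names(mapping), , drop = FALSE]
    entries <- rowsum(sub, group = mapping)
    entries <- entries[sort(rownames(entries)), , drop = FALSE]

    tot <- colSums(entries)
    if (any(tot == 0))
        warning("sample(s) with zero transporter TPM reported as zeros: ",
                paste(colnames(entries)[tot == 0], collapse = ", "))
    relative <- sweep(entries, 2L, ifelse(tot > 0, tot, 1), `/`)
    abundant <- rownames(entries)[
        apply(relative > threshold, 1L, any)]
    new("ClusterAbundance", entries = entries, relative = relative,
        abundant = abundant, threshold = threshold, dataset = dataset)
}

#' Union of abundant transporter sets across datasets
#'
#' A transporter is "abundant" when it exceeds the relative-abundance
#' threshold in at least one sample of \emph{either} dataset, i.e. the
#' union (not the intersection) over MG and MT.
#'
#' @param ... one or more [ClusterAbundance-class] objects.
#' @return Sorted character vector of abundant cluster ids.
#' @export
abundantUnion <- function(...) {
    sets <- lapply(list(...), abundantSet)
    sort(unique(unlist(sets, use.names = FALSE)))
}
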