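#' Read and write the pipeline's plain-text tables
#'
#' Thin TSV readers/writers for the on-disk interface: family metadata
#' (\code{families.tsv}), cross-references (\code{xrefs.tsv}, accessions
#' comma-separated), operons (\code{operons.tsv}), the ORF catalogue
#' (\code{orfs.tsv}), count matrices (first column the ORF id), sample
#' metadata and environmental variables.
#'
#' @param path file path.
#' @return \code{readFamilyTable}, \code{readXrefTable},
#'   \code{readOperonTable}, \code{readOrfTable}, \code{readSampleTable}:
#'   a data.frame; \code{readCountMatrix}: an integer matrix with ORF
#'   rownames; \code{readEnvTable}: a data.frame with sample rownames.
#' @name tsv-io
NULL

.readTsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname tsv-io
#' @export
readFamilyTable <- function(path) .readTsv(path)

#' @rdname tsv-io
#' @export
readXrefTable <- function(path) {
    x <- .readTsv(path)
    x$reviewed <- as.logical(x$reviewed)
    x
}

#' @rdname tsv-io
#' @export
readOperonTable <- function(path) .readTsv(path)

#' @rdname tsv-io
#' @export
readOrfTable <- function(path) .readTsv(path)

#' @rdname tsv-io
#' @export
readSampleTable <- function(path) .readTsv(path)

#' @rdname tsv-io
#' @export
readCountMatrix <- function(path) {
    x <- .readTsv(path)
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- x[[1L]]
    storage.mode(m) <- "numeric"
    m
}

#' @rdname tsv-io
#' @export
readEnvTable <- function(path) {
    x <- .readTsv(path)
    rownames(x) <- x[[1L]]
    x[, -1L, drop = FALSE]
}

#' @rdname tsv-io
#' @param x the object to write (data.frame or matrix).
#' @export
writeTsv <- function(x, path) {
    if (is.matrix(x))
        x <- data.frame(id = rownames(x), x, check.names = FALSE,
                        stringsAsFactors = FALSE)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a cluster set as a flat TSV
#'
#' Members are comma-joined; annotation columns are carried along when
#' present.
#'
#' @param clusters a [TransportClusterSet-class].
#' @param path output file.
#' @export
writeClusterTable <- function(clusters, path) {
    cl <- as.data.frame(clusterTable(clusters))
    cl$members <- vapply(clusterMembers(clusters), paste, "",
                         collapse = ",")
    writeTsv(cl, path)
}

#' Serialise simulation ground truth as JSON
#'
#' Writes the planted partition, hub set, candidate set and per-cluster
#' annotation of a [simulateReference()] run to a JSON file (requires the
#' jsonlite package).
#'
#' @param truth the \code{truth} element of a [simulateReference()] result.
#' @param path output file.
#' @export
writeGroundTruth <- function(truth, path) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("writeGroundTruth requires the 'jsonlite' package")
    jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' Write a taxon x category x sample tensor in long format
#'
#' @param tensor array from [aggregateByTaxon()].
#' @param path output file.
#' @export
writeTensorLong <- function(tensor, path) {
    long <- as.data.frame.table(tensor, responseName = "tpm",
                                stringsAsFactors = FALSE)
    writeTsv(long, path)
}
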