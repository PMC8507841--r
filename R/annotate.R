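#' @include AllClasses.R
NULL

.hintMap <- function(tab, what) {
    if (is.null(tab) || nrow(tab) == 0L) return(character())
    if (!all(c("accession", "category") %in% names(tab)))
        stop(what, " table must have columns 'accession' and 'category'")
    bad <- setdiff(tab$category, substrateCategories())
    if (length(bad))
        stop("unknown substrate category in ", what, ": ",
             paste(unique(bad), collapse = ", "))
    setNames(as.character(tab$category), tab$accession)
}

## Override lookup: a cluster-level row wins; otherwise the row of the
## lexicographically smallest member accession with an override.
.lookupOverride <- function(clusterId, members, overrides) {
    if (is.null(overrides) || nrow(overrides) == 0L) return(NULL)
    i <- match(clusterId, overrides$id)
    if (is.na(i)) {
        hit <- sort(intersect(members, overrides$id))
        if (length(hit) == 0L) return(NULL)
        i <- match(hit[1L], overrides$id)
    }
    overrides[i, , drop = FALSE]
}

.majority <- function(hints) {
    if (length(hints) == 0L) return(NULL)
    tab <- table(hints)
    top <- sort(names(tab)[tab == max(tab)])
    list(category = top[1L], tie = length(top) > 1L)
}

#' Annotate transport clusters with substrate categories
#'
#' Each cluster is assigned one of the nine substrate categories (or
#' \code{"unannotated"}) by the following resolution order: (1) a curated
#' override matching the cluster id or any member accession; (2) a majority
#' vote among the members' TIGRFAM-role hints (the TIGRFAM role takes
#' precedence over Gene Ontology); (3) a majority vote among the members'
#' GO hints; (4) \code{"unannotated"}, which flags the cluster as excluded
#' from all downstream abundance analysis. Ties within a vote are broken by
#' the lexicographically smallest category name and recorded in the
#' \code{tie_flag} column so curators can audit them.
#'
#' @param clusters a [TransportClusterSet-class].
#' @param tigrRoles,goMap data.frames mapping \code{accession} to
#'   \code{category}; either may be \code{NULL}.
#' @param overrides optional data.frame with columns \code{id} (cluster id
#'   or member accession) and \code{category}; may also carry
#'   \code{transport_class}, \code{secretion_type}, \code{tcdb} and
#'   \code{gene_name} used by [classifyTransportClass()].
#' @return The cluster set with columns \code{category},
#'   \code{annotation_source} (override/tigr/go/none), \code{tie_flag} and
#'   \code{excluded} added.
#' @export
annotateClusters <- function(clusters, tigrRoles = NULL, goMap = NULL,
                             overrides = NULL) {
    stopifnot(is(clusters, "TransportClusterSet"))
    tigr <- .hintMap(tigrRoles, "TIGRFAM role")
    go <- .hintMap(goMap, "GO map")
    if (!is.null(overrides) && nrow(overrides)) {
        bad <- setdiff(stats::na.omit(overrides$category),
                       c(substrateCategories(), "unannotated"))
        if (length(bad))
            stop("unknown substrate category in overrides: ",
                 paste(unique(bad), collapse = ", "))
    }

    cl <- clusters@clusters
    n <- nrow(cl)
    category <- character(n)
    source <- character(n)
    tie <- logical(n)
    for (i in seq_len(n)) {
        members <- sort(cl$members[[i]])
        ov <- .lookupOverride(cl$cluster_id[i], members, overrides)
        if (!is.null(ov) && !is.na(ov$category)) {
            category[i] <- ov$category
            source[i] <- "override"
            next
        }
        v <- .majority(unname(tigr[members[members %in% names(tigr)]]))
        if (!is.null(v)) {
            category[i] <- v$category; tie[i] <- v$tie; source[i] <- "tigr"
            next
        }
        v <- .majority(unname(go[members[members %in% names(go)]]))
        if (!is.null(v)) {
            category[i] <- v$category; tie[i] <- v$tie; source[i] <- "go"
            next
        }
        category[i] <- "unannotated"
        source[i] <- "none"
    }
    cl$category <- category
    cl$annotation_source <- source
    cl$tie_flag <- tie
    cl$excluded <- category == "unannotated"
    initialize(clusters, clusters = cl)
}

## Secretion-type detection from free text; longest tokens checked first so
## "type ii" is not swallowed by "type i".
.detectSecretionType <- function(text) {
    text <- tolower(text)
    pats <- c(T3 = "type[ -]?(iii|3)", T2 = "type[ -]?(ii|2)",
              T6 = "type[ -]?(vi|6)", T5 = "type[ -]?(v|5)",
              T1 = "type[ -]?(i|1)")
    for (ty in names(pats)) {
        if (any(grepl(pats[[ty]], text, perl = TRUE))) return(ty)
    }
    "other"
}

#' Classify transport clusters by direction of transport
#'
#' Splits clusters into importers and exporters, with metal-ion
#' transporters kept as their own class because their direction is often
#' ambiguous, and toxin-secretion exporters separated from utility
#' exporters. A curated override wins; otherwise the first rule in
#' \code{rules} whose terms match any member family's name or description
#' (case-insensitive substring) assigns the class, and clusters matching no
#' rule become \code{"other"}. Toxin exporters additionally receive a
#' secretion type (Type I/II/III/V/VI or other) detected from the member
#' descriptions, and TCDB classes are taken from the override table only.
#'
#' @param clusters an annotated [TransportClusterSet-class].
#' @param families the family metadata table (for member descriptions).
#' @param overrides optional override table, see [annotateClusters()].
#' @param rules ordered keyword rules; default [defaultClassRules()].
#' @return The cluster set with columns \code{transport_class},
#'   \code{secretion_type}, \code{tcdb} and \code{gene_name} added.
#' @export
classifyTransportClass <- function(clusters, families, overrides = NULL,
                                   rules = defaultClassRules()) {
    stopifnot(is(clusters, "TransportClusterSet"), length(rules) > 0L)
    badClass <- setdiff(vapply(rules, `[[`, "", "class"), transportClasses())
    if (length(badClass))
        stop("unknown transport class in rules: ",
             paste(badClass, collapse = ", "))
    if (!is.null(overrides) && nrow(overrides)) {
        bad <- setdiff(stats::na.omit(overrides$transport_class),
                       transportClasses())
        if (length(bad))
            stop("unknown transport class in overrides: ",
                 paste(unique(bad), collapse = ", "))
    }
    textOf <- setNames(tolower(paste(families$name, families$description)),
                       families$accession)

    cl <- clusters@clusters
    n <- nrow(cl)
    klass <- rep("other", n)
    secretion <- rep(NA_character_, n)
    tcdb <- rep(NA_character_, n)
    gene <- rep(NA_character_, n)
    for (i in seq_len(n)) {
        members <- sort(cl$members[[i]])
        texts <- textOf[members[members %in% names(textOf)]]
        ov <- .lookupOverride(cl$cluster_id[i], members, overrides)
        if (!is.null(ov)) {
            if (!is.null(ov$tcdb)) tcdb[i] <- ov$tcdb
            if (!is.null(ov$gene_name)) gene[i] <- ov$gene_name
        }
        if (!is.null(ov) && !is.null(ov$transport_class) &&
            !is.na(ov$transport_class)) {
            klass[i] <- ov$transport_class
            if (klass[i] == "exporter_toxin") {
                secretion[i] <- if (!is.null(ov$secretion_type) &&
                                    !is.na(ov$secretion_type))
                    ov$secretion_type else .detectSecretionType(texts)
            }
            next
        }
        for (rule in rules) {
            hit <- any(vapply(tolower(rule$terms),
                              function(t) any(grepl(t, texts, fixed = TRUE)),
                              logical(1)))
            if (hit) {
                klass[i] <- rule$class
                break
            }
        }
        if (klass[i] == "exporter_toxin")
            secretion[i] <- .detectSecretionType(texts)
    }
    bad <- !is.na(secretion) & !secretion %in% secretionTypes()
    if (any(bad)) stop("invalid secretion type")
    bad <- !is.na(tcdb) & !tcdb %in% tcdbClasses()
    if (any(bad)) stop("invalid TCDB class in overrides")

    cl$transport_class <- klass
    cl$secretion_type <- secretion
    cl$tcdb <- tcdb
    cl$gene_name <- gene
    initialize(clusters, clusters = cl)
}
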