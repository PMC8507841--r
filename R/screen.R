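#' Screen protein families for transporter relevance
#'
#' Flags a protein family as a transporter candidate when any of the screen
#' terms matches its name or description, case-insensitively. Both fields
#' are searched because COG entries often carry the informative text in the
#' name. With \code{mode = "substring"} a term matches anywhere
#' ("transport" matches "transporter", "symport" matches "symporter");
#' \code{mode = "word"} requires word boundaries for stricter screens.
#'
#' The result is independent of row order, idempotent (screening the
#' candidate subset returns the same set) and monotone in the term list.
#'
#' @param families data.frame with columns \code{accession},
#'   \code{source_db}, \code{name}, \code{description}; accessions must be
#'   unique.
#' @param terms character vector of match terms; default
#'   [defaultScreenTerms()].
#' @param mode \code{"substring"} (default) or \code{"word"}.
#' @return A [FamilyScreen-class] with the sorted candidate accessions and
#'   per-source counts (one entry per source database present in the
#'   input, including zeroes).
#' @examples
#' fam <- data.frame(accession = c("PF00001", "COG0001"),
#'                   source_db = c("PFAM", "COG"),
#'                   name = c("SSF", "rpoB"),
#'                   description = c("sodium/proline symporter",
#'                                   "RNA polymerase beta subunit"))
#' candidateAccessions(screenFamilies(fam))
#' @export
screenFamilies <- function(families, terms = defaultScreenTerms(),
                           mode = c("substring", "word")) {
    mode <- match.arg(mode)
    if (is.null(families) || nrow(families) == 0L)
        stop("family table is empty")
    req <- c("accession", "source_db", "name", "description")
    if (!all(req %in% names(families)))
        stop("family table must have columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(families$accession))
        stop("duplicate accessions in family table")
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L)
        stop("screen pattern has no terms")

    text <- tolower(paste(families$name, families$description))
    hit <- rep(FALSE, nrow(families))
    for (term in tolower(terms)) {
        hit <- hit | if (mode == "substring") {
            grepl(term, text, fixed = TRUE)
        } else {
            grepl(paste0("\\b", term, "\\b"), text, perl = TRUE)
        }
    }

    src <- as.character(families$source_db)
    counts <- vapply(sort(unique(src)), function(s) sum(hit & src == s),
                     integer(1))
    new("FamilyScreen",
        candidates = sort(families$accession[hit]),
        counts = counts, terms = terms, mode = mode)
}
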