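#' Closed vocabularies used across the pipeline
#'
#' The nine putative substrate categories of transporter clusters, the
#' transport direction classes, the bacterial secretion-system types, the
#' TCDB mechanism classes and the taxonomic ranks are closed enumerations;
#' every annotation in the package is drawn from them.
#'
#' @return A character vector of allowed values.
#' @examples
#' substrateCategories()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
substrateCategories <- function() {
    c("amino_acids_peptides_ammonium", "anion", "carbohydrate", "cation",
      "nitrate", "nucleoside", "phosphate", "phosphonate", "urea")
}

#' @rdname vocabularies
#' @export
transportClasses <- function() {
    c("importer", "exporter_utility", "exporter_toxin", "metal", "other")
}

#' @rdname vocabularies
#' @export
secretionTypes <- function() {
    c("T1", "T2", "T3", "T5", "T6", "other")
}

#' @rdname vocabularies
#' @export
tcdbClasses <- function() {
    c("1A", "1B", "2A", "2C", "3A", "3D", "4A", "4B", "9A")
}

#' @rdname vocabularies
#' @export
taxonomicRanks <- function() {
    c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Default transporter screen terms
#'
#' The five case-insensitive terms used to flag a protein family as
#' transporter-related when they occur in its name or description. The
#' default is a documented reduction of the full curated pattern; pass your
#' own term list to [screenFamilies()] for stricter or wider screens.
#'
#' @return Character vector of match terms.
#' @export
defaultScreenTerms <- function() {
    c("transport", "efflux", "uptake", "symport", "antiport")
}

#' Default transport-class keyword rules
#'
#' Ordered keyword rules used by [classifyTransportClass()]. Metal-ion terms
#' are ranked first because the transport direction of metal transporters is
#' often ambiguous and they are kept as their own class; toxin-secretion
#' terms come next, then utility export, then import. The first rule whose
#' terms match any member family description assigns the class; no match
#' falls through to \code{"other"}.
#'
#' @return A list of rules, each a list with elements \code{terms}
#'   (character) and \code{class} (one of [transportClasses()]).
#' @export
defaultClassRules <- function() {
    list(
        list(terms = c("cobalt", "zinc", "cadmium", "nickel", "manganese",
                       "metal ion"),
             class = "metal"),
        list(terms = c("secretion", "toxin", "hemolysin", "autotransporter"),
             class = "exporter_toxin"),
        list(terms = c("efflux", "export"),
             class = "exporter_utility"),
        list(terms = c("uptake", "import", "symport", "antiport", "permease",
                       "substrate-binding", "channel"),
             class = "importer")
    )
}
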