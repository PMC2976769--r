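#' Read a family configuration (YAML or JSON)
#'
#' A family configuration names the representative structure, the motif
#' and beta-hairpin residue ranges (author numbering of the representative
#' structure) and the catalytic-role map, e.g.:
#' \preformatted{
#' familyId: GH22i
#' representative: 2dqa
#' representativeStart: 1
#' motifRange: [34, 42]
#' hairpinRange: [34, 43]
#' roles:
#'   A: {resno: 18, resname: GLU}
#'   B: {resno: 30, resname: ASP}
#'   C: {resno: 35, resname: SER}
#'   D: {resno: 40, resname: GLN}
#' }
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a [FamilyConfig-class].
#' @export
readFamilyConfig <- function(path) {
    if (!file.exists(path))
        .stopf("family config not found: '%s'", path)
    x <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    familyConfig(
        familyId = x$familyId %||% "unnamed",
        representative = x$representative %||% NA_character_,
        motifRange = x$motifRange, hairpinRange = x$hairpinRange,
        strand1 = x$strand1, strand2 = x$strand2,
        roles = x$roles, representativeStart = x$representativeStart %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a FamilyConfig
#'
#' @param familyId family name.
#' @param representative representative structure code.
#' @param motifRange,hairpinRange integer start/end author residue numbers
#'   (or \code{NULL}).
#' @param strand1,strand2 explicit residue ranges of the hairpin strands
#'   (or \code{NULL} to rely on [detectStrands()]).
#' @param roles named list of \code{list(resno =, resname =)} entries for
#'   roles \code{A}/\code{B}/\code{C}/\code{D}; absent roles omitted.
#' @param representativeStart author number of the representative's first
#'   aligned residue.
#' @return a [FamilyConfig-class].
#' @export
familyConfig <- function(familyId, representative = NA_character_,
                         motifRange = NULL, hairpinRange = NULL,
                         strand1 = NULL, strand2 = NULL,
                         roles = list(), representativeStart = 1L) {
    asRange <- function(x) {
        if (is.null(x)) return(c(NA_integer_, NA_integer_))
        x <- as.integer(unlist(x))
        if (length(x) == 1L) x <- c(x, x)
        x[1:2]
    }
    roles <- lapply(roles %||% list(), function(r)
        list(resno = as.integer(r$resno), resname = toupper(r$resname)))
    strands <- list()
    if (!is.null(strand1) && !is.null(strand2))
        strands <- list(asRange(strand1), asRange(strand2))
    methods::new("FamilyConfig", familyId = as.character(familyId),
                 representative = as.character(representative),
                 motifRange = asRange(motifRange),
                 hairpinRange = asRange(hairpinRange),
                 strandRanges = strands, roles = roles,
                 representativeStart = as.integer(representativeStart))
}
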