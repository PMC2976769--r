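#' Read a FASTA multiple alignment into an AlignedFamily
#'
#' Reads an aligned protein FASTA file.  Rows are uppercased and the
#' alternative gap character \code{.} is normalized to \code{-}; \code{X}
#' is kept and treated as missing by the frequency machinery.  Row order is
#' preserved.
#'
#' @param path path to a FASTA file with \code{>} headers.
#' @param familyId family name to attach (default: file base name).
#' @param representativeId id of the representative sequence (default:
#'   first record).
#' @return an [AlignedFamily-class].
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACD-", ">b", "acde"), tf)
#' aln <- readFastaAlignment(tf, familyId = "toy")
#' alignmentMatrix(aln)
#' @export
readFastaAlignment <- function(path, familyId = NULL,
                               representativeId = NULL) {
    if (!file.exists(path))
        .stopf("alignment file not found: '%s'", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        .stopf("empty alignment file: '%s'", path)
    rows <- toupper(as.character(raw))
    rows <- gsub(".", "-", rows, fixed = TRUE)
    # header up to first whitespace is the id, as in most alignment tools
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        .stopf("duplicate sequence ids in '%s'", path)
    if (length(unique(nchar(rows))) != 1L)
        .stopf("ragged alignment in '%s': row lengths %s", path,
               paste(sort(unique(nchar(rows))), collapse = ", "))
    badch <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]),
                     c(AA20, "-", "X"))
    if (length(badch))
        .stopf("non amino-acid characters in '%s': %s", path,
               paste(badch, collapse = " "))
    if (is.null(familyId))
        familyId <- sub("\\.[^.]*$", "", basename(path))
    if (is.null(representativeId))
        representativeId <- ids[1]
    newAlignedFamily(familyId, setNames(rows, ids), representativeId)
}

#' Construct an AlignedFamily from character rows
#'
#' @param familyId family name.
#' @param rows named character vector of equal-length aligned rows.
#' @param representativeId one of \code{names(rows)}.
#' @return an [AlignedFamily-class].
#' @export
newAlignedFamily <- function(familyId, rows, representativeId = names(rows)[1]) {
    aln <- Biostrings::AAStringSet(rows)
    names(aln) <- names(rows)
    methods::new("AlignedFamily", familyId = as.character(familyId),
                 alignment = aln,
                 representativeId = as.character(representativeId))
}

#' Write an AlignedFamily (or labelled sequences) as FASTA
#'
#' @param x an [AlignedFamily-class] or a named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaAlignment <- function(x, path) {
    rows <- if (methods::is(x, "AlignedFamily"))
        setNames(as.character(x@alignment), names(x@alignment))
    else x
    .atomicWrite(function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        for (i in seq_along(rows))
            writeLines(c(paste0(">", names(rows)[i]), rows[[i]]), con)
    }, path)
}
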