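#' Read one chain of a PDB file into a StructureModel
#'
#' Parses ATOM records of a PDB-format file (via \pkg{bio3d}) and keeps a
#' single chain.  When several chains are present and none is requested,
#' the first chain encountered is used.  Alternate locations are resolved
#' by keeping the blank or \code{'A'} altloc; HETATM records are ignored.
#' Author residue numbering (with insertion codes as part of the residue
#' key) is kept throughout.
#'
#' @param path path to a PDB-format file.
#' @param chain chain identifier, or \code{NULL} (default) for the first
#'   chain encountered.
#' @param structureId id to attach (default: file base name).
#' @return a [StructureModel-class].
#' @export
readPdbSubset <- function(path, chain = NULL, structureId = NULL) {
    if (!file.exists(path))
        .stopf("PDB file not found: '%s'", path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
    a <- pdb$atom
    a <- a[a$type == "ATOM", , drop = FALSE]
    if (!nrow(a))
        .stopf("no ATOM records in '%s'", path)
    a$chain[is.na(a$chain)] <- " "
    chains <- unique(a$chain)
    if (is.null(chain)) {
        chain <- chains[1]
    } else if (!(chain %in% chains)) {
        .stopf("chain '%s' not present in '%s' (available: %s)",
               chain, path, paste(chains, collapse = ", "))
    }
    a <- a[a$chain == chain, , drop = FALSE]
    # altloc resolution: keep blank or 'A'
    alt <- a$alt
    alt[is.na(alt)] <- ""
    a <- a[alt %in% c("", "A"), , drop = FALSE]
    ins <- a$insert
    ins[is.na(ins)] <- ""
    atoms <- data.frame(resno = as.integer(a$resno), icode = ins,
                        resname = toupper(a$resid), atom = a$elety,
                        x = a$x, y = a$y, z = a$z,
                        stringsAsFactors = FALSE)
    # drop duplicate atoms left by exotic altloc labelling (keep first)
    atoms <- atoms[!duplicated(atoms[, c("resno", "icode", "atom")]), ,
                   drop = FALSE]
    rownames(atoms) <- NULL
    if (is.null(structureId))
        structureId <- sub("\\.[^.]*$", "", basename(path))
    methods::new("StructureModel", structureId = as.character(structureId),
                 chainId = as.character(chain), atoms = atoms)
}

#' Write a StructureModel as minimal PDB ATOM records
#'
#' Fixed-column ATOM records (one chain, no header), sufficient for
#' round-tripping the synthetic coordinate generators through any standard
#' PDB reader.
#'
#' @param x a [StructureModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePdb <- function(x, path) {
    a <- x@atoms
    ch <- substr(paste0(x@chainId, " "), 1, 1)
    .atomicWrite(function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        for (i in seq_len(nrow(a))) {
            nm <- a$atom[i]
            # columns 13-16: element right-justified into col 14 for short names
            nm4 <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
            writeLines(sprintf(
                "ATOM  %5d %4s %3s %s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
                i, nm4, a$resname[i], ch, a$resno[i],
                ifelse(nzchar(a$icode[i]), a$icode[i], " "),
                a$x[i], a$y[i], a$z[i]), con)
        }
        writeLines("END", con)
    }, path)
}

#' Retrieve coordinates of one atom
#'
#' @param x a [StructureModel-class].
#' @param resno author residue number.
#' @param atom atom name (e.g. \code{"CA"}, \code{"CB"}, \code{"OE1"}).
#' @param icode insertion code (default \code{""}).
#' @return numeric xyz vector, or \code{NULL} when absent.
#' @export
atomCoord <- function(x, resno, atom, icode = "") {
    a <- x@atoms
    i <- which(a$resno == resno & a$icode == icode & a$atom == atom)
    if (!length(i)) return(NULL)
    as.numeric(a[i[1], c("x", "y", "z")])
}
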