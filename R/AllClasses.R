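#' @import methods
#' @importFrom stats sd setNames quantile
#' @importFrom utils head tail
NULL

setOldClass("phylo")

.checkLabelledSquare <- function(m, what = "matrix") {
    msg <- character()
    if (!is.matrix(m) || !is.numeric(m))
        msg <- c(msg, sprintf("%s must be a numeric matrix", what))
    else {
        if (nrow(m) != ncol(m))
            msg <- c(msg, sprintf("%s must be square", what))
        if (is.null(rownames(m)) || is.null(colnames(m)) ||
            !identical(rownames(m), colnames(m)))
            msg <- c(msg, sprintf("%s must carry identical row/col labels", what))
        if (anyDuplicated(rownames(m)))
            msg <- c(msg, "labels must be unique")
    }
    msg
}

#' Labelled symmetric matrix of pairwise structural-similarity scores
#'
#' Holds pairwise structure-similarity scores (e.g. DaliLite Z-scores)
#' between a set of structures, with the per-structure self-scores on the
#' diagonal.  The matrix is symmetric and carries one unique label per
#' structure.
#'
#' @slot values numeric matrix, square, symmetric, with identical row and
#'   column labels; the diagonal holds the self-scores.
#' @seealso [readSquareMatrix()], [similarityToDistance()],
#'   [generateSimilarityMatrix()]
#' @export
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
    m <- object@values
    msg <- .checkLabelledSquare(m, "similarity matrix")
    if (!length(msg)) {
        if (any(!is.finite(m)))
            msg <- c(msg, "similarity values must be finite")
        else if (max(abs(m - t(m))) > 1e-6)
            msg <- c(msg, "similarity matrix must be symmetric (tol 1e-6)")
    }
    if (length(msg)) msg else TRUE
})

#' Labelled symmetric distance matrix between structures
#'
#' @slot values numeric matrix, square, symmetric, non-negative, zero
#'   diagonal, identical row/column labels.
#' @seealso [similarityToDistance()], [upgmaTree()], [familyDistances()]
#' @export
setClass("DistanceMatrix", representation(values = "matrix"))

setValidity("DistanceMatrix", function(object) {
    m <- object@values
    msg <- .checkLabelledSquare(m, "distance matrix")
    if (!length(msg)) {
        if (any(!is.finite(m)))
            msg <- c(msg, "distances must be finite")
        else {
            if (max(abs(m - t(m))) > 1e-9)
                msg <- c(msg, "distance matrix must be symmetric")
            if (any(m < -1e-12))
                msg <- c(msg, "distances must be non-negative")
            if (any(abs(diag(m)) > 1e-9))
                msg <- c(msg, "diagonal must be zero")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Rooted ultrametric cluster tree with node reliability flags
#'
#' The result of UPGMA clustering of a [DistanceMatrix-class].  The tree is
#' stored as an \pkg{ape} \code{phylo} object whose branch lengths are
#' differences of node heights (height of a merge = merge distance / 2, so
#' all leaves are equidistant from the root).  After
#' [jackknifeReliability()] each internal node carries a reliability flag:
#' \code{TRUE} when the node's clade was recovered in every leave-one-out
#' replicate tree.
#'
#' @slot phylo rooted binary \code{phylo} tree with branch lengths.
#' @slot heights numeric, height of each internal node (named by the
#'   \code{phylo} internal node number).
#' @slot reliability logical, one flag per internal node (\code{NA} before
#'   the jackknife has been run), named like \code{heights}.
#' @seealso [upgmaTree()], [jackknifeReliability()], [writeNewick()]
#' @export
setClass("ClusterTree",
    representation(phylo = "phylo", heights = "numeric",
                   reliability = "logical"))

setValidity("ClusterTree", function(object) {
    tr <- object@phylo
    msg <- character()
    nint <- tr$Nnode
    if (length(object@heights) != nint)
        msg <- c(msg, "one height per internal node required")
    if (length(object@reliability) != nint)
        msg <- c(msg, "one reliability flag per internal node required")
    if (length(msg)) msg else TRUE
})

#' Multiple sequence alignment of one GH family
#'
#' An aligned protein family: equal-length rows over the 20 amino acids,
#' the gap character \code{-} and the unknown-residue character \code{X},
#' together with the identifier of the representative sequence whose
#' (structure) numbering is used to report motif positions.
#'
#' @slot familyId single character family name (e.g. \code{"GH19"}).
#' @slot alignment [Biostrings::AAStringSet-class] of equal-width rows.
#' @slot representativeId id of the representative sequence; must be one of
#'   \code{names(alignment)}.
#' @seealso [readFastaAlignment()], [generateMsa()], [conservationProfile()]
#' @export
setClass("AlignedFamily",
    representation(familyId = "character", alignment = "ANY",
                   representativeId = "character"))

setValidity("AlignedFamily", function(object) {
    msg <- character()
    aln <- object@alignment
    if (!methods::is(aln, "AAStringSet"))
        return("alignment must be an AAStringSet")
    if (length(aln) >= 1L && length(unique(Biostrings::width(aln))) != 1L)
        msg <- c(msg, "alignment rows must have equal length")
    if (is.null(names(aln)) || anyDuplicated(names(aln)))
        msg <- c(msg, "alignment rows must carry unique names")
    if (length(object@representativeId) == 1L &&
        !is.na(object@representativeId) &&
        !(object@representativeId %in% names(aln)))
        msg <- c(msg, "representativeId not found among sequence ids")
    if (length(msg)) msg else TRUE
})

#' Per-column conservation profile of a family alignment
#'
#' Weighted residue frequencies, gap fractions and the raw (negative
#' Shannon entropy), window-smoothed and z-normalized conservation indices
#' for every column of a family alignment, optionally mapped onto the
#' author residue numbers of the representative structure.
#'
#' @slot familyId family name.
#' @slot frequencies 20 x L matrix of weighted amino-acid frequencies
#'   (columns sum to 1 over the 20 residues unless the column is flagged).
#' @slot gapFraction per-column fraction of gap/unknown symbols.
#' @slot flagged logical; columns with gap fraction above the threshold are
#'   excluded from smoothing input and normalization statistics.
#' @slot raw,smoothed,normalized numeric conservation indices per column
#'   (\code{NA} at flagged columns).
#' @slot residueNumbers integer per column: author residue number on the
#'   representative sequence, or \code{NA} where the representative has a
#'   gap (all \code{NA} before [mapToRepresentative()]).
#' @slot representativeId id of the representative sequence.
#' @seealso [conservationProfile()], [extractMotif()]
#' @export
setClass("ConservationProfile",
    representation(familyId = "character", frequencies = "matrix",
                   gapFraction = "numeric", flagged = "logical",
                   raw = "numeric", smoothed = "numeric",
                   normalized = "numeric", residueNumbers = "integer",
                   representativeId = "character"))

setValidity("ConservationProfile", function(object) {
    L <- ncol(object@frequencies)
    msg <- character()
    if (nrow(object@frequencies) != 20L)
        msg <- c(msg, "frequencies must have 20 rows (amino acids)")
    for (s in c("gapFraction", "flagged", "raw", "smoothed", "normalized",
                "residueNumbers"))
        if (length(slot(object, s)) != L)
            msg <- c(msg, sprintf("slot '%s' must have one entry per column", s))
    ok <- !object@flagged
    if (any(ok) && any(object@raw[ok] > 1e-9, na.rm = TRUE))
        msg <- c(msg, "raw entropy index must be <= 0")
    if (length(msg)) msg else TRUE
})

#' Signature motif region of a family alignment
#'
#' The contiguous alignment region of strongest conservation that contains
#' the family's common beta-hairpin, reported both in alignment columns and
#' in author residue numbers of the representative structure.
#'
#' @slot familyId family name.
#' @slot columnRange integer start/end alignment columns.
#' @slot residueRange integer start/end representative residue numbers
#'   (\code{NA} when no mapping is available).
#' @slot meanConservation mean normalized conservation over the region.
#' @export
setClass("MotifRegion",
    representation(familyId = "character", columnRange = "integer",
                   residueRange = "integer", meanConservation = "numeric"))

#' Position frequency/information content matrix of a motif (sequence logo)
#'
#' @slot frequencies 20 x m matrix of weighted relative frequencies.
#' @slot information per-position information content in bits, in
#'   \code{[0, log2(20)]}.
#' @slot consensus per-position consensus residue.
#' @seealso [buildLogo()]
#' @export
setClass("LogoMatrix",
    representation(frequencies = "matrix", information = "numeric",
                   consensus = "character"))

setValidity("LogoMatrix", function(object) {
    m <- ncol(object@frequencies)
    msg <- character()
    if (nrow(object@frequencies) != 20L)
        msg <- c(msg, "frequencies must have 20 rows")
    if (length(object@information) != m || length(object@consensus) != m)
        msg <- c(msg, "information/consensus must have one entry per position")
    if (any(object@information < -1e-9 |
            object@information > log2(20) + 1e-9))
        msg <- c(msg, "information content out of [0, log2 20]")
    if (length(msg)) msg else TRUE
})

#' Position-specific log-odds profile model of a signature motif
#'
#' A glocal (motif-global, sequence-local) scoring model: per-position
#' emission log-odds against a background composition, with affine gap
#' penalties (in nats) for insertions and deletions, and a score threshold
#' used to call hits.
#'
#' @slot logOdds 20 x m matrix of emission log-odds (nats).
#' @slot background length-20 background frequencies (sum 1).
#' @slot gapOpen,gapExtend affine gap penalties in nats (positive numbers,
#'   subtracted from the score).
#' @slot threshold score threshold for [evaluateSearch()].
#' @seealso [buildProfile()], [scoreSequence()], [calibrateThreshold()]
#' @export
setClass("ProfileModel",
    representation(logOdds = "matrix", background = "numeric",
                   gapOpen = "numeric", gapExtend = "numeric",
                   threshold = "numeric"))

setValidity("ProfileModel", function(object) {
    msg <- character()
    if (nrow(object@logOdds) != 20L)
        msg <- c(msg, "logOdds must have 20 rows")
    if (length(object@background) != 20L ||
        abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "background must be 20 frequencies summing to 1")
    if (object@gapOpen < 0 || object@gapExtend < 0)
        msg <- c(msg, "gap penalties must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Search evaluation against a labelled sequence set
#'
#' @slot tpr,fpr true/false positive rates in \code{[0, 1]} (\code{NA} when
#'   the corresponding class is empty).
#' @slot threshold the score threshold used.
#' @slot hits data.frame with one row per query sequence: \code{id},
#'   \code{score}, \code{start}, \code{member} (label), \code{hit}.
#' @seealso [evaluateSearch()]
#' @export
setClass("SearchEvaluation",
    representation(tpr = "numeric", fpr = "numeric", threshold = "numeric",
                   hits = "data.frame"))

#' Atomic coordinates of one protein chain
#'
#' A single-chain structural model with author residue numbering (never
#' serial renumbering: all catalytic-residue labels in this package,
#' e.g. Glu67 or Ser120, are author numbers).  Insertion codes are part of
#' the residue key.
#'
#' @slot structureId structure code (e.g. a PDB id).
#' @slot chainId one-letter chain id.
#' @slot atoms data.frame with columns \code{resno} (integer author
#'   number), \code{icode} (insertion code, \code{""} when absent),
#'   \code{resname} (3-letter), \code{atom} (atom name), \code{x,y,z}
#'   (Angstrom).
#' @seealso [readPdbSubset()], [generatePeptide()], [backboneTorsions()]
#' @export
setClass("StructureModel",
    representation(structureId = "character", chainId = "character",
                   atoms = "data.frame"))

setValidity("StructureModel", function(object) {
    a <- object@atoms
    need <- c("resno", "icode", "resname", "atom", "x", "y", "z")
    msg <- character()
    if (!all(need %in% names(a)))
        msg <- c(msg, paste("atoms must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(a) && any(!is.finite(c(a$x, a$y, a$z))))
            msg <- c(msg, "coordinates must be finite")
        if (nrow(a) &&
            anyDuplicated(a[, c("resno", "icode", "atom")]))
            msg <- c(msg, "duplicate (residue, atom) entries (unresolved altlocs?)")
    }
    if (length(msg)) msg else TRUE
})

#' Per-family configuration: representative structure, motif ranges, roles
#'
#' Names the representative structure of a GH family, the residue ranges
#' (author numbering) of its signature motif and beta-hairpin, and the
#' catalytic-role map: role A is the general-acid glutamate, role B the
#' general-base Glu/Asp, role C the catalytic-water-positioning Ser/Thr and
#' role D the accessory glutamine of the hairpin motif.  Absent roles are
#' simply omitted.
#'
#' @slot familyId family name.
#' @slot representative structure code of the representative.
#' @slot motifRange,hairpinRange integer start/end author residue numbers
#'   (length 2 each; \code{NA} when not configured).
#' @slot strandRanges list of two integer start/end ranges naming the
#'   hairpin's strands explicitly (empty when left to detection;
#'   configured ranges always override [detectStrands()]).
#' @slot roles named list; each entry \code{A}/\code{B}/\code{C}/\code{D}
#'   is \code{list(resno =, resname =)}.
#' @slot representativeStart author number of the representative
#'   sequence's first alignment residue (for [mapToRepresentative()]).
#' @seealso [readFamilyConfig()], [activeSiteDistances()]
#' @export
setClass("FamilyConfig",
    representation(familyId = "character", representative = "character",
                   motifRange = "integer", hairpinRange = "integer",
                   strandRanges = "list", roles = "list",
                   representativeStart = "integer"))

.roleResnames <- list(A = "GLU", B = c("GLU", "ASP"), C = c("SER", "THR"),
                      D = "GLN")

setValidity("FamilyConfig", function(object) {
    msg <- character()
    bad <- setdiff(names(object@roles), c("A", "B", "C", "D"))
    if (length(bad))
        msg <- c(msg, paste("unknown roles:", paste(bad, collapse = ", ")))
    for (r in intersect(names(object@roles), c("A", "B", "C", "D"))) {
        spec <- object@roles[[r]]
        if (!is.list(spec) || !all(c("resno", "resname") %in% names(spec))) {
            msg <- c(msg, sprintf("role %s must be list(resno=, resname=)", r))
            next
        }
        if (!(toupper(spec$resname) %in% .roleResnames[[r]]))
            msg <- c(msg, sprintf("role %s must be one of %s, got %s", r,
                                  paste(.roleResnames[[r]], collapse = "/"),
                                  spec$resname))
    }
    for (s in c("motifRange", "hairpinRange")) {
        rg <- slot(object, s)
        if (length(rg) == 2L && !anyNA(rg) && rg[1] > rg[2])
            msg <- c(msg, sprintf("%s start must be <= end", s))
    }
    if (length(msg)) msg else TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix with %d structures\n", nrow(object@values)))
    cat("  labels:", paste(head(rownames(object@values), 6), collapse = ", "),
        if (nrow(object@values) > 6) "..." else "", "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
    v <- object@values[upper.tri(object@values)]
    cat(sprintf("DistanceMatrix with %d structures\n", nrow(object@values)))
    if (length(v))
        cat(sprintf("  off-diagonal range: %.3g .. %.3g\n", min(v), max(v)))
})

setMethod("show", "ClusterTree", function(object) {
    rel <- object@reliability
    cat(sprintf("ClusterTree: %d leaves, %d internal nodes\n",
                length(object@phylo$tip.label), object@phylo$Nnode))
    if (all(is.na(rel)))
        cat("  reliability: not assessed\n")
    else
        cat(sprintf("  reliability: %d/%d nodes reliable\n",
                    sum(rel, na.rm = TRUE), length(rel)))
})

setMethod("show", "AlignedFamily", function(object) {
    cat(sprintf("AlignedFamily '%s': %d sequences, %d columns (rep: %s)\n",
                object@familyId, length(object@alignment),
                if (length(object@alignment))
                    Biostrings::width(object@alignment)[1] else 0L,
                object@representativeId))
})

setMethod("show", "ConservationProfile", function(object) {
    cat(sprintf("ConservationProfile '%s': %d columns (%d flagged)\n",
                object@familyId, ncol(object@frequencies),
                sum(object@flagged)))
})

setMethod("show", "MotifRegion", function(object) {
    cat(sprintf(
        "MotifRegion '%s': columns %d-%d, residues %s-%s, mean cons %.3f\n",
        object@familyId, object@columnRange[1], object@columnRange[2],
        object@residueRange[1], object@residueRange[2],
        object@meanConservation))
})

setMethod("show", "ProfileModel", function(object) {
    cat(sprintf(
        "ProfileModel: %d positions, gapOpen %.2f, gapExtend %.2f, threshold %s\n",
        ncol(object@logOdds), object@gapOpen, object@gapExtend,
        format(object@threshold, digits = 4)))
})

setMethod("show", "SearchEvaluation", function(object) {
    cat(sprintf("SearchEvaluation: TPR %s, FPR %s at threshold %s (%d sequences)\n",
                format(object@tpr, digits = 3), format(object@fpr, digits = 3),
                format(object@threshold, digits = 4), nrow(object@hits)))
})

setMethod("show", "StructureModel", function(object) {
    cat(sprintf("StructureModel '%s' chain %s: %d atoms, %d residues\n",
                object@structureId, object@chainId, nrow(object@atoms),
                nrow(unique(object@atoms[, c("resno", "icode")]))))
})

setMethod("show", "FamilyConfig", function(object) {
    cat(sprintf("FamilyConfig '%s' (rep %s): roles %s\n", object@familyId,
                object@representative,
                if (length(object@roles))
                    paste(names(object@roles), collapse = "")
                else "none"))
})
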