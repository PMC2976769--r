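# Accessor generics + methods: slot access stays internal to the package.

#' Accessors for ghMotif data classes
#'
#' Small accessor family for the package's S4 containers.
#'
#' @param x an object of the documented class.
#' @return \code{scoreValues} and \code{distValues} return the underlying
#'   labelled numeric matrix; \code{structureLabels} the label vector;
#'   \code{asPhylo} the \pkg{ape} \code{phylo} tree; \code{nodeHeights} and
#'   \code{nodeReliability} per-internal-node numerics/logicals;
#'   \code{alignmentMatrix} a character matrix (sequences x columns);
#'   \code{atomTable} the atom data.frame of a [StructureModel-class].
#' @name accessors
#' @aliases scoreValues distValues structureLabels asPhylo nodeHeights
#'   nodeReliability alignmentMatrix atomTable
#' @examples
#' sm <- generateSimilarityMatrix(familySizes = c(2, 2), seed = 1)$matrix
#' structureLabels(sm)
#' scoreValues(sm)[1, 2]
NULL

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setMethod("scoreValues", "SimilarityMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))
#' @rdname accessors
#' @export
setMethod("distValues", "DistanceMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("structureLabels", function(x) standardGeneric("structureLabels"))
#' @rdname accessors
#' @export
setMethod("structureLabels", "SimilarityMatrix",
          function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("structureLabels", "DistanceMatrix",
          function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("structureLabels", "ClusterTree",
          function(x) x@phylo$tip.label)

#' @rdname accessors
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))
#' @rdname accessors
#' @export
setMethod("asPhylo", "ClusterTree", function(x) x@phylo)

#' @rdname accessors
#' @export
setGeneric("nodeHeights", function(x) standardGeneric("nodeHeights"))
#' @rdname accessors
#' @export
setMethod("nodeHeights", "ClusterTree", function(x) x@heights)

#' @rdname accessors
#' @export
setGeneric("nodeReliability", function(x) standardGeneric("nodeReliability"))
#' @rdname accessors
#' @export
setMethod("nodeReliability", "ClusterTree", function(x) x@reliability)

#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @rdname accessors
#' @export
setMethod("alignmentMatrix", "AlignedFamily", function(x) {
    if (!length(x@alignment))
        return(matrix(character(), 0, 0))
    m <- do.call(rbind, strsplit(as.character(x@alignment), ""))
    rownames(m) <- names(x@alignment)
    m
})

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)
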