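#' Write a ClusterTree as Newick
#'
#' Branch lengths are node-height differences (so all leaves lie at the
#' root height); when the jackknife has been run, internal nodes carry
#' their reliability flag (\code{1} reliable, \code{0} unreliable) as node
#' labels.
#'
#' @param tree a [ClusterTree-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
    stopifnot(methods::is(tree, "ClusterTree"))
    ph <- tree@phylo
    if (is.null(ph$tip.label) || length(ph$tip.label) < 2L)
        .stopf("cannot write a tree with fewer than 2 leaves")
    rel <- tree@reliability
    if (!all(is.na(rel)))
        ph$node.label <- ifelse(is.na(rel), "", as.character(as.integer(rel)))
    .atomicWrite(function(tmp) ape::write.tree(ph, file = tmp,
                                               digits = 15), path)
}

#' Read a Newick tree back into a ClusterTree
#'
#' Inverse of [writeNewick()] for ultrametric trees: node heights are
#' recovered from root-to-node path lengths and numeric \code{0}/\code{1}
#' node labels are interpreted as reliability flags.
#'
#' @param path path to a Newick file.
#' @return a [ClusterTree-class].
#' @export
readNewick <- function(path) {
    ph <- ape::read.tree(path)
    if (is.null(ph)) .stopf("could not parse Newick file '%s'", path)
    nt <- length(ph$tip.label)
    depth <- ape::node.depth.edgelength(ph)
    hts <- max(depth[seq_len(nt)]) - depth[(nt + 1L):(nt + ph$Nnode)]
    names(hts) <- as.character((nt + 1L):(nt + ph$Nnode))
    rel <- setNames(rep(NA, ph$Nnode), names(hts))
    if (!is.null(ph$node.label)) {
        lab <- ph$node.label
        rel[lab %in% c("0", "1")] <- as.logical(as.integer(
            lab[lab %in% c("0", "1")]))
    }
    methods::new("ClusterTree", phylo = ph, heights = hts, reliability = rel)
}
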