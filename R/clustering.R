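#' Transform structural-similarity Z-scores into distances
#'
#' Converts a symmetric matrix of pairwise structure-similarity scores
#' \eqn{S_{ij}} (self-scores \eqn{S_{ii}} on the diagonal) into a distance
#' matrix.  The default transform is
#' \deqn{D_{ij} = 100 (1 - 2 S_{ij} / (S_{ii} + S_{jj}))}
#' which is zero for a structure against itself, decreases strictly with
#' increasing similarity at fixed self-scores, and lives on a 0-100 scale.
#' Pairs whose similarity exceeds the self-score average (which would give
#' a negative distance) are clamped to 0 and reported.
#'
#' @param S a [SimilarityMatrix-class].
#' @param transform \code{"default"} or a function taking the similarity
#'   matrix and returning a same-shaped distance matrix.
#' @return a [DistanceMatrix-class].
#' @examples
#' m <- matrix(c(40, 10, 10, 40), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' distValues(similarityToDistance(methods::new("SimilarityMatrix", values = m)))
#' @export
similarityToDistance <- function(S, transform = "default") {
    stopifnot(methods::is(S, "SimilarityMatrix"))
    m <- S@values
    if (is.function(transform)) {
        d <- transform(m)
    } else if (identical(transform, "default")) {
        self <- diag(m)
        viol <- which(m > pmin(outer(self, self, pmin)) &
                      row(m) != col(m), arr.ind = TRUE)
        if (nrow(viol))
            message(sprintf(
                "similarityToDistance: %d pair(s) with Sij > min(Sii, Sjj)",
                nrow(viol) / 2L))
        d <- 100 * (1 - 2 * m / outer(self, self, `+`))
        neg <- d < 0 & row(d) != col(d)
        if (any(neg)) {
            message(sprintf(
                "similarityToDistance: clamped %d negative distance(s) to 0",
                sum(neg) / 2L))
            d[neg] <- 0
        }
    } else {
        .stopf("unknown transform '%s'", transform)
    }
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- dimnames(m)
    methods::new("DistanceMatrix", values = d)
}

# core UPGMA agglomeration; returns hclust-style merge/height plus the
# leaf-label set of every merge, with the deterministic tie rule: among
# equally close pairs, merge the pair whose (sorted) smallest member labels
# are lexicographically smallest
.upgmaCore <- function(m) {
    n <- nrow(m)
    labs <- rownames(m)
    cur <- m
    slotOf <- seq_len(n)           # cluster slot -> row of cur
    alive <- rep(TRUE, n)
    members <- as.list(seq_len(n)) # leaf indices per cluster
    minLab <- labs                 # lexicographically smallest member label
    sizes <- rep(1L, n)
    code <- -seq_len(n)            # hclust coding: -leaf or +merge
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    clades <- vector("list", n - 1L)
    for (step in seq_len(n - 1L)) {
        idx <- which(alive)
        sub <- cur[idx, idx, drop = FALSE]
        off <- sub
        off[lower.tri(off, diag = TRUE)] <- Inf
        dmin <- min(off)
        # distances within a relative epsilon of the minimum count as
        # tied, so that exact ties perturbed only by floating-point
        # round-off (size-weighted averaging of equal values) still fall
        # to the deterministic label rule
        cand <- which(off <= dmin + abs(dmin) * 1e-9 + 1e-12,
                      arr.ind = TRUE)
        if (nrow(cand) > 1L) {
            keys <- apply(cand, 1L, function(rc) {
                p <- sort(c(minLab[idx[rc[1]]], minLab[idx[rc[2]]]))
                paste(p, collapse = "\r")
            })
            cand <- cand[order(keys)[1L], , drop = FALSE]
        }
        i <- idx[cand[1, 1]]; j <- idx[cand[1, 2]]
        # order children deterministically by smallest member label
        if (minLab[j] < minLab[i]) { k <- i; i <- j; j <- k }
        merge[step, ] <- c(code[i], code[j])
        height[step] <- dmin
        clades[[step]] <- labs[sort(c(members[[i]], members[[j]]))]
        # size-weighted arithmetic mean linkage
        newd <- (sizes[i] * cur[i, ] + sizes[j] * cur[j, ]) /
            (sizes[i] + sizes[j])
        cur[i, ] <- newd
        cur[, i] <- newd
        cur[i, i] <- 0
        members[[i]] <- c(members[[i]], members[[j]])
        sizes[i] <- sizes[i] + sizes[j]
        minLab[i] <- min(minLab[i], minLab[j])
        code[i] <- step
        alive[j] <- FALSE
    }
    list(merge = merge, height = height, clades = clades, labels = labs)
}

.hclustOrder <- function(merge) {
    n <- nrow(merge) + 1L
    rec <- function(k) {
        if (k < 0L) return(-k)
        c(rec(merge[k, 1L]), rec(merge[k, 2L]))
    }
    rec(nrow(merge))
}

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic averages: repeatedly joins
#' the closest pair of clusters, the distance from a merged cluster to any
#' other being the size-weighted mean of its parts.  The resulting tree is
#' ultrametric, with each merge placed at half the merge distance.  Ties
#' are broken deterministically (lexicographically smallest pair of
#' smallest member labels).
#'
#' @param D a [DistanceMatrix-class] with at least two structures.
#' @return a [ClusterTree-class] with per-node heights; reliability flags
#'   are \code{NA} until [jackknifeReliability()] is run.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgmaTree(methods::new("DistanceMatrix", values = m))
#' nodeHeights(tr)  # 4 (root) and 1
#' @export
upgmaTree <- function(D) {
    stopifnot(methods::is(D, "DistanceMatrix"))
    m <- D@values
    if (anyNA(m)) .stopf("distance matrix contains NA/NaN")
    n <- nrow(m)
    if (n < 2L) .stopf("UPGMA needs at least 2 structures")
    core <- .upgmaCore(m)
    hc <- structure(list(merge = core$merge, height = core$height,
                         order = .hclustOrder(core$merge),
                         labels = core$labels, method = "average",
                         call = NULL, dist.method = NULL),
                    class = "hclust")
    ph <- ape::as.phylo(hc)
    nt <- length(ph$tip.label)
    depth <- ape::node.depth.edgelength(ph)
    hts <- max(depth[seq_len(nt)]) - depth[(nt + 1L):(nt + ph$Nnode)]
    names(hts) <- as.character((nt + 1L):(nt + ph$Nnode))
    methods::new("ClusterTree", phylo = ph, heights = hts,
                 reliability = setNames(rep(NA, ph$Nnode), names(hts)))
}

# clade label sets per internal node, named by phylo node number
.treeClades <- function(ph) {
    pp <- ape::prop.part(ph)
    labs <- attr(pp, "labels")
    nt <- length(ph$tip.label)
    out <- lapply(pp, function(i) sort(labs[i]))
    names(out) <- as.character((nt + 1L):(nt + ph$Nnode))
    out
}

#' Leave-one-out (Lanyon jackknife) node reliability of the UPGMA tree
#'
#' Each structure is singled out in turn and the tree is rebuilt from the
#' remaining structures (similarity to distance transform re-applied to
#' the reduced matrix, then UPGMA).  An internal node of the full tree is
#' reliable only if, in every replicate, its clade restricted to the
#' surviving structures is either of size below two (vacuously present) or
#' appears as a clade of the replicate tree.
#'
#' @param S a [SimilarityMatrix-class] with at least 4 structures.
#' @param transform passed to [similarityToDistance()].
#' @return a list with components \code{tree} (the full
#'   [ClusterTree-class], reliability flags filled in) and \code{report}
#'   (data.frame: node, clade, reliable, absentIn).
#' @export
jackknifeReliability <- function(S, transform = "default") {
    stopifnot(methods::is(S, "SimilarityMatrix"))
    labs <- rownames(S@values)
    n <- length(labs)
    if (n < 4L)
        .stopf("jackknife needs at least 4 structures (no testable internal node below that)")
    full <- upgmaTree(similarityToDistance(S, transform))
    clades <- .treeClades(full@phylo)
    absent <- setNames(vector("list", length(clades)), names(clades))
    for (drop in labs) {
        keep <- setdiff(labs, drop)
        sub <- methods::new("SimilarityMatrix",
                            values = S@values[keep, keep, drop = FALSE])
        reptree <- upgmaTree(similarityToDistance(sub, transform))
        repClades <- .treeClades(reptree@phylo)
        repKeys <- vapply(repClades, paste, "", collapse = "\r")
        for (nd in names(clades)) {
            restricted <- setdiff(clades[[nd]], drop)
            if (length(restricted) < 2L) next  # vacuously present
            if (!(paste(restricted, collapse = "\r") %in% repKeys))
                absent[[nd]] <- c(absent[[nd]], drop)
        }
    }
    rel <- vapply(absent, function(a) length(a) == 0L, logical(1))
    full@reliability <- rel
    report <- data.frame(
        node = as.integer(names(clades)),
        clade = vapply(clades, paste, "", collapse = ","),
        reliable = rel,
        absentIn = vapply(absent, function(a)
            if (length(a)) paste(a, collapse = ",") else "", ""),
        stringsAsFactors = FALSE, row.names = NULL)
    list(tree = full, report = report)
}

#' Within- and between-family mean structural distances
#'
#' Computes, for a family assignment of the structures, the mean distance
#' over unordered within-family pairs (the \eqn{\langle D_{ij}\rangle} of
#' the family summary table; \code{NA} for singleton families, printed as
#' \code{"-"}) and the matrix of mean between-family distances over all
#' cross pairs.
#'
#' @param D a [DistanceMatrix-class].
#' @param families named character vector mapping every structure label to
#'   its family.
#' @return list with \code{within} (data.frame: family, n, meanWithin) and
#'   \code{between} (family x family matrix of mean cross distances, with
#'   within-family means on the diagonal).
#' @export
familyDistances <- function(D, families) {
    stopifnot(methods::is(D, "DistanceMatrix"))
    m <- D@values
    labs <- rownames(m)
    if (is.data.frame(families))
        families <- setNames(as.character(families[[2]]),
                             as.character(families[[1]]))
    unknown <- setdiff(names(families), labs)
    if (length(unknown))
        .stopf("family assignment names unknown label(s): %s",
               paste(unknown, collapse = ", "))
    missing <- setdiff(labs, names(families))
    if (length(missing))
        .stopf("no family assigned for label(s): %s",
               paste(missing, collapse = ", "))
    fam <- families[labs]
    fams <- sort(unique(fam))
    within <- data.frame(family = fams,
                         n = as.integer(table(fam)[fams]),
                         meanWithin = NA_real_, stringsAsFactors = FALSE)
    between <- matrix(NA_real_, length(fams), length(fams),
                      dimnames = list(fams, fams))
    for (a in seq_along(fams)) {
        ia <- which(fam == fams[a])
        if (length(ia) > 1L) {
            sub <- m[ia, ia]
            within$meanWithin[a] <- mean(sub[upper.tri(sub)])
        }
        between[a, a] <- within$meanWithin[a]
        for (b in seq_along(fams)) {
            if (b <= a) next
            ib <- which(fam == fams[b])
            between[a, b] <- between[b, a] <- mean(m[ia, ib])
        }
    }
    list(within = within, between = between)
}
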