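# Independent oracles used across the suite.  These deliberately do not
# share code with the package implementation they check.

# random strictly ultrametric distance matrix via a random rooted tree
# with decreasing node heights; D(a, b) = height of the lowest common
# ancestor (in merge-distance units)
randomUltrametric <- function(n, rootHeight = 100) {
    labs <- paste0("t", sprintf("%02d", seq_len(n)))
    D <- matrix(0, n, n, dimnames = list(labs, labs))
    build <- function(idx, h) {
        if (length(idx) < 2L) return(invisible())
        k <- sample(seq_len(length(idx) - 1L), 1L)
        g <- sample(idx)
        left <- g[seq_len(k)]; right <- g[-seq_len(k)]
        D[left, right] <<- h
        D[right, left] <<- h
        build(left, h * runif(1, 0.3, 0.8))
        build(right, h * runif(1, 0.3, 0.8))
    }
    build(seq_len(n), rootHeight)
    D
}

# tip-to-tip cophenetic distances of a ClusterTree, recomputed directly
# from the phylo edge lengths by an independent route
copheneticOf <- function(tree) {
    ph <- asPhylo(tree)
    as.matrix(ape::cophenetic.phylo(ph))
}

# exhaustive glocal alignment scorer: enumerates every alignment of the
# full motif against the sequence (free flanks, internal insertions,
# affine gap runs scored go + (len-1)*ge) by plain recursion
exhaustiveScore <- function(profile, sequence) {
    lo <- profile@logOdds
    go <- profile@gapOpen
    ge <- profile@gapExtend
    s <- strsplit(sequence, "")[[1]]
    m <- ncol(lo); n <- length(s)
    best <- -Inf
    rec <- function(i, j, last, acc) {
        if (i == m) {
            if (acc > best) best <<- acc
            return(invisible())
        }
        if (j <= n)
            rec(i + 1L, j + 1L, "M", acc + as.numeric(lo[s[j], i + 1L]))
        rec(i + 1L, j, "D", acc - if (last == "D") ge else go)
        if (i > 0L && i < m && j <= n)
            rec(i, j + 1L, "I", acc - if (last == "I") ge else go)
    }
    for (j0 in seq_len(n + 1L)) rec(0L, j0, "S", 0)
    best
}

# brute-force motif-window scan: z-scores the raw profile and evaluates
# every admissible window by direct summation
bruteForceMotifScan <- function(raw, hairpin, minLength = 8L,
                                maxLength = 18L) {
    ok <- !is.na(raw)
    z <- rep(NA_real_, length(raw))
    z[ok] <- (raw[ok] - mean(raw[ok])) /
        sqrt(mean((raw[ok] - mean(raw[ok]))^2))
    L <- length(raw)
    best <- NULL; bestScore <- -Inf
    for (s in 1:L) for (e in s:L) {
        len <- e - s + 1L
        if (len < minLength || len > maxLength) next
        if (s > hairpin[1] || e < hairpin[2]) next
        sc <- sum(z[s:e], na.rm = TRUE)
        if (sc > bestScore + 1e-12) { best <- c(s, e); bestScore <- sc }
        else if (abs(sc - bestScore) <= 1e-12 && !is.null(best)) {
            if (len < best[2] - best[1] + 1L ||
                (len == best[2] - best[1] + 1L && s < best[1]))
                best <- c(s, e)
        }
    }
    best
}

# clades (as sorted label sets) of an hclust average-linkage tree --
# independent UPGMA route used to cross-check jackknife bookkeeping
hclustClades <- function(D) {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    labs <- hc$labels
    res <- list()
    members <- function(k)
        if (k < 0) labs[-k] else res[[k]]
    for (k in seq_len(nrow(hc$merge)))
        res[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
    res
}

# minimal two-chain PDB text for reader tests
twoChainPdbText <- function() {
    c("ATOM      1  N   GLN A  10       0.000   0.000   0.000  1.00  0.00",
      "ATOM      2  CA  GLN A  10       1.458   0.000   0.000  1.00  0.00",
      "ATOM      3  CB  GLN A  10       2.000   1.400   0.000  1.00  0.00",
      "ATOM      4  N   ALA B   1       5.000   0.000   0.000  1.00  0.00",
      "ATOM      5  CA  ALA B   1       6.458   0.000   0.000  1.00  0.00",
      "END")
}
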