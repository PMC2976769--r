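simMat <- function(m) methods::new("SimilarityMatrix", values = m)
distMat <- function(m) methods::new("DistanceMatrix", values = m)

test_that("the default similarity transform has the declared arithmetic", {
    lab <- c("a", "b")
    m <- matrix(c(40, 10, 10, 40), 2, dimnames = list(lab, lab))
    D <- distValues(similarityToDistance(simMat(m)))
    expect_equal(D["a", "b"], 75)              # 100*(1 - 2*10/80)
    expect_equal(diag(D), c(a = 0, b = 0))

    # identical copy: Sij = Sii = Sjj -> distance 0
    m2 <- matrix(40, 2, 2, dimnames = list(lab, lab))
    expect_equal(distValues(similarityToDistance(simMat(m2)))["a", "b"], 0)

    # no similarity at all -> maximal distance 100
    m3 <- matrix(c(40, 0, 0, 40), 2, dimnames = list(lab, lab))
    expect_equal(distValues(similarityToDistance(simMat(m3)))["a", "b"], 100)

    # Sij above the self-score mean is clamped to distance 0
    m4 <- matrix(c(40, 45, 45, 40), 2, dimnames = list(lab, lab))
    expect_message(D4 <- similarityToDistance(simMat(m4)), "clamped")
    expect_equal(distValues(D4)["a", "b"], 0)
})

test_that("the similarity transform is strictly monotone decreasing", {
    lab <- paste0("s", 1:6)
    set.seed(31)
    for (rep in 1:20) {
        sij <- sort(runif(2, 0, 39))
        m <- diag(40, 4)
        m[1, 2] <- m[2, 1] <- sij[1]
        m[3, 4] <- m[4, 3] <- sij[2]
        m[1, 3] <- m[3, 1] <- m[1, 4] <- m[4, 1] <-
            m[2, 3] <- m[3, 2] <- m[2, 4] <- m[4, 2] <- 5
        dimnames(m) <- list(lab[1:4], lab[1:4])
        D <- distValues(similarityToDistance(simMat(m)))
        expect_gt(D[1, 2], D[3, 4])  # lower similarity, larger distance
    }
})

test_that("UPGMA reproduces hand-computable trees", {
    lab <- c("A", "B", "C")
    m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, dimnames = list(lab, lab))
    tr <- upgmaTree(distMat(m))
    expect_equal(sort(unname(nodeHeights(tr))), c(1, 4))
    expect_identical(ape::write.tree(asPhylo(tr)), "((A:1,B:1):3,C:4);")

    lab4 <- c("A", "B", "C", "D")
    m4 <- matrix(10, 4, 4, dimnames = list(lab4, lab4))
    diag(m4) <- 0
    m4["A", "B"] <- m4["B", "A"] <- 2
    m4["C", "D"] <- m4["D", "C"] <- 2
    tr4 <- upgmaTree(distMat(m4))
    expect_equal(sort(unname(nodeHeights(tr4))), c(1, 1, 5))
    clades <- lapply(ape::prop.part(asPhylo(tr4)), function(i)
        sort(asPhylo(tr4)$tip.label[i]))
    expect_true(any(vapply(clades, identical, TRUE, c("A", "B"))))
    expect_true(any(vapply(clades, identical, TRUE, c("C", "D"))))

    expect_error(upgmaTree(distMat(matrix(0, 1, 1,
        dimnames = list("A", "A")))), "at least 2")
    mNA <- m; mNA[1, 2] <- mNA[2, 1] <- NA
    expect_error(upgmaTree(distMat(mNA)), "finite|NA")
})

test_that("UPGMA trees are ultrametric and cophenetic-exact on ultrametric input", {
    set.seed(101)
    for (rep in 1:10) {
        n <- sample(4:12, 1)
        D <- randomUltrametric(n)
        tr <- upgmaTree(distMat(D))
        # ultrametricity: all leaves equidistant from the root
        ph <- asPhylo(tr)
        depth <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
        expect_lt(max(abs(depth - mean(depth))), 1e-9)
        # cophenetic identity against the generated matrix
        cop <- copheneticOf(tr)[rownames(D), colnames(D)]
        expect_lt(max(abs(cop - D)), 1e-9)
    }
})

test_that("UPGMA agrees with average-linkage hclust on general matrices", {
    set.seed(55)
    for (rep in 1:5) {
        n <- 9
        x <- matrix(rnorm(n * 3), n)
        D <- as.matrix(dist(x))
        dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
        tr <- upgmaTree(distMat(D))
        hc <- stats::hclust(stats::as.dist(D), method = "average")
        cop <- as.matrix(stats::cophenetic(hc))[rownames(D), colnames(D)]
        expect_lt(max(abs(copheneticOf(tr)[rownames(D), colnames(D)] - cop)),
                  1e-8)
    }
})

test_that("UPGMA ties are broken towards the lexicographically smallest pair", {
    lab <- c("b", "a", "c")
    m <- matrix(2, 3, 3, dimnames = list(lab, lab))
    diag(m) <- 0
    tr <- upgmaTree(distMat(m))          # all pairs tie at 2
    clades <- lapply(ape::prop.part(asPhylo(tr)), function(i)
        sort(asPhylo(tr)$tip.label[i]))
    expect_true(any(vapply(clades, identical, TRUE, c("a", "b"))))
})

test_that("jackknife marks all nodes reliable on clean clusters", {
    sim <- generateSimilarityMatrix(familySizes = c(3L, 3L), withinSD = 0,
                                    betweenSD = 0, selfSD = 0, seed = 2L)
    jk <- jackknifeReliability(sim$matrix)
    expect_true(all(nodeReliability(jk$tree)))
    expect_true(all(jk$report$absentIn == ""))

    # cross-check the replicate bookkeeping against an independent
    # UPGMA route (hclust) on every leave-one-out submatrix
    S <- scoreValues(sim$matrix)
    D <- distValues(similarityToDistance(sim$matrix))
    fullClades <- lapply(ape::prop.part(asPhylo(jk$tree)), function(i)
        sort(asPhylo(jk$tree)$tip.label[i]))
    for (drop in rownames(S)) {
        keep <- setdiff(rownames(S), drop)
        repClades <- hclustClades(D[keep, keep])
        for (cl in fullClades) {
            r <- setdiff(cl, drop)
            if (length(r) < 2L || length(r) == length(keep)) next
            expect_true(any(vapply(repClades, identical, TRUE, sort(r))))
        }
    }
})

test_that("jackknife flags the node joining an ambiguous taxon", {
    # two clean clusters plus a conflicted taxon 'amb': strongly similar
    # to a1 alone (distance 15) but closer to the b cluster on average
    # (55 vs mean(15, 87.5, 87.5) = 63.3), so the full tree puts it with
    # the b's while dropping a2 or a3 pulls it to the a side -- the node
    # joining amb must lose support
    labs <- c("a1", "a2", "a3", "b1", "b2", "b3", "amb")
    S <- matrix(5, 7, 7, dimnames = list(labs, labs))
    diag(S) <- 40
    for (p in list(c("a1","a2"), c("a1","a3"), c("a2","a3"),
                   c("b1","b2"), c("b1","b3"), c("b2","b3")))
        S[p[1], p[2]] <- S[p[2], p[1]] <- 35
    S["amb", "a1"] <- S["a1", "amb"] <- 34
    S["amb", c("b1","b2","b3")] <- S[c("b1","b2","b3"), "amb"] <- 18
    jk <- jackknifeReliability(simMat(S))
    expect_false(all(nodeReliability(jk$tree)))
    # the unreliable clades are exactly those containing 'amb' (root aside)
    bad <- jk$report[!jk$report$reliable, ]
    expect_true(all(grepl("amb", bad$clade)))
    expect_error(jackknifeReliability(simMat(S[1:2, 1:2])), "at least 4")
    expect_error(jackknifeReliability(simMat(S[1:3, 1:3])), "at least 4")
})

test_that("family distance summaries follow the pair-mean and singleton rules", {
    labs <- c("A", "B", "X", "Y")
    D <- matrix(0, 4, 4, dimnames = list(labs, labs))
    D["A", "B"] <- D["B", "A"] <- 23.32
    D["X", "Y"] <- D["Y", "X"] <- 46.2
    D["A", c("X", "Y")] <- D[c("X", "Y"), "A"] <- 50
    D["B", c("X", "Y")] <- D[c("X", "Y"), "B"] <- 60
    fam <- c(A = "GH19", B = "GH19", X = "GH22", Y = "GH24")
    fd <- familyDistances(distMat(D), fam)
    expect_equal(fd$within$meanWithin[fd$within$family == "GH19"], 23.32)
    # singleton families have no within-family mean
    expect_true(is.na(fd$within$meanWithin[fd$within$family == "GH22"]))
    # two singletons: between-family mean is their single distance
    expect_equal(fd$between["GH22", "GH24"], 46.2)
    expect_equal(fd$between["GH19", "GH22"], mean(c(50, 60)))
    expect_error(familyDistances(distMat(D), c(fam, Z = "GH46")), "unknown")
    expect_error(familyDistances(distMat(D), fam[1:3]), "no family")
})
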