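aamat <- function(...) {
    rows <- c(...)
    m <- do.call(rbind, strsplit(rows, ""))
    rownames(m) <- paste0("s", seq_along(rows))
    m
}

test_that("logo information content matches its closed forms", {
    lg <- buildLogo(aamat("AA", "AA", "AA"))
    expect_equal(lg@information, rep(log2(20), 2))
    expect_identical(lg@consensus, c("A", "A"))
    # 50/50 two-residue column: log2(20) - 1 bits
    lg2 <- buildLogo(aamat("AC", "CC"))
    expect_equal(lg2@information[1], log2(20) - 1)
    # uniform column over the 20 residues: 0 bits
    m <- matrix(ghMotif:::AA20, ncol = 1)
    rownames(m) <- paste0("s", 1:20)
    expect_equal(buildLogo(m)@information, 0)
    # all-gap position: IC 0, frequencies 0
    lg3 <- buildLogo(aamat("A-", "A-"))
    expect_equal(lg3@information[2], 0)
    expect_equal(sum(lg3@frequencies[, 2]), 0)
})

test_that("profile emissions follow the pseudocount formula", {
    # single sequence, alpha 0: probability 1 on the observed residue
    pm <- buildProfile(aamat("ACD"), alpha = 0)
    expect_equal(unname(exp(pm@logOdds["A", 1])) / 20, 1)
    expect_equal(unname(pm@logOdds["C", 1]), -Inf)
    # all-Trp column, 10 unit weights, alpha 1, uniform background:
    # emission (10 + 1/20) / 11
    m <- aamat(rep("W", 10))
    pm2 <- buildProfile(m, alpha = 1)
    expect_equal(unname(exp(pm2@logOdds["W", 1])) / 20, 10.05 / 11)
    # alpha -> infinity: log-odds -> 0 everywhere
    pm3 <- buildProfile(aamat("ACD"), alpha = 1e9)
    expect_lt(max(abs(pm3@logOdds)), 1e-6)
})

test_that("glocal scoring gives the consensus its maximal score", {
    g <- generateMsa(n = 20L, L = 40L, motifRange = c(10L, 19L), seed = 17L)
    block <- alignmentMatrix(g$msa)[, 10:19]
    pm <- buildProfile(block)
    cons <- paste(buildLogo(block)@consensus, collapse = "")
    sc <- scoreSequence(pm, cons)
    expect_equal(sc$score, sum(apply(pm@logOdds, 2, max)))
    expect_equal(sc$start, 1L)
    # glocal semantics: background flanks shift the start, not the score
    sc2 <- scoreSequence(pm, paste0("AAAA", cons, "WWWW"))
    expect_equal(sc2$score, sc$score)
    expect_equal(sc2$start, 5L)
    # deletion cap: too-short sequences are inadmissible
    expect_equal(scoreSequence(pm, "AC", maxDeletions = 2)$score, -Inf)
    # unknown residues are neutral
    expect_equal(scoreSequence(pm, gsub("^.", "X", cons))$score,
                 sum(apply(pm@logOdds, 2, max)[-1]))
})

test_that("dynamic programming equals the exhaustive alignment oracle", {
    set.seed(23)
    alphabet <- c("A", "C", "D", "E")   # reduced alphabet
    for (rep in 1:40) {
        m <- sample(2:4, 1)
        L <- sample(1:8, 1)
        block <- matrix(sample(alphabet, 3 * m, replace = TRUE), 3, m)
        rownames(block) <- paste0("s", 1:3)
        pm <- buildProfile(block, alpha = 0.5)
        seq <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
        expect_equal(scoreSequence(pm, seq)$score,
                     exhaustiveScore(pm, seq),
                     tolerance = 1e-9)
    }
})

test_that("search evaluation reports the right rates and NA conventions", {
    g <- generateMsa(n = 20L, L = 40L, motifRange = c(10L, 19L), seed = 29L)
    block <- alignmentMatrix(g$msa)[, 10:19]
    pm <- buildProfile(block)
    cons <- buildLogo(block)@consensus
    db <- generateSequenceDb(cons, nPos = 10L, nNeg = 40L,
                             divergence = 0, seed = 2L)
    # threshold -Inf: everything is a hit
    ev <- evaluateSearch(pm, db$sequences, db$member, threshold = -Inf)
    expect_equal(ev@tpr, 1)
    expect_equal(ev@fpr, 1)
    # threshold above the consensus maximum: nothing is a hit
    hi <- sum(apply(pm@logOdds, 2, max)) + 1
    ev2 <- evaluateSearch(pm, db$sequences, db$member, threshold = hi)
    expect_equal(ev2@tpr, 0)
    expect_equal(ev2@fpr, 0)
    # empty classes give NA rates
    ev3 <- evaluateSearch(pm, db$sequences[db$member], db$member[db$member],
                          threshold = 0)
    expect_true(is.na(ev3@fpr))
    expect_false(is.na(ev3@tpr))
    # hand arithmetic on a crafted score split
    scores <- vapply(db$sequences, function(s) scoreSequence(pm, s)$score, 0)
    thr <- sort(scores[db$member])[3]   # admits 8 of 10 members
    ev4 <- evaluateSearch(pm, db$sequences, db$member, threshold = thr)
    expect_equal(ev4@tpr, mean(scores[db$member] >= thr))
    expect_equal(ev4@fpr, mean(scores[!db$member] >= thr))
})

test_that("raising the threshold never raises TPR or FPR", {
    g <- generateMsa(n = 15L, L = 40L, motifRange = c(12L, 21L), seed = 37L)
    block <- alignmentMatrix(g$msa)[, 12:21]
    pm <- buildProfile(block)
    db <- generateSequenceDb(buildLogo(block)@consensus, nPos = 25L,
                             nNeg = 60L, divergence = 0.3, seed = 3L)
    thrs <- seq(-5, 30, length.out = 12)
    evs <- lapply(thrs, function(t)
        evaluateSearch(pm, db$sequences, db$member, threshold = t))
    tpr <- vapply(evs, function(e) e@tpr, 0)
    fpr <- vapply(evs, function(e) e@fpr, 0)
    expect_true(all(diff(tpr) <= 1e-12))
    expect_true(all(diff(fpr) <= 1e-12))
})

test_that("profiles built from half the members generalize to the rest", {
    g <- generateMsa(n = 40L, L = 60L, motifRange = c(20L, 32L), seed = 41L)
    m <- alignmentMatrix(g$msa)[, 20:32]
    train <- m[1:20, , drop = FALSE]
    pm <- buildProfile(train)
    db <- generateSequenceDb(g$truth$consensus, nPos = 30L, nNeg = 200L,
                             divergence = 0.1, seed = 7L)
    pm <- calibrateThreshold(pm, n = 600L,
                             length = as.integer(
                                 stats::median(nchar(db$sequences))),
                             fpr = 0.01, seed = 11L)
    ev <- evaluateSearch(pm, db$sequences, db$member)
    expect_gte(ev@tpr, 0.9)
    expect_lte(ev@fpr, 0.05)
})
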