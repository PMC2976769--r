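test_that("Henikoff weights down-weight duplicates and keep symmetry", {
    # identical sequences share weight equally
    w <- sequenceWeights(newAlignedFamily("t", c(a = "ACD", b = "ACD",
                                                 c = "ACD")))
    expect_equal(unname(w), c(1, 1, 1))
    # hand computation on the 3x2 toy: col1 A,A,G -> 1/4,1/4,1/2;
    # col2 C,C,C -> 1/3 each; rescaled to sum 3
    w2 <- sequenceWeights(newAlignedFamily("t", c(a = "AC", b = "AC",
                                                  c = "GC")))
    expect_equal(unname(w2), c(0.875, 0.875, 1.25))
    expect_gt(w2[["c"]], w2[["a"]])
    # single sequence
    expect_equal(unname(sequenceWeights(newAlignedFamily("t", c(a = "ACD")))),
                 1)
    # weights sum to n and are permutation-equivariant
    g <- generateMsa(n = 12L, L = 40L, motifRange = c(10L, 20L), seed = 8L)
    m <- alignmentMatrix(g$msa)
    w3 <- sequenceWeights(m)
    expect_equal(sum(w3), nrow(m))
    perm <- sample(nrow(m))
    expect_equal(unname(sequenceWeights(m[perm, ])), unname(w3[perm]))
})

test_that("entropy conservation index matches its closed forms", {
    expect_equal(entropyConservation(c(1, rep(0, 19))), 0)
    expect_equal(entropyConservation(c(0.5, 0.5, rep(0, 18))), log(0.5))
    expect_equal(entropyConservation(rep(1 / 20, 20)), -log(20))
    expect_error(entropyConservation(c(0.5, 0.4)), "sum to 1")
})

test_that("raw index is maximal only for invariant columns and monotone", {
    # replacing any minority residue by the column majority never
    # decreases the index
    set.seed(13)
    for (rep in 1:20) {
        col <- sample(c("A", "C", "G"), 10, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
        f <- function(cc) entropyConservation(
            vapply(ghMotif:::AA20, function(a) mean(cc == a), 0))
        maj <- names(which.max(table(col)))
        i <- which(col != maj)
        if (!length(i)) next
        col2 <- col; col2[i[1]] <- maj
        expect_gte(f(col2), f(col) - 1e-12)
        expect_lte(f(col), 0)
    }
})

test_that("smoothing averages a centred shrinking window", {
    expect_equal(smoothProfile(c(0, 3, 0))[2], 1)
    expect_equal(smoothProfile(rep(2, 7)), rep(2, 7))
    expect_equal(smoothProfile(c(6, 0, 0, 0))[1], 3)  # edge: mean of 1..2
    # flagged columns stay NA and are skipped inside windows
    x <- c(1, NA, 4)
    expect_equal(smoothProfile(x), c(1, NA, 4))
    expect_error(smoothProfile(1:3, window = 2), "odd")
})

test_that("normalization gives population z-scores and affine invariance", {
    expect_equal(normalizeProfile(c(1, 2, 3)),
                 c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
    expect_warning(z <- normalizeProfile(c(2, 2, 2)), "zero-variance")
    expect_equal(z, c(0, 0, 0))
    x <- rnorm(30)
    expect_equal(normalizeProfile(3.7 * x + 11), normalizeProfile(x))
    out <- normalizeProfile(c(NA, 1, 5, NA, 3))
    expect_true(all(is.na(out[c(1, 4)])))
    expect_equal(mean(out, na.rm = TRUE), 0)
    expect_equal(sqrt(mean(out[!is.na(out)]^2)), 1)
})

test_that("profiles have unit-sum frequencies and normalized indices", {
    g <- generateMsa(n = 30L, L = 60L, motifRange = c(20L, 32L), seed = 21L)
    prof <- conservationProfile(g$msa)
    ok <- !prof@flagged
    expect_true(all(abs(colSums(prof@frequencies[, ok]) - 1) < 1e-9))
    expect_lt(abs(mean(prof@normalized[ok])), 1e-9)
    expect_lt(abs(sqrt(mean(prof@normalized[ok]^2)) - 1), 1e-9)
    expect_true(all(prof@raw[ok] <= 1e-12))
})

test_that("duplicate down-weighting suppresses redundancy artefacts", {
    # a 10-sequence alignment where sequence 1 carries a minority W;
    # flooding the alignment with 6 exact copies of sequence 1 moves the
    # unweighted W frequency from 0.2 to 0.5, but the weighted frequency
    # must stay close to its duplicate-free value
    rows <- c(s1 = "WADKL", s2 = "WCEKL", s3 = "ACDKM", s4 = "ADDKM",
              s5 = "AEDRM", s6 = "AFDRM", s7 = "AGERN", s8 = "AHERN",
              s9 = "AIFRN", s10 = "AKFRN")
    base <- conservationProfile(newAlignedFamily("t", rows))
    dup <- c(rows, setNames(rep(rows[["s1"]], 6), paste0("d", 1:6)))
    prof <- conservationProfile(newAlignedFamily("t", dup))
    fW0 <- unname(base@frequencies["W", 1])
    fWdup <- unname(prof@frequencies["W", 1])
    expect_lt(fWdup, 0.4)                      # unweighted would be 0.5
    expect_lt(abs(fWdup - fW0), abs(0.5 - fW0))  # closer than unweighted
})

test_that("representative mapping assigns author numbers and round-trips", {
    msa <- newAlignedFamily("t", c(rep1 = "A-CD", x = "AGCD"), "rep1")
    prof <- suppressWarnings(conservationProfile(msa))
    prof <- mapToRepresentative(prof, msa, startResno = 10L)
    expect_equal(prof@residueNumbers, c(10L, NA, 11L, 12L))
    # inverse lookup: residue -> column -> residue is the identity
    resno <- prof@residueNumbers
    for (r in resno[!is.na(resno)])
        expect_equal(resno[which(resno == r)], r)
    msa2 <- newAlignedFamily("t", c(rep1 = "----", x = "AGCD"), "rep1")
    prof2 <- suppressWarnings(conservationProfile(msa2))
    expect_error(mapToRepresentative(prof2, msa2), "all gaps")
})

test_that("representative mapping cross-checks against structure residues", {
    msa <- newAlignedFamily("t", c(rep1 = "GQ", x = "GQ"), "rep1")
    prof <- suppressWarnings(conservationProfile(msa))
    st <- generatePeptide(rep(-120, 2), rep(130, 2),
                          resnames = c("GLY", "GLN"))
    expect_silent(mapToRepresentative(prof, msa, 1L, st))
    stBad <- generatePeptide(rep(-120, 2), rep(130, 2),
                             resnames = c("GLY", "ALA"))
    expect_error(mapToRepresentative(prof, msa, 1L, stBad), "mismatch")
})

test_that("motif extraction matches the brute-force window scan", {
    for (seed in c(3L, 14L, 27L)) {
        g <- generateMsa(seed = seed)
        prof <- conservationProfile(g$msa)
        mot <- extractMotif(prof, c(43L, 49L))
        oracle <- bruteForceMotifScan(prof@raw, c(43L, 49L))
        expect_equal(unname(mot@columnRange), oracle)
        # and the planted block is recovered exactly
        expect_equal(unname(mot@columnRange), c(40L, 52L))
    }
})

test_that("motif extraction tie and overflow rules behave as documented", {
    # flat profile: every window ties, so the shortest admissible window
    # (here the hairpin itself) wins
    flat <- methods::new("ConservationProfile", familyId = "t",
        frequencies = matrix(1 / 20, 20, 30), gapFraction = rep(0, 30),
        flagged = rep(FALSE, 30), raw = rep(-1, 30),
        smoothed = rep(-1, 30), normalized = rep(0, 30),
        residueNumbers = 1:30, representativeId = "r")
    mot <- suppressWarnings(extractMotif(flat, c(11L, 18L)))
    expect_equal(unname(mot@columnRange), c(11L, 18L))
    # hairpin longer than the maximal window: returned as-is with warning
    expect_warning(big <- extractMotif(flat, c(5L, 26L)), "exceeds")
    expect_equal(unname(big@columnRange), c(5L, 26L))
    # a sharp peak inside the hairpin stays inside the returned window
    peak <- flat
    peak@raw[14] <- 0
    mot2 <- suppressWarnings(extractMotif(peak, c(12L, 16L)))
    expect_true(mot2@columnRange[1] <= 14 && mot2@columnRange[2] >= 14)
    expect_equal(unname(mot2@columnRange),
                 bruteForceMotifScan(peak@raw, c(12L, 16L)))
})
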