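#' Position-based (Henikoff) sequence weights
#'
#' Down-weights redundant sequences: at each column, a residue type shared
#' by s sequences among r distinct types contributes 1/(r s) to each of
#' those sequences; the per-sequence sums are rescaled so that the weights
#' sum to the number of sequences.  Gap (\code{-}) and unknown (\code{X})
#' symbols do not contribute.  Exact duplicates therefore share weight,
#' while a duplicate-free alignment keeps equal weights.
#'
#' @param msa an [AlignedFamily-class] or character matrix
#'   (sequences x columns).
#' @return numeric weights, one per sequence, summing to the number of
#'   sequences.
#' @examples
#' aln <- newAlignedFamily("toy", c(a = "AC", b = "AC", c = "GC"))
#' sequenceWeights(aln)  # the distinct sequence outweighs the duplicates
#' @export
sequenceWeights <- function(msa) {
    m <- if (methods::is(msa, "AlignedFamily")) alignmentMatrix(msa) else msa
    n <- nrow(m)
    if (n == 0L) .stopf("empty alignment")
    if (n == 1L) return(setNames(1, rownames(m)))
    w <- numeric(n)
    used <- 0L
    for (j in seq_len(ncol(m))) {
        col <- m[, j]
        ok <- !.isGapSym(col)
        if (!any(ok)) next
        used <- used + 1L
        tab <- table(col[ok])
        r <- length(tab)
        w[ok] <- w[ok] + 1 / (r * as.numeric(tab[col[ok]]))
    }
    if (used == 0L || sum(w) == 0)
        w <- rep(1, n)             # all-gap alignment: fall back to equal
    w <- w * n / sum(w)
    setNames(w, rownames(m))
}

#' Entropy conservation index of one column
#'
#' The raw AL2CO-style entropy measure \eqn{C = \sum_a f_a \ln f_a}
#' (natural log) over the 20 amino-acid frequencies of a column: 0 for an
#' invariant column, \eqn{-\ln 20} for a uniform one; higher means more
#' conserved.
#'
#' @param f numeric frequency vector summing to 1 (zeros allowed).
#' @return the raw conservation index (non-positive).
#' @examples
#' entropyConservation(c(1, rep(0, 19)))          # 0
#' entropyConservation(rep(1 / 20, 20))           # -log(20)
#' @export
entropyConservation <- function(f) {
    if (abs(sum(f) - 1) > 1e-6)
        .stopf("frequencies must sum to 1 (got %.6f)", sum(f))
    nz <- f[f > 0]
    sum(nz * log(nz))
}

#' Moving-average smoothing of a conservation profile
#'
#' Centred moving average of odd window size; the window shrinks at the
#' profile edges and over flagged (\code{NA}) columns, averaging whatever
#' defined values fall inside it.  Flagged columns stay \code{NA}.
#'
#' @param x numeric indices (\code{NA} = flagged column).
#' @param window odd window size (default 3).
#' @return smoothed numeric vector of the same length.
#' @export
smoothProfile <- function(x, window = 3L) {
    window <- as.integer(window)
    if (window < 1L || window %% 2L == 0L)
        .stopf("window must be a positive odd integer")
    h <- window %/% 2L
    L <- length(x)
    out <- rep(NA_real_, L)
    for (i in seq_len(L)) {
        if (is.na(x[i])) next
        win <- x[max(1L, i - h):min(L, i + h)]
        out[i] <- mean(win, na.rm = TRUE)
    }
    out
}

#' Z-score normalization of a conservation profile
#'
#' Rescales the defined (unflagged) columns to mean 0 and population
#' standard deviation 1.  A zero-variance profile yields all zeros with a
#' warning.  Invariant under positive affine transforms of the input.
#'
#' @param x numeric indices (\code{NA} = flagged column, left \code{NA}).
#' @return normalized numeric vector.
#' @export
normalizeProfile <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2L)
        .stopf("need at least 2 unflagged columns to normalize")
    mu <- mean(x[ok])
    s <- .popSD(x[ok])
    out <- rep(NA_real_, length(x))
    if (s == 0) {
        .warnf("zero-variance profile: normalized indices set to 0")
        out[ok] <- 0
    } else {
        out[ok] <- (x[ok] - mu) / s
    }
    out
}

#' Full conservation profile of a family alignment
#'
#' Computes Henikoff sequence weights, per-column weighted amino-acid
#' frequencies and gap fractions, the raw entropy index, its smoothed
#' (window 3 by default) and z-normalized versions, flagging columns whose
#' gap fraction exceeds \code{gapThreshold} (excluded from smoothing input
#' and normalization statistics).
#'
#' @param msa an [AlignedFamily-class].
#' @param window smoothing window (odd, default 3).
#' @param gapThreshold columns with a larger gap/unknown fraction are
#'   flagged (default 0.5).
#' @param weights optional precomputed sequence weights.
#' @return a [ConservationProfile-class] (residue numbers unmapped; see
#'   [mapToRepresentative()]).
#' @export
conservationProfile <- function(msa, window = 3L, gapThreshold = 0.5,
                                weights = NULL) {
    stopifnot(methods::is(msa, "AlignedFamily"))
    m <- alignmentMatrix(msa)
    if (!nrow(m) || !ncol(m)) .stopf("empty alignment")
    if (is.null(weights)) weights <- sequenceWeights(m)
    L <- ncol(m)
    freq <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
    gapFrac <- numeric(L)
    raw <- rep(NA_real_, L)
    for (j in seq_len(L)) {
        col <- m[, j]
        gap <- .isGapSym(col)
        gapFrac[j] <- mean(gap)
        if (all(gap)) next
        wsub <- weights[!gap]
        f <- vapply(AA20, function(a) sum(wsub[col[!gap] == a]), 0)
        f <- f / sum(wsub)
        freq[, j] <- f
        raw[j] <- entropyConservation(f)
    }
    flagged <- gapFrac > gapThreshold | is.na(raw)
    rawUse <- raw
    rawUse[flagged] <- NA_real_
    smoothed <- smoothProfile(rawUse, window)
    normalized <- if (sum(!flagged) >= 2L) normalizeProfile(smoothed)
                  else { .warnf("fewer than 2 unflagged columns: raw profile kept unnormalized")
                         smoothed }
    methods::new("ConservationProfile", familyId = msa@familyId,
                 frequencies = freq, gapFraction = gapFrac,
                 flagged = flagged, raw = rawUse, smoothed = smoothed,
                 normalized = normalized,
                 residueNumbers = rep(NA_integer_, L),
                 representativeId = msa@representativeId)
}

#' Map a conservation profile onto the representative's residue numbers
#'
#' Assigns to every alignment column where the representative sequence has
#' a residue the corresponding author residue number, counting from
#' \code{startResno}; columns where the representative has a gap get
#' \code{NA}.  Optionally cross-checks the representative's residue types
#' against a structure.
#'
#' @param profile a [ConservationProfile-class].
#' @param msa the [AlignedFamily-class] the profile was computed from.
#' @param startResno author number of the representative's first aligned
#'   residue.
#' @param structure optional [StructureModel-class]; when given, the
#'   mapping stops with an error at the first residue-type discrepancy
#'   between the representative sequence and the structure.
#' @return the profile with \code{residueNumbers} filled in.
#' @export
mapToRepresentative <- function(profile, msa, startResno = 1L,
                                structure = NULL) {
    stopifnot(methods::is(profile, "ConservationProfile"),
              methods::is(msa, "AlignedFamily"))
    m <- alignmentMatrix(msa)
    rep <- profile@representativeId
    if (!(rep %in% rownames(m)))
        .stopf("representative '%s' not in alignment", rep)
    row <- m[rep, ]
    keep <- !(row %in% "-")
    if (!any(keep))
        .stopf("representative row '%s' is all gaps", rep)
    resno <- rep(NA_integer_, length(row))
    resno[keep] <- as.integer(startResno) + seq_len(sum(keep)) - 1L
    if (!is.null(structure)) {
        a <- structure@atoms
        res <- unique(a[, c("resno", "resname")])
        code <- setNames(res$resname, res$resno)
        three <- .aaThree[row[keep]]
        got <- code[as.character(resno[keep])]
        bad <- which(!is.na(got) & !is.na(three) & got != three)
        if (length(bad)) {
            i <- bad[1]
            .stopf("representative/structure mismatch at residue %d: sequence %s vs structure %s",
                   resno[keep][i], three[i], got[i])
        }
    }
    profile@residueNumbers <- resno
    profile
}

.aaThree <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Extract the signature motif region around the beta-hairpin
#'
#' Among all contiguous column windows whose length lies in
#' \code{[minLength, maxLength]} and which fully contain the configured
#' beta-hairpin column range, returns the window maximizing the summed
#' z-scored raw conservation (ties: shortest window, then leftmost).
#' Because columns of above-average conservation contribute positively and
#' background columns negatively, the optimum extends exactly across a
#' contiguous conserved block; a plain windowed mean would instead shrink
#' towards the most conserved interior columns.  The z-scores are computed
#' from the unsmoothed raw index so that smoothing bleed does not drag
#' background columns into the motif.  A hairpin longer than
#' \code{maxLength} is returned as-is with a warning.
#'
#' @param profile a [ConservationProfile-class].
#' @param hairpinColumns integer length-2 start/end alignment columns of
#'   the hairpin.
#' @param minLength,maxLength admissible motif lengths (defaults 8 and 18,
#'   bracketing the 9-17 residue signature motifs of the lysozyme
#'   superfamily).
#' @return a [MotifRegion-class].
#' @export
extractMotif <- function(profile, hairpinColumns, minLength = 8L,
                         maxLength = 18L) {
    stopifnot(methods::is(profile, "ConservationProfile"))
    hp <- as.integer(hairpinColumns)
    L <- length(profile@normalized)
    if (length(hp) != 2L || anyNA(hp) || hp[1] > hp[2] ||
        hp[1] < 1L || hp[2] > L)
        .stopf("invalid hairpin column range")
    x <- tryCatch(normalizeProfile(profile@raw),
                  error = function(e) profile@raw)
    winScore <- function(s, e) sum(x[s:e], na.rm = TRUE)
    winMean <- function(s, e) mean(profile@normalized[s:e], na.rm = TRUE)
    hpLen <- hp[2] - hp[1] + 1L
    if (hpLen > maxLength) {
        .warnf("hairpin range (%d columns) exceeds maxLength %d: returning the hairpin range itself",
               hpLen, maxLength)
        best <- hp
    } else {
        best <- NULL; bestMean <- -Inf; bestLen <- Inf
        for (len in max(minLength, hpLen):maxLength) {
            if (len > L) break
            sLo <- max(1L, hp[2] - len + 1L)
            sHi <- min(hp[1], L - len + 1L)
            if (sLo > sHi) next
            for (s in sLo:sHi) {
                e <- s + len - 1L
                sc <- winScore(s, e)
                better <- sc > bestMean + 1e-12 ||
                    (abs(sc - bestMean) <= 1e-12 &&
                     (len < bestLen || (len == bestLen && s < best[1])))
                if (better) { best <- c(s, e); bestMean <- sc; bestLen <- len }
            }
        }
        if (is.null(best)) .stopf("no admissible motif window")
    }
    rr <- profile@residueNumbers[best[1]:best[2]]
    rr <- rr[!is.na(rr)]
    methods::new("MotifRegion", familyId = profile@familyId,
                 columnRange = as.integer(best),
                 residueRange = if (length(rr)) range(rr)
                                else c(NA_integer_, NA_integer_),
                 meanConservation = winMean(best[1], best[2]))
}
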