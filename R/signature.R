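#' Sequence-logo matrix of a motif alignment
#'
#' Per-position weighted relative amino-acid frequencies with information
#' content \eqn{IC = \log_2 20 - H_2(f)} (Shannon entropy in bits, no
#' small-sample correction): \eqn{\log_2 20 \approx 4.32} bits for an
#' invariant position, 0 for a uniform one.  All-gap positions get
#' \eqn{IC = 0}.
#'
#' @param motif an [AlignedFamily-class] or character matrix holding the
#'   aligned motif block.
#' @param weights optional sequence weights (default: Henikoff weights).
#' @return a [LogoMatrix-class].
#' @export
buildLogo <- function(motif, weights = NULL) {
    m <- if (methods::is(motif, "AlignedFamily")) alignmentMatrix(motif)
         else motif
    if (!nrow(m)) .stopf("empty motif alignment")
    if (is.null(weights)) weights <- sequenceWeights(m)
    L <- ncol(m)
    freq <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
    ic <- numeric(L)
    cons <- rep("-", L)
    for (j in seq_len(L)) {
        col <- m[, j]
        ok <- !.isGapSym(col)
        if (!any(ok)) next                 # all-gap: IC stays 0
        w <- weights[ok]
        f <- vapply(AA20, function(a) sum(w[col[ok] == a]), 0) / sum(w)
        freq[, j] <- f
        h2 <- -sum(f[f > 0] * log2(f[f > 0]))
        ic[j] <- log2(20) - h2
        cons[j] <- AA20[which.max(f)]
    }
    methods::new("LogoMatrix", frequencies = freq, information = ic,
                 consensus = cons)
}

#' Build a position-specific log-odds profile from a motif alignment
#'
#' Emission probabilities mix weighted observed counts with background
#' pseudocounts, \eqn{e(p, a) = (w_{p,a} + \alpha\, bg_a) / (W_p + \alpha)}
#' where \eqn{W_p} is the summed weight of non-gap rows at position p;
#' log-odds are \eqn{\ln(e / bg)}.  With \eqn{\alpha = 0} unseen residues
#' get \eqn{-\infty} log-odds.
#'
#' @param motif an [AlignedFamily-class] or character matrix.
#' @param weights optional sequence weights (default: Henikoff weights).
#' @param alpha pseudocount strength (default 1).
#' @param background length-20 background frequencies (default uniform).
#' @param gapOpen,gapExtend affine gap penalties in nats (defaults 4.0 and
#'   0.5).
#' @param threshold score threshold (default \code{NA}; see
#'   [calibrateThreshold()]).
#' @return a [ProfileModel-class].
#' @export
buildProfile <- function(motif, weights = NULL, alpha = 1,
                         background = rep(1 / 20, 20), gapOpen = 4.0,
                         gapExtend = 0.5, threshold = NA_real_) {
    m <- if (methods::is(motif, "AlignedFamily")) alignmentMatrix(motif)
         else motif
    if (!nrow(m) || !ncol(m)) .stopf("empty motif alignment")
    if (alpha < 0) .stopf("alpha must be >= 0")
    if (length(background) != 20L || abs(sum(background) - 1) > 1e-6)
        .stopf("background must be 20 frequencies summing to 1")
    background <- setNames(as.numeric(background), AA20)
    if (is.null(weights)) weights <- sequenceWeights(m)
    L <- ncol(m)
    lo <- matrix(-Inf, 20L, L, dimnames = list(AA20, NULL))
    for (j in seq_len(L)) {
        col <- m[, j]
        ok <- !.isGapSym(col)
        w <- weights[ok]
        cnt <- vapply(AA20, function(a) sum(w[col[ok] == a]), 0)
        W <- sum(w)
        if (W + alpha <= 0) .stopf("position %d has no counts and alpha = 0", j)
        e <- (cnt + alpha * background) / (W + alpha)
        lo[, j] <- ifelse(e > 0, log(e / background), -Inf)
    }
    methods::new("ProfileModel", logOdds = lo, background = background,
                 gapOpen = gapOpen, gapExtend = gapExtend,
                 threshold = threshold)
}

#' Score a sequence against a profile (glocal affine-gap alignment)
#'
#' Best alignment of the full motif (every profile position matched or
#' deleted) against any window of the sequence (free flanks), allowing
#' internal insertions and deletions with affine penalties: the first
#' residue of a gap costs \code{gapOpen}, each further one
#' \code{gapExtend} (nats, subtracted).  Computed by three-state dynamic
#' programming.
#'
#' @param profile a [ProfileModel-class].
#' @param sequence a character string over the amino-acid alphabet
#'   (\code{X} scores 0 at every position).
#' @param maxDeletions cap on the number of deleted profile positions
#'   (default unlimited); sequences shorter than
#'   \code{m - maxDeletions} return \code{-Inf}.
#' @return list with \code{score} (best score, \code{-Inf} when no
#'   alignment is admissible) and \code{start} (1-based sequence position
#'   of the first aligned residue, \code{NA} when all positions were
#'   deleted).
#' @export
scoreSequence <- function(profile, sequence, maxDeletions = Inf) {
    stopifnot(methods::is(profile, "ProfileModel"))
    lo <- profile@logOdds
    m <- ncol(lo)
    go <- profile@gapOpen
    ge <- profile@gapExtend
    s <- strsplit(toupper(sequence), "")[[1]]
    n <- length(s)
    if (n < m - maxDeletions)
        return(list(score = -Inf, start = NA_integer_))
    # emission lookup; unknown residue 'X' is neutral (log-odds 0)
    emit <- matrix(0, m, n)
    for (j in seq_len(n)) {
        if (s[j] %in% AA20) emit[, j] <- lo[s[j], ]
        else if (s[j] != "X") .stopf("invalid residue '%s'", s[j])
    }
    NEG <- -Inf
    # state matrices over i = 0..m profile positions, j = 0..n seq positions
    M <- matrix(NEG, m + 1L, n + 1L)  # pos i matched to seq j
    D <- matrix(NEG, m + 1L, n + 1L)  # pos i deleted, seq consumed j
    I <- matrix(NEG, m + 1L, n + 1L)  # seq j inserted after pos i
    Ms <- matrix(NA_integer_, m + 1L, n + 1L)  # start bookkeeping
    Ds <- matrix(NA_integer_, m + 1L, n + 1L)
    Is <- matrix(NA_integer_, m + 1L, n + 1L)
    for (i in 1L:(m + 1L)) {
        ii <- i - 1L                  # profile positions consumed
        for (j in 1L:(n + 1L)) {
            jj <- j - 1L              # sequence positions consumed
            if (ii >= 1L) {
                if (jj >= 1L) {
                    # match: predecessor consumed (ii-1, jj-1); free start at ii==1
                    prev <- c(if (ii == 1L) 0 else NEG,
                              M[i - 1L, j - 1L], D[i - 1L, j - 1L],
                              I[i - 1L, j - 1L])
                    st <- c(jj, Ms[i - 1L, j - 1L], Ds[i - 1L, j - 1L],
                            Is[i - 1L, j - 1L])
                    k <- which.max(prev)
                    if (prev[k] > NEG) {
                        M[i, j] <- prev[k] + emit[ii, jj]
                        Ms[i, j] <- st[k]
                    }
                }
                # deletion of profile position ii
                prev <- c(if (ii == 1L) 0 else NEG,
                          M[i - 1L, j] - go, D[i - 1L, j] - ge,
                          I[i - 1L, j] - go)
                st <- c(NA_integer_, Ms[i - 1L, j], Ds[i - 1L, j],
                        Is[i - 1L, j])
                if (ii == 1L) prev[1] <- -go
                k <- which.max(prev)
                if (prev[k] > NEG) {
                    D[i, j] <- prev[k]
                    Ds[i, j] <- st[k]
                }
            }
            if (ii >= 1L && ii < m && jj >= 1L) {
                # internal insertion of sequence position jj after profile pos ii
                prev <- c(M[i, j - 1L] - go, D[i, j - 1L] - go,
                          I[i, j - 1L] - ge)
                st <- c(Ms[i, j - 1L], Ds[i, j - 1L], Is[i, j - 1L])
                k <- which.max(prev)
                if (prev[k] > NEG) {
                    I[i, j] <- prev[k]
                    Is[i, j] <- st[k]
                }
            }
        }
    }
    fin <- pmax(M[m + 1L, ], D[m + 1L, ])
    j <- which.max(fin)
    if (!is.finite(fin[j]) && fin[j] == NEG)
        return(list(score = -Inf, start = NA_integer_))
    start <- if (M[m + 1L, j] >= D[m + 1L, j]) Ms[m + 1L, j] else Ds[m + 1L, j]
    list(score = fin[j], start = as.integer(start))
}

#' Calibrate the profile score threshold on a simulated null
#'
#' Scores \code{n} random background-composition sequences and sets the
#' threshold at the \code{1 - fpr} empirical quantile of their scores.
#'
#' @param profile a [ProfileModel-class].
#' @param n number of null sequences (default 1000).
#' @param length length of each null sequence (default 3x motif length).
#' @param fpr target false-positive rate on the null (default 0.01).
#' @param seed RNG seed.
#' @return the profile with its \code{threshold} slot set.
#' @export
calibrateThreshold <- function(profile, n = 1000L, length = NULL,
                               fpr = 0.01, seed = 1L) {
    stopifnot(methods::is(profile, "ProfileModel"))
    m <- ncol(profile@logOdds)
    if (is.null(length)) length <- 3L * m
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    scores <- vapply(seq_len(n), function(i) {
        seq <- paste(sample(AA20, length, replace = TRUE,
                            prob = profile@background), collapse = "")
        scoreSequence(profile, seq)$score
    }, 0)
    profile@threshold <- as.numeric(quantile(scores, 1 - fpr, type = 1))
    profile
}

#' Evaluate a profile search against labelled sequences
#'
#' Scores every sequence, calls hits at \code{score >= threshold} and
#' reports the true-positive rate (hits among members / members) and
#' false-positive rate (hits among non-members / non-members); a rate with
#' an empty denominator is \code{NA}.
#'
#' @param profile a [ProfileModel-class].
#' @param sequences named character vector of query sequences.
#' @param member logical vector (same length/order) marking family members.
#' @param threshold score threshold (default: the profile's).
#' @return a [SearchEvaluation-class].
#' @export
evaluateSearch <- function(profile, sequences, member,
                           threshold = profile@threshold) {
    stopifnot(methods::is(profile, "ProfileModel"),
              length(sequences) == length(member))
    if (is.na(threshold))
        .stopf("no threshold set; run calibrateThreshold() or pass one")
    res <- lapply(sequences, function(s) scoreSequence(profile, s))
    hits <- data.frame(
        id = if (is.null(names(sequences)))
                 as.character(seq_along(sequences)) else names(sequences),
        score = vapply(res, `[[`, 0, "score"),
        start = vapply(res, function(r) as.integer(r$start), 0L),
        member = as.logical(member),
        stringsAsFactors = FALSE, row.names = NULL)
    hits$hit <- hits$score >= threshold
    tpr <- if (any(hits$member)) mean(hits$hit[hits$member]) else NA_real_
    fpr <- if (any(!hits$member)) mean(hits$hit[!hits$member]) else NA_real_
    methods::new("SearchEvaluation", tpr = tpr, fpr = fpr,
                 threshold = as.numeric(threshold), hits = hits)
}
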