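# Synthetic-data generators: planted-motif alignments, clustered
# similarity matrices, peptide backbones with prescribed torsions, and
# labelled benchmark sequence sets.  Every generator is a pure function of
# its arguments plus an explicit seed.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else if (exists(".Random.seed", .GlobalEnv))
                rm(".Random.seed", envir = .GlobalEnv))
    set.seed(seed)
    force(expr)
}

#' Generate a family alignment with a planted conserved motif block
#'
#' Background columns draw residues from \code{background} independently
#' per sequence (with gaps at rate \code{gapProb}); columns inside the
#' planted motif emit the column consensus with probability \code{pCons}
#' and a background draw otherwise (no gaps inside the motif, emulating a
#' hand-adjusted family alignment around its signature).
#'
#' @param n number of sequences.
#' @param L alignment length (columns).
#' @param motifRange integer start/end columns of the planted motif.
#' @param consensus motif consensus residues (recycled/generated when
#'   \code{NULL}).
#' @param pCons per-column probability of emitting the consensus residue
#'   (default 0.95).
#' @param background length-20 residue distribution (default uniform).
#' @param gapProb per-cell gap probability outside the motif (default
#'   0.05).
#' @param seed RNG seed.
#' @param familyId family name for the result.
#' @return list with \code{msa} (an [AlignedFamily-class]) and
#'   \code{truth} (list: motifRange, consensus).
#' @export
generateMsa <- function(n = 50L, L = 120L, motifRange = c(40L, 52L),
                        consensus = NULL, pCons = 0.95,
                        background = rep(1 / 20, 20), gapProb = 0.05,
                        seed = 1L, familyId = "SYN") {
    stopifnot(pCons >= 0, pCons <= 1, motifRange[1] >= 1,
              motifRange[2] <= L, motifRange[1] <= motifRange[2])
    .withSeed(seed, {
        mcols <- motifRange[1]:motifRange[2]
        if (is.null(consensus))
            consensus <- sample(AA20, length(mcols), replace = TRUE)
        stopifnot(length(consensus) == length(mcols))
        m <- matrix("", n, L)
        for (j in seq_len(L)) {
            bg <- sample(AA20, n, replace = TRUE, prob = background)
            if (j %in% mcols) {
                k <- match(j, mcols)
                hit <- stats::runif(n) < pCons
                m[, j] <- ifelse(hit, consensus[k], bg)
            } else {
                gap <- stats::runif(n) < gapProb
                m[, j] <- ifelse(gap, "-", bg)
            }
        }
        rows <- setNames(apply(m, 1, paste, collapse = ""),
                         sprintf("%s_seq%03d", familyId, seq_len(n)))
        list(msa = newAlignedFamily(familyId, rows, names(rows)[1]),
             truth = list(motifRange = as.integer(motifRange),
                          consensus = consensus))
    })
}

#' Generate a clustered structural-similarity matrix
#'
#' Emulates the regime of pairwise structure-similarity Z-scores within a
#' superfamily: high similarity within planted families, low between, with
#' Gaussian noise; self-scores on the diagonal.  Labels carry the family
#' tag (\code{F<k>_<i>}).  Negative draws are clamped at 0.
#'
#' @param familySizes integer vector of structures per family.
#' @param withinMean,withinSD within-family similarity distribution
#'   (defaults 35 and 2).
#' @param betweenMean,betweenSD between-family similarity distribution
#'   (defaults 5 and 2).
#' @param selfMean,selfSD self-score distribution (defaults 45 and 1).
#' @param seed RNG seed.
#' @return list with \code{matrix} (a [SimilarityMatrix-class]) and
#'   \code{families} (named character vector label -> family).
#' @export
generateSimilarityMatrix <- function(familySizes = c(4L, 4L, 4L),
                                     withinMean = 35, withinSD = 2,
                                     betweenMean = 5, betweenSD = 2,
                                     selfMean = 45, selfSD = 1,
                                     seed = 1L) {
    stopifnot(all(familySizes >= 1L))
    .withSeed(seed, {
        fam <- rep(sprintf("F%d", seq_along(familySizes)), familySizes)
        labs <- unlist(lapply(seq_along(familySizes), function(k)
            sprintf("F%d_%d", k, seq_len(familySizes[k]))))
        n <- length(labs)
        m <- matrix(0, n, n, dimnames = list(labs, labs))
        diag(m) <- pmax(0, stats::rnorm(n, selfMean, selfSD))
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            v <- if (fam[i] == fam[j])
                stats::rnorm(1, withinMean, withinSD)
            else stats::rnorm(1, betweenMean, betweenSD)
            m[i, j] <- m[j, i] <- max(0, v)
        }
        list(matrix = methods::new("SimilarityMatrix", values = m),
             families = setNames(fam, labs))
    })
}

# ---- internal-to-Cartesian (NeRF) peptide construction --------------------

# standard peptide geometry (Angstrom / degrees)
.pepGeom <- list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
                 aNCAC = 111.2, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.5)

# place atom D from A-B-C with bond |C-D|, angle B-C-D and torsion A-B-C-D
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
    th <- angle * pi / 180
    ph <- dihedral * pi / 180
    d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph),
            bond * sin(th) * sin(ph))
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    n <- .cross3(b - a, bc); n <- n / sqrt(sum(n^2))
    mm <- .cross3(n, bc)
    as.numeric(c + cbind(bc, mm, n) %*% d2)
}

#' Build a peptide backbone from prescribed torsion angles
#'
#' Constructs N/CA/C/O coordinates residue by residue with standard
#' peptide bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329
#' Angstrom), so that recomputing [backboneTorsions()] on the result
#' recovers the prescribed phi/psi (and omega) to within numerical
#' round-off.  Optional side-chain pseudo-atoms with explicit coordinates
#' can be appended afterwards via [addAtoms()].
#'
#' @param phi,psi torsion vectors in degrees, one per residue
#'   (\code{phi[1]} is unused; \code{psi} of the last residue only places
#'   its carbonyl oxygen).
#' @param omega peptide-bond torsions (recycled, default 180).
#' @param resnames residue names (recycled, default \code{"ALA"}).
#' @param structureId id for the resulting model.
#' @return a [StructureModel-class] (chain \code{"A"}).
#' @export
generatePeptide <- function(phi, psi, omega = 180, resnames = "ALA",
                            structureId = "synthetic") {
    n <- length(phi)
    stopifnot(n >= 2L, length(psi) == n)
    omega <- rep_len(omega, n)
    resnames <- rep_len(toupper(resnames), n)
    g <- .pepGeom
    N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(g$bNCA, 0, 0)
    C[1, ] <- .placeAtom(c(0, -1, 0), N[1, ], CA[1, ], g$bCAC, g$aNCAC, 0)
    for (i in seq_len(n - 1L)) {
        N[i + 1L, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$bCN,
                                  g$aCACN, psi[i])
        CA[i + 1L, ] <- .placeAtom(CA[i, ], C[i, ], N[i + 1L, ], g$bNCA,
                                   g$aCNCA, omega[i + 1L])
        C[i + 1L, ] <- .placeAtom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                                  g$bCAC, g$aNCAC, phi[i + 1L])
    }
    for (i in seq_len(n))
        O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$bCO, g$aCACO,
                             .wrap180(psi[i] + 180))
    atoms <- do.call(rbind, lapply(seq_len(n), function(i)
        data.frame(resno = i, icode = "", resname = resnames[i],
                   atom = c("N", "CA", "C", "O"),
                   x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
                   y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
                   z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
                   stringsAsFactors = FALSE)))
    methods::new("StructureModel", structureId = structureId,
                 chainId = "A", atoms = atoms)
}

#' Append explicitly placed atoms to a StructureModel
#'
#' Used by the generators to drop side-chain pseudo-atoms (OE1, OD1, OG,
#' OG1, CB, ...) at prescribed coordinates.
#'
#' @param structure a [StructureModel-class].
#' @param atoms data.frame with columns resno, resname, atom, x, y, z (and
#'   optionally icode).
#' @return the extended [StructureModel-class].
#' @export
addAtoms <- function(structure, atoms) {
    if (is.null(atoms$icode)) atoms$icode <- ""
    atoms <- atoms[, c("resno", "icode", "resname", "atom", "x", "y", "z")]
    methods::new("StructureModel", structureId = structure@structureId,
                 chainId = structure@chainId,
                 atoms = rbind(structure@atoms, atoms))
}

# torsion presets for generated test geometry; loop torsions of the
# hairpin presets were fixed once, at design time, so that the built
# coordinates close into an antiparallel hairpin with the canonical type I
# turn at the loop centre
.presets <- new.env(parent = emptyenv())

#' Torsion presets for generated peptides
#'
#' \code{presetStrand(n)} gives an ideal extended strand
#' (phi -120, psi 130).  \code{presetTypeITurn()} embeds the canonical
#' type I beta-turn (central dihedrals -60,-30 / -90,0) between short
#' extended flanks.  \code{presetHairpin(loopLen)} builds a two-strand
#' antiparallel beta-hairpin with a 4- or 2-residue loop whose centre is a
#' type I turn (4:4 and 2:2 hairpin classes respectively).
#'
#' @param n strand length in residues.
#' @param loopLen loop length, 4 (default) or 2.
#' @return list with numeric \code{phi} and \code{psi} vectors and, for
#'   the hairpin, \code{strand1}/\code{strand2} residue ranges and
#'   \code{turnStart} (first residue of the type I turn window).
#' @name presets
NULL

#' @rdname presets
#' @export
presetStrand <- function(n = 6L) {
    list(phi = rep(-120, n), psi = rep(130, n))
}

#' @rdname presets
#' @export
presetTypeITurn <- function() {
    # residues 1-2 and 5-6 extended, turn window 2..5, centrals 3 and 4
    list(phi = c(-120, -120, -60, -90, -120, -120),
         psi = c(130, 130, -30, 0, 130, 130),
         turnStart = 2L)
}

#' @rdname presets
#' @export
presetHairpin <- function(loopLen = 4L) {
    if (!loopLen %in% c(2L, 4L))
        .stopf("loopLen must be 2 or 4")
    key <- sprintf("hairpin%d", loopLen)
    if (!is.null(.presets[[key]])) return(.presets[[key]])
    strand <- 4L
    if (loopLen == 4L) {
        # loop: pre-turn bridge, type I centrals, alphaL exit
        loopPhi <- c(-95, -60, -90, 75)
        loopPsi <- c(120, -30, 0, 15)
    } else {
        # tight 2-residue loops pair with mirror-image (type I-prime)
        # turns in real hairpins; type I does not close a 2:2 loop
        loopPhi <- c(60, 90)
        loopPsi <- c(30, 0)
    }
    phi <- c(rep(-120, strand), loopPhi, rep(-120, strand))
    psi <- c(rep(130, strand), loopPsi, rep(130, strand))
    out <- .optimizeHairpin(phi, psi, strand, loopLen)
    .presets[[key]] <- out
    out
}

# adjust the torsions at the strand/loop junctions so the two strands pair
# antiparallel (innermost Calpha pair under 5.5 A); loop centre is pinned
# to the canonical type I turn.  Deterministic Nelder-Mead refinement of a
# fixed starting geometry -- no randomness involved.
.optimizeHairpin <- function(phi, psi, strand, loopLen) {
    n <- length(phi)
    s1 <- c(1L, strand)
    s2 <- c(strand + loopLen + 1L, n)
    freeIdx <- if (loopLen == 4L)
        list(phi = c(strand + 1L, strand + 4L, s2[1]),
             psi = c(strand, strand + 1L, strand + 4L))
    else
        list(phi = s2[1], psi = strand)
    target <- function(par) {
        p <- phi; q <- psi
        p[freeIdx$phi] <- par[seq_along(freeIdx$phi)]
        q[freeIdx$psi] <- par[length(freeIdx$phi) + seq_along(freeIdx$psi)]
        st <- generatePeptide(p, q)
        caAll <- atomTable(st)
        caAll <- as.matrix(caAll[caAll$atom == "CA", c("x", "y", "z")])
        # pair strand residues inward from the loop
        cost <- 0
        for (k in 0:(strand - 1L)) {
            d <- sqrt(sum((caAll[s2[1] + k, ] - caAll[strand - k, ])^2))
            cost <- cost + (d - 4.9)^2
        }
        # steric penalty: non-neighbouring Calphas must stay apart
        dm <- as.matrix(stats::dist(caAll))
        sep <- abs(row(dm) - col(dm)) > 1
        clash <- pmax(0, 4.2 - dm[sep])
        cost + 25 * sum(clash^2)
    }
    par0 <- c(phi[freeIdx$phi], psi[freeIdx$psi])
    fit <- stats::optim(par0, target, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    phi[freeIdx$phi] <- fit$par[seq_along(freeIdx$phi)]
    psi[freeIdx$psi] <- fit$par[length(freeIdx$phi) + seq_along(freeIdx$psi)]
    list(phi = phi, psi = psi, strand1 = s1, strand2 = s2,
         turnStart = if (loopLen == 4L) strand + 1L else strand,
         converged = fit$value < 1.5)
}

#' Generate a labelled benchmark sequence set for profile search
#'
#' Positives carry one motif instance (each position mutated to a random
#' other residue with probability \code{divergence}) embedded in random
#' background flanks; negatives are pure background sequences of matching
#' length.
#'
#' @param consensus character vector of motif consensus residues.
#' @param nPos,nNeg numbers of member / non-member sequences (defaults 50
#'   and 500).
#' @param divergence per-position mutation probability in \code{[0, 1]}.
#' @param flank integer range of flank lengths (default \code{c(10, 30)}).
#' @param background length-20 residue distribution (default uniform).
#' @param seed RNG seed.
#' @return list with \code{sequences} (named character), \code{member}
#'   (logical) and \code{truth} (data.frame id, start of the planted
#'   instance, \code{NA} for negatives).
#' @export
generateSequenceDb <- function(consensus, nPos = 50L, nNeg = 500L,
                               divergence = 0.1, flank = c(10L, 30L),
                               background = rep(1 / 20, 20), seed = 1L) {
    stopifnot(divergence >= 0, divergence <= 1)
    m <- length(consensus)
    .withSeed(seed, {
        bg <- function(k) paste(sample(AA20, k, replace = TRUE,
                                       prob = background), collapse = "")
        seqs <- character(nPos + nNeg)
        starts <- rep(NA_integer_, nPos + nNeg)
        for (i in seq_len(nPos)) {
            inst <- consensus
            mut <- stats::runif(m) < divergence
            if (any(mut))
                inst[mut] <- vapply(which(mut), function(k)
                    sample(setdiff(AA20, consensus[k]), 1L), "")
            lf <- sample(flank[1]:flank[2], 1L)
            rf <- sample(flank[1]:flank[2], 1L)
            seqs[i] <- paste0(bg(lf), paste(inst, collapse = ""), bg(rf))
            starts[i] <- lf + 1L
        }
        medLen <- m + sum(flank)
        for (i in seq_len(nNeg))
            seqs[nPos + i] <- bg(medLen)
        names(seqs) <- c(sprintf("pos%03d", seq_len(nPos)),
                         sprintf("neg%03d", seq_len(nNeg)))
        list(sequences = seqs,
             member = rep(c(TRUE, FALSE), c(nPos, nNeg)),
             truth = data.frame(id = names(seqs), start = starts,
                                stringsAsFactors = FALSE))
    })
}
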