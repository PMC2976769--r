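# Backbone geometry: torsions, conformational classes, beta-turns,
# hairpins and active-site distance tables.

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Dihedral angle of four points
#'
#' IUPAC sign convention, degrees in \code{(-180, 180]}.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return the torsion angle p1-p2-p3-p4 in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
    m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
    x <- sum(n1 * n2); y <- sum(m1 * n2)
    .wrap180(-atan2(y, x) * 180 / pi)
}

# per-residue backbone atom coordinate list (ordered by resno, icode)
.backboneList <- function(structure) {
    a <- structure@atoms
    key <- paste(a$resno, a$icode, sep = "\r")
    res <- unique(data.frame(resno = a$resno, icode = a$icode,
                             resname = a$resname, key = key,
                             stringsAsFactors = FALSE))
    ic <- match(res$icode, c("", LETTERS))
    res <- res[order(res$resno, ic), , drop = FALSE]
    get1 <- function(k, nm) {
        i <- which(key == k & a$atom == nm)
        if (length(i)) as.numeric(a[i[1], c("x", "y", "z")]) else NULL
    }
    lapply(seq_len(nrow(res)), function(i) {
        k <- res$key[i]
        list(resno = res$resno[i], icode = res$icode[i],
             resname = res$resname[i],
             N = get1(k, "N"), CA = get1(k, "CA"), C = get1(k, "C"))
    })
}

#' Backbone torsion angles of a chain
#'
#' Computes phi, psi and omega per residue from N/CA/C coordinates.
#' Torsions are undefined (\code{NA}) at chain termini, where a backbone
#' atom is missing, and across chain breaks (peptide-bond C-N distance
#' above \code{breakCutoff}).
#'
#' @param structure a [StructureModel-class].
#' @param breakCutoff chain-break C(i-1)-N(i) distance cutoff in Angstrom
#'   (default 2.5).
#' @return data.frame with columns resno, icode, resname, phi, psi, omega.
#' @export
backboneTorsions <- function(structure, breakCutoff = 2.5) {
    bb <- .backboneList(structure)
    n <- length(bb)
    out <- data.frame(
        resno = vapply(bb, `[[`, 0L, "resno"),
        icode = vapply(bb, `[[`, "", "icode"),
        resname = vapply(bb, `[[`, "", "resname"),
        phi = NA_real_, psi = NA_real_, omega = NA_real_,
        stringsAsFactors = FALSE)
    if (n == 0L) return(out)
    linked <- function(i) {   # peptide bond between residues i-1 and i?
        if (i < 2L) return(FALSE)
        Cp <- bb[[i - 1L]]$C; Ni <- bb[[i]]$N
        !is.null(Cp) && !is.null(Ni) &&
            sqrt(sum((Ni - Cp)^2)) <= breakCutoff
    }
    for (i in seq_len(n)) {
        r <- bb[[i]]
        if (linked(i) && !is.null(r$N) && !is.null(r$CA) && !is.null(r$C))
            out$phi[i] <- dihedralAngle(bb[[i - 1L]]$C, r$N, r$CA, r$C)
        if (i < n && linked(i + 1L) &&
            !is.null(r$N) && !is.null(r$CA) && !is.null(r$C))
            out$psi[i] <- dihedralAngle(r$N, r$CA, r$C, bb[[i + 1L]]$N)
        if (linked(i) && !is.null(bb[[i - 1L]]$CA) && !is.null(r$CA))
            out$omega[i] <- dihedralAngle(bb[[i - 1L]]$CA, bb[[i - 1L]]$C,
                                          r$N, r$CA)
    }
    out
}

#' Backbone conformational class of a (phi, psi) pair
#'
#' Partitions the Ramachandran plane into left-handed helical
#' (\eqn{\phi \in (20, 125], \psi \in [-45, 90)}), left-handed extended
#' (\eqn{\phi \in (20, 180], \psi \in [90, 240)} mod 360), their
#' right-handed mirror images, and \code{"unclassified"}.  The two
#' left-handed classes require positive phi.  The boxes are this package's
#' explicit formalization of the usual alphaL/epsilon regions and are
#' configurable through the mirror symmetry of the implementation.
#'
#' @param phi,psi backbone torsions in degrees (vectorized).
#' @return character vector: \code{"lh-helical"}, \code{"lh-extended"},
#'   \code{"rh-helical"}, \code{"rh-extended"} or \code{"unclassified"}
#'   (also for undefined input).
#' @examples
#' classifyConformation(57, 47)    # lh-helical (alpha-L)
#' classifyConformation(-60, -45)  # rh-helical
#' classifyConformation(75, 170)   # lh-extended
#' @export
classifyConformation <- function(phi, psi) {
    f <- function(phi, psi) {
        if (is.na(phi) || is.na(psi)) return("unclassified")
        phi <- .wrap180(phi); psi <- .wrap180(psi)
        if (phi > 20 && phi <= 125 && psi >= -45 && psi < 90)
            return("lh-helical")
        if (phi > 20 && phi <= 180 && (psi >= 90 || psi < -120))
            return("lh-extended")
        if (phi >= -125 && phi < -20 && psi > -90 && psi <= 45)
            return("rh-helical")
        if (phi >= -180 && phi < -20 && (psi <= -90 || psi > 120))
            return("rh-extended")
        "unclassified"
    }
    mapply(f, phi, psi, USE.NAMES = FALSE)
}

# canonical central dihedrals (phi2, psi2, phi3, psi3) per named turn type
.turnCanon <- list(
    I   = c(-60, -30, -90, 0),
    Ip  = c(60, 30, 90, 0),
    II  = c(-60, 120, 80, 0),
    IIp = c(60, -120, -80, 0))

.matchTurnType <- function(ang) {
    for (ty in names(.turnCanon)) {
        d <- .angDiff(ang, .turnCanon[[ty]])
        if (all(d <= 30) || (sum(d > 30) == 1L && all(d <= 45)))
            return(ty)
    }
    "IV"
}

#' Beta-turn assignment along a chain
#'
#' Scans all four-residue windows i..i+3: a window is a turn candidate
#' when the Calpha(i)-Calpha(i+3) distance is below 7.0 Angstrom and the
#' two central residues are not part of a helix (proxy: a run of at least
#' \code{helixRun} consecutive right-handed-helical residues).  Candidates
#' are typed by the central dihedrals against the canonical values (type
#' I: -60,-30 / -90,0; type II: -60,120 / 80,0; primed types mirrored),
#' tolerance 30 degrees with a single angle allowed 45; candidates
#' matching no named type are type IV.
#'
#' @param structure a [StructureModel-class].
#' @param torsions optional precomputed [backboneTorsions()] table.
#' @param maxCaDistance Calpha(i)-Calpha(i+3) gate (default 7.0).
#' @param helixRun minimal run of helical residues treated as helix
#'   (default 4).
#' @return data.frame with columns resno (of residue i), type
#'   (\code{"I"}, \code{"Ip"}, \code{"II"}, \code{"IIp"}, \code{"IV"}) and
#'   caDistance; one row per assigned turn.
#' @export
assignBetaTurns <- function(structure, torsions = NULL,
                            maxCaDistance = 7.0, helixRun = 4L) {
    if (is.null(torsions)) torsions <- backboneTorsions(structure)
    bb <- .backboneList(structure)
    n <- length(bb)
    if (n < 4L)
        return(data.frame(resno = integer(), type = character(),
                          caDistance = numeric(), stringsAsFactors = FALSE))
    cls <- classifyConformation(torsions$phi, torsions$psi)
    helical <- cls == "rh-helical"
    r <- rle(helical)
    inHelix <- inverse.rle(list(
        lengths = r$lengths,
        values = r$values & r$lengths >= helixRun))
    rows <- list()
    for (i in seq_len(n - 3L)) {
        ca1 <- bb[[i]]$CA; ca4 <- bb[[i + 3L]]$CA
        if (is.null(ca1) || is.null(ca4)) next
        d <- sqrt(sum((ca4 - ca1)^2))
        if (d >= maxCaDistance) next
        ang <- c(torsions$phi[i + 1L], torsions$psi[i + 1L],
                 torsions$phi[i + 2L], torsions$psi[i + 2L])
        if (anyNA(ang)) next
        if (inHelix[i + 1L] || inHelix[i + 2L]) next
        rows[[length(rows) + 1L]] <- data.frame(
            resno = bb[[i]]$resno, type = .matchTurnType(ang),
            caDistance = d, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(resno = integer(), type = character(),
                          caDistance = numeric(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Classify a beta-hairpin from two strand residue ranges
#'
#' Given the residue ranges of the two strands (author numbering; from
#' configuration or from [detectStrands()]), verifies that the strands
#' pair antiparallel (nearest cross-strand Calpha partners occur in
#' reversed order) and returns the hairpin class \code{"X:Y"}: X counts
#' the loop residues bracketed by the supplied strand boundaries, Y those
#' bracketed by the innermost geometrically paired residues (Calpha
#' distance below \code{pairCutoff}).  For an ideal hairpin both
#' conventions agree (e.g. \code{"4:4"}).
#'
#' @param structure a [StructureModel-class].
#' @param strand1,strand2 integer length-2 residue-number ranges, strand1
#'   N-terminal of strand2.
#' @param pairCutoff cross-strand Calpha pairing cutoff in Angstrom
#'   (default 5.5).
#' @return list with \code{class} (character \code{"X:Y"}), \code{loop}
#'   (integer residue numbers of the loop) and \code{pairs} (data.frame of
#'   paired residue numbers).
#' @export
detectHairpin <- function(structure, strand1, strand2, pairCutoff = 5.5) {
    bb <- .backboneList(structure)
    resno <- vapply(bb, `[[`, 0L, "resno")
    caOf <- function(r) {
        i <- which(resno == r)
        if (!length(i)) return(NULL)
        bb[[i[1]]]$CA
    }
    s1 <- strand1[1]:strand1[2]
    s2 <- strand2[1]:strand2[2]
    if (max(s1) >= min(s2))
        .stopf("strand1 must precede strand2")
    # nearest cross-strand partner of every strand1 residue
    partner <- vapply(s1, function(r1) {
        ca1 <- caOf(r1)
        if (is.null(ca1)) return(NA_integer_)
        d <- vapply(s2, function(r2) {
            ca2 <- caOf(r2)
            if (is.null(ca2)) return(Inf)
            sqrt(sum((ca2 - ca1)^2))
        }, 0)
        if (min(d) > pairCutoff * 1.6) return(NA_integer_)
        s2[which.min(d)]
    }, 0L)
    ok <- !is.na(partner)
    if (sum(ok) >= 2L) {
        ord <- partner[ok]
        if (!all(diff(ord) <= 0))
            .stopf("strands do not pair antiparallel (partner order not reversed)")
    }
    x <- min(s2) - max(s1) - 1L
    # innermost geometric pair: largest strand1 residue with a partner
    # within pairCutoff, and its smallest-numbered close partner
    y <- NA_integer_
    for (r1 in rev(s1)) {
        ca1 <- caOf(r1)
        if (is.null(ca1)) next
        close <- s2[vapply(s2, function(r2) {
            ca2 <- caOf(r2)
            !is.null(ca2) && sqrt(sum((ca2 - ca1)^2)) < pairCutoff
        }, TRUE)]
        if (length(close)) { y <- min(close) - r1 - 1L; break }
    }
    if (is.na(y)) .stopf("no cross-strand Calpha pairing below %.1f A", pairCutoff)
    loop <- if (x > 0) (max(s1) + 1L):(min(s2) - 1L) else integer()
    list(class = sprintf("%d:%d", x, y), loop = loop,
         pairs = data.frame(strand1 = s1[ok], strand2 = partner[ok]))
}

#' Simplified strand detection from backbone geometry
#'
#' Finds runs of at least \code{minRun} consecutive residues in extended
#' backbone conformation.  A fallback for structures without configured
#' strand ranges; explicit ranges always take precedence.
#'
#' @param structure a [StructureModel-class].
#' @param minRun minimal run length (default 3).
#' @return data.frame with columns start, end (author residue numbers).
#' @export
detectStrands <- function(structure, minRun = 3L) {
    tor <- backboneTorsions(structure)
    ext <- classifyConformation(tor$phi, tor$psi) == "rh-extended"
    r <- rle(ext)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minRun
    data.frame(start = tor$resno[starts[keep]],
               end = tor$resno[ends[keep]])
}

# side-chain atoms entering the distance rule, per residue type:
# carboxyl/hydroxyl oxygens for Asp/Glu/Ser/Thr, C-beta for Gln
.roleAtoms <- c(GLU = "OE1 OE2", ASP = "OD1 OD2", SER = "OG",
                THR = "OG1", GLN = "CB")

#' Pairwise active-site distances between catalytic roles
#'
#' For every pair of configured roles (A general acid, B general base,
#' C water-positioning Ser/Thr, D accessory Gln) reports the shortest
#' separation between their side-chain atom sets: the carboxyl or
#' hydroxyl oxygens of Glu/Asp/Ser/Thr and the C-beta atom of Gln.
#' Roles that are absent from the configuration, or whose residue is
#' missing or mutated in the structure, yield \code{NA} (printed as
#' \code{"/"}).
#'
#' @param structure a [StructureModel-class].
#' @param config a [FamilyConfig-class] whose \code{roles} name the
#'   residues.
#' @return 4 x 4 symmetric numeric matrix over roles A-D (Angstrom),
#'   \code{NA} where a role is unresolved.
#' @export
activeSiteDistances <- function(structure, config) {
    stopifnot(methods::is(structure, "StructureModel"),
              methods::is(config, "FamilyConfig"))
    a <- structure@atoms
    coords <- function(role) {
        spec <- config@roles[[role]]
        if (is.null(spec)) return(NULL)
        rn <- toupper(spec$resname)
        sel <- a[a$resno == spec$resno & a$resname == rn &
                 a$atom %in% strsplit(.roleAtoms[[rn]], " ")[[1]], ,
                 drop = FALSE]
        if (!nrow(sel)) {
            here <- unique(a$resname[a$resno == spec$resno])
            message(sprintf(
                "activeSiteDistances: role %s (%s%d) unresolved in %s%s",
                role, rn, spec$resno, structure@structureId,
                if (length(here)) sprintf(" (found %s)",
                                          paste(here, collapse = "/"))
                else " (residue absent)"))
            return(NULL)
        }
        as.matrix(sel[, c("x", "y", "z")])
    }
    roles <- c("A", "B", "C", "D")
    xyz <- lapply(setNames(roles, roles), coords)
    out <- matrix(NA_real_, 4L, 4L, dimnames = list(roles, roles))
    for (i in 1:3) for (j in (i + 1):4) {
        p <- xyz[[roles[i]]]; q <- xyz[[roles[j]]]
        if (is.null(p) || is.null(q)) next
        d2 <- outer(rowSums(p^2), rowSums(q^2), `+`) - 2 * p %*% t(q)
        out[i, j] <- out[j, i] <- sqrt(max(0, min(d2)))
    }
    diag(out) <- 0
    out
}

#' Per-family active-site distance summary
#'
#' Means and population standard deviations of the per-structure minimum
#' role-pair distances over the structures of one family, following the
#' conventions of the superfamily's active-site table: \code{NA} distance
#' pairs are skipped structure-wise, singleton samples have no SD
#' (printed \code{"-"}).
#'
#' @param structures list of [StructureModel-class] objects of one family.
#' @param configs a single [FamilyConfig-class] or a list parallel to
#'   \code{structures}.
#' @return data.frame with columns pair (e.g. \code{"A-B"}), n, mean, sd
#'   (sd \code{NA} when n < 2).
#' @export
familyDistanceSummary <- function(structures, configs) {
    if (methods::is(configs, "FamilyConfig"))
        configs <- rep(list(configs), length(structures))
    stopifnot(length(structures) == length(configs), length(structures) >= 1L)
    pairs <- t(utils::combn(c("A", "B", "C", "D"), 2))
    tabs <- mapply(activeSiteDistances, structures, configs,
                   SIMPLIFY = FALSE)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
        v <- vapply(tabs, function(m) m[pairs[k, 1], pairs[k, 2]], 0)
        v <- v[!is.na(v)]
        data.frame(pair = paste(pairs[k, ], collapse = "-"),
                   n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) >= 2L) .popSD(v) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
}

#' Format an active-site distance table with the "/" and "-" conventions
#'
#' @param summary output of [familyDistanceSummary()].
#' @return data.frame with a formatted \code{value} column like
#'   \code{"6.26(-)"} or \code{"/"} for unresolved pairs.
#' @export
formatDistanceTable <- function(summary) {
    summary$value <- ifelse(
        is.na(summary$mean), "/",
        sprintf("%.2f(%s)", summary$mean,
                ifelse(is.na(summary$sd), "-",
                       sprintf("%.2f", summary$sd))))
    summary
}
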