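# End-to-end orchestration: a run configuration (YAML/JSON) names the
# inputs, and one function per stage validates them, computes, and writes
# its outputs atomically (temp file + rename), logging one line per stage.

#' Read and validate a run configuration
#'
#' The configuration is a YAML or JSON file; recognized top-level keys:
#' \describe{
#'   \item{outDir}{output directory (created when missing).}
#'   \item{seed}{integer seed used by every stochastic stage.}
#'   \item{transform}{similarity-to-distance transform name.}
#'   \item{similarity}{\code{matrix} (PHYLIP square file) and optional
#'     \code{assignment} (TSV label, family).}
#'   \item{families}{list of per-family blocks: \code{alignment} (FASTA),
#'     optional \code{structure} (PDB), \code{config} (family config
#'     file), optional \code{chain}.}
#'   \item{motif}{\code{window}, \code{gapThreshold}, \code{minLength},
#'     \code{maxLength}.}
#'   \item{search}{optional \code{targets} (FASTA) and \code{labels}
#'     (TSV id, member); otherwise a synthetic benchmark is generated:
#'     \code{nPos}, \code{nNeg}, \code{divergence}, \code{fpr}.}
#' }
#' Relative paths are resolved against the configuration file's
#' directory.  Referenced input paths must exist.
#'
#' @param path configuration file.
#' @param overrides named list applied over the file contents (logged).
#' @return validated configuration (named list, class \code{"ghMotifRun"}).
#' @export
readRunConfig <- function(path, overrides = list()) {
    if (!file.exists(path))
        .stopf("run config not found: '%s'", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    for (k in names(overrides)) {
        message(sprintf("config override: %s = %s", k,
                        paste(format(overrides[[k]]), collapse = " ")))
        cfg[[k]] <- overrides[[k]]
    }
    base <- dirname(normalizePath(path))
    resolve <- function(p)
        if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
    for (k in c("matrix", "assignment"))
        cfg$similarity[[k]] <- resolve(cfg$similarity[[k]])
    if (!is.null(cfg$families))
        cfg$families <- lapply(cfg$families, function(f) {
            for (k in c("alignment", "structure", "config",
                        "structureConfig"))
                f[[k]] <- resolve(f[[k]])
            f
        })
    for (k in c("targets", "labels"))
        cfg$search[[k]] <- resolve(cfg$search[[k]])
    cfg$outDir <- cfg$outDir %||% "ghmotif-out"
    if (!grepl("^/", cfg$outDir)) cfg$outDir <- file.path(base, cfg$outDir)
    cfg$seed <- as.integer(cfg$seed %||% 1L)
    cfg$transform <- cfg$transform %||% "default"
    refs <- c(cfg$similarity$matrix, cfg$similarity$assignment,
              unlist(lapply(cfg$families, function(f)
                  c(f$alignment, f$structure, f$config))),
              cfg$search$targets, cfg$search$labels)
    missing <- refs[!vapply(refs, file.exists, TRUE)]
    if (length(missing))
        .stopf("missing input file(s): %s", paste(missing, collapse = ", "))
    class(cfg) <- c("ghMotifRun", class(cfg))
    cfg
}

.logStage <- function(stage, params, outputs) {
    sums <- tools::md5sum(outputs)
    message(sprintf("[%s] %s -> %s", stage, params,
                    paste(sprintf("%s(%s)", basename(outputs),
                                  substr(sums, 1, 8)), collapse = " ")))
}

.asRunConfig <- function(config)
    if (inherits(config, "ghMotifRun")) config else readRunConfig(config)

#' Run the structure-clustering stage
#'
#' Reads the similarity matrix, transforms it to distances, builds the
#' UPGMA tree with jackknife node reliability, and (when a family
#' assignment is configured) the within/between family distance tables.
#'
#' @param config a configuration list from [readRunConfig()] or a path.
#' @return invisibly, the paths of the written outputs (\code{tree.nwk},
#'   \code{jackknife.tsv}, and \code{family_distances_*.tsv} when
#'   applicable).
#' @export
runCluster <- function(config) {
    cfg <- .asRunConfig(config)
    if (is.null(cfg$similarity$matrix))
        .stopf("no similarity matrix configured")
    S <- readSquareMatrix(cfg$similarity$matrix)
    out <- file.path(cfg$outDir, "cluster")
    n <- length(structureLabels(S))
    if (n >= 4L) {
        jk <- jackknifeReliability(S, cfg$transform)
        tree <- jk$tree
        report <- jk$report
    } else {
        tree <- upgmaTree(similarityToDistance(S, cfg$transform))
        report <- data.frame(node = integer(), clade = character(),
                             reliable = logical(), absentIn = character())
    }
    paths <- c(tree = file.path(out, "tree.nwk"),
               jackknife = file.path(out, "jackknife.tsv"))
    writeNewick(tree, paths["tree"])
    .writeTSV(report, paths["jackknife"])
    if (!is.null(cfg$similarity$assignment)) {
        asg <- utils::read.delim(cfg$similarity$assignment,
                                 header = TRUE, stringsAsFactors = FALSE)
        fd <- familyDistances(similarityToDistance(S, cfg$transform),
                              setNames(asg[[2]], asg[[1]]))
        w <- fd$within
        w$meanWithin <- ifelse(is.na(w$meanWithin), "-",
                               sprintf("%.2f", w$meanWithin))
        b <- data.frame(family = rownames(fd$between),
                        round(fd$between, 2), check.names = FALSE)
        paths <- c(paths,
                   within = file.path(out, "family_distances_within.tsv"),
                   between = file.path(out, "family_distances_between.tsv"))
        .writeTSV(w, paths["within"])
        .writeTSV(b, paths["between"])
    }
    .logStage("cluster", sprintf("n=%d transform=%s", n, cfg$transform),
              paths)
    invisible(paths)
}

# conservation profile + mapped numbering for one configured family
.familyProfile <- function(f, cfg) {
    msa <- readFastaAlignment(f$alignment, familyId = f$familyId)
    fc <- if (!is.null(f$config)) readFamilyConfig(f$config)
          else familyConfig(msa@familyId)
    if (!is.na(fc@representative) &&
        fc@representative %in% names(msa@alignment))
        msa@representativeId <- fc@representative
    mo <- cfg$motif %||% list()
    if (length(msa@alignment) < 2L) {
        .warnf("family %s has a single sequence: raw profile used, no normalization",
               msa@familyId)
    }
    prof <- conservationProfile(msa, window = mo$window %||% 3L,
                                gapThreshold = mo$gapThreshold %||% 0.5)
    prof <- mapToRepresentative(prof, msa, fc@representativeStart)
    list(msa = msa, fc = fc, prof = prof, motifOpts = mo)
}

.profileTable <- function(prof) {
    data.frame(column = seq_along(prof@raw),
               residue = prof@residueNumbers,
               gapFraction = round(prof@gapFraction, 4),
               flagged = prof@flagged,
               raw = round(prof@raw, 6),
               smoothed = round(prof@smoothed, 6),
               normalized = round(prof@normalized, 6))
}

# hairpin residue range (author numbers) -> alignment column range
.hairpinColumns <- function(prof, fc) {
    if (anyNA(fc@hairpinRange)) return(NULL)
    cols <- which(!is.na(prof@residueNumbers) &
                  prof@residueNumbers >= fc@hairpinRange[1] &
                  prof@residueNumbers <= fc@hairpinRange[2])
    if (!length(cols)) return(NULL)
    range(cols)
}

#' Run the conservation-profiling / motif-extraction stage
#'
#' For every configured family: conservation profile TSV, extracted motif
#' region TSV and the logo matrix TSV of the motif block.
#'
#' @param config a configuration list from [readRunConfig()] or a path.
#' @return invisibly, the paths of the written outputs.
#' @export
runMotifs <- function(config) {
    cfg <- .asRunConfig(config)
    if (!length(cfg$families)) .stopf("no families configured")
    out <- file.path(cfg$outDir, "motifs")
    paths <- character()
    for (f in cfg$families) {
        fp <- .familyProfile(f, cfg)
        id <- fp$msa@familyId
        hp <- .hairpinColumns(fp$prof, fp$fc)
        if (is.null(hp))
            .stopf("family %s: no hairpin range configured/mappable", id)
        motif <- extractMotif(fp$prof, hp,
                              minLength = fp$motifOpts$minLength %||% 8L,
                              maxLength = fp$motifOpts$maxLength %||% 18L)
        cols <- motif@columnRange[1]:motif@columnRange[2]
        logo <- buildLogo(alignmentMatrix(fp$msa)[, cols, drop = FALSE])
        p <- c(file.path(out, sprintf("%s_profile.tsv", id)),
               file.path(out, sprintf("%s_motif.tsv", id)),
               file.path(out, sprintf("%s_logo.tsv", id)))
        .writeTSV(.profileTable(fp$prof), p[1])
        .writeTSV(data.frame(family = id,
                             colStart = motif@columnRange[1],
                             colEnd = motif@columnRange[2],
                             resStart = motif@residueRange[1],
                             resEnd = motif@residueRange[2],
                             meanConservation = round(motif@meanConservation, 6)),
                  p[2])
        .writeTSV(data.frame(position = seq_along(logo@information),
                             consensus = logo@consensus,
                             informationBits = round(logo@information, 6),
                             round(t(logo@frequencies), 6)), p[3])
        paths <- c(paths, p)
        .logStage("motifs", sprintf("family=%s columns=%d-%d", id,
                                    motif@columnRange[1],
                                    motif@columnRange[2]), p)
    }
    invisible(paths)
}

#' Run the signature-search evaluation stage
#'
#' Builds a profile from each family's motif region, calibrates its score
#' threshold on a simulated null at the configured false-positive rate,
#' scores the target set (configured FASTA + labels, or a generated
#' synthetic benchmark) and writes hits TSV + evaluation JSON.
#'
#' @param config a configuration list from [readRunConfig()] or a path.
#' @return invisibly, the paths of the written outputs.
#' @export
runSearch <- function(config) {
    cfg <- .asRunConfig(config)
    if (!length(cfg$families)) .stopf("no families configured")
    out <- file.path(cfg$outDir, "search")
    sr <- cfg$search %||% list()
    paths <- character()
    for (f in cfg$families) {
        fp <- .familyProfile(f, cfg)
        id <- fp$msa@familyId
        hp <- .hairpinColumns(fp$prof, fp$fc)
        if (is.null(hp))
            .stopf("family %s: no hairpin range configured/mappable", id)
        motif <- extractMotif(fp$prof, hp)
        cols <- motif@columnRange[1]:motif@columnRange[2]
        block <- alignmentMatrix(fp$msa)[, cols, drop = FALSE]
        profile <- buildProfile(block)
        if (!is.null(sr$targets)) {
            seqs <- gsub("-", "",
                         setNames(as.character(
                             Biostrings::readBStringSet(sr$targets)), NULL))
            names(seqs) <- sub("\\s.*$", "",
                               names(Biostrings::readBStringSet(sr$targets)))
            lab <- utils::read.delim(sr$labels, stringsAsFactors = FALSE)
            member <- as.logical(setNames(lab[[2]], lab[[1]])[names(seqs)])
        } else {
            cons <- buildLogo(block)@consensus
            db <- generateSequenceDb(cons, nPos = sr$nPos %||% 50L,
                                     nNeg = sr$nNeg %||% 500L,
                                     divergence = sr$divergence %||% 0.1,
                                     seed = cfg$seed)
            seqs <- db$sequences
            member <- db$member
        }
        # null calibration at the target sequences' typical length
        profile <- calibrateThreshold(profile, fpr = sr$fpr %||% 0.01,
                                      length = as.integer(
                                          stats::median(nchar(seqs))),
                                      seed = cfg$seed)
        ev <- evaluateSearch(profile, seqs, member)
        p <- c(file.path(out, sprintf("%s_hits.tsv", id)),
               file.path(out, sprintf("%s_evaluation.json", id)))
        .writeTSV(ev@hits, p[1])
        .atomicWrite(function(tmp) jsonlite::write_json(
            list(family = id, tpr = ev@tpr, fpr = ev@fpr,
                 threshold = ev@threshold),
            tmp, auto_unbox = TRUE, digits = NA, na = "null"), p[2])
        paths <- c(paths, p)
        .logStage("search", sprintf("family=%s TPR=%s FPR=%s", id,
                                    format(ev@tpr, digits = 3),
                                    format(ev@fpr, digits = 3)), p)
    }
    invisible(paths)
}

#' Run the structural-characterization stage
#'
#' For every configured family with a structure: backbone torsion table,
#' beta-turn assignments with hairpin class, and the active-site
#' role-distance table (\code{"/"} for unresolved roles).
#'
#' @param config a configuration list from [readRunConfig()] or a path.
#' @return invisibly, the paths of the written outputs.
#' @export
runStructures <- function(config) {
    cfg <- .asRunConfig(config)
    fams <- Filter(function(f) !is.null(f$structure), cfg$families)
    if (!length(fams)) .stopf("no families with structures configured")
    out <- file.path(cfg$outDir, "structures")
    paths <- character()
    for (f in fams) {
        cfPath <- f$structureConfig %||% f$config
        fc <- if (!is.null(cfPath)) readFamilyConfig(cfPath)
              else familyConfig(f$familyId %||% "unnamed")
        st <- readPdbSubset(f$structure, chain = f$chain)
        id <- fc@familyId
        tor <- backboneTorsions(st)
        tor$class <- classifyConformation(tor$phi, tor$psi)
        turns <- assignBetaTurns(st, tor)
        hair <- NULL
        ranges <- fc@strandRanges
        if (!length(ranges) && !anyNA(fc@hairpinRange)) {
            # fall back to geometric detection inside the hairpin range
            strands <- detectStrands(st)
            inRange <- strands$start >= fc@hairpinRange[1] - 1L &
                strands$end <= fc@hairpinRange[2] + 1L
            sIn <- strands[inRange, , drop = FALSE]
            if (nrow(sIn) >= 2L)
                ranges <- list(c(sIn$start[1], sIn$end[1]),
                               c(sIn$start[2], sIn$end[2]))
        }
        if (length(ranges) == 2L)
            hair <- tryCatch(
                detectHairpin(st, ranges[[1]], ranges[[2]]),
                error = function(e) {
                    message(sprintf("structures: %s hairpin: %s", id,
                                    conditionMessage(e)))
                    NULL
                })
        dist <- formatDistanceTable(familyDistanceSummary(list(st), fc))
        p <- c(file.path(out, sprintf("%s_torsions.tsv", id)),
               file.path(out, sprintf("%s_turns.tsv", id)),
               file.path(out, sprintf("%s_active_site.tsv", id)))
        .writeTSV(cbind(tor[, c("resno", "icode", "resname")],
                        phi = round(tor$phi, 2), psi = round(tor$psi, 2),
                        omega = round(tor$omega, 2), class = tor$class),
                  p[1])
        turns$caDistance <- round(turns$caDistance, 2)
        turns$hairpinClass <- if (!is.null(hair)) hair$class
                              else rep(NA_character_, nrow(turns))
        turns <- data.frame(family = rep(id, nrow(turns)), turns,
                            stringsAsFactors = FALSE)
        .writeTSV(turns, p[2])
        .writeTSV(cbind(family = id, dist[, c("pair", "n", "value")]), p[3])
        paths <- c(paths, p)
        .logStage("structures", sprintf("family=%s residues=%d", id,
                                        nrow(tor)), p)
    }
    invisible(paths)
}

#' Write a complete synthetic fixture set for the pipeline
#'
#' Generates a clustered similarity matrix with its family assignment,
#' one planted-motif alignment plus family configuration per family, and
#' a hairpin-peptide structure, in the same formats the readers consume,
#' together with a ready-to-run configuration file.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param nFamilies number of synthetic families (default 2).
#' @return the path of the written run-configuration file.
#' @export
simulateInputs <- function(dir, seed = 1L, nFamilies = 2L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sim <- generateSimilarityMatrix(familySizes = rep(4L, max(2L, nFamilies)),
                                    seed = seed)
    writeSquareMatrix(sim$matrix, file.path(dir, "similarity.phy"))
    .writeTSV(data.frame(label = names(sim$families),
                         family = unname(sim$families)),
              file.path(dir, "families.tsv"))
    fams <- list()
    for (k in seq_len(nFamilies)) {
        id <- sprintf("SYN%d", k)
        g <- generateMsa(seed = seed + k, familyId = id)
        writeFastaAlignment(g$msa, file.path(dir, sprintf("%s.fasta", id)))
        hpRes <- c(g$truth$motifRange[1] + 3L, g$truth$motifRange[2] - 3L)
        cfgPath <- file.path(dir, sprintf("%s_config.yaml", id))
        .atomicWrite(function(tmp) yaml::write_yaml(list(
            familyId = id, representative = names(g$msa@alignment)[1],
            representativeStart = 1L,
            motifRange = as.integer(g$truth$motifRange),
            hairpinRange = as.integer(hpRes)), tmp), cfgPath)
        fams[[k]] <- list(familyId = id,
                          alignment = sprintf("%s.fasta", id),
                          config = sprintf("%s_config.yaml", id))
    }
    hp <- presetHairpin(4L)
    pep <- generatePeptide(hp$phi, hp$psi, structureId = "synthetic_hairpin")
    writePdb(pep, file.path(dir, "hairpin.pdb"))
    fams[[1]]$structure <- "hairpin.pdb"
    fams[[1]]$structureConfig <- "SYN1_structure_config.yaml"
    .atomicWrite(function(tmp) yaml::write_yaml(list(
        familyId = "SYN1",
        hairpinRange = as.integer(c(hp$strand1[1], hp$strand2[2])),
        strand1 = as.integer(hp$strand1),
        strand2 = as.integer(hp$strand2)), tmp),
        file.path(dir, "SYN1_structure_config.yaml"))
    runCfg <- file.path(dir, "run_config.yaml")
    .atomicWrite(function(tmp) yaml::write_yaml(list(
        outDir = "out", seed = as.integer(seed), transform = "default",
        similarity = list(matrix = "similarity.phy",
                          assignment = "families.tsv"),
        families = fams), tmp), runCfg)
    runCfg
}

#' Run every pipeline stage in sequence
#'
#' @param config a configuration list from [readRunConfig()] or a path.
#' @return invisibly, all output paths.
#' @export
runAll <- function(config) {
    cfg <- .asRunConfig(config)
    paths <- c(runCluster(cfg), runMotifs(cfg), runSearch(cfg))
    if (length(Filter(function(f) !is.null(f$structure), cfg$families)))
        paths <- c(paths, runStructures(cfg))
    invisible(paths)
}
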