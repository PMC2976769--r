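#' Read a PHYLIP-style square similarity matrix
#'
#' Parses the one square-matrix dialect this package reads and writes: a
#' first line with the number of structures n, then n lines each holding a
#' label followed by n whitespace-separated values.  Off-diagonal
#' asymmetries are resolved by averaging, \code{Sij := (Sij + Sji) / 2}; an
#' asymmetry larger than 0.5 triggers a warning.  The diagonal holds the
#' per-structure self-scores.
#'
#' @param path path to the matrix file.
#' @return a [SimilarityMatrix-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("2", "A 10 3", "B 3 8"), tf)
#' scoreValues(readSquareMatrix(tf))
#' @export
readSquareMatrix <- function(path) {
    if (!file.exists(path))
        .stopf("matrix file not found: '%s'", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        .stopf("empty matrix file: '%s'", path)
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n) || n < 1L)
        .stopf("first line of '%s' must be the structure count", path)
    if (length(lines) != n + 1L)
        .stopf("expected %d matrix rows in '%s', found %d", n, path,
               length(lines) - 1L)
    labs <- character(n)
    m <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
        tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
        if (length(tok) != n + 1L)
            .stopf("row %d of '%s' is not square: %d values for n = %d",
                   i, path, length(tok) - 1L, n)
        labs[i] <- tok[1]
        vals <- suppressWarnings(as.numeric(tok[-1]))
        if (anyNA(vals))
            .stopf("non-numeric value in row %d of '%s'", i, path)
        m[i, ] <- vals
    }
    if (anyDuplicated(labs))
        .stopf("duplicate labels in '%s': %s", path,
               paste(unique(labs[duplicated(labs)]), collapse = ", "))
    asym <- max(abs(m - t(m)))
    if (asym > 0.5)
        .warnf("matrix '%s' asymmetric by up to %.3g; averaging", path, asym)
    m <- (m + t(m)) / 2
    dimnames(m) <- list(labs, labs)
    methods::new("SimilarityMatrix", values = m)
}

#' Write a labelled square matrix in PHYLIP square format
#'
#' @param x a [SimilarityMatrix-class], [DistanceMatrix-class] or labelled
#'   square numeric matrix.
#' @param path output path.
#' @param digits significant digits written (default 10, enough for
#'   read/write round trips at 1e-9).
#' @return the path, invisibly.
#' @export
writeSquareMatrix <- function(x, path, digits = 10L) {
    m <- if (methods::is(x, "SimilarityMatrix")) x@values
         else if (methods::is(x, "DistanceMatrix")) x@values
         else x
    stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
    .atomicWrite(function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines(as.character(nrow(m)), con)
        for (i in seq_len(nrow(m)))
            writeLines(paste(rownames(m)[i],
                             paste(format(m[i, ], digits = digits,
                                          trim = TRUE, scientific = FALSE),
                                   collapse = " ")), con)
    }, path)
}
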