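# Shared constants and small helpers.

# canonical 20-letter amino-acid alphabet (alphabetical one-letter codes)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.isGapSym <- function(x) x %in% c("-", "X")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# wrap angle into (-180, 180]
.wrap180 <- function(a) {
    a <- (a + 180) %% 360 - 180
    a[a == -180] <- 180
    a
}

# smallest absolute circular difference in degrees
.angDiff <- function(a, b) {
    d <- abs(.wrap180(a - b))
    d
}

# population standard deviation (divide by n)
.popSD <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 1L) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
}

# atomic write: write to a temp file in the same directory, then rename,
# so a failed stage never leaves a partial output behind
.atomicWrite <- function(writer, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        .stopf("could not move temporary output to '%s'", path)
    invisible(path)
}

.writeTSV <- function(df, path) {
    .atomicWrite(function(tmp)
        utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA"),
        path)
}
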