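# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    eval.parent(substitute(expr))
}

# Derive a child seed; keeps results < 2^31 and decorrelates sub-streams.
childSeed <- function(seed, k) {
    as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' Write a data.frame as TSV (tab-separated, no quoting, no row names)
#' @param x data.frame.
#' @param path output path.
#' @export
writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a TSV written by [writeTSV()]
#' @param path input path.
#' @export
readTSV <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}

# canonical undirected edge key
edgeKey <- function(a, b) {
    ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
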