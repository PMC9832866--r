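#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement width
NULL

.baseOrder <- c("A", "C", "G", "T")

#' Construct a MotifModel
#'
#' @param id motif identifier.
#' @param matrix 4 x width (rows A, C, G, T) or width x 4 matrix of
#'   probabilities or counts; normalized column-wise with the pseudocount.
#' @param background length-4 background probabilities (default uniform).
#' @param pseudocount added before normalization (default 1e-3).
#' @return a [MotifModel].
#' @export
motifModel <- function(id, matrix, background = rep(0.25, 4),
                       pseudocount = 1e-3) {
    m <- as.matrix(matrix)
    if (nrow(m) != 4L && ncol(m) == 4L) m <- t(m)
    if (nrow(m) != 4L) stopf("motif matrix must have 4 rows or 4 columns")
    m <- sweep(m + pseudocount, 2L, colSums(m) + 4 * pseudocount, "/")
    rownames(m) <- .baseOrder
    background <- background / sum(background)
    new("MotifModel", id = id, probMatrix = m,
        background = as.numeric(background), pseudocount = pseudocount)
}

#' @rdname motifModel
#' @export
setMethod("motifWidth", "MotifModel", function(object) ncol(object@probMatrix))

#' @rdname motifModel
#' @export
setMethod("motifConsensus", "MotifModel", function(object)
    paste(.baseOrder[apply(object@probMatrix, 2L, which.max)], collapse = ""))

setMethod("show", "MotifModel", function(object) {
    cat("MotifModel", object@id, "width", motifWidth(object),
        "consensus", motifConsensus(object), "\n")
})

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` records with their `letter-probability matrix` blocks; a
#' `Background letter frequencies` line, when present, supplies the
#' background, otherwise it is uniform.  Malformed matrix rows (not 4 fields,
#' or probabilities not summing to ~1) raise an error naming the line.
#'
#' @param path MEME minimal format file.
#' @param pseudocount passed to [motifModel()].
#' @return list of [MotifModel] (possibly empty, with a warning).
#' @export
readMEME <- function(path, pseudocount = 1e-3) {
    lines <- readLines(path)
    bg <- rep(0.25, 4)
    bgLine <- grep("^Background letter frequencies", lines)
    if (length(bgLine)) {
        f <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1L]]
        vals <- suppressWarnings(as.numeric(f[seq(2, length(f), 2)]))
        if (length(vals) == 4L && !any(is.na(vals))) bg <- vals
    }
    starts <- grep("^MOTIF\\b", lines)
    if (!length(starts)) {
        warnf("no MOTIF records in %s", basename(path))
        return(list())
    }
    out <- vector("list", length(starts))
    for (i in seq_along(starts)) {
        id <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1L]][2L]
        j <- starts[i] + 1L
        while (j <= length(lines) &&
               !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
        if (j > length(lines)) stopf("motif %s has no probability matrix", id)
        hdr <- lines[j]
        w <- suppressWarnings(as.integer(
            sub(".*w=\\s*([0-9]+).*", "\\1", hdr)))
        rows <- list()
        k <- j + 1L
        while (k <= length(lines) && nzchar(trimws(lines[k])) &&
               !grepl("^(MOTIF|URL)", lines[k])) {
            f <- suppressWarnings(as.numeric(
                strsplit(trimws(lines[k]), "\\s+")[[1L]]))
            if (length(f) != 4L || any(is.na(f)))
                stopf("malformed matrix row at line %d of %s", k,
                      basename(path))
            if (abs(sum(f) - 1) > 0.01)
                stopf("matrix row at line %d does not sum to 1", k)
            rows[[length(rows) + 1L]] <- f
            k <- k + 1L
        }
        if (!is.na(w) && length(rows) != w)
            stopf("motif %s: expected %d rows, found %d", id, w, length(rows))
        out[[i]] <- motifModel(id, t(do.call(rbind, rows)), background = bg,
                               pseudocount = pseudocount)
    }
    out
}

#' @rdname readMEME
#' @param motifs list of [MotifModel].
#' @param background length-4 background written to the file header.
#' @export
writeMEME <- function(motifs, path, background = rep(0.25, 4)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "", "Background letter frequencies",
                 sprintf("A %.5f C %.5f G %.5f T %.5f", background[1L],
                         background[2L], background[3L], background[4L]), ""),
               con)
    for (m in motifs) {
        writeLines(sprintf("MOTIF %s", m@id), con)
        writeLines(sprintf(
            "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            motifWidth(m)), con)
        for (j in seq_len(motifWidth(m)))
            writeLines(paste(sprintf("%.6f", m@probMatrix[, j]),
                             collapse = " "), con)
        writeLines("", con)
    }
    invisible(path)
}

#' Exact score -> p-value table of a PWM
#'
#' Log-odds scores `log(p_ij / bg_i)` are discretized to integers at
#' `granularity` units per nat; the null distribution of the total window
#' score under the i.i.d. background is computed by exact convolution across
#' positions, yielding `p(s) = P(score >= s)`.  The table is monotone
#' non-increasing in the score and `p` at the minimum attainable score is 1.
#'
#' @param motif a [MotifModel].
#' @param background length-4 positive background probabilities (defaults to
#'   the motif's).
#' @param granularity integer discretization (default 1000 units per nat; the
#'   source of <= 1e-3 p-value rounding).
#' @return list with `scoreMatrix` (integer 4 x w), `minScore`, `maxScore`,
#'   `pvalues` (vector over minScore:maxScore), `granularity`, `background`.
#' @export
scoreDistribution <- function(motif, background = motif@background,
                              granularity = 1000L) {
    if (any(background <= 0)) stopf("background probabilities must be positive")
    background <- background / sum(background)
    S <- matrix(as.integer(round(granularity *
                                 log(motif@probMatrix / background))),
                nrow = 4L, dimnames = dimnames(motif@probMatrix))
    w <- ncol(S)
    dist <- 1
    lo <- 0L
    for (j in seq_len(w)) {
        cmin <- min(S[, j]); cmax <- max(S[, j])
        nd <- numeric(length(dist) + cmax - cmin)
        for (b in 1:4) {
            off <- S[b, j] - cmin
            idx <- seq_along(dist) + off
            nd[idx] <- nd[idx] + dist * background[b]
        }
        dist <- nd
        lo <- lo + cmin
    }
    pv <- rev(cumsum(rev(dist)))
    pv <- pmin(pv, 1)
    list(scoreMatrix = S, minScore = lo, maxScore = lo + length(dist) - 1L,
         pvalues = pv, granularity = as.integer(granularity),
         background = background)
}

# integer codes 1..4 for A,C,G,T; NA otherwise
.encodeDNA <- function(s) {
    x <- match(strsplit(toupper(as.character(s)), "")[[1L]], .baseOrder)
    x
}

#' Scan sequences with PWMs at an exact p-value threshold
#'
#' Slides every motif over both strands of every sequence and reports every
#' window with exact p-value strictly below `pCutoff`.  Windows containing
#' non-ACGT letters are skipped.  Coordinates are 0-based half-open on the
#' forward strand; minus-strand hits give the forward-strand window that the
#' reverse complement of the motif matches.
#'
#' @param motifs a [MotifModel] or list of them.
#' @param sequences named `DNAStringSet` or named character vector.
#' @param pCutoff exact p-value threshold (default 1e-4, strict `<`).
#' @param background `"estimate"` (0-order composition of `sequences`;
#'   uniform fallback), `"uniform"`, or a length-4 numeric.
#' @param granularity see [scoreDistribution()].
#' @return data.frame (seq, motif, start, end, strand, score, p) sorted by
#'   (seq, start); `score` is the log-odds in nats.
#' @export
scanMotifs <- function(motifs, sequences, pCutoff = 1e-4,
                       background = "estimate", granularity = 1000L) {
    if (methods::is(motifs, "MotifModel")) motifs <- list(motifs)
    seqs <- vapply(as.character(sequences), identity, character(1))
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stopf("sequences must be named")
    if (identical(background, "estimate")) {
        tab <- table(factor(unlist(strsplit(toupper(seqs), "")),
                            levels = .baseOrder))
        background <- if (sum(tab) == 0 || any(tab == 0)) rep(0.25, 4)
                      else as.numeric(tab / sum(tab))
    } else if (identical(background, "uniform")) {
        background <- rep(0.25, 4)
    }
    codes <- lapply(seqs, .encodeDNA)
    hits <- list()
    for (m in motifs) {
        sd <- scoreDistribution(m, background = background,
                                granularity = granularity)
        w <- ncol(sd$scoreMatrix)
        Sfwd <- sd$scoreMatrix
        Srev <- Sfwd[4:1, w:1, drop = FALSE]   # reverse complement
        for (sn in names(codes)) {
            code <- codes[[sn]]
            L <- length(code)
            if (L < w) next
            n <- L - w + 1L
            for (strand in c("+", "-")) {
                S <- if (strand == "+") Sfwd else Srev
                sc <- integer(n)
                bad <- logical(n)
                for (j in seq_len(w)) {
                    cj <- code[j:(j + n - 1L)]
                    bad <- bad | is.na(cj)
                    sc <- sc + ifelse(is.na(cj), 0L, S[cbind(cj, j)])
                }
                p <- sd$pvalues[pmax(sc, sd$minScore) - sd$minScore + 1L]
                ok <- !bad & p < pCutoff
                if (any(ok))
                    hits[[length(hits) + 1L]] <- data.frame(
                        seq = sn, motif = m@id,
                        start = which(ok) - 1L,
                        end = which(ok) - 1L + w,
                        strand = strand,
                        score = sc[ok] / sd$granularity,
                        p = p[ok], stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(hits))
        return(data.frame(seq = character(), motif = character(),
                          start = integer(), end = integer(),
                          strand = character(), score = numeric(),
                          p = numeric(), stringsAsFactors = FALSE))
    out <- do.call(rbind, hits)
    out <- out[order(out$seq, out$start, out$strand, out$motif), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Confirm regulator-target edges by binding sites in target promoters
#'
#' An edge is `confirmed` when at least one hit of the regulator's motif lies
#' in the target's upstream sequence; edges whose regulator has no motif are
#' flagged `untestable`; remaining edges are `unconfirmed`.  No edge is
#' dropped.
#'
#' @param edges data.frame with columns `regulator` and `target`.
#' @param hits scan results from [scanMotifs()] over the targets' upstream
#'   sequences (sequence names = target gene ids).
#' @param tfMotifMap named character: regulator gene id -> motif id.
#' @return `edges` with an added `status` column.
#' @export
confirmEdges <- function(edges, hits, tfMotifMap) {
    hitKey <- unique(paste(hits$seq, hits$motif))
    motif <- unname(tfMotifMap[edges$regulator])
    status <- ifelse(is.na(motif), "untestable",
                     ifelse(paste(edges$target, motif) %in% hitKey,
                            "confirmed", "unconfirmed"))
    edges$status <- status
    edges
}
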