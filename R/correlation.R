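#' Pearson correlation table between two gene sets
#'
#' Computes product-moment correlations between every gene of `genesA` (rows)
#' and every gene of `genesB` (columns).  By default the correlation is taken
#' over per-time-point replicate-mean profiles (`sampleMode = "means"`,
#' n = D samples) of log2(TPM + 1); count-level noise in individual
#' replicates otherwise dilutes profile correlations toward zero
#' (regression dilution), which matters at a fixed edge cutoff.
#' Per-replicate vectors (n = D x R) and untransformed TPM are available for
#' sensitivity analysis.
#'
#' Genes with zero variance across the chosen samples cannot be correlated;
#' they are dropped with a warning (their rows/columns are absent from the
#' result), not an error.
#'
#' @param object a [TimeCourseSet].
#' @param genesA,genesB character vectors of gene ids.
#' @param sampleMode `"means"` (default) or `"replicates"`.
#' @param transform `"log2"` (default; log2(TPM+1)) or `"none"`.
#' @return matrix of correlations, rows `genesA`, columns `genesB`.
#' @export
correlationTable <- function(object, genesA, genesB,
                             sampleMode = c("means", "replicates"),
                             transform = c("log2", "none")) {
    sampleMode <- match.arg(sampleMode)
    transform <- match.arg(transform)
    genes <- union(genesA, genesB)
    missing <- setdiff(genes, rownames(object))
    if (length(missing))
        stopf("gene(s) absent from dataset: %s",
              paste(utils::head(missing, 5L), collapse = ", "))
    m <- expressionProfiles(object, genes, sampleMode, transform)
    v <- apply(m, 1L, stats::var)
    dead <- rownames(m)[v == 0]
    if (length(dead)) {
        warnf("excluding %d zero-variance gene(s): %s", length(dead),
              paste(utils::head(dead, 5L), collapse = ", "))
        genesA <- setdiff(genesA, dead)
        genesB <- setdiff(genesB, dead)
    }
    if (!length(genesA) || !length(genesB))
        return(matrix(numeric(0), length(genesA), length(genesB),
                      dimnames = list(genesA, genesB)))
    stats::cor(t(m[genesA, , drop = FALSE]), t(m[genesB, , drop = FALSE]))
}

# genes x samples (or genes x time points) value matrix used for correlation
expressionProfiles <- function(object, genes, sampleMode, transform) {
    x <- tpm(object)[genes, , drop = FALSE]
    if (sampleMode == "means") {
        tp <- timePoints(object)
        tps <- sort(unique(tp))
        x <- vapply(tps, function(t) rowMeans(x[, tp == t, drop = FALSE]),
                    numeric(length(genes)))
        if (length(genes) == 1L)
            x <- matrix(x, nrow = 1L)
        dimnames(x) <- list(genes, paste0("T", tps))
    }
    if (transform == "log2") x <- log2(x + 1)
    x
}

#' Threshold a correlation table into a typed edge set
#'
#' An edge is kept iff its correlation reaches the cutoff (inclusive; the boundary
#' value itself passes).  Rows of `corr` must be TF genes; columns may be any
#' coding genes, so the resulting edges are TF-TF or TF-target only.
#' Duplicate TF-TF pairs (appearing both above and below the diagonal) and
#' self-pairs are collapsed.
#'
#' @param corr correlation matrix with TF rows, as from [correlationTable()].
#' @param cutoff correlation cutoff in (0, 1], default 0.81.
#' @param tfIds character vector marking which node ids are TFs (defaults to
#'   the row names of `corr`).
#' @return a [CoexpressionEdgeSet].
#' @export
buildEdges <- function(corr, cutoff = 0.81, tfIds = rownames(corr)) {
    if (cutoff <= 0 || cutoff > 1)
        stopf("cutoff must be in (0, 1], got %g", cutoff)
    tfs <- rownames(corr)
    targets <- colnames(corr)
    hit <- which(corr >= cutoff, arr.ind = TRUE)
    a <- tfs[hit[, 1L]]
    b <- targets[hit[, 2L]]
    r <- corr[hit]
    keep <- a != b
    a <- a[keep]; b <- b[keep]; r <- r[keep]
    bIsTF <- b %in% tfIds
    swap <- bIsTF & b < a
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    key <- paste(a, b, sep = "\r")
    dup <- duplicated(key)
    e <- data.frame(a = a[!dup], b = b[!dup], r = r[!dup],
                    a_is_tf = rep(TRUE, sum(!dup)), b_is_tf = bIsTF[!dup],
                    stringsAsFactors = FALSE, row.names = NULL)
    e <- e[order(e$a, e$b), , drop = FALSE]
    rownames(e) <- NULL
    new("CoexpressionEdgeSet", edges = e,
        nodes = union(tfs, targets), tfNodes = intersect(union(tfs, targets), tfIds),
        cutoff = cutoff, mode = "C1+")
}

setMethod("show", "CoexpressionEdgeSet", function(object) {
    cat("CoexpressionEdgeSet:", nrow(object@edges), "edges over",
        length(object@nodes), "nodes (", length(object@tfNodes), "TFs ), r >=",
        object@cutoff, "\n")
})
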