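#' Pairwise time-point differential-expression filter
#'
#' For every pair of time points, computes per gene the log2 fold change of
#' pseudocounted mean TPM and a Welch two-sample t-test on log2(TPM + 1)
#' across replicates, with Benjamini-Hochberg adjustment across genes within
#' each pair.  A gene is flagged as a DEG when at least one pair has
#' `|log2FC| >= lfcCutoff` and adjusted p `< fdrCutoff`.
#'
#' The test is deliberately self-contained (no dispersion shrinkage); the
#' contract downstream stages rely on is the thresholded filter, not the
#' particular caller.  An alternative test can be plugged in via `testFun`.
#'
#' @param object a [TimeCourseSet] with at least 2 replicates per time point.
#' @param lfcCutoff absolute log2 fold-change cutoff (default 1).
#' @param fdrCutoff BH-adjusted p cutoff (default 0.05, strict `<`).
#' @param pseudocount added to mean TPM before the fold change (default 1).
#' @param testFun function(xa, xb) -> p-value on two vectors of log2(TPM+1);
#'   defaults to Welch's t-test.
#' @return a [DEResult].
#' @export
pairwiseDE <- function(object, lfcCutoff = 1, fdrCutoff = 0.05,
                       pseudocount = 1, testFun = NULL) {
    tp <- timePoints(object)
    tps <- sort(unique(tp))
    reps <- table(tp)
    if (any(reps < 2L))
        stopf("time point(s) with fewer than 2 replicates: %s",
              paste(names(reps)[reps < 2L], collapse = ", "))
    if (is.null(testFun))
        testFun <- function(xa, xb) {
            if (stats::var(xa) + stats::var(xb) == 0)
                return(if (mean(xa) == mean(xb)) 1 else 0)
            stats::t.test(xa, xb)$p.value
        }
    x <- tpm(object)
    lx <- log2(x + 1)
    genes <- rownames(x)
    pairs <- utils::combn(tps, 2L)
    tabs <- vector("list", ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
        t1 <- pairs[1L, j]; t2 <- pairs[2L, j]
        i1 <- which(tp == t1); i2 <- which(tp == t2)
        m1 <- rowMeans(x[, i1, drop = FALSE])
        m2 <- rowMeans(x[, i2, drop = FALSE])
        lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
        p <- vapply(seq_along(genes), function(g)
            testFun(lx[g, i1], lx[g, i2]), numeric(1))
        padj <- stats::p.adjust(p, method = "BH")
        tabs[[j]] <- data.frame(
            gene = genes, pair = sprintf("T%d-T%d", t1, t2),
            log2FC = lfc, p = p, padj = padj,
            significant = abs(lfc) >= lfcCutoff & padj < fdrCutoff,
            stringsAsFactors = FALSE, row.names = NULL)
    }
    tab <- do.call(rbind, tabs)
    flags <- tapply(tab$significant, tab$gene, any)
    flags <- stats::setNames(as.logical(flags[genes]), genes)
    new("DEResult", table = tab, degFlags = flags,
        params = list(lfcCutoff = lfcCutoff, fdrCutoff = fdrCutoff,
                      pseudocount = pseudocount,
                      test = "welch-log2tpm", adjust = "BH-within-pair"))
}

setMethod("show", "DEResult", function(object) {
    cat("DEResult:", length(object@degFlags), "genes,",
        length(unique(object@table$pair)), "time-point pairs;",
        sum(object@degFlags), "DEGs (|log2FC| >=",
        object@params$lfcCutoff, ", FDR <", object@params$fdrCutoff, ")\n")
})

#' @rdname pairwiseDE
#' @param de a [DEResult].
#' @export
degGenes <- function(de) names(de@degFlags)[de@degFlags]

#' @rdname pairwiseDE
#' @export
deTable <- function(de) de@table

#' Write a DE table as TSV
#' @param de a [DEResult].
#' @param path output path.
#' @export
writeDETable <- function(de, path) writeTSV(de@table, path)

#' Select "expressed DEGs": the node universe of the networks
#'
#' A gene qualifies when it is a DEG for at least one time-point pair and its
#' mean TPM over all samples is strictly greater than `minMeanTPM`.
#'
#' @param object a [TimeCourseSet].
#' @param de the [DEResult] computed on `object`.
#' @param minMeanTPM floor on the all-sample mean TPM (default 0.5, strict).
#' @return character vector of gene ids.
#' @export
selectExpressedDEGs <- function(object, de, minMeanTPM = 0.5) {
    if (!identical(sort(names(de@degFlags)), sort(rownames(object))))
        stopf("DE result does not match the dataset's genes")
    meanTPM <- rowMeans(tpm(object))
    keep <- de@degFlags[rownames(object)] & meanTPM > minMeanTPM
    rownames(object)[keep]
}

#' Rank monotone-decreasing seed-TF candidates
#'
#' The seed of a TO-GCN is a TF highly expressed at the first time point
#' whose mean TPM decreases strictly across every consecutive pair of time
#' points.  Candidates are scored by mean TPM at T1 scaled by the fraction of
#' strictly decreasing steps, so ineligible TFs still rank sensibly.
#'
#' @param object a [TimeCourseSet].
#' @param tfIds TF gene ids to consider (non-empty, subset of the dataset).
#' @param margin minimum drop per step required to count as decreasing
#'   (default 0: any strict decrease).
#' @return data.frame (gene, score, eligible), sorted by decreasing score.
#' @export
selectSeedTFs <- function(object, tfIds, margin = 0) {
    if (length(tfIds) == 0L) stopf("no TF ids supplied")
    missing <- setdiff(tfIds, rownames(object))
    if (length(missing))
        stopf("TF id(s) absent from dataset: %s",
              paste(missing, collapse = ", "))
    tp <- timePoints(object)
    tps <- sort(unique(tp))
    prof <- vapply(tps, function(t)
        rowMeans(tpm(object)[tfIds, tp == t, drop = FALSE]),
        numeric(length(tfIds)))
    if (length(tfIds) == 1L) prof <- matrix(prof, nrow = 1L,
                                            dimnames = list(tfIds, NULL))
    drops <- -t(apply(prof, 1L, diff))
    if (length(tps) == 2L) drops <- matrix(drops, ncol = 1L)
    nDecr <- rowSums(drops > margin)
    eligible <- nDecr == (length(tps) - 1L)
    score <- prof[, 1L] * nDecr / (length(tps) - 1L)
    out <- data.frame(gene = tfIds, score = as.numeric(score),
                      eligible = as.logical(eligible),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(-out$score, out$gene), , drop = FALSE]
}
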