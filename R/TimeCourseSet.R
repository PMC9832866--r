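#' Construct a TimeCourseSet
#'
#' @param counts genes x samples matrix of non-negative counts with unique
#'   rownames (gene ids).
#' @param timePoint integer vector (one per sample), 1..D.
#' @param replicate integer vector (one per sample), 1..R within time point.
#' @param geneLength numeric vector of effective lengths (bp), one per gene;
#'   required unless `tpm` is supplied.
#' @param tpm optional precomputed TPM matrix of the same shape; computed from
#'   `counts` and `geneLength` when missing.
#' @return a [TimeCourseSet].
#' @examples
#' cnt <- matrix(rpois(40, 50), nrow = 4,
#'               dimnames = list(paste0("g", 1:4), NULL))
#' tcs <- TimeCourseSet(cnt, timePoint = rep(1:5, each = 2),
#'                      replicate = rep(1:2, 5), geneLength = rep(1000, 4))
#' colSums(tpm(tcs))   # each 1e6
#' @export
TimeCourseSet <- function(counts, timePoint, replicate, geneLength = NULL,
                          tpm = NULL) {
    counts <- as.matrix(counts)
    timePoint <- as.integer(timePoint)
    replicate <- as.integer(replicate)
    if (length(timePoint) != ncol(counts) || length(replicate) != ncol(counts))
        stopf("timePoint/replicate must have one entry per sample column")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("T", timePoint, "_R", replicate)
    if (anyDuplicated(colnames(counts)))
        stopf("duplicate sample columns: %s",
              paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                    collapse = ", "))
    if (is.null(tpm)) {
        if (is.null(geneLength))
            stopf("either 'tpm' or 'geneLength' must be supplied")
        tpm <- computeTPM(counts, geneLength)
    }
    if (is.null(geneLength)) geneLength <- rep(NA_real_, nrow(counts))
    se <- SummarizedExperiment(
        assays = list(counts = counts, tpm = as.matrix(tpm)),
        colData = DataFrame(timePoint = timePoint, replicate = replicate,
                            row.names = colnames(counts)),
        rowData = DataFrame(geneLength = as.numeric(geneLength)))
    new("TimeCourseSet", se)
}

#' @rdname TimeCourseSet
#' @export
setMethod("counts", "TimeCourseSet", function(object) assay(object, "counts"))

#' @rdname TimeCourseSet
#' @export
setMethod("tpm", "TimeCourseSet", function(object) assay(object, "tpm"))

#' @rdname TimeCourseSet
#' @export
setMethod("geneLengths", "TimeCourseSet", function(object) {
    stats::setNames(rowData(object)$geneLength, rownames(object))
})

#' @rdname TimeCourseSet
#' @export
setMethod("timePoints", "TimeCourseSet", function(object)
    colData(object)$timePoint)

#' @rdname TimeCourseSet
#' @export
setMethod("replicates", "TimeCourseSet", function(object)
    colData(object)$replicate)

setMethod("show", "TimeCourseSet", function(object) {
    tp <- timePoints(object)
    cat("TimeCourseSet:", nrow(object), "genes x", ncol(object), "samples;",
        length(unique(tp)), "time points,",
        max(table(tp)), "replicates\n")
})

#' Transcripts-per-kilobase-million normalization
#'
#' `TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6` per
#' sample, so every sample column sums to one million.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param lengths positive effective lengths (bp), one per gene.
#' @return TPM matrix of the same shape.
#' @examples
#' computeTPM(matrix(c(10, 10), 2, dimnames = list(c("a", "b"), "s1")),
#'            lengths = c(1000, 2000))
#' @export
computeTPM <- function(counts, lengths) {
    counts <- as.matrix(counts)
    lengths <- as.numeric(lengths)
    if (length(lengths) != nrow(counts))
        stopf("need one length per gene (%d genes, %d lengths)",
              nrow(counts), length(lengths))
    if (any(is.na(lengths)) || any(lengths <= 0))
        stopf("gene lengths must be positive")
    if (any(counts < 0)) stopf("counts must be non-negative")
    rate <- counts / lengths
    tot <- colSums(rate)
    zero <- tot == 0
    if (any(zero))
        stopf("sample(s) with all-zero counts: %s",
              paste(colnames(counts)[zero], collapse = ", "))
    sweep(rate, 2, tot, "/") * 1e6
}

#' Read / write count matrices with the T<i>_R<j> sample-header convention
#'
#' The on-disk format is a TSV whose first column holds gene ids and whose
#' remaining column names encode the design as `T<timePoint>_R<replicate>`.
#'
#' @param path TSV file path.
#' @param geneLength optional lengths for TPM computation (named or in file
#'   order); if `NULL` the file must be accompanied by lengths later and the
#'   object carries counts only with TPM equal to the length-1000 convention.
#' @return `readExpression`: a [TimeCourseSet].
#' @export
readExpression <- function(path, geneLength = NULL) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(d[[1L]])
    if (anyDuplicated(ids))
        stopf("duplicate gene id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
    hdr <- colnames(d)[-1L]          # before subsetting, which mangles dups
    m <- as.matrix(d[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stopf("non-numeric expression values in %s", basename(path))
    rownames(m) <- ids
    colnames(m) <- hdr
    ok <- grepl("^T[0-9]+_R[0-9]+$", hdr)
    if (!all(ok))
        stopf("malformed sample header(s): %s",
              paste(hdr[!ok], collapse = ", "))
    if (anyDuplicated(hdr))
        stopf("duplicate sample header(s): %s",
              paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
    tpv <- as.integer(sub("^T([0-9]+)_R[0-9]+$", "\\1", hdr))
    rpv <- as.integer(sub("^T[0-9]+_R([0-9]+)$", "\\1", hdr))
    reps <- table(tpv)
    if (length(unique(reps)) != 1L)
        stopf("inconsistent replicate counts across time points: %s",
              paste(sprintf("T%s:%d", names(reps), reps), collapse = ", "))
    if (is.null(geneLength)) geneLength <- rep(1000, nrow(m))
    if (!is.null(names(geneLength))) geneLength <- geneLength[ids]
    TimeCourseSet(m, tpv, rpv, geneLength = geneLength)
}

#' @rdname readExpression
#' @param object a [TimeCourseSet].
#' @param what which assay to write ("counts" or "tpm").
#' @export
writeExpression <- function(object, path, what = c("counts", "tpm")) {
    what <- match.arg(what)
    m <- assay(object, what)
    d <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
    writeTSV(d, path)
}
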