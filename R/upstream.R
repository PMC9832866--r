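#' Extract upstream (promoter) sequences for genes
#'
#' For a forward-strand gene with 1-based start `s`, the upstream region is
#' `[max(1, s - length), s - 1]` on the forward strand; for a reverse-strand
#' gene with end `e` it is `[e + 1, min(contig length, e + length)]`
#' reverse-complemented.  Sequences are returned 5'->3' relative to the gene;
#' regions shorter than requested (contig boundary) are clipped, and genes
#' with an empty upstream region are skipped with a warning.
#'
#' @param genome a `DNAStringSet` or FASTA path.
#' @param annotations a `GRanges` with gene features (needs an `ID` or `Name`
#'   metadata column) or a GFF3 path.
#' @param length upstream length in bp (default 2000).
#' @return named `DNAStringSet` (names = gene ids).
#' @export
extractUpstream <- function(genome, annotations, length = 2000L) {
    if (is.character(genome)) genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (is.character(annotations)) {
        annotations <- rtracklayer::import(annotations, format = "gff3")
    }
    gr <- annotations
    if ("type" %in% colnames(S4Vectors::mcols(gr)))
        gr <- gr[gr$type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
    if (is.null(ids)) stopf("gene features need an ID or Name attribute")
    contigs <- as.character(GenomicRanges::seqnames(gr))
    missing <- setdiff(unique(contigs), names(genome))
    if (length(missing))
        stopf("contig(s) absent from the FASTA: %s",
              paste(utils::head(missing, 5L), collapse = ", "))
    out <- character(0)
    skipped <- character(0)
    for (i in seq_along(gr)) {
        ctg <- contigs[i]
        clen <- width(genome[ctg])
        strand <- as.character(GenomicRanges::strand(gr[i]))
        if (strand == "-") {
            from <- GenomicRanges::end(gr[i]) + 1L
            to <- min(clen, GenomicRanges::end(gr[i]) + length)
        } else {
            from <- max(1L, GenomicRanges::start(gr[i]) - length)
            to <- GenomicRanges::start(gr[i]) - 1L
        }
        if (from > to) { skipped <- c(skipped, ids[i]); next }
        s <- Biostrings::subseq(genome[[ctg]], from, to)
        if (strand == "-") s <- reverseComplement(s)
        out[ids[i]] <- as.character(s)
    }
    if (length(skipped))
        warnf("skipped %d gene(s) with empty upstream region: %s",
              length(skipped), paste(utils::head(skipped, 5L), collapse = ", "))
    DNAStringSet(out)
}
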