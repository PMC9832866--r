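#' Construct a GeneCatalog
#'
#' @param data a data.frame with columns `gene_id`, `is_tf` (logical),
#'   `tf_family` (character, `""`/`NA` for non-TFs), `pathway` (one of
#'   carotenoid, chlorophyll, anthocyanin, flavonol, none) and `length` (bp).
#' @return a [GeneCatalog].
#' @export
GeneCatalog <- function(data) {
    d <- as.data.frame(data, stringsAsFactors = FALSE)
    d$gene_id <- as.character(d$gene_id)
    d$is_tf <- as.logical(d$is_tf)
    d$tf_family <- as.character(d$tf_family)
    d$pathway <- as.character(d$pathway)
    d$length <- as.numeric(d$length)
    new("GeneCatalog", data = DataFrame(d))
}

#' @rdname GeneCatalog
#' @param object a [GeneCatalog].
#' @param genes character vector of gene ids.
#' @export
setMethod("isTF", "GeneCatalog", function(object, genes) {
    idx <- match(genes, object@data$gene_id)
    out <- object@data$is_tf[idx]
    out[is.na(out)] <- FALSE
    stats::setNames(out, genes)
})

#' @rdname GeneCatalog
#' @export
setMethod("tfGenes", "GeneCatalog", function(object)
    object@data$gene_id[object@data$is_tf])

#' @rdname GeneCatalog
#' @param pathways character vector of pathway labels.
#' @export
setMethod("pathwayGenes", "GeneCatalog", function(object, pathways) {
    bad <- setdiff(pathways, validPathways())
    if (length(bad))
        stopf("unknown pathway label(s): %s (valid: %s)",
              paste(bad, collapse = ", "),
              paste(validPathways(), collapse = ", "))
    object@data$gene_id[object@data$pathway %in% pathways]
})

setMethod("show", "GeneCatalog", function(object) {
    d <- object@data
    cat("GeneCatalog:", nrow(d), "genes;", sum(d$is_tf), "TFs;",
        sum(d$pathway != "none"), "pathway enzymes\n")
})

#' @rdname GeneCatalog
#' @export
tfFamilies <- function(object) {
    d <- object@data
    stats::setNames(d$tf_family[d$is_tf], d$gene_id[d$is_tf])
}

#' Read / write gene catalogs as TSV
#' @param path TSV path with the [GeneCatalog] columns.
#' @export
readGeneCatalog <- function(path) GeneCatalog(readTSV(path))

#' @rdname readGeneCatalog
#' @param object a [GeneCatalog].
#' @export
writeGeneCatalog <- function(object, path)
    writeTSV(as.data.frame(object@data), path)

#' Read / write two-column ortholog maps
#'
#' Pairs are required to be 1:1 after resolution; a gene appearing in more
#' than one pair is rejected at load time.
#'
#' @param path two-column TSV (`gene1`, `gene2`).
#' @return data.frame with columns `gene1`, `gene2`.
#' @export
readOrthologMap <- function(path) {
    d <- readTSV(path)
    if (ncol(d) < 2L) stopf("ortholog map needs two columns")
    d <- data.frame(gene1 = as.character(d[[1L]]),
                    gene2 = as.character(d[[2L]]),
                    stringsAsFactors = FALSE)
    validateOrthologMap(d)
}

#' @rdname readOrthologMap
#' @param map data.frame of pairs.
#' @export
validateOrthologMap <- function(map) {
    if (anyDuplicated(map$gene1) || anyDuplicated(map$gene2))
        stopf("ortholog map is not 1:1 (duplicated partner)")
    map
}

#' @rdname readOrthologMap
#' @export
writeOrthologMap <- function(map, path) writeTSV(map, path)
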