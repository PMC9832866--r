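#' Assign time-order levels to TFs by breadth-first search from a seed
#'
#' Level 1 is the seed; every other TF receives `1 + min(level of already-
#' leveled TF neighbours)`, i.e. one plus its hop distance from the seed over
#' TF-TF edges only.  Nodes are processed in ascending (level, lexicographic
#' id) order so the result is independent of node insertion order.  TFs
#' unreachable from the seed stay unleveled and are reported, not dropped.
#'
#' @param edgeSet a [CoexpressionEdgeSet].
#' @param seed seed TF id (must be a TF node of the edge set).
#' @return list with `levels` (named integer vector over leveled TFs),
#'   `unleveled` (character) and `seed`.
#' @export
assignLevels <- function(edgeSet, seed) {
    tfs <- edgeSet@tfNodes
    if (!seed %in% edgeSet@nodes)
        stopf("seed '%s' is not a node of the edge set", seed)
    if (!seed %in% tfs)
        stopf("seed '%s' is not a TF node", seed)
    e <- edgeSet@edges
    e <- e[e$a_is_tf & e$b_is_tf, , drop = FALSE]
    adj <- split(c(e$b, e$a), c(e$a, e$b))
    levels <- stats::setNames(1L, seed)
    frontier <- seed
    current <- 1L
    while (length(frontier)) {
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- sort(setdiff(nxt, names(levels)))
        if (!length(nxt)) break
        levels[nxt] <- current + 1L
        frontier <- nxt
        current <- current + 1L
    }
    list(levels = levels, unleveled = sort(setdiff(tfs, names(levels))),
         seed = seed)
}

#' Attach non-TF target genes to a leveled TF network
#'
#' Every non-TF gene adjacent to at least one leveled TF receives the minimum
#' level among its leveled TF neighbours.  Targets never propagate levels
#' further; targets without a leveled TF neighbour are excluded from the
#' network.
#'
#' @param edgeSet a [CoexpressionEdgeSet].
#' @param levelMap result of [assignLevels()].
#' @param profiles optional nodes x time-points matrix of mean log2(TPM+1)
#'   profiles stored in the result.
#' @param provenance optional list recorded in the result.
#' @return a [TOGCN] whose nodes are the leveled TFs plus attached targets,
#'   with edges restricted to node pairs at least one of which is a leveled TF.
#' @export
attachTargets <- function(edgeSet, levelMap, profiles = NULL,
                          provenance = list()) {
    lv <- levelMap$levels
    e <- edgeSet@edges
    keepTF <- names(lv)
    tgtE <- e[!e$b_is_tf & e$a %in% keepTF, , drop = FALSE]
    tgtLv <- integer(0)
    if (nrow(tgtE)) {
        agg <- tapply(lv[tgtE$a], tgtE$b, min)
        tgtLv <- stats::setNames(as.integer(agg), names(agg))
    }
    allLv <- c(lv, tgtLv)
    keep <- (e$a %in% keepTF) & (ifelse(e$b_is_tf, e$b %in% keepTF,
                                        e$b %in% names(tgtLv)))
    e <- e[keep, , drop = FALSE]
    rownames(e) <- NULL
    if (is.null(profiles))
        profiles <- matrix(numeric(0), 0, 0)
    else
        profiles <- profiles[intersect(rownames(profiles), names(allLv)), ,
                             drop = FALSE]
    new("TOGCN", edges = e, levels = allLv,
        unleveled = levelMap$unleveled, seed = levelMap$seed,
        cutoff = edgeSet@cutoff, profiles = profiles,
        tfNodes = intersect(edgeSet@tfNodes, names(allLv)),
        provenance = provenance)
}

#' Build a species' time-ordered co-expression network
#'
#' Composition of the four elementary steps: select the node universe
#' (expressed DEGs, with the seed whitelisted on request), correlate TFs
#' against all nodes, threshold into edges, BFS-level the TFs from the seed
#' and attach enzyme/target genes.
#'
#' @param object a [TimeCourseSet].
#' @param catalog a [GeneCatalog].
#' @param seed seed TF gene id.
#' @param genes node universe (e.g. from [selectExpressedDEGs()]); defaults
#'   to all genes of `object`.
#' @param cutoff correlation cutoff (default 0.81, inclusive).
#' @param sampleMode,transform see [correlationTable()].
#' @return a [TOGCN].
#' @export
buildTOGCN <- function(object, catalog, seed, genes = rownames(object),
                       cutoff = 0.81,
                       sampleMode = c("means", "replicates"),
                       transform = c("log2", "none")) {
    sampleMode <- match.arg(sampleMode)
    transform <- match.arg(transform)
    if (!length(genes)) stopf("no nodes: empty gene universe")
    if (!seed %in% genes) {
        if (seed %in% rownames(object))
            stopf(paste0("seed '", seed, "' was filtered out of the gene ",
                         "universe; pass it explicitly via 'genes' to ",
                         "whitelist it"))
        stopf("seed '%s' is not in the dataset", seed)
    }
    tfs <- intersect(genes, tfGenes(catalog))
    if (!length(tfs)) stopf("no TF genes in the universe")
    corr <- correlationTable(object, tfs, genes,
                             sampleMode = sampleMode, transform = transform)
    es <- buildEdges(corr, cutoff = cutoff, tfIds = tfs)
    lm <- assignLevels(es, seed)
    prof <- expressionProfiles(object, genes, "means", "log2")
    attachTargets(es, lm, profiles = prof,
                  provenance = list(cutoff = cutoff, seed = seed,
                                    sampleMode = sampleMode,
                                    transform = transform,
                                    nGenes = length(genes),
                                    nTFs = length(tfs)))
}

#' @rdname TOGCN-class
#' @export
setMethod("edgeTable", "TOGCN", function(object) object@edges)

#' @rdname TOGCN-class
#' @export
setMethod("levelMap", "TOGCN", function(object) object@levels)

#' @rdname TOGCN-class
#' @export
setMethod("networkNodes", "TOGCN", function(object) names(object@levels))

#' @rdname TOGCN-class
#' @export
setMethod("networkSeed", "TOGCN", function(object) object@seed)

setMethod("show", "TOGCN", function(object) {
    lv <- object@levels
    tflv <- lv[names(lv) %in% object@tfNodes]
    cat("TOGCN: seed", object@seed, "| r >=", object@cutoff, "\n")
    cat(" ", length(lv), "nodes (", length(tflv), "TFs ),",
        nrow(object@edges), "edges,",
        if (length(tflv)) max(tflv) else 0L, "levels;",
        length(object@unleveled), "unleveled TFs\n")
})

#' Write network tables
#'
#' `writeEdgeTable` writes the edge TSV (a, b, r, a_is_tf, b_is_tf);
#' `writeLevelTable` writes the node -> level TSV; `exportNodeLink` writes a
#' node-link JSON document for visualization tools.
#'
#' @param object a [TOGCN].
#' @param path output file.
#' @export
writeEdgeTable <- function(object, path) writeTSV(edgeTable(object), path)

#' @rdname writeEdgeTable
#' @export
writeLevelTable <- function(object, path) {
    writeTSV(data.frame(node = names(object@levels),
                        level = as.integer(object@levels),
                        is_tf = names(object@levels) %in% object@tfNodes,
                        stringsAsFactors = FALSE), path)
}

#' @rdname writeEdgeTable
#' @export
exportNodeLink <- function(object, path) {
    nodes <- lapply(names(object@levels), function(n) list(
        id = n, level = as.integer(object@levels[[n]]),
        is_tf = n %in% object@tfNodes))
    links <- lapply(seq_len(nrow(object@edges)), function(i) list(
        source = object@edges$a[i], target = object@edges$b[i],
        r = object@edges$r[i]))
    jsonlite::write_json(
        list(directed = FALSE, seed = object@seed, cutoff = object@cutoff,
             nodes = nodes, links = links),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
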