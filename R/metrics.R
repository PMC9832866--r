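#' Score recovered networks against the planted truth
#'
#' Computes, pooled over both species where applicable:
#' \describe{
#'   \item{edge_precision / edge_recall}{recovered network edges versus the
#'     truth co-expression edge sets ([latentEdges()] at the networks'
#'     cutoff).}
#'   \item{level_accuracy}{fraction of planted TFs assigned exactly their
#'     planted level (unleveled TFs count as wrong).}
#'   \item{scope_accuracy}{among recovered edges that are truth edges, the
#'     fraction whose consensus/species-specific classification matches the
#'     truth scope (a truth edge is "both" when its ortholog image is also a
#'     truth edge in the other species).}
#'   \item{hub_recovery}{fraction of planted hub enzymes called as hubs in
#'     the all-pathway subnetwork at `hubCutoff` (default: 1.5 x TFs per
#'     level, the midpoint between the planted hub and non-hub degrees).}
#' }
#'
#' @param truth a [TruthRegulome].
#' @param togcns named list of the two species' [TOGCN] objects.
#' @param comparative the [ComparativeTOGCN] built from them.
#' @param hubCutoff degree cutoff for hub recovery.
#' @return named numeric vector of the five metrics.
#' @export
evaluateRecovery <- function(truth, togcns, comparative, hubCutoff = NULL) {
    cutoff <- togcns[[1L]]@cutoff
    if (is.null(hubCutoff))
        hubCutoff <- round(1.5 * truth@config@tfsPerLevel)
    orth <- truth@orthologPairs
    to2 <- stats::setNames(orth$gene2, orth$gene1)
    to1 <- stats::setNames(orth$gene1, orth$gene2)

    truthE <- lapply(1:2, function(s) latentEdges(truth, cutoff, s))
    truthKeys <- lapply(truthE, function(e) edgeKey(e$a, e$b))
    recKeys <- lapply(togcns, function(tg)
        edgeKey(tg@edges$a, tg@edges$b))

    nTP <- sum(vapply(1:2, function(s)
        sum(recKeys[[s]] %in% truthKeys[[s]]), numeric(1)))
    nRec <- sum(lengths(recKeys))
    nTruth <- sum(lengths(truthKeys))
    precision <- if (nRec) nTP / nRec else NA_real_
    recall <- if (nTruth) nTP / nTruth else NA_real_

    levelAcc <- {
        ok <- 0L; tot <- 0L
        for (s in 1:2) {
            planted <- truth@tfLevels[[s]]
            got <- togcns[[s]]@levels
            tot <- tot + length(planted)
            ok <- ok + sum(!is.na(got[names(planted)]) &
                           got[names(planted)] == planted, na.rm = TRUE)
        }
        ok / tot
    }

    # scope: classify each recovered-and-true edge by consensus membership
    consKeys <- list(
        edgeKey(splitMerged(comparative@consensus@edges$a, 1L),
                splitMerged(comparative@consensus@edges$b, 1L)),
        edgeKey(splitMerged(comparative@consensus@edges$a, 2L),
                splitMerged(comparative@consensus@edges$b, 2L)))
    scopeOK <- 0L; scopeTot <- 0L
    for (s in 1:2) {
        e <- togcns[[s]]@edges
        isTruth <- edgeKey(e$a, e$b) %in% truthKeys[[s]]
        e <- e[isTruth, , drop = FALSE]
        if (!nrow(e)) next
        map <- if (s == 1L) to2 else to1
        ia <- unname(map[e$a]); ib <- unname(map[e$b])
        mapped <- !is.na(ia) & !is.na(ib)
        trueBoth <- mapped & edgeKey(ifelse(mapped, ia, ""),
                                     ifelse(mapped, ib, "")) %in%
            truthKeys[[3L - s]]
        predBoth <- edgeKey(e$a, e$b) %in% consKeys[[s]]
        scopeOK <- scopeOK + sum(predBoth == trueBoth)
        scopeTot <- scopeTot + nrow(e)
    }
    scopeAcc <- if (scopeTot) scopeOK / scopeTot else NA_real_

    hubRec <- {
        got <- 0L; tot <- 0L
        for (s in 1:2) {
            catalog <- makeGeneCatalog(truth, s)
            sub <- extractSubnetwork(togcns[[s]], catalog, validPathways())
            called <- callHubs(nodeDegrees(sub), hubCutoff, enzymeOnly = TRUE)
            planted <- truth@enzymes$gene[truth@enzymes$is_hub &
                                          truth@enzymes$species == s]
            tot <- tot + length(planted)
            got <- got + sum(planted %in% called)
        }
        if (tot) got / tot else NA_real_
    }

    c(edge_precision = precision, edge_recall = recall,
      level_accuracy = levelAcc, scope_accuracy = scopeAcc,
      hub_recovery = hubRec)
}

#' Run the full recovery pipeline on one simulated dataset
#'
#' Convenience wrapper used by the validation suite: simulate, filter
#' (pairwise DE + expressed-DEG rule with the seeds whitelisted), build both
#' species' TO-GCNs, compare, and score against truth.
#'
#' @param config a [SimulationConfig].
#' @param cutoff correlation cutoff.
#' @param runDE apply the DE filter (TRUE) or use all genes (FALSE).
#' @return list with `truth`, `togcns`, `comparative`, `metrics`.
#' @export
recoveryRun <- function(config, cutoff = 0.81, runDE = TRUE) {
    truth <- generateTruth(config)
    expr <- simulateExpression(truth, config)
    togcns <- lapply(1:2, function(s) {
        tcs <- expr[[s]]
        catalog <- makeGeneCatalog(truth, s)
        genes <- rownames(tcs)
        if (runDE) {
            de <- pairwiseDE(tcs)
            genes <- union(selectExpressedDEGs(tcs, de),
                           truth@seeds[[s]])
        }
        buildTOGCN(tcs, catalog, truth@seeds[[s]], genes = genes,
                   cutoff = cutoff)
    })
    names(togcns) <- truth@speciesIds
    comp <- compareTOGCNs(togcns[[1L]], togcns[[2L]], truth@orthologPairs,
                          species = truth@speciesIds)
    list(truth = truth, togcns = togcns, comparative = comp,
         metrics = evaluateRecovery(truth, togcns, comp))
}
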