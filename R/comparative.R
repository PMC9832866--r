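# For consensus networks node ids are "gene1|gene2"; catalog and pathway
# lookups use the species-1 component.
splitMerged <- function(ids, side = 1L)
    vapply(strsplit(ids, "|", fixed = TRUE), `[`, character(1), side)

#' Consensus network of two species' TO-GCNs ("C1+C2+" rule)
#'
#' Ortholog-paired nodes are merged into single nodes (`"id1|id2"`); a merged
#' edge exists iff the corresponding edge passes the correlation cutoff in
#' species 1 AND in species 2 (both networks are already thresholded at the
#' same cutoff, so this is the intersection of their edge sets under the
#' ortholog map).  Both correlations are stored (`r1`, `r2`); `r` carries
#' their minimum.  Merged node levels are recomputed by BFS from the merged
#' seed pair.
#'
#' @param togcn1,togcn2 [TOGCN] objects built at the same cutoff.
#' @param orthologMap data.frame `gene1`, `gene2` (1:1).
#' @return a [TOGCN] over merged nodes.
#' @export
consensusNetwork <- function(togcn1, togcn2, orthologMap) {
    if (!isTRUE(all.equal(togcn1@cutoff, togcn2@cutoff)))
        stopf("the two networks were built with different cutoffs")
    validateOrthologMap(orthologMap)
    to2 <- stats::setNames(orthologMap$gene2, orthologMap$gene1)
    e1 <- togcn1@edges
    e2 <- togcn2@edges
    key2 <- edgeKey(e2$a, e2$b)
    a2 <- unname(to2[e1$a]); b2 <- unname(to2[e1$b])
    mapped <- !is.na(a2) & !is.na(b2)
    hit <- match(edgeKey(a2, b2), key2)
    keep <- mapped & !is.na(hit)
    if (!any(keep)) {
        empty <- new("CoexpressionEdgeSet",
                     edges = data.frame(a = character(), b = character(),
                                        r = numeric(), a_is_tf = logical(),
                                        b_is_tf = logical()),
                     nodes = character(), tfNodes = character(),
                     cutoff = togcn1@cutoff, mode = "C1+C2+")
        return(new("TOGCN", edges = cbind(empty@edges,
                                          data.frame(r1 = numeric(),
                                                     r2 = numeric())),
                   levels = stats::setNames(integer(0), character(0)),
                   unleveled = character(), seed = NA_character_,
                   cutoff = togcn1@cutoff, profiles = matrix(numeric(0), 0, 0),
                   tfNodes = character(),
                   provenance = list(mode = "C1+C2+")))
    }
    mid <- function(g1) unname(paste(g1, to2[g1], sep = "|"))
    me <- data.frame(a = mid(e1$a[keep]), b = mid(e1$b[keep]),
                     r = pmin(e1$r[keep], e2$r[hit[keep]]),
                     a_is_tf = e1$a_is_tf[keep], b_is_tf = e1$b_is_tf[keep],
                     r1 = e1$r[keep], r2 = e2$r[hit[keep]],
                     stringsAsFactors = FALSE, row.names = NULL)
    me <- me[order(me$a, me$b), , drop = FALSE]
    rownames(me) <- NULL
    nodes <- union(me$a, me$b)
    tfn <- union(me$a[me$a_is_tf], me$b[me$b_is_tf])
    es <- new("CoexpressionEdgeSet", edges = me[, 1:5], nodes = nodes,
              tfNodes = tfn, cutoff = togcn1@cutoff, mode = "C1+C2+")
    seed1 <- togcn1@seed; seed2 <- togcn2@seed
    seedPair <- paste(seed1, to2[seed1], sep = "|")
    if (is.na(to2[seed1]) || !identical(unname(to2[seed1]), seed2))
        warnf("seeds are not ortholog-paired; leveling consensus from the species-1 seed image")
    if (!seedPair %in% nodes) {
        # seed pair absent from consensus: return unleveled network
        lm <- list(levels = stats::setNames(integer(0), character(0)),
                   unleveled = sort(intersect(tfn, nodes)),
                   seed = seedPair)
    } else {
        lm <- assignLevels(es, seedPair)
    }
    prof <- togcn1@profiles
    if (nrow(prof)) {
        g1 <- splitMerged(nodes, 1L)
        sel <- g1 %in% rownames(prof)
        prof <- prof[g1[sel], , drop = FALSE]
        rownames(prof) <- nodes[sel]
    }
    out <- attachTargets(es, lm, profiles = prof,
                         provenance = list(mode = "C1+C2+",
                                           cutoff = togcn1@cutoff))
    out@edges <- merge(out@edges, me[, c("a", "b", "r1", "r2")],
                       by = c("a", "b"), sort = TRUE)
    rownames(out@edges) <- NULL
    out
}

#' Species-specific networks by consensus subtraction
#'
#' The species-k specific edge set is the set of edges of that species'
#' TO-GCN whose ortholog image is absent from the consensus — including every
#' edge with at least one unmapped endpoint.  Together with the consensus
#' image this partitions each species' edges exactly.
#'
#' @param togcn1,togcn2 the species networks.
#' @param consensus result of [consensusNetwork()].
#' @param orthologMap the same ortholog map.
#' @return list of two [TOGCN] objects (`specific1`, `specific2`) carrying
#'   the parent networks' level maps restricted to the nodes involved.
#' @export
specificNetworks <- function(togcn1, togcn2, consensus, orthologMap) {
    consKey1 <- edgeKey(splitMerged(consensus@edges$a, 1L),
                        splitMerged(consensus@edges$b, 1L))
    consKey2 <- edgeKey(splitMerged(consensus@edges$a, 2L),
                        splitMerged(consensus@edges$b, 2L))
    strip <- function(togcn, consKey) {
        e <- togcn@edges
        keep <- !(edgeKey(e$a, e$b) %in% consKey)
        out <- togcn
        out@edges <- e[keep, , drop = FALSE]
        rownames(out@edges) <- NULL
        nodes <- union(out@edges$a, out@edges$b)
        out@levels <- togcn@levels[names(togcn@levels) %in% nodes]
        out@tfNodes <- intersect(togcn@tfNodes, nodes)
        out@provenance <- c(togcn@provenance, list(component = "specific"))
        out
    }
    list(specific1 = strip(togcn1, consKey1),
         specific2 = strip(togcn2, consKey2))
}

#' Map network levels onto flower-coloring stages
#'
#' By default a level's stage is data-driven: the z-scored mean log2
#' expression profiles of the level's genes are averaged and the stage is
#' decided by the argmax time point — T1/T2 initial, T3 transitional, T4/T5
#' terminal (5 time points required).  The fixed rule reproduces the
#' published level blocks verbatim: L1-L3 initial, L4 transitional, L5+
#' terminal.
#'
#' @param togcn a [TOGCN] with stored profiles (profile rule).
#' @param rule `"profile"` (default) or `"fixed"`.
#' @return data.frame (level, stage, peak) where `peak` is the argmax time
#'   point (NA under the fixed rule).
#' @export
stageMap <- function(togcn, rule = c("profile", "fixed")) {
    rule <- match.arg(rule)
    lv <- togcn@levels
    if (!length(lv)) return(data.frame(level = integer(), stage = character(),
                                       peak = integer()))
    lvs <- sort(unique(as.integer(lv)))
    if (rule == "fixed") {
        stage <- ifelse(lvs <= 3L, "initial",
                        ifelse(lvs == 4L, "transitional", "terminal"))
        return(data.frame(level = lvs, stage = stage, peak = NA_integer_,
                          stringsAsFactors = FALSE))
    }
    prof <- togcn@profiles
    if (ncol(prof) != 5L)
        stopf("the profile stage rule requires 5 time points (got %d)",
              ncol(prof))
    peak <- vapply(lvs, function(l) {
        g <- intersect(names(lv)[lv == l], rownames(prof))
        if (!length(g))
            stopf("level %d has no expression profiles", l)
        m <- prof[g, , drop = FALSE]
        sdv <- apply(m, 1L, stats::sd)
        z <- (m - rowMeans(m)) / ifelse(sdv == 0, 1, sdv)
        which.max(colMeans(z))
    }, integer(1))
    stage <- ifelse(peak <= 2L, "initial",
                    ifelse(peak == 3L, "transitional", "terminal"))
    data.frame(level = lvs, stage = stage, peak = peak,
               stringsAsFactors = FALSE)
}

#' Extract a stage/pathway subnetwork
#'
#' Nodes are the enzymatic genes of the requested pathways whose level falls
#' in the requested stage, plus (optionally) every TF adjacent to them in the
#' network.  Edges are restricted to TF-enzyme and TF-TF pairs among the
#' included nodes (enzyme-enzyme edges cannot occur by construction).
#'
#' @param togcn a [TOGCN] (species-specific, consensus, or full).
#' @param catalog the species' [GeneCatalog] (consensus node ids are matched
#'   on their species-1 component).
#' @param pathways character: subset of carotenoid, chlorophyll, anthocyanin,
#'   flavonol.
#' @param stage optional stage label (initial/transitional/terminal) used to
#'   filter enzyme levels via `stages`.
#' @param stages optional stage table from [stageMap()]; computed with the
#'   profile rule when needed and missing.
#' @param includeRegulatingTFs include TFs adjacent to the selected enzymes
#'   (default TRUE).
#' @return a [TOGCN] restricted to the subnetwork (possibly empty).
#' @export
extractSubnetwork <- function(togcn, catalog, pathways, stage = NULL,
                              stages = NULL, includeRegulatingTFs = TRUE) {
    pw <- pathwayGenes(catalog, pathways)
    lv <- togcn@levels
    nodes1 <- splitMerged(names(lv), 1L)
    enz <- names(lv)[nodes1 %in% pw & !(names(lv) %in% togcn@tfNodes)]
    if (!is.null(stage)) {
        if (is.null(stages)) stages <- stageMap(togcn)
        okLv <- stages$level[stages$stage == stage]
        enz <- enz[lv[enz] %in% okLv]
    }
    e <- togcn@edges
    if (includeRegulatingTFs) {
        tfs <- unique(c(e$a[e$b %in% enz], e$b[e$b_is_tf & e$a %in% enz]))
        keepNodes <- union(enz, tfs)
        keep <- (e$a %in% keepNodes) & (e$b %in% keepNodes) &
            (e$a_is_tf | e$b_is_tf)
    } else {
        keepNodes <- enz
        keep <- (e$a %in% enz) & (e$b %in% enz)
    }
    out <- togcn
    out@edges <- e[keep, , drop = FALSE]
    rownames(out@edges) <- NULL
    out@levels <- lv[names(lv) %in% keepNodes]
    out@tfNodes <- intersect(togcn@tfNodes, keepNodes)
    out@profiles <- togcn@profiles[intersect(rownames(togcn@profiles),
                                             keepNodes), , drop = FALSE]
    out@provenance <- c(togcn@provenance,
                        list(subnetwork = list(pathways = pathways,
                                               stage = stage)))
    if (!length(out@levels))
        message("empty subnetwork: no enzymatic genes match pathway/stage")
    out
}

#' Node degrees of a (sub)network
#'
#' The degree of a node is the number of edges incident to it within the
#' given network.
#'
#' @param togcn a [TOGCN].
#' @return data.frame (node, degree, is_tf, level), including degree-0 nodes.
#' @export
nodeDegrees <- function(togcn) {
    nodes <- names(togcn@levels)
    deg <- table(factor(c(togcn@edges$a, togcn@edges$b), levels = nodes))
    data.frame(node = nodes, degree = as.integer(deg),
               is_tf = nodes %in% togcn@tfNodes,
               level = as.integer(togcn@levels),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Call hub genes by degree
#'
#' @param degrees degree table from [nodeDegrees()].
#' @param cutoff inclusive degree cutoff (>= 0); e.g. 40 for the carotenoid/
#'   chlorophyll subnetworks, 25 for anthocyanin in the original analyses.
#' @param tfOnly,enzymeOnly optionally restrict the candidate set.
#' @return character vector of hub gene ids.
#' @export
callHubs <- function(degrees, cutoff, tfOnly = FALSE, enzymeOnly = FALSE) {
    if (cutoff < 0) stopf("degree cutoff must be >= 0")
    d <- degrees
    if (tfOnly) d <- d[d$is_tf, , drop = FALSE]
    if (enzymeOnly) d <- d[!d$is_tf, , drop = FALSE]
    sort(d$node[d$degree >= cutoff])
}

#' Resolve the hierarchical regulator chain upstream of a hub gene
#'
#' Tier 1 ("direct regulators") comprises the TF neighbours of the hub at a
#' level not exceeding the hub's; each subsequent tier comprises TF
#' neighbours of the previous tier at a strictly lower level than their
#' partner, excluding genes already placed — encoding the time-ordered
#' direction of regulation (ties in level are allowed only at tier 1).
#'
#' @param togcn a [TOGCN].
#' @param hub hub gene id (must be a network node).
#' @param maxTiers number of tiers to resolve (default 3: direct, second,
#'   third regulators).
#' @return a [RegulatorChain].
#' @export
resolveHierarchy <- function(togcn, hub, maxTiers = 3L) {
    lv <- togcn@levels
    if (!hub %in% names(lv)) stopf("hub '%s' is not a network node", hub)
    e <- togcn@edges
    tfE <- e[e$a_is_tf | e$b_is_tf, , drop = FALSE]
    neighbours <- function(n) {
        tf <- c(tfE$a[tfE$b == n], tfE$b[tfE$a == n & tfE$b_is_tf])
        tf <- tf[tf %in% togcn@tfNodes]
        data.frame(partner = rep(n, length(tf)), tf = tf,
                   stringsAsFactors = FALSE)
    }
    tiers <- list()
    placed <- hub
    sup <- data.frame(tier = integer(), tf = character(),
                      partner = character(), stringsAsFactors = FALSE)
    cur <- data.frame(tf = hub, stringsAsFactors = FALSE)
    for (t in seq_len(maxTiers)) {
        tiers[[t]] <- character(0)
        cand <- do.call(rbind, lapply(unique(cur$tf), neighbours))
        if (is.null(cand) || !nrow(cand)) next
        ok <- if (t == 1L) lv[cand$tf] <= lv[[hub]]
              else lv[cand$tf] < lv[cand$partner]
        cand <- cand[ok & !(cand$tf %in% placed), , drop = FALSE]
        members <- sort(unique(cand$tf))
        tiers[[t]] <- members
        if (nrow(cand))
            sup <- rbind(sup, data.frame(tier = t, tf = cand$tf,
                                         partner = cand$partner,
                                         stringsAsFactors = FALSE))
        placed <- c(placed, members)
        if (!length(members)) break
        cur <- data.frame(tf = members, stringsAsFactors = FALSE)
    }
    tiers <- c(tiers, rep(list(character(0)), maxTiers - length(tiers)))
    names(tiers) <- c("direct", "second", "third",
                      paste0("tier", seq_len(max(0, maxTiers - 3L)) + 3L))[
                          seq_len(maxTiers)]
    new("RegulatorChain", hub = hub, tiers = tiers,
        levels = stats::setNames(as.integer(lv[unique(c(hub, unlist(tiers)))]),
                                 unique(c(hub, unlist(tiers)))),
        supportingEdges = sup)
}

setMethod("show", "RegulatorChain", function(object) {
    cat("RegulatorChain for hub", object@hub, "\n")
    for (nm in names(object@tiers))
        cat(" ", nm, ":", length(object@tiers[[nm]]), "TFs\n")
})

#' @rdname resolveHierarchy
#' @param chain a [RegulatorChain].
#' @export
chainTable <- function(chain) {
    do.call(rbind, lapply(seq_along(chain@tiers), function(t) {
        tfs <- chain@tiers[[t]]
        if (!length(tfs)) return(NULL)
        data.frame(hub = chain@hub, tier = t, tf = tfs,
                   level = as.integer(chain@levels[tfs]),
                   stringsAsFactors = FALSE)
    }))
}

#' Compare two species' TO-GCNs
#'
#' Runs [consensusNetwork()] and [specificNetworks()] and labels every
#' network's levels with coloring stages.
#'
#' @param togcn1,togcn2 the species networks.
#' @param orthologMap 1:1 ortholog pairs.
#' @param species character(2) labels.
#' @param stageRule passed to [stageMap()].
#' @return a [ComparativeTOGCN].
#' @export
compareTOGCNs <- function(togcn1, togcn2, orthologMap,
                          species = c("species1", "species2"),
                          stageRule = "profile") {
    species <- unname(species)
    cons <- consensusNetwork(togcn1, togcn2, orthologMap)
    spec <- specificNetworks(togcn1, togcn2, cons, orthologMap)
    stageOf <- function(net, label) {
        if (!length(net@levels))
            return(NULL)
        s <- stageMap(net, rule = stageRule)
        cbind(network = label, s)
    }
    stages <- do.call(rbind, list(stageOf(cons, "consensus"),
                                  stageOf(spec$specific1, species[1L]),
                                  stageOf(spec$specific2, species[2L])))
    if (is.null(stages))
        stages <- data.frame(network = character(), level = integer(),
                             stage = character(), peak = integer())
    new("ComparativeTOGCN", species = species, consensus = cons,
        specific1 = spec$specific1, specific2 = spec$specific2,
        orthologMap = orthologMap, stages = stages,
        provenance = list(cutoff = togcn1@cutoff, stageRule = stageRule))
}

setMethod("show", "ComparativeTOGCN", function(object) {
    cat("ComparativeTOGCN (", paste(object@species, collapse = " vs "), ")\n")
    cat("  consensus:", nrow(object@consensus@edges), "edges /",
        length(object@consensus@levels), "merged nodes\n")
    cat("  ", object@species[1L], "-specific:",
        nrow(object@specific1@edges), "edges\n")
    cat("  ", object@species[2L], "-specific:",
        nrow(object@specific2@edges), "edges\n")
})
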