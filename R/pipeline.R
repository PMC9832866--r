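#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML file with two species blocks (`counts`,
#' `catalog`, optional `fasta`/`gff`/`motifs`), an `orthologs` path, a
#' `seeds` block (gene ids, or `auto` for monotone-decrease selection), an
#' optional `thresholds` block and an `outdir`.  All validation problems are
#' reported at once.  Defaults: r cutoff 0.81, |log2FC| cutoff 1, FDR 0.05,
#' mean TPM floor 0.5, hub degree cutoff 40, motif p cutoff 1e-4, upstream
#' length 2000, sample mode "means".
#'
#' @param path YAML configuration file.
#' @return validated configuration list (class `togcnRunConfig`).
#' @export
loadRunConfig <- function(path) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    defaults <- list(cutoff = 0.81, lfcCutoff = 1, fdrCutoff = 0.05,
                     minMeanTPM = 0.5, hubCutoff = 40, pCutoff = 1e-4,
                     upstreamLength = 2000, sampleMode = "means",
                     stageRule = "profile")
    th <- utils::modifyList(defaults, cfg$thresholds %||% list())
    problems <- character(0)
    need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
    resolve <- function(p) {
        if (is.null(p)) return(NULL)
        if (file.exists(p)) return(normalizePath(p))
        p2 <- file.path(base, p)
        if (file.exists(p2)) return(normalizePath(p2))
        problems <<- c(problems, paste("missing file:", p))
        p
    }
    species <- list()
    for (k in c("species1", "species2")) {
        blk <- cfg[[k]]
        need(!is.null(blk), paste(k, "block is required"))
        if (is.null(blk)) next
        species[[k]] <- list(
            name = blk$name %||% k,
            counts = resolve(blk$counts),
            catalog = resolve(blk$catalog),
            fasta = resolve(blk$fasta),
            gff = resolve(blk$gff))
        need(!is.null(blk$counts), paste(k, "needs a counts path"))
        need(!is.null(blk$catalog), paste(k, "needs a catalog path"))
    }
    orthologs <- resolve(cfg$orthologs)
    need(!is.null(cfg$orthologs), "an orthologs path is required")
    motifs <- resolve(cfg$motifs)
    need(th$cutoff > 0 && th$cutoff <= 1,
         sprintf("r cutoff %g outside (0, 1]", th$cutoff))
    need(th$fdrCutoff > 0 && th$fdrCutoff < 1, "FDR cutoff outside (0, 1)")
    need(th$lfcCutoff >= 0, "log2FC cutoff must be >= 0")
    need(th$pCutoff > 0 && th$pCutoff < 1, "motif p cutoff outside (0, 1)")
    need(th$minMeanTPM >= 0, "minMeanTPM must be >= 0")
    need(th$hubCutoff >= 0, "hub cutoff must be >= 0")
    need(th$sampleMode %in% c("means", "replicates"), "bad sampleMode")
    seeds <- cfg$seeds %||% list(species1 = "auto", species2 = "auto")
    need(!is.null(cfg$outdir), "an outdir is required")
    if (length(problems))
        stopf("invalid configuration:\n  - %s",
              paste(problems, collapse = "\n  - "))
    out <- list(species = species, orthologs = orthologs, motifs = motifs,
                thresholds = th, seeds = seeds,
                outdir = cfg$outdir, seed = cfg$seed %||% 1L,
                force = isTRUE(cfg$force))
    class(out) <- "togcnRunConfig"
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparative TO-GCN pipeline
#'
#' Executes DE filtering, per-species TO-GCN construction, the comparative
#' consensus/specific decomposition, stage mapping, all-pathway subnetwork
#' extraction with hub calling and regulator-chain resolution, and (when
#' genome + annotation + motifs are configured) motif-based edge
#' confirmation.  All tables are written under `outdir` together with a
#' machine-readable `summary.json` and a checksum manifest; an existing
#' output directory is only overwritten with `force`.
#'
#' @param config a `togcnRunConfig` from [loadRunConfig()], or a path to one.
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- loadRunConfig(config)
    th <- config$thresholds
    outdir <- config$outdir
    if (file.exists(file.path(outdir, "summary.json")) && !config$force)
        stopf("output in '%s' exists; set force: true to overwrite", outdir)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    put <- function(p) { paths <<- c(paths, file.path(outdir, p));
                         file.path(outdir, p) }

    stage <- "input"
    res <- tryCatch({
        catalogs <- lapply(config$species, function(s)
            readGeneCatalog(s$catalog))
        datasets <- lapply(seq_along(config$species), function(i) {
            s <- config$species[[i]]
            lens <- stats::setNames(
                as.numeric(catalogs[[i]]@data$length),
                catalogs[[i]]@data$gene_id)
            readExpression(s$counts, geneLength = lens)
        })
        orthomap <- readOrthologMap(config$orthologs)
        spNames <- vapply(config$species, `[[`, character(1), "name")

        stage <- "expression_prep"
        universes <- list(); seeds <- character(2); deResults <- list()
        for (i in 1:2) {
            de <- pairwiseDE(datasets[[i]], lfcCutoff = th$lfcCutoff,
                             fdrCutoff = th$fdrCutoff)
            deResults[[i]] <- de
            expressed <- selectExpressedDEGs(datasets[[i]], de,
                                             minMeanTPM = th$minMeanTPM)
            sd <- config$seeds[[paste0("species", i)]] %||% "auto"
            if (identical(sd, "auto")) {
                cand <- selectSeedTFs(datasets[[i]],
                                      intersect(rownames(datasets[[i]]),
                                                tfGenes(catalogs[[i]])))
                cand <- cand[cand$eligible, , drop = FALSE]
                if (!nrow(cand))
                    stopf("no monotone-decreasing seed TF found for %s",
                          spNames[i])
                sd <- cand$gene[1L]
            }
            seeds[i] <- sd
            universes[[i]] <- union(expressed, sd)
            writeDETable(de, put(sprintf("%s_de.tsv", spNames[i])))
            writeLines(expressed,
                       put(sprintf("%s_expressed_degs.txt", spNames[i])))
        }

        stage <- "togcn"
        togcns <- lapply(1:2, function(i)
            buildTOGCN(datasets[[i]], catalogs[[i]], seeds[i],
                       genes = universes[[i]], cutoff = th$cutoff,
                       sampleMode = th$sampleMode))
        for (i in 1:2) {
            writeEdgeTable(togcns[[i]],
                           put(sprintf("%s_edges.tsv", spNames[i])))
            writeLevelTable(togcns[[i]],
                            put(sprintf("%s_levels.tsv", spNames[i])))
            exportNodeLink(togcns[[i]],
                           put(sprintf("%s_network.json", spNames[i])))
        }

        stage <- "comparative"
        comp <- compareTOGCNs(togcns[[1L]], togcns[[2L]], orthomap,
                              species = spNames, stageRule = th$stageRule)
        writeEdgeTable(comp@consensus, put("consensus_edges.tsv"))
        writeLevelTable(comp@consensus, put("consensus_levels.tsv"))
        writeEdgeTable(comp@specific1,
                       put(sprintf("%s_specific_edges.tsv", spNames[1L])))
        writeEdgeTable(comp@specific2,
                       put(sprintf("%s_specific_edges.tsv", spNames[2L])))
        writeTSV(comp@stages, put("stages.tsv"))

        stage <- "subnetworks"
        hubs <- list(); chains <- list()
        for (i in 1:2) {
            net <- if (i == 1L) comp@specific1 else comp@specific2
            sub <- extractSubnetwork(net, catalogs[[i]], validPathways())
            deg <- nodeDegrees(sub)
            writeTSV(deg, put(sprintf("%s_subnet_degrees.tsv", spNames[i])))
            hb <- callHubs(deg, th$hubCutoff, enzymeOnly = TRUE)
            hubs[[spNames[i]]] <- hb
            writeLines(hb, put(sprintf("%s_hubs.txt", spNames[i])))
            ch <- do.call(rbind, lapply(hb, function(h)
                chainTable(resolveHierarchy(sub, h))))
            if (!is.null(ch) && nrow(ch)) {
                chains[[spNames[i]]] <- ch
                writeTSV(ch, put(sprintf("%s_chains.tsv", spNames[i])))
            }
        }

        stage <- "motif_scan"
        confirmed <- NULL
        haveMotifs <- !is.null(config$motifs) &&
            all(vapply(config$species, function(s)
                !is.null(s$fasta) && !is.null(s$gff), logical(1)))
        if (haveMotifs) {
            motifs <- readMEME(config$motifs)
            motifIds <- vapply(motifs, function(m) m@id, character(1))
            for (i in 1:2) {
                ups <- extractUpstream(config$species[[i]]$fasta,
                                       config$species[[i]]$gff,
                                       length = th$upstreamLength)
                hits <- scanMotifs(motifs, ups, pCutoff = th$pCutoff)
                writeTSV(hits, put(sprintf("%s_tfbs_hits.tsv", spNames[i])))
                fams <- tfFamilies(catalogs[[i]])
                map <- stats::setNames(
                    motifIds[match(paste0("MOTIF_", fams), motifIds)],
                    names(fams))
                map <- map[!is.na(map)]
                net <- if (i == 1L) comp@specific1 else comp@specific2
                e <- net@edges
                te <- e[!e$b_is_tf, c("a", "b"), drop = FALSE]
                names(te) <- c("regulator", "target")
                ce <- confirmEdges(te, hits, map)
                writeTSV(ce, put(sprintf("%s_confirmed_edges.tsv",
                                         spNames[i])))
                confirmed <- c(confirmed,
                               stats::setNames(list(table(ce$status)),
                                               spNames[i]))
            }
        }

        summary <- list(
            species = as.list(stats::setNames(lapply(1:2, function(i) list(
                genes = nrow(datasets[[i]]),
                expressed_degs = length(universes[[i]]),
                seed = seeds[i],
                nodes = length(togcns[[i]]@levels),
                edges = nrow(togcns[[i]]@edges),
                levels = max(togcns[[i]]@levels[
                    names(togcns[[i]]@levels) %in% togcns[[i]]@tfNodes]),
                hubs = length(hubs[[spNames[i]]]))), spNames)),
            consensus = list(nodes = length(comp@consensus@levels),
                             edges = nrow(comp@consensus@edges)),
            specific = list(nrow(comp@specific1@edges),
                            nrow(comp@specific2@edges)),
            thresholds = th)
        jsonlite::write_json(summary, put("summary.json"),
                             auto_unbox = TRUE, digits = NA)
        sums <- tools::md5sum(paths)
        writeTSV(data.frame(file = basename(names(sums)),
                            md5 = unname(sums), stringsAsFactors = FALSE),
                 file.path(outdir, "MANIFEST.tsv"))
        list(summary = summary, togcns = togcns, comparative = comp,
             hubs = hubs, chains = chains, confirmed = confirmed)
    }, error = function(e) {
        stopf("pipeline failed at stage '%s': %s (partial outputs kept in %s)",
              stage, conditionMessage(e), outdir)
    })
    invisible(res)
}
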