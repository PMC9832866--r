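#' Synthetic family motifs for the planted regulome
#'
#' One information-rich motif per TF family (width 10, consensus probability
#' 0.955 per position), so the consensus word's exact p-value is far below
#' 1e-6 and planted sites are unambiguously recoverable.
#'
#' @param truth a [TruthRegulome].
#' @param width motif width.
#' @return named list of [MotifModel] (names = motif ids).
#' @export
syntheticMotifs <- function(truth, width = 10L) {
    withSeed(childSeed(truth@config@seed, 4L), {
        out <- list()
        for (famName in names(truth@motifAssignment)) {
            id <- truth@motifAssignment[[famName]]
            cons <- sample(1:4, width, replace = TRUE)
            m <- matrix(0.015, 4L, width)
            m[cbind(cons, seq_len(width))] <- 0.955
            out[[id]] <- motifModel(id, m, pseudocount = 0)
        }
        out
    })
}

#' Simulate promoters with planted binding sites
#'
#' Every gene receives an i.i.d. uniform-ACGT promoter of
#' `config@promoterLength` bp.  For each planted regulator->target edge the
#' consensus of the regulator family's motif is inserted at a recorded
#' offset and strand with probability `config@motifPlantProb` (insertions
#' within one promoter never overlap).  A per-gene contig genome and gene
#' annotation are also built (alternating gene strands), so that
#' [extractUpstream()] recovers exactly the simulated promoters.
#'
#' @param truth a [TruthRegulome].
#' @param config the [SimulationConfig] (defaults to `truth@config`).
#' @return list with `motifs` and, per species, `promoters` (DNAStringSet),
#'   `genome` (DNAStringSet), `genes` (GRanges), `trueHits` (data.frame
#'   gene, motif, start 0-based, strand).
#' @export
simulatePromoters <- function(truth, config = truth@config) {
    if (!length(truth@motifAssignment)) stopf("no motif assignment in truth")
    motifs <- syntheticMotifs(truth)
    wmax <- max(vapply(motifs, motifWidth, integer(1)))
    if (config@promoterLength < wmax)
        stopf("promoterLength (%d) is smaller than the motif width (%d)",
              config@promoterLength, wmax)
    famOfTF <- function(catalog) tfFamilies(catalog)
    withSeed(childSeed(config@seed, 5L), {
        out <- list(motifs = motifs)
        for (s in 1:2) {
            spId <- truth@speciesIds[s]
            catalog <- makeGeneCatalog(truth, s)
            fams <- famOfTF(catalog)
            genes <- rownames(truth@latentProfiles[[s]])
            L <- config@promoterLength
            prom <- vapply(genes, function(g)
                paste(sample(.baseOrder, L, replace = TRUE), collapse = ""),
                character(1))
            occupied <- stats::setNames(
                rep(list(integer(0)), length(genes)), genes)
            ed <- truth@edges[truth@edges$species == s, , drop = FALSE]
            hits <- list()
            for (i in seq_len(nrow(ed))) {
                if (stats::runif(1) > config@motifPlantProb) next
                fam <- fams[[ed$regulator[i]]]
                if (is.null(fam) || is.na(fam)) next
                mid <- truth@motifAssignment[[fam]]
                cons <- motifConsensus(motifs[[mid]])
                w <- nchar(cons)
                g <- ed$target[i]
                pos <- NA_integer_
                for (try in 1:50) {
                    cand <- sample.int(L - w + 1L, 1L) - 1L  # 0-based
                    if (!any(abs(occupied[[g]] - cand) < w)) {
                        pos <- cand; break
                    }
                }
                if (is.na(pos)) next
                strand <- sample(c("+", "-"), 1L)
                word <- if (strand == "+") cons else
                    as.character(reverseComplement(DNAStringSet(cons)[[1L]]))
                substr(prom[[g]], pos + 1L, pos + w) <- word
                occupied[[g]] <- c(occupied[[g]], pos)
                hits[[length(hits) + 1L]] <- data.frame(
                    gene = g, motif = mid, start = pos, strand = strand,
                    stringsAsFactors = FALSE)
            }
            trueHits <- if (length(hits)) do.call(rbind, hits) else
                data.frame(gene = character(), motif = character(),
                           start = integer(), strand = character(),
                           stringsAsFactors = FALSE)
            # per-gene contigs; alternate gene strands
            bodyLen <- 300L
            body <- vapply(genes, function(g)
                paste(sample(.baseOrder, bodyLen, replace = TRUE),
                      collapse = ""), character(1))
            fwd <- seq_along(genes) %% 2L == 1L
            contig <- character(length(genes))
            gstart <- integer(length(genes)); gend <- integer(length(genes))
            for (i in seq_along(genes)) {
                if (fwd[i]) {
                    contig[i] <- paste0(prom[[i]], body[[i]])
                    gstart[i] <- L + 1L; gend[i] <- L + bodyLen
                } else {
                    rcProm <- as.character(
                        reverseComplement(DNAStringSet(prom[[i]])[[1L]]))
                    contig[i] <- paste0(body[[i]], rcProm)
                    gstart[i] <- 1L; gend[i] <- bodyLen
                }
            }
            ctgNames <- paste0(genes, "_ctg")
            genome <- DNAStringSet(stats::setNames(contig, ctgNames))
            gr <- GenomicRanges::GRanges(
                seqnames = ctgNames,
                ranges = IRanges::IRanges(start = gstart, end = gend),
                strand = ifelse(fwd, "+", "-"))
            gr$type <- "gene"
            gr$ID <- genes
            out[[spId]] <- list(
                promoters = DNAStringSet(stats::setNames(unlist(prom), genes)),
                genome = genome, genes = gr, trueHits = trueHits)
        }
        out
    })
}

#' Write a synthetic dataset to disk
#'
#' Writes, per species, the counts and TPM TSVs (T<i>_R<j> headers), gene
#' catalog, promoter FASTA, genome FASTA, gene GFF3 and true-hit table; plus
#' the ortholog map, the planted-edge and TF-level truth tables, the motif
#' file (MEME minimal format) and a checksum manifest.
#'
#' @param truth a [TruthRegulome].
#' @param expr result of [simulateExpression()].
#' @param prom optional result of [simulatePromoters()].
#' @param dir output directory (created; must not already contain a manifest
#'   unless `force = TRUE`).
#' @param force overwrite existing outputs.
#' @return the directory, invisibly.
#' @export
writeSyntheticData <- function(truth, expr, prom = NULL, dir, force = FALSE) {
    if (file.exists(file.path(dir, "MANIFEST.tsv")) && !force)
        stopf("output in '%s' exists; use force = TRUE to overwrite", dir)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    put <- function(p) { paths <<- c(paths, p); p }
    for (s in 1:2) {
        spId <- truth@speciesIds[s]
        writeExpression(expr[[spId]],
                        put(file.path(dir, paste0(spId, "_counts.tsv"))),
                        what = "counts")
        writeExpression(expr[[spId]],
                        put(file.path(dir, paste0(spId, "_tpm.tsv"))),
                        what = "tpm")
        writeGeneCatalog(makeGeneCatalog(truth, s),
                         put(file.path(dir, paste0(spId, "_catalog.tsv"))))
        if (!is.null(prom)) {
            pr <- prom[[spId]]
            writeXStringSet(pr$promoters,
                put(file.path(dir, paste0(spId, "_promoters.fa"))))
            writeXStringSet(pr$genome,
                put(file.path(dir, paste0(spId, "_genome.fa"))))
            rtracklayer::export(pr$genes,
                put(file.path(dir, paste0(spId, "_genes.gff3"))),
                format = "gff3")
            writeTSV(pr$trueHits,
                put(file.path(dir, paste0(spId, "_true_hits.tsv"))))
        }
    }
    writeOrthologMap(truth@orthologPairs,
                     put(file.path(dir, "orthologs.tsv")))
    writeTSV(truth@edges, put(file.path(dir, "truth_edges.tsv")))
    lvTab <- do.call(rbind, lapply(1:2, function(s) data.frame(
        species = truth@speciesIds[s],
        gene = names(truth@tfLevels[[s]]),
        level = as.integer(truth@tfLevels[[s]]),
        stringsAsFactors = FALSE)))
    writeTSV(lvTab, put(file.path(dir, "truth_tf_levels.tsv")))
    writeTSV(truth@enzymes, put(file.path(dir, "truth_enzymes.tsv")))
    if (!is.null(prom))
        writeMEME(prom$motifs, put(file.path(dir, "motifs.meme")))
    sums <- tools::md5sum(paths)
    writeTSV(data.frame(file = basename(names(sums)), md5 = unname(sums),
                        stringsAsFactors = FALSE),
             file.path(dir, "MANIFEST.tsv"))
    invisible(dir)
}
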