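#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   colData rowData
#' @importFrom BiocGenerics counts
NULL

#' Time-course expression dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a genes x samples
#' count matrix (assay `"counts"`) and, usually, a TPM matrix (assay `"tpm"`)
#' for a replicated time-course design.  `colData` carries integer columns
#' `timePoint` (1..D) and `replicate` (1..R); `rowData` carries `geneLength`
#' (effective length in bp, used for TPM).
#'
#' Sample names follow the `T<i>_R<j>` convention used by the on-disk TSV
#' format (see [readExpression()]).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [TimeCourseSet()], [computeTPM()], [pairwiseDE()]
#' @export
setClass("TimeCourseSet", contains = "SummarizedExperiment")

setValidity("TimeCourseSet", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- colData(object)
    if (!all(c("timePoint", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'timePoint' and 'replicate'")
    else {
        tp <- cd$timePoint
        if (any(is.na(tp)) || any(tp < 1L))
            msg <- c(msg, "timePoint indices must be positive integers")
        if (length(unique(tp)) < 2L)
            msg <- c(msg, "at least two time points are required")
    }
    if ("counts" %in% assayNames(object)) {
        cnt <- assay(object, "counts")
        if (any(cnt < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Gene catalog: TF and pathway annotation consumed by the network stages
#'
#' Per-gene labels: whether the gene encodes a transcription factor, its TF
#' family (e.g. bHLH, WRKY, ERF, B3, MYB_related), membership in a
#' pigment-biosynthesis pathway (carotenoid, chlorophyll, anthocyanin,
#' flavonol, or none), and effective gene length in bp.  The catalog is an
#' input; the package never predicts TF families or pathway membership.
#'
#' @slot data a `DataFrame` with columns `gene_id`, `is_tf`, `tf_family`,
#'   `pathway`, `length`.
#' @export
setClass("GeneCatalog", representation(data = "DataFrame"))

setValidity("GeneCatalog", function(object) {
    d <- object@data
    need <- c("gene_id", "is_tf", "tf_family", "pathway", "length")
    if (!all(need %in% colnames(d)))
        return(paste("catalog needs columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(d$gene_id)) return("duplicate gene ids in catalog")
    if (any(d$length <= 0)) return("gene lengths must be positive")
    bad <- setdiff(unique(d$pathway), c(validPathways(), "none"))
    if (length(bad))
        return(paste("unknown pathway label(s):", paste(bad, collapse = ", ")))
    TRUE
})

#' Co-expression edge set between TFs and coding genes
#'
#' Undirected edges kept at correlation at or above the cutoff (inclusive).  Following the TO-GCN
#' construction, correlations are only computed between TF genes and all
#' coding genes, so every edge has at least one TF endpoint; edges between two
#' non-TF genes never occur.
#'
#' @slot edges data.frame with columns `a`, `b`, `r`, `a_is_tf`, `b_is_tf`
#'   (node `a` is always a TF; for TF-TF edges `a < b` lexicographically).
#' @slot nodes character vector of all node ids in the underlying universe.
#' @slot tfNodes character vector of TF node ids.
#' @slot cutoff correlation cutoff used (inclusive).
#' @slot mode label recording the correlation mode ("C1+" style single-condition).
#' @export
setClass("CoexpressionEdgeSet", representation(
    edges = "data.frame", nodes = "character", tfNodes = "character",
    cutoff = "numeric", mode = "character"))

setValidity("CoexpressionEdgeSet", function(object) {
    e <- object@edges
    need <- c("a", "b", "r", "a_is_tf", "b_is_tf")
    if (!all(need %in% colnames(e)))
        return(paste("edge table needs columns:", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$r < object@cutoff)) return("edge with r below cutoff")
        if (any(e$a == e$b)) return("self-edges are not allowed")
        if (!all(e$a_is_tf)) return("first endpoint of every edge must be a TF")
    }
    if (object@cutoff <= 0 || object@cutoff > 1)
        return("cutoff must be in (0, 1]")
    TRUE
})

#' Time-ordered gene co-expression network
#'
#' A co-expression network whose TF nodes carry levels L1..Lk assigned by
#' breadth-first search from a seed TF over TF-TF edges; non-TF target genes
#' are attached afterwards at the minimum level of their leveled TF
#' neighbours.  Network depth is a proxy for the temporal order of regulatory
#' activation.
#'
#' @slot edges edge table as in [CoexpressionEdgeSet] (consensus networks add
#'   `r1`/`r2` columns carrying the two species' correlations).
#' @slot levels named integer vector: node id -> level (>= 1).
#' @slot unleveled character vector of nodes unreachable from the seed.
#' @slot seed seed TF id (level 1 root).
#' @slot cutoff correlation cutoff.
#' @slot profiles matrix (nodes x time points) of mean log2(TPM+1) profiles.
#' @slot tfNodes character: which nodes are TFs.
#' @slot provenance list of run parameters (cutoff, sampleMode, transform,
#'   gene counts).
#' @export
setClass("TOGCN", representation(
    edges = "data.frame", levels = "integer", unleveled = "character",
    seed = "character", cutoff = "numeric", profiles = "matrix",
    tfNodes = "character", provenance = "list"))

setValidity("TOGCN", function(object) {
    lv <- object@levels
    if (length(lv)) {
        if (is.null(names(lv))) return("levels must be named by node id")
        if (any(lv < 1L)) return("levels must be >= 1")
        if (length(object@seed) == 1L && !is.na(object@seed) &&
            object@seed %in% names(lv) && lv[[object@seed]] != 1L)
            return("seed must carry level 1")
        tflv <- lv[names(lv) %in% object@tfNodes]
        if (length(tflv) && !identical(sort(unique(as.integer(tflv))),
                                       seq_len(max(tflv))))
            return("TF levels must form a contiguous range starting at 1")
    }
    TRUE
})

#' Comparative decomposition of two species' TO-GCNs
#'
#' Holds the consensus network (nodes are merged ortholog pairs; an edge
#' requires r >= cutoff in both species, the "C1+C2+" rule), the two
#' species-specific networks (edges whose ortholog image is absent from the
#' consensus, including edges with unmapped endpoints), the ortholog map, and
#' stage labels per level.
#'
#' @slot species character(2), species labels.
#' @slot consensus a [TOGCN] over merged nodes ("id1|id2"), edge table with
#'   `r1` and `r2`.
#' @slot specific1,specific2 [TOGCN] objects restricted to species-specific edges.
#' @slot orthologMap data.frame with columns `gene1`, `gene2` (1:1).
#' @slot stages data.frame (network, level, stage) with stage in
#'   initial/transitional/terminal.
#' @slot provenance list.
#' @export
setClass("ComparativeTOGCN", representation(
    species = "character", consensus = "TOGCN",
    specific1 = "TOGCN", specific2 = "TOGCN",
    orthologMap = "data.frame", stages = "data.frame", provenance = "list"))

#' Hierarchical regulator chain upstream of a hub gene
#'
#' @slot hub hub gene id.
#' @slot tiers list of character vectors: direct, second, third (... up to
#'   `maxTiers`) regulators.
#' @slot levels named integer vector of network levels for chain members.
#' @slot supportingEdges data.frame of the network edges supporting each tier
#'   link.
#' @export
setClass("RegulatorChain", representation(
    hub = "character", tiers = "list", levels = "integer",
    supportingEdges = "data.frame"))

#' Position weight matrix with exact score distribution
#'
#' A probability matrix over A/C/G/T per position together with a background
#' distribution and a pseudocount.  Scores are integer-discretized log-odds
#' (natural log, `granularity` units per nat); the exact null distribution of
#' the total score under the i.i.d. background is obtained by dynamic-
#' programming convolution, giving an exact score -> p-value table.
#'
#' @slot id motif identifier.
#' @slot probMatrix 4 x width matrix (rows A, C, G, T), columns sum to 1.
#' @slot background length-4 background probabilities used when the matrix was
#'   read (uniform unless the source file provided one).
#' @slot pseudocount pseudocount applied when normalizing.
#' @export
setClass("MotifModel", representation(
    id = "character", probMatrix = "matrix", background = "numeric",
    pseudocount = "numeric"))

setValidity("MotifModel", function(object) {
    pm <- object@probMatrix
    if (nrow(pm) != 4L) return("probability matrix must have 4 rows (A,C,G,T)")
    if (ncol(pm) < 1L) return("motif width must be >= 1")
    if (any(abs(colSums(pm) - 1) > 1e-9))
        return("probability matrix columns must sum to 1")
    if (length(object@background) != 4L || any(object@background <= 0))
        return("background must be 4 positive probabilities")
    TRUE
})

#' Configuration of the synthetic two-species simulator
#'
#' Defaults mirror the study design the simulator emulates: five flowering
#' time points with five biological replicates per point, a seven-level TF
#' cascade of ten TFs per level rooted at a monotonically decreasing seed TF,
#' thirty pathway enzyme genes, negative-binomial count noise, 2000-bp
#' promoters with planted binding-site occurrences for true regulator-target
#' pairs.
#'
#' @slot nTimePoints,nReplicates design dimensions (5 x 5).
#' @slot nLevels,tfsPerLevel cascade depth and width (7, 10).
#' @slot nEnzymeGenes named integer: enzyme genes per pathway.
#' @slot nHubEnzymes number of enzymes planted as high-degree hubs.
#' @slot nBackgroundGenes flat-profile genes that must fail the DEG filter.
#' @slot specificTFsPerLevel species-specific (unpaired) TFs added per level.
#' @slot rewiredEnzymeFraction fraction of ortholog-paired enzymes re-wired to
#'   a distant level in species 2 (their edges become species-specific).
#' @slot unmappedFraction fraction of background genes left out of the
#'   ortholog map.
#' @slot libSize expected library-size scale (mean counts baseline 2^log2Baseline).
#' @slot dispersion negative-binomial dispersion (var = mu + dispersion*mu^2).
#' @slot levelCorrelation correlation between adjacent level profiles.
#' @slot targetCorrelation planted within-edge correlation for regulator ->
#'   enzyme edges (hub enzymes use min(targetCorrelation + 0.05, 0.99)).
#' @slot log2Amplitude,log2Baseline latent profile amplitude / baseline (log2).
#' @slot promoterLength promoter length in bp (2000).
#' @slot motifPlantProb probability a true edge's motif is planted.
#' @slot noiseFree if TRUE, counts equal latent means exactly.
#' @slot seed mandatory integer random seed.
#' @export
setClass("SimulationConfig", representation(
    nTimePoints = "integer", nReplicates = "integer",
    nLevels = "integer", tfsPerLevel = "integer",
    nEnzymeGenes = "integer", nHubEnzymes = "integer",
    nBackgroundGenes = "integer", specificTFsPerLevel = "integer",
    rewiredEnzymeFraction = "numeric", unmappedFraction = "numeric",
    libSize = "numeric", dispersion = "numeric",
    levelCorrelation = "numeric", targetCorrelation = "numeric",
    log2Amplitude = "numeric", log2Baseline = "numeric",
    promoterLength = "integer", motifPlantProb = "numeric",
    noiseFree = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nTimePoints < 2L) msg <- c(msg, "nTimePoints must be >= 2")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (object@nLevels < 2L) msg <- c(msg, "nLevels must be >= 2")
    if (object@tfsPerLevel < 1L) msg <- c(msg, "tfsPerLevel must be >= 1")
    if (any(object@nEnzymeGenes < 0L)) msg <- c(msg, "nEnzymeGenes must be >= 0")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (object@levelCorrelation <= 0 || object@levelCorrelation >= 1)
        msg <- c(msg, "levelCorrelation must be in (0, 1)")
    if (object@targetCorrelation <= 0 || object@targetCorrelation > 1)
        msg <- c(msg, "targetCorrelation must be in (0, 1]")
    if (object@motifPlantProb < 0 || object@motifPlantProb > 1)
        msg <- c(msg, "motifPlantProb must be in [0, 1]")
    if (object@promoterLength < 1L) msg <- c(msg, "promoterLength must be >= 1")
    if (is.na(object@seed)) msg <- c(msg, "a random seed is mandatory")
    if (length(msg)) msg else TRUE
})

#' Planted ground truth of the synthetic two-species regulome
#'
#' Everything the simulator planted and that downstream stages may be scored
#' against: TF levels per species, the directed regulatory cascade with its
#' cross-species scope, enzyme-gene regulator assignments, the ortholog map,
#' the seed TFs, the motif assigned to each TF family, and the latent
#' (noise-free) log2 expression profiles from which the truth co-expression
#' edge set can be recomputed at any cutoff (see [latentEdges()]).
#'
#' @slot speciesIds character(2).
#' @slot tfLevels list of two named integer vectors (per species).
#' @slot seeds named character(2): seed TF per species.
#' @slot edges data.frame: `regulator`, `target`, `species` (1 or 2),
#'   `scope` ("both"/"species1"/"species2"), `type` ("tf"/"enzyme").
#' @slot enzymes data.frame: per species enzyme annotation (gene, pathway,
#'   level, is_hub).
#' @slot orthologPairs data.frame `gene1`, `gene2`.
#' @slot motifAssignment named character: TF family -> motif id.
#' @slot latentProfiles list of two matrices (genes x time points) of latent
#'   log2 mean expression.
#' @slot geneLengths list of two named numeric vectors.
#' @slot config the [SimulationConfig] used.
#' @export
setClass("TruthRegulome", representation(
    speciesIds = "character", tfLevels = "list", seeds = "character",
    edges = "data.frame", enzymes = "data.frame",
    orthologPairs = "data.frame", motifAssignment = "character",
    latentProfiles = "list", geneLengths = "list",
    config = "SimulationConfig"))

#' Differential-expression result over all time-point pairs
#'
#' @slot table data.frame: `gene`, `pair` ("T1-T2", ...), `log2FC`, `p`,
#'   `padj` (BH within pair), `significant`.
#' @slot degFlags named logical: gene is a DEG in at least one pair.
#' @slot params list (lfcCutoff, fdrCutoff, pseudocount, test).
#' @export
setClass("DEResult", representation(
    table = "data.frame", degFlags = "logical", params = "list"))

validPathways <- function() c("carotenoid", "chlorophyll", "anthocyanin", "flavonol")
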