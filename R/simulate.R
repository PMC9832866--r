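#' Simulator configuration
#'
#' Constructs a [SimulationConfig] with defaults matching the emulated study
#' design: 5 time points x 5 replicates per species, a 7-level cascade of 10
#' TFs per level (a fifth of the slots species-specific), 30 enzymatic genes
#' split over the four pigment pathways with 5 planted hub enzymes, flat
#' background genes, negative-binomial dispersion 0.05, and 2000-bp promoters.
#'
#' @param seed mandatory integer random seed; fixing it makes every output
#'   byte-identical.
#' @param nTimePoints,nReplicates,nLevels,tfsPerLevel design dimensions.
#' @param specificFraction fraction of TF slots per level that are
#'   species-specific (unpaired) rather than conserved.
#' @param nEnzymeGenes named integer vector: enzymes per pathway.
#' @param nHubEnzymes how many enzymes are planted as hubs (regulated by two
#'   adjacent TF levels; planted degree twice that of ordinary enzymes).
#' @param nBackgroundGenes flat-profile genes (fail the DEG filter).
#' @param rewiredEnzymeFraction fraction of conserved non-hub enzymes whose
#'   species-2 ortholog is regulated at a distant level (their edges are
#'   species-specific although both endpoints are ortholog-mapped).
#' @param unmappedFraction fraction of background genes left unpaired.
#' @param libSize library-size scale multiplier.
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2); 0 gives
#'   Poisson-free deterministic counts only together with `noiseFree`.
#' @param levelCorrelation correlation between adjacent level profiles.
#' @param targetCorrelation planted within-edge correlation of
#'   regulator-enzyme edges.
#' @param log2Amplitude,log2Baseline latent log2 profile amplitude/baseline.
#' @param promoterLength promoter length (bp).
#' @param motifPlantProb probability of planting a motif for a true edge.
#' @param noiseFree if TRUE counts equal the latent means exactly (the
#'   dispersion -> 0 diagnostic limit; counts are then not integers).
#' @return a [SimulationConfig].
#' @export
simulationConfig <- function(seed,
                             nTimePoints = 5L, nReplicates = 5L,
                             nLevels = 7L, tfsPerLevel = 10L,
                             specificFraction = 0.2,
                             nEnzymeGenes = c(carotenoid = 8L, chlorophyll = 8L,
                                              anthocyanin = 7L, flavonol = 7L),
                             nHubEnzymes = 5L, nBackgroundGenes = 40L,
                             rewiredEnzymeFraction = 0.2,
                             unmappedFraction = 0.1,
                             libSize = 1, dispersion = 0.05,
                             levelCorrelation = 0.855,
                             targetCorrelation = 0.90,
                             log2Amplitude = 4.5, log2Baseline = 9,
                             promoterLength = 2000L, motifPlantProb = 1,
                             noiseFree = FALSE) {
    if (missing(seed)) stopf("'seed' is mandatory")
    cfg <- new("SimulationConfig",
        nTimePoints = as.integer(nTimePoints),
        nReplicates = as.integer(nReplicates),
        nLevels = as.integer(nLevels), tfsPerLevel = as.integer(tfsPerLevel),
        nEnzymeGenes = stats::setNames(as.integer(nEnzymeGenes),
                                       names(nEnzymeGenes)),
        nHubEnzymes = as.integer(min(nHubEnzymes, sum(nEnzymeGenes))),
        nBackgroundGenes = as.integer(nBackgroundGenes),
        specificTFsPerLevel = as.integer(round(specificFraction * tfsPerLevel)),
        rewiredEnzymeFraction = rewiredEnzymeFraction,
        unmappedFraction = unmappedFraction,
        libSize = libSize, dispersion = dispersion,
        levelCorrelation = levelCorrelation,
        targetCorrelation = targetCorrelation,
        log2Amplitude = log2Amplitude, log2Baseline = log2Baseline,
        promoterLength = as.integer(promoterLength),
        motifPlantProb = motifPlantProb,
        noiseFree = noiseFree, seed = as.integer(seed))
    methods::validObject(cfg)
    cfg
}

# Level-profile basis: a planar rotation chain in the centered profile space.
# Level k's latent shape is z_k = cos(theta_k) u1 + sin(theta_k) u2 with
# theta_k = offset + (k-1) * acos(c1), so adjacent levels correlate exactly c1
# and levels two apart correlate 2*c1^2 - 1 (the smallest value any
# construction with adjacent correlation c1 can achieve).  u1 is a declining
# trend (the seed level is strictly decreasing), u2 a calibrated mid-late
# shape making the level peaks sweep T1 -> T5.
levelProfileBasis <- function(D, nLevels, c1) {
    u1 <- seq(D - 1, 0, length.out = D) - (D - 1) / 2
    u1 <- u1 / sqrt(sum(u1^2))
    template <- c(-0.5, 0.25, 0.45, 0.4, -0.6)
    v <- if (D == 5L) template else
        stats::approx(seq(0, 1, length.out = 5L), template,
                      xout = seq(0, 1, length.out = D))$y
    v <- v - mean(v)
    v <- v - sum(v * u1) * u1
    u2 <- v / sqrt(sum(v^2))
    offset <- -15 * pi / 180
    delta <- acos(c1)
    Z <- vapply(seq_len(nLevels), function(k)
        cos(offset + (k - 1) * delta) * u1 + sin(offset + (k - 1) * delta) * u2,
        numeric(D))
    colnames(Z) <- paste0("L", seq_len(nLevels))
    list(Z = Z, u1 = u1, u2 = u2)
}

.tfFamilyPool <- c("bHLH", "WRKY", "ERF", "B3", "MYB_related",
                   "C2H2", "NAC", "WD40", "GRAS", "MYB")

#' Generate the planted two-species regulome
#'
#' Builds the ground truth that [simulateExpression()] and
#' [simulatePromoters()] realize: TF levels per species (a conserved core
#' plus species-specific TFs), the directed cascade (each non-seed TF wired
#' to a parent one level up), enzyme genes with designated regulators (hub
#' enzymes regulated by two adjacent levels), the 1:1 ortholog map, seed TFs,
#' per-family motif assignment, and the latent (noise-free) log2 expression
#' profiles of every gene.
#'
#' @param config a [SimulationConfig].
#' @return a [TruthRegulome].
#' @export
generateTruth <- function(config) {
    methods::validObject(config)
    withSeed(childSeed(config@seed, 1L), generateTruthImpl(config))
}

generateTruthImpl <- function(config) {
    D <- config@nTimePoints; L <- config@nLevels
    nTF <- config@tfsPerLevel
    nSpec <- min(config@specificTFsPerLevel, nTF)
    nCons <- nTF - nSpec
    basis <- levelProfileBasis(D, L, config@levelCorrelation)
    Z <- basis$Z
    sp <- c("spA", "spB")

    fam <- function(i) .tfFamilyPool[(i - 1L) %% length(.tfFamilyPool) + 1L]

    tfTab <- list()
    for (k in seq_len(L)) {
        if (nCons > 0L)
            tfTab[[length(tfTab) + 1L]] <- data.frame(
                slot = sprintf("TF_L%d_%02d", k, seq_len(nCons)),
                level = k, conserved = TRUE, species = NA_integer_,
                family = fam(seq_len(nCons) + (k - 1L) * nTF),
                stringsAsFactors = FALSE)
        if (nSpec > 0L)
            for (s in 1:2)
                tfTab[[length(tfTab) + 1L]] <- data.frame(
                    slot = sprintf("TFs%d_L%d_%02d", s, k, seq_len(nSpec)),
                    level = k, conserved = FALSE, species = s,
                    family = fam(seq_len(nSpec) + nCons + (k - 1L) * nTF),
                    stringsAsFactors = FALSE)
    }
    tfTab <- do.call(rbind, tfTab)
    gid <- function(s, slot) {
        if (!length(slot)) return(character(0))
        paste0(sp[s], "_", slot)
    }

    # seed: first level-1 TF; conserved when a conserved slot exists
    l1 <- tfTab[tfTab$level == 1L, , drop = FALSE]
    seedSlots <- character(2)
    if (any(l1$conserved)) {
        seedSlots[] <- l1$slot[l1$conserved][1L]
    } else {
        seedSlots[1L] <- l1$slot[!is.na(l1$species) & l1$species == 1L][1L]
        seedSlots[2L] <- l1$slot[!is.na(l1$species) & l1$species == 2L][1L]
    }

    # Network levels follow hop distance from the seed: the seed alone is
    # level 1; the other first-wave TFs and the second wave are its direct
    # neighbours (level 2); wave k >= 2 keeps level k.
    netLevel <- function(slot, waveLv)
        ifelse(slot %in% seedSlots, 1L, ifelse(waveLv == 1L, 2L, waveLv))

    # cascade edges: every non-seed TF gets one parent one network level up
    edges <- list()
    for (i in seq_len(nrow(tfTab))) {
        if (tfTab$slot[i] %in% seedSlots) next
        k <- tfTab$level[i]
        if (tfTab$conserved[i]) {
            par <- if (k <= 2L) seedSlots[1L] else {
                pp <- tfTab[tfTab$level == k - 1L & tfTab$conserved, ,
                            drop = FALSE]
                if (nrow(pp))
                    pp$slot[(match(tfTab$slot[i], tfTab$slot) %% nrow(pp)) + 1L]
                else NA_character_
            }
            if (!is.na(par) && (k <= 2L || any(tfTab$conserved &
                                               tfTab$level == k - 1L))) {
                for (s in 1:2)
                    edges[[length(edges) + 1L]] <- data.frame(
                        regulator = gid(s, if (k <= 2L) seedSlots[s] else par),
                        target = gid(s, tfTab$slot[i]),
                        species = s, scope = "both", type = "tf",
                        stringsAsFactors = FALSE)
                next
            }
        }
        s <- tfTab$species[i]
        ss <- if (is.na(s)) 1:2 else s
        for (s2 in ss) {
            p <- if (k <= 2L) seedSlots[s2] else {
                par <- tfTab[tfTab$level == k - 1L &
                             (tfTab$conserved |
                              (!is.na(tfTab$species) & tfTab$species == s2)), ,
                             drop = FALSE]
                par$slot[sample.int(nrow(par), 1L)]
            }
            edges[[length(edges) + 1L]] <- data.frame(
                regulator = gid(s2, p), target = gid(s2, tfTab$slot[i]),
                species = s2, scope = paste0("species", s2), type = "tf",
                stringsAsFactors = FALSE)
        }
    }

    # enzymes: pathway labels, levels spread over 2..L, hubs first
    nE <- sum(config@nEnzymeGenes)
    pwy <- rep(names(config@nEnzymeGenes), config@nEnzymeGenes)
    enzLv <- rep(seq(2L, max(2L, L - 1L)), length.out = nE)
    isHub <- seq_len(nE) <= config@nHubEnzymes
    # hubs need an interior level (regulated by levels l and l+1)
    enzLv[isHub] <- rep(seq(2L, max(2L, L - 1L)),
                        length.out = sum(isHub))
    nRewire <- round(config@rewiredEnzymeFraction * sum(!isHub))
    rewired <- rep(FALSE, nE)
    rewired[which(!isHub)[seq_len(nRewire)]] <- TRUE
    enzSlot <- sprintf("E%02d_%s", seq_len(nE), substr(pwy, 1L, 4L))
    lv2 <- enzLv
    if (any(rewired)) {
        # species-2 level far enough for the latent correlation to drop
        lv2[rewired] <- ((enzLv[rewired] - 2L + 3L) %% (L - 1L)) + 2L
        tooClose <- abs(lv2 - enzLv) < 3L & rewired
        lv2[tooClose] <- ifelse(enzLv[tooClose] + 3L <= L,
                                enzLv[tooClose] + 3L,
                                pmax(2L, enzLv[tooClose] - 3L))
    }
    consTF <- function(s, k) {
        cand <- tfTab$slot[tfTab$level == k & tfTab$conserved]
        if (!length(cand))
            cand <- tfTab$slot[tfTab$level == k &
                               !is.na(tfTab$species) & tfTab$species == s]
        gid(s, cand[(k %% length(cand)) + 1L])
    }
    enzymes <- list()
    for (i in seq_len(nE)) {
        for (s in 1:2) {
            lv <- if (s == 1L) enzLv[i] else lv2[i]
            g <- gid(s, enzSlot[i])
            scope <- if (rewired[i]) paste0("species", s) else "both"
            regs <- consTF(s, lv)
            if (isHub[i] && lv < L) regs <- c(regs, consTF(s, lv + 1L))
            for (rg in regs)
                edges[[length(edges) + 1L]] <- data.frame(
                    regulator = rg, target = g, species = s, scope = scope,
                    type = "enzyme", stringsAsFactors = FALSE)
            enzymes[[length(enzymes) + 1L]] <- data.frame(
                gene = g, species = s, pathway = pwy[i], level = lv,
                is_hub = isHub[i], rewired = rewired[i],
                stringsAsFactors = FALSE)
        }
    }
    enzymes <- if (length(enzymes)) do.call(rbind, enzymes) else
        data.frame(gene = character(), species = integer(),
                   pathway = character(), level = integer(),
                   is_hub = logical(), rewired = logical(),
                   stringsAsFactors = FALSE)
    edges <- if (length(edges)) do.call(rbind, edges) else
        data.frame(regulator = character(), target = character(),
                   species = integer(), scope = character(),
                   type = character(), stringsAsFactors = FALSE)

    # ortholog pairs: conserved TFs, all enzymes, mapped background genes
    nBG <- config@nBackgroundGenes
    bgSlot <- sprintf("BG%03d", seq_len(nBG))
    bgMapped <- seq_len(nBG) > round(config@unmappedFraction * nBG)
    orth <- rbind(
        data.frame(gene1 = gid(1L, tfTab$slot[tfTab$conserved]),
                   gene2 = gid(2L, tfTab$slot[tfTab$conserved]),
                   stringsAsFactors = FALSE),
        data.frame(gene1 = gid(1L, enzSlot), gene2 = gid(2L, enzSlot),
                   stringsAsFactors = FALSE),
        data.frame(gene1 = gid(1L, bgSlot[bgMapped]),
                   gene2 = gid(2L, bgSlot[bgMapped]),
                   stringsAsFactors = FALSE))

    # latent log2 profiles
    resid <- residualBasis(D, basis)
    profiles <- vector("list", 2L)
    lengths <- vector("list", 2L)
    tfLevels <- vector("list", 2L)
    for (s in 1:2) {
        rows <- list()
        tfs <- tfTab[tfTab$conserved |
                     (!is.na(tfTab$species) & tfTab$species == s), ,
                     drop = FALSE]
        tfLevels[[s]] <- stats::setNames(
            as.integer(netLevel(tfs$slot, tfs$level)), gid(s, tfs$slot))
        for (i in seq_len(nrow(tfs)))
            rows[[gid(s, tfs$slot[i])]] <- Z[, tfs$level[i]]
        for (i in seq_len(nE)) {
            lv <- if (s == 1L) enzLv[i] else lv2[i]
            zdir <- if (isHub[i] && lv < L) {
                zm <- Z[, lv] + Z[, lv + 1L]
                zm / sqrt(sum(zm^2))
            } else Z[, lv]
            rho <- if (isHub[i]) min(config@targetCorrelation + 0.05, 0.99)
                   else config@targetCorrelation
            w <- drawResidual(resid)
            rows[[gid(s, enzSlot[i])]] <- rho * zdir + sqrt(1 - rho^2) * w
        }
        for (i in seq_len(nBG)) rows[[gid(s, bgSlot[i])]] <- rep(0, D)
        m <- do.call(rbind, rows)
        amp <- config@log2Amplitude * stats::runif(nrow(m), 0.9, 1.1)
        amp[rownames(m) %in% gid(s, bgSlot)] <- 0
        base <- config@log2Baseline + stats::rnorm(nrow(m), 0, 0.5)
        m <- base + amp * m
        # "bulk transcriptome" compensator: one high-abundance gene whose
        # latent level absorbs the fluctuation of the library total, so the
        # expected per-sample total (and hence the TPM denominator) is
        # time-invariant and TPM profiles equal the designed profiles
        # a large constant part keeps the compensator's own fold change well
        # under the DEG threshold, so it never enters the network universe
        tot <- colSums(2^m)
        m <- rbind(m, log2(3 * max(tot) - tot))
        rownames(m)[nrow(m)] <- paste0(sp[s], "_BULK01")
        colnames(m) <- paste0("T", seq_len(D))
        profiles[[s]] <- m
        lengths[[s]] <- stats::setNames(
            round(stats::runif(nrow(m), 500, 3000)), rownames(m))
    }
    names(profiles) <- names(lengths) <- names(tfLevels) <- sp

    fams <- unique(tfTab$family)
    motifAssignment <- stats::setNames(paste0("MOTIF_", fams), fams)

    new("TruthRegulome", speciesIds = sp, tfLevels = tfLevels,
        seeds = stats::setNames(c(gid(1L, seedSlots[1L]),
                                  gid(2L, seedSlots[2L])), sp),
        edges = edges, enzymes = enzymes, orthologPairs = orth,
        motifAssignment = motifAssignment, latentProfiles = profiles,
        geneLengths = lengths, config = config)
}

# basis of the centered profile space orthogonal to the planar chain,
# used for enzyme residual directions
residualBasis <- function(D, basis) {
    Q <- cbind(rep(1, D) / sqrt(D), basis$u1, basis$u2)
    P <- diag(D) - Q %*% t(Q)
    P
}

drawResidual <- function(P) {
    w <- as.numeric(P %*% stats::rnorm(nrow(P)))
    n <- sqrt(sum(w^2))
    if (n < 1e-12) rep(0, nrow(P)) else w / n
}

setMethod("show", "TruthRegulome", function(object) {
    cat("TruthRegulome:", length(object@tfLevels[[1L]]), "+",
        length(object@tfLevels[[2L]]), "leveled TFs,",
        nrow(object@edges), "planted edges,",
        nrow(object@orthologPairs), "ortholog pairs\n")
})

#' Truth co-expression edge set at a cutoff
#'
#' Recomputes, from the latent (noise-free) log2 profiles, the set of
#' TF-gene pairs whose profile correlation is at least `cutoff` — the edge
#' set a perfect (noise-free) run of the pipeline recovers, and the reference
#' for precision/recall scoring.
#'
#' @return data.frame `a` (TF), `b`, `r`.
#' @rdname TruthRegulome-class
#' @export
setMethod("latentEdges", "TruthRegulome", function(object, cutoff = 0.81,
                                                   species = 1L) {
    prof <- latentLogTPM(object, species)
    tfs <- names(object@tfLevels[[species]])
    # the truth universe mirrors the expressed-DEG contract in the
    # noise-free limit: a gene belongs iff some pair of time points has
    # |log2 fold change| >= 1 on pseudocounted TPM (flat background genes
    # and the bulk compensator are static by design and drop out)
    dynamic <- apply(prof, 1L, function(v) max(v) - min(v) >= 1)
    prof <- prof[dynamic, , drop = FALSE]
    tfs <- intersect(tfs, rownames(prof))
    corr <- stats::cor(t(prof[tfs, , drop = FALSE]), t(prof))
    es <- buildEdges(corr, cutoff = cutoff, tfIds = tfs)
    es@edges[, c("a", "b", "r")]
})

# latent log2(TPM + 1) profiles: the same quantity a noise-free run of the
# pipeline correlates (TPM inherits a per-time-point compositional shift
# from the library total, so truth is defined on the TPM scale, not on raw
# latent means)
latentLogTPM <- function(truth, species) {
    prof <- truth@latentProfiles[[species]]
    len <- truth@geneLengths[[species]][rownames(prof)]
    mu <- 2^prof * (len / 1500) * truth@config@libSize
    log2(computeTPM(mu, len) + 1)
}

#' Gene catalog of one simulated species
#'
#' @param truth a [TruthRegulome].
#' @param species 1 or 2.
#' @return a [GeneCatalog].
#' @export
makeGeneCatalog <- function(truth, species = 1L) {
    prof <- truth@latentProfiles[[species]]
    genes <- rownames(prof)
    tfs <- names(truth@tfLevels[[species]])
    enz <- truth@enzymes[truth@enzymes$species == species, , drop = FALSE]
    famOf <- function(g) {
        # TF ids end in the slot index; families are assigned cyclically
        # from the same index at generation time
        slot <- sub("^sp[AB]_", "", g)
        lv <- as.integer(sub("^TFs?[0-9]?_L([0-9]+)_.*$", "\\1", slot))
        i <- as.integer(sub(".*_([0-9]+)$", "\\1", slot))
        off <- if (grepl("^TFs", slot))
            i + (truth@config@tfsPerLevel - truth@config@specificTFsPerLevel)
        else i
        .tfFamilyPool[(off + (lv - 1L) * truth@config@tfsPerLevel - 1L) %%
                      length(.tfFamilyPool) + 1L]
    }
    pw <- rep("none", length(genes))
    pw[match(enz$gene, genes)] <- enz$pathway
    isTF <- genes %in% tfs
    fams <- rep("", length(genes))
    fams[isTF] <- vapply(genes[isTF], famOf, character(1))
    GeneCatalog(data.frame(
        gene_id = genes, is_tf = isTF,
        tf_family = fams,
        pathway = pw,
        length = as.numeric(truth@geneLengths[[species]][genes]),
        stringsAsFactors = FALSE))
}

#' Simulate two species' time-course expression
#'
#' Counts are drawn per replicate from a negative-binomial model around the
#' latent mean `2^profile * length/1500 * libSize`; TPM is then computed from
#' counts and lengths.  In the `noiseFree` limit counts equal the latent
#' means exactly.  The seed-TF latent profile is strictly decreasing by
#' construction; a level-k profile never peaks before a level-(k-1) profile.
#'
#' @param truth a [TruthRegulome].
#' @param config the same [SimulationConfig] (defaults to `truth@config`).
#' @return named list of two [TimeCourseSet] objects.
#' @export
simulateExpression <- function(truth, config = truth@config) {
    withSeed(childSeed(config@seed, 2L), {
        out <- lapply(1:2, function(s) {
            prof <- truth@latentProfiles[[s]]
            len <- truth@geneLengths[[s]][rownames(prof)]
            D <- ncol(prof); R <- config@nReplicates
            mu <- 2^prof * (len / 1500) * config@libSize
            tp <- rep(seq_len(D), each = R)
            rp <- rep(seq_len(R), D)
            m <- mu[, tp, drop = FALSE]
            if (!config@noiseFree && config@dispersion > 0) {
                cnt <- matrix(stats::rnbinom(length(m), mu = m,
                                             size = 1 / config@dispersion),
                              nrow = nrow(m))
            } else if (!config@noiseFree) {
                cnt <- matrix(stats::rpois(length(m), m), nrow = nrow(m))
            } else {
                cnt <- m
            }
            dimnames(cnt) <- list(rownames(prof), paste0("T", tp, "_R", rp))
            TimeCourseSet(cnt, tp, rp, geneLength = len)
        })
        names(out) <- truth@speciesIds
        out
    })
}
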