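test_that("a minimal two-level cascade has one seed and one downstream TF", {
    cfg <- simulationConfig(seed = 51, nLevels = 2L, tfsPerLevel = 1L,
                            specificFraction = 0,
                            nEnzymeGenes = c(carotenoid = 0L),
                            nHubEnzymes = 0L, nBackgroundGenes = 2L)
    truth <- generateTruth(cfg)
    for (s in 1:2) {
        lv <- truth@tfLevels[[s]]
        expect_equal(sort(unname(lv)), c(1L, 2L))
        expect_equal(lv[[truth@seeds[[s]]]], 1L)
    }
    expect_true(all(truth@edges$scope == "both"))
})

test_that("fully species-specific cascades leave the consensus truth empty", {
    cfg <- simulationConfig(seed = 52, nLevels = 3L, tfsPerLevel = 2L,
                            specificFraction = 1,
                            nEnzymeGenes = c(carotenoid = 0L),
                            nHubEnzymes = 0L, nBackgroundGenes = 2L,
                            unmappedFraction = 1)
    truth <- generateTruth(cfg)
    expect_true(all(grepl("^species", truth@edges$scope)))
    expect_equal(nrow(truth@orthologPairs), 0L)
    expr <- simulateExpression(truth, cfg)
    tg <- lapply(1:2, function(s)
        buildTOGCN(expr[[s]], makeGeneCatalog(truth, s), truth@seeds[[s]]))
    cons <- consensusNetwork(tg[[1]], tg[[2]], truth@orthologPairs)
    expect_equal(nrow(cons@edges), 0L)
})

test_that("cascade dimensions follow the configuration", {
    cfg <- simulationConfig(seed = 53, nLevels = 7L, tfsPerLevel = 10L,
                            specificFraction = 0.2)
    truth <- generateTruth(cfg)
    for (s in 1:2) {
        lv <- truth@tfLevels[[s]]
        expect_length(lv, 70L)                 # 7 x 10 leveled TFs per species
        expect_equal(max(lv), 7L)
        expect_equal(sum(lv == 1L), 1L)        # the seed alone roots level 1
    }
    # every non-seed TF has a planted parent exactly one level up
    for (s in 1:2) {
        lv <- truth@tfLevels[[s]]
        ed <- truth@edges[truth@edges$species == s &
                          truth@edges$type == "tf", ]
        for (g in setdiff(names(lv), truth@seeds[[s]])) {
            par <- ed$regulator[ed$target == g]
            expect_true(length(par) >= 1)
            expect_true(any(lv[par] == lv[[g]] - 1L))
        }
    }
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(seed = 1, nLevels = 1L), "nLevels")
    expect_error(simulationConfig(seed = 1, dispersion = -1), "dispersion")
    expect_error(simulationConfig(seed = 1, levelCorrelation = 1.2),
                 "levelCorrelation")
    expect_error(simulationConfig(), "mandatory")
})

test_that("the seed latent profile decreases strictly; later levels peak later", {
    cfg <- simulationConfig(seed = 54)
    truth <- generateTruth(cfg)
    for (s in 1:2) {
        prof <- truth@latentProfiles[[s]]
        expect_true(all(diff(prof[truth@seeds[[s]], ]) < 0))
        lv <- truth@tfLevels[[s]]
        peaks <- vapply(names(lv), function(g) which.max(prof[g, ]),
                        integer(1))
        byLevel <- tapply(peaks, lv[names(peaks)], stats::median)
        expect_true(all(diff(byLevel) >= 0))   # peaks sweep forward in time
    }
})

test_that("noise-free counts equal the latent means exactly", {
    cfg <- smallConfig(55, noiseFree = TRUE)
    truth <- generateTruth(cfg)
    expr <- simulateExpression(truth, cfg)
    for (s in 1:2) {
        prof <- truth@latentProfiles[[s]]
        len <- truth@geneLengths[[s]][rownames(prof)]
        mu <- 2^prof * (len / 1500)
        cnt <- counts(expr[[s]])
        tp <- timePoints(expr[[s]])
        for (t in unique(tp))
            expect_equal(unname(cnt[, which(tp == t)[1]]),
                         unname(mu[, t]))
        # replicates within a time point are identical
        expect_equal(cnt[, tp == 1][, 1], cnt[, tp == 1][, 2])
    }
})

test_that("TPM columns of simulated data each sum to one million", {
    cfg <- smallConfig(56)
    expr <- simulateExpression(generateTruth(cfg), cfg)
    expect_equal(unname(colSums(tpm(expr[[1]]))),
                 rep(1e6, ncol(expr[[1]])), tolerance = 1e-6)
})

test_that("identical configs give byte-identical outputs; files round-trip", {
    cfg <- smallConfig(57)
    d1 <- tempfile(); d2 <- tempfile()
    for (d in c(d1, d2)) {
        truth <- generateTruth(cfg)
        expr <- simulateExpression(truth, cfg)
        prom <- simulatePromoters(truth, cfg)
        writeSyntheticData(truth, expr, prom, d)
    }
    m1 <- readTSV(file.path(d1, "MANIFEST.tsv"))
    m2 <- readTSV(file.path(d2, "MANIFEST.tsv"))
    expect_identical(m1, m2)
    # refusing to overwrite without force
    expect_error(writeSyntheticData(generateTruth(cfg),
                                    simulateExpression(generateTruth(cfg)),
                                    dir = d1), "force")

    # counts round-trip losslessly through the reader
    truth <- generateTruth(cfg)
    expr <- simulateExpression(truth, cfg)
    back <- readExpression(file.path(d1, "spA_counts.tsv"),
                           geneLength = truth@geneLengths[[1]])
    expect_equal(counts(back), counts(expr[[1]]), tolerance = 1e-9)
    expect_identical(timePoints(back), timePoints(expr[[1]]))
    # catalog and ortholog round trips
    cat1 <- makeGeneCatalog(truth, 1)
    cat2 <- readGeneCatalog(file.path(d1, "spA_catalog.tsv"))
    expect_identical(as.data.frame(cat2@data), as.data.frame(cat1@data))
    expect_identical(readOrthologMap(file.path(d1, "orthologs.tsv")),
                     truth@orthologPairs)
})

test_that("malformed expression tables are rejected with diagnostics", {
    p <- tempfile()
    writeLines(c("gene_id\tT1_R1\tT1_R1", "g1\t1\t2"), p)
    expect_error(readExpression(p), "duplicate sample")
    writeLines(c("gene_id\tT1_R1\tT2_R1", "g1\t1\t2", "g1\t3\t4"), p)
    expect_error(readExpression(p), "duplicate gene")
    writeLines(c("gene_id\tT1_R1\tbad", "g1\t1\t2"), p)
    expect_error(readExpression(p), "malformed sample")
    writeLines(c("gene_id\tT1_R1\tT1_R2\tT2_R1", "g1\t1\t2\t3"), p)
    expect_error(readExpression(p), "inconsistent replicate")
})

test_that("a planted 0.95-correlation edge survives count noise (n = 25)", {
    # Monte-Carlo contract of the generator: with target correlation 0.95
    # and the default dispersion, the per-replicate sample correlation of a
    # planted conserved edge reaches the 0.81 cutoff in at least 95% of
    # re-simulations.
    cfg0 <- simulationConfig(seed = 1, nLevels = 2L, tfsPerLevel = 2L,
                             specificFraction = 0,
                             nEnzymeGenes = c(carotenoid = 1L),
                             nHubEnzymes = 0L, nBackgroundGenes = 3L,
                             targetCorrelation = 0.95)
    truth0 <- generateTruth(cfg0)
    enz <- truth0@enzymes$gene[truth0@enzymes$species == 1L][1L]
    reg <- truth0@edges$regulator[truth0@edges$target == enz &
                                  truth0@edges$species == 1L][1L]
    ok <- vapply(1:200, function(i) {
        cfg <- simulationConfig(seed = 6000 + i, nLevels = 2L,
                                tfsPerLevel = 2L, specificFraction = 0,
                                nEnzymeGenes = c(carotenoid = 1L),
                                nHubEnzymes = 0L, nBackgroundGenes = 3L,
                                targetCorrelation = 0.95)
        tcs <- simulateExpression(generateTruth(cfg), cfg)[[1]]
        r <- correlationTable(tcs, reg, enz, sampleMode = "replicates")
        r[1, 1] >= 0.81
    }, logical(1))
    expect_gte(mean(ok), 0.95)
})
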