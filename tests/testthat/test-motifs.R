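rndMotif <- function(w, seed = 1) {
    set.seed(seed)
    m <- matrix(runif(4 * w, 0.05, 1), 4, w)
    m <- sweep(m, 2, colSums(m), "/")
    motifModel(sprintf("M%d", w), m)
}

test_that("MEME minimal format round-trips motifs and background", {
    m1 <- rndMotif(8, 3); m2 <- rndMotif(5, 4)
    path <- tempfile(fileext = ".meme")
    writeMEME(list(m1, m2), path, background = c(0.3, 0.2, 0.2, 0.3))
    back <- readMEME(path)
    expect_length(back, 2L)
    expect_equal(motifWidth(back[[1]]), 8L)
    expect_equal(back[[1]]@probMatrix, m1@probMatrix, tolerance = 2e-3)
    expect_equal(back[[1]]@background, c(0.3, 0.2, 0.2, 0.3))
    # empty file: empty list plus warning
    empty <- tempfile()
    writeLines("MEME version 4", empty)
    expect_warning(none <- readMEME(empty), "no MOTIF")
    expect_length(none, 0L)
    # malformed row
    bad <- tempfile()
    writeLines(c("MEME version 4", "MOTIF bad",
                 "letter-probability matrix: alength= 4 w= 1",
                 "0.5 0.5"), bad)
    expect_error(readMEME(bad), "malformed")
})

test_that("the exact p-value table behaves as a survival function", {
    m <- rndMotif(6, 5)
    sd <- scoreDistribution(m)
    expect_equal(sd$pvalues[1], 1)                       # p(min score) = 1
    expect_true(all(diff(sd$pvalues) <= 1e-15))          # monotone
    expect_equal(sum(diff(-sd$pvalues) >= 0), length(sd$pvalues) - 1L)

    # width-1 motif, uniform background: best base has p = 0.25
    m1 <- motifModel("w1", matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1),
                     pseudocount = 0)
    s1 <- scoreDistribution(m1)
    best <- max(s1$scoreMatrix)
    expect_equal(s1$pvalues[best - s1$minScore + 1L], 0.25)
    expect_error(scoreDistribution(m1, background = c(0, 0.5, 0.25, 0.25)),
                 "positive")
})

test_that("the DP distribution equals brute-force enumeration for width <= 6", {
    for (w in c(2L, 4L, 6L)) {
        m <- rndMotif(w, 10 + w)
        sd <- scoreDistribution(m)
        words <- as.matrix(expand.grid(rep(list(1:4), w)))
        sc <- vapply(seq_len(nrow(words)), function(i)
            sum(sd$scoreMatrix[cbind(words[i, ], seq_len(w))]), integer(1))
        for (thr in sort(unique(sc))) {
            pEnum <- mean(sc >= thr)
            pDP <- sd$pvalues[thr - sd$minScore + 1L]
            expect_equal(pDP, pEnum, tolerance = 1e-12)
        }
    }
})

test_that("scanning finds the consensus and is strand-symmetric", {
    m <- rndMotif(8, 21)
    cons <- motifConsensus(m)
    seqs <- c(hit = paste0("ACGTACGTAC", cons, "GGGTTTAAAC"))
    hits <- scanMotifs(m, seqs, pCutoff = 1e-3, background = "uniform")
    expect_true(any(hits$start == 10 & hits$strand == "+"))

    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqs[["hit"]])))
    hitsRC <- scanMotifs(m, c(hit = rc), pCutoff = 1e-3,
                         background = "uniform")
    expect_equal(nrow(hitsRC), nrow(hits))
    expect_setequal(hitsRC$score, hits$score)
    fwd <- hits[hits$strand == "+", ]
    mir <- hitsRC[hitsRC$strand == "-", ]
    expect_equal(sort(unname(nchar(seqs[[1]]) - (fwd$start + 8L))),
                 sort(mir$start))

    # windows containing non-ACGT letters are skipped silently
    seqN <- c(n = paste0(substr(seqs[[1]], 1, 12), "N",
                         substr(seqs[[1]], 14, nchar(seqs[[1]]))))
    hitsN <- scanMotifs(m, seqN, pCutoff = 1e-3, background = "uniform")
    expect_false(any(hitsN$start %in% 5:12))
    # shorter than the motif: no hits, no error
    expect_equal(nrow(scanMotifs(m, c(s = "ACGT"), 1e-3)), 0L)
})

test_that("planted promoter sites are recovered verbatim and in full", {
    cfg <- smallConfig(31, motifPlantProb = 1)
    truth <- generateTruth(cfg)
    prom <- simulatePromoters(truth, cfg)
    th <- prom$spA$trueHits
    expect_gt(nrow(th), 0)
    proms <- prom$spA$promoters
    consOf <- vapply(prom$motifs, motifConsensus, character(1))
    for (i in seq_len(nrow(th))) {
        w <- nchar(consOf[[th$motif[i]]])
        word <- substr(as.character(proms[[th$gene[i]]]),
                       th$start[i] + 1L, th$start[i] + w)
        expected <- if (th$strand[i] == "+") consOf[[th$motif[i]]]
            else as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(consOf[[th$motif[i]]])))
        expect_identical(word, expected)
    }
    # every true edge of the species has at least one recorded hit
    ed <- truth@edges[truth@edges$species == 1L, ]
    expect_true(all(ed$target %in% th$gene))

    # planting probability 0 leaves the true-hit table empty
    cfg0 <- smallConfig(32, motifPlantProb = 0)
    truth0 <- generateTruth(cfg0)
    prom0 <- simulatePromoters(truth0, cfg0)
    expect_equal(nrow(prom0$spA$trueHits), 0L)
})

test_that("edge confirmation flags confirmed, unconfirmed and untestable", {
    edges <- data.frame(regulator = c("tfA", "tfB", "tfC"),
                        target = c("g1", "g2", "g3"),
                        stringsAsFactors = FALSE)
    hits <- data.frame(seq = "g1", motif = "MA", start = 0L, end = 8L,
                       strand = "+", score = 5, p = 1e-6)
    map <- c(tfA = "MA", tfB = "MB")
    out <- confirmEdges(edges, hits, map)
    expect_identical(out$status, c("confirmed", "unconfirmed", "untestable"))
    expect_equal(nrow(out), 3L)    # nothing dropped
})
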