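test_that("BFS leveling reproduces hand-derived chains and diamonds", {
    # 3-chain S - A - B
    es <- esFromEdges(list(c("S", "A"), c("A", "B")), tfs = c("S", "A", "B"))
    lm <- assignLevels(es, "S")
    expect_equal(lm$levels, c(S = 1L, A = 2L, B = 3L))

    # diamond: C adjacent to A and B (both level 2) -> level 3
    es <- esFromEdges(list(c("S", "A"), c("S", "B"), c("A", "C"), c("B", "C")),
                      tfs = c("S", "A", "B", "C"))
    lm <- assignLevels(es, "S")
    expect_equal(lm$levels[["C"]], 3L)

    # isolated TF stays unleveled
    es <- esFromEdges(list(c("S", "A")), tfs = c("S", "A", "Z"),
                      nodes = c("S", "A", "Z"))
    lm <- assignLevels(es, "S")
    expect_identical(lm$unleveled, "Z")
    expect_false("Z" %in% names(lm$levels))
})

test_that("seed validation errors are specific", {
    es <- esFromEdges(list(c("S", "A"), c("S", "E")), tfs = c("S", "A"))
    expect_error(assignLevels(es, "missing"), "not a node")
    expect_error(assignLevels(es, "E"), "not a TF")
})

test_that("level maps equal 1 + BFS hop distance on random graphs (igraph oracle)", {
    skip_if_not_installed("igraph")
    set.seed(11)
    for (rep in 1:25) {
        n <- sample(5:15, 1)
        tfs <- paste0("t", seq_len(n))
        prs <- which(upper.tri(matrix(0, n, n)) &
                     matrix(runif(n * n) < 0.25, n, n), arr.ind = TRUE)
        if (!nrow(prs)) next
        pairs <- lapply(seq_len(nrow(prs)), function(i)
            c(tfs[prs[i, 1]], tfs[prs[i, 2]]))
        es <- esFromEdges(pairs, tfs = tfs, nodes = tfs)
        lm <- assignLevels(es, "t1")
        g <- igraph::graph_from_data_frame(
            data.frame(from = es@edges$a, to = es@edges$b),
            directed = FALSE, vertices = tfs)
        d <- igraph::distances(g, v = "t1")[1, ]
        reach <- names(d)[is.finite(d)]
        expect_setequal(names(lm$levels), reach)
        expect_equal(unname(lm$levels[reach]), unname(d[reach]) + 1)
    }
})

test_that("levels are contiguous with a parent one level up, whatever the node order", {
    set.seed(13)
    for (rep in 1:20) {
        n <- 12
        tfs <- paste0("t", sample(LETTERS, n))
        prs <- which(upper.tri(matrix(0, n, n)) &
                     matrix(runif(n * n) < 0.3, n, n), arr.ind = TRUE)
        if (!nrow(prs)) next
        pairs <- lapply(seq_len(nrow(prs)), function(i)
            c(tfs[prs[i, 1]], tfs[prs[i, 2]]))
        es <- esFromEdges(pairs, tfs = tfs, nodes = tfs)
        lm <- assignLevels(es, tfs[1])
        lv <- lm$levels
        expect_identical(sort(unique(as.integer(lv))), seq_len(max(lv)))
        e <- es@edges
        for (nd in names(lv)[lv >= 2L]) {
            nb <- c(e$b[e$a == nd], e$a[e$b == nd])
            expect_true(any(lv[intersect(nb, names(lv))] == lv[[nd]] - 1L))
        }
        # permuting the edge-list order never changes the level map
        perm <- sample(length(pairs))
        es2 <- esFromEdges(pairs[perm], tfs = tfs, nodes = tfs)
        lm2 <- assignLevels(es2, tfs[1])
        expect_identical(lm2$levels[sort(names(lm2$levels))],
                         lv[sort(names(lv))])
    }
})

test_that("targets attach at the minimum neighbouring TF level", {
    pairs <- list(c("S", "A"), c("A", "B"), c("B", "C"),
                  c("A", "E1"),                 # E1 only via level-2 TF
                  c("B", "E2"), c("C", "E2"))   # E2 sees levels 3 and 4
    tfs <- c("S", "A", "B", "C")
    net <- mkNet(pairs, tfs, "S", nodes = c(tfs, "E1", "E2", "E3"))
    expect_equal(net@levels[["E1"]], 2L)
    expect_equal(net@levels[["E2"]], 3L)        # min rule
    expect_false("E3" %in% names(net@levels))   # no leveled TF neighbour
})

test_that("buildTOGCN validates universe and seed", {
    cfg <- smallConfig(5)
    truth <- generateTruth(cfg)
    expr <- simulateExpression(truth, cfg)
    catalog <- makeGeneCatalog(truth, 1)
    tcs <- expr[[1]]
    expect_error(buildTOGCN(tcs, catalog, truth@seeds[[1]],
                            genes = character(0)), "no nodes")
    notSeed <- setdiff(rownames(tcs), truth@seeds[[1]])[1:10]
    expect_error(buildTOGCN(tcs, catalog, truth@seeds[[1]], genes = notSeed),
                 "whitelist")
    expect_error(buildTOGCN(tcs, catalog, "nope", genes = rownames(tcs)),
                 "not in the dataset")
})

test_that("a noise-free cascade is recovered exactly", {
    cfg <- smallConfig(6, noiseFree = TRUE)
    truth <- generateTruth(cfg)
    expr <- simulateExpression(truth, cfg)
    catalog <- makeGeneCatalog(truth, 1)
    # flat background genes have zero variance in the noise-free limit and
    # are excluded from the correlation with a warning
    net <- suppressWarnings(buildTOGCN(expr[[1]], catalog, truth@seeds[[1]]))
    planted <- truth@tfLevels[[1]]
    expect_identical(unname(net@levels[names(planted)]), unname(planted))
})
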