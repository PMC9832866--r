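# two hand-built species networks over an ortholog map ------------------
mkPairNets <- function(r2low = FALSE) {
    tfs1 <- c("a_S", "a_T1", "a_T2"); tfs2 <- c("b_S", "b_T1", "b_T2")
    p1 <- list(c("a_S", "a_T1"), c("a_T1", "a_T2"), c("a_T1", "a_E"))
    # under r2low the T1-T2 correlation fell below the cutoff in species 2,
    # so its thresholded network never contained that edge
    p2 <- if (r2low) list(c("b_S", "b_T1"), c("b_T1", "b_E"))
          else list(c("b_S", "b_T1"), c("b_T1", "b_T2"), c("b_T1", "b_E"))
    n1 <- mkNet(p1, tfs1, "a_S", r = 0.9)
    n2 <- mkNet(p2, tfs2, "b_S", r = 0.9)
    orth <- data.frame(gene1 = c("a_S", "a_T1", "a_T2", "a_E"),
                       gene2 = c("b_S", "b_T1", "b_T2", "b_E"),
                       stringsAsFactors = FALSE)
    list(n1 = n1, n2 = n2, orth = orth)
}

test_that("identical networks under an identity map give full consensus", {
    x <- mkPairNets()
    cons <- consensusNetwork(x$n1, x$n2, x$orth)
    expect_equal(nrow(cons@edges), nrow(x$n1@edges))
    expect_true(all(cons@edges$r1 >= 0.81 & cons@edges$r2 >= 0.81))
    spec <- specificNetworks(x$n1, x$n2, cons, x$orth)
    expect_equal(nrow(spec$specific1@edges), 0L)
    expect_equal(nrow(spec$specific2@edges), 0L)
    # merged levels re-derived from the merged seed
    expect_equal(cons@levels[["a_S|b_S"]], 1L)
    expect_equal(cons@levels[["a_T1|b_T1"]], 2L)
})

test_that("an edge below the cutoff in species 2 fails the C1+C2+ rule", {
    x <- mkPairNets(r2low = TRUE)
    cons <- consensusNetwork(x$n1, x$n2, x$orth)
    keys <- paste(cons@edges$a, cons@edges$b)
    expect_false(any(grepl("T2", keys)))
    spec <- specificNetworks(x$n1, x$n2, cons, x$orth)
    expect_true(any(grepl("T2", paste(spec$specific1@edges$a,
                                      spec$specific1@edges$b))))
})

test_that("an empty ortholog map gives an empty consensus", {
    x <- mkPairNets()
    cons <- consensusNetwork(x$n1, x$n2,
                             data.frame(gene1 = character(),
                                        gene2 = character()))
    expect_equal(nrow(cons@edges), 0L)
    spec <- specificNetworks(x$n1, x$n2, cons, x$orth)
    expect_equal(nrow(spec$specific1@edges), nrow(x$n1@edges))
})

test_that("edges between unmapped genes are species-specific", {
    x <- mkPairNets()
    orth <- x$orth[x$orth$gene1 != "a_E", ]        # unmap the enzyme
    cons <- consensusNetwork(x$n1, x$n2, orth)
    spec <- specificNetworks(x$n1, x$n2, cons, orth)
    expect_true("a_E" %in% spec$specific1@edges$b)
    expect_true("b_E" %in% spec$specific2@edges$b)
})

test_that("consensus/specific is a partition and is symmetric in species order", {
    for (sd in 1:6) {
        cfg <- smallConfig(100 + sd)
        res <- recoveryRun(cfg, runDE = FALSE)
        tg <- res$togcns; comp <- res$comparative
        key <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
        for (s in 1:2) {
            consKeys <- key(
                TOGCNet:::splitMerged(comp@consensus@edges$a, s),
                TOGCNet:::splitMerged(comp@consensus@edges$b, s))
            specE <- if (s == 1) comp@specific1@edges else comp@specific2@edges
            eK <- key(tg[[s]]@edges$a, tg[[s]]@edges$b)
            sK <- key(specE$a, specE$b)
            inCons <- eK %in% consKeys
            inSpec <- eK %in% sK
            expect_true(all(xor(inCons, inSpec)))  # exactly one side
        }
        expect_true(all(comp@consensus@edges$r1 >= 0.81 &
                        comp@consensus@edges$r2 >= 0.81))
        # swapping species yields the same merged edge set, labels swapped
        orthSwap <- data.frame(gene1 = res$truth@orthologPairs$gene2,
                               gene2 = res$truth@orthologPairs$gene1)
        consSwap <- consensusNetwork(tg[[2]], tg[[1]], orthSwap)
        k1 <- sort(key(TOGCNet:::splitMerged(comp@consensus@edges$a, 1),
                       TOGCNet:::splitMerged(comp@consensus@edges$b, 1)))
        k2 <- sort(key(TOGCNet:::splitMerged(consSwap@edges$a, 2),
                       TOGCNet:::splitMerged(consSwap@edges$b, 2)))
        expect_identical(k1, k2)
    }
})

test_that("stage mapping follows the argmax rule and the fixed map", {
    prof <- rbind(s = c(10, 8, 6, 4, 2),     # peak T1 -> initial
                  m = c(1, 2, 9, 2, 1),      # peak T3 -> transitional
                  l = c(1, 2, 3, 9, 8))      # peak T4 -> terminal
    net <- new("TOGCN",
               edges = data.frame(a = c("s", "m"), b = c("m", "l"),
                                  r = c(0.9, 0.9), a_is_tf = TRUE,
                                  b_is_tf = TRUE),
               levels = c(s = 1L, m = 2L, l = 3L), unleveled = character(),
               seed = "s", cutoff = 0.81, profiles = prof,
               tfNodes = c("s", "m", "l"), provenance = list())
    sm <- stageMap(net, rule = "profile")
    expect_identical(sm$stage, c("initial", "transitional", "terminal"))

    net7 <- net
    net7@levels <- stats::setNames(1:7, paste0("n", 1:7))
    fm <- stageMap(net7, rule = "fixed")
    expect_identical(fm$stage,
                     c(rep("initial", 3), "transitional", rep("terminal", 3)))
})

test_that("subnetwork extraction includes enzymes of the stage plus their TFs", {
    tfs <- c("S", "A", "B", "C")
    pairs <- list(c("S", "A"), c("A", "B"), c("B", "C"),
                  c("A", "E1"), c("B", "E1"), c("C", "E1"), c("A", "B"))
    net <- mkNet(pairs, tfs, "S")
    catalog <- GeneCatalog(data.frame(
        gene_id = c(tfs, "E1"), is_tf = c(rep(TRUE, 4), FALSE),
        tf_family = c("bHLH", "WRKY", "ERF", "B3", ""),
        pathway = c(rep("none", 4), "carotenoid"),
        length = rep(1000, 5)))
    sub <- extractSubnetwork(net, catalog, "carotenoid")
    # E1 + its three TF neighbours; TF-TF edges among included TFs kept
    expect_setequal(names(sub@levels), c("E1", "A", "B", "C"))
    expect_equal(sum(!sub@edges$b_is_tf), 3L)       # three TF-enzyme edges
    expect_true(all(sub@edges$a_is_tf))
    deg <- nodeDegrees(sub)
    expect_equal(deg$degree[deg$node == "E1"], 3L)

    none <- extractSubnetwork(net, catalog, "flavonol")
    expect_equal(length(none@levels), 0L)

    solo <- extractSubnetwork(net, catalog, "carotenoid",
                              includeRegulatingTFs = FALSE)
    expect_equal(nrow(solo@edges), 0L)              # enzymes only, no edges
    expect_error(extractSubnetwork(net, catalog, "nope"), "carotenoid")
})

test_that("degrees match brute-force incidence counting on random graphs", {
    set.seed(17)
    for (rep in 1:20) {
        n <- sample(6:14, 1)
        tfs <- paste0("t", seq_len(n))
        prs <- which(upper.tri(matrix(0, n, n)) &
                     matrix(runif(n * n) < 0.35, n, n), arr.ind = TRUE)
        if (!nrow(prs)) next
        pairs <- lapply(seq_len(nrow(prs)), function(i)
            c(tfs[prs[i, 1]], tfs[prs[i, 2]]))
        net <- mkNet(pairs, tfs, "t1", nodes = tfs)
        deg <- nodeDegrees(net)
        for (i in seq_len(nrow(deg))) {
            nd <- deg$node[i]
            expect_equal(deg$degree[i],
                         sum(net@edges$a == nd) + sum(net@edges$b == nd))
        }
    }
})

test_that("hub calling is inclusive at the cutoff and monotone", {
    deg <- data.frame(node = c("A", "B", "C"), degree = c(45L, 40L, 30L),
                      is_tf = FALSE, level = 1L)
    expect_setequal(callHubs(deg, 40), c("A", "B"))  # 40 itself included
    expect_setequal(callHubs(deg, 0), c("A", "B", "C"))
    expect_true(all(callHubs(deg, 41) %in% callHubs(deg, 40)))
    expect_error(callHubs(deg, -1), ">= 0")
})

test_that("regulator hierarchy walks strictly earlier levels upstream", {
    # chain TF_c(L2) - TF_b(L3) - TF_a(L4) - hub(E, level 4)
    tfs <- c("S", "TF_c", "TF_b", "TF_a")
    pairs <- list(c("S", "TF_c"), c("TF_c", "TF_b"), c("TF_b", "TF_a"),
                  c("TF_a", "E"))
    net <- mkNet(pairs, tfs, "S")
    ch <- resolveHierarchy(net, "E")
    expect_identical(ch@tiers$direct, "TF_a")
    expect_identical(ch@tiers$second, "TF_b")
    expect_identical(ch@tiers$third, "TF_c")
    expect_equal(length(intersect(ch@tiers$direct, ch@tiers$second)), 0L)

    ch1 <- resolveHierarchy(net, "E", maxTiers = 1L)
    expect_identical(names(ch1@tiers), "direct")

    # a hub with no TF neighbours yields empty tiers
    net2 <- mkNet(list(c("S", "A"), c("A", "E")), c("S", "A"), "S")
    lonely <- resolveHierarchy(net2, "S")   # seed's only upstream is itself
    expect_equal(length(lonely@tiers$second), 0L)
    expect_error(resolveHierarchy(net, "missing"), "not a network node")
})
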