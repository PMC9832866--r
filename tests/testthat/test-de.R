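test_that("pairwise log2 fold change follows the pseudocounted mean formula", {
    # group mean TPM 2 vs 16 with pseudocount 1 -> log2(17/3)
    tpmv <- rbind(g1 = c(2, 2, 2, 16, 16, 16),
                  g2 = c(5, 5, 5, 5, 5, 5))
    cnt <- tpmv  # counts unused by the fold-change arithmetic
    tcs <- TimeCourseSet(cnt, timePoint = rep(1:2, each = 3),
                         replicate = rep(1:3, 2), tpm = tpmv,
                         geneLength = c(1000, 1000))
    de <- pairwiseDE(tcs)
    tab <- deTable(de)
    expect_equal(tab$log2FC[tab$gene == "g1"], log2(17 / 3))
    expect_gt(abs(log2(17 / 3)), 1)          # passes the lfc cutoff
    expect_equal(tab$log2FC[tab$gene == "g2"], 0)
})

test_that("identical replicate values give log2FC 0 and no DEG call", {
    tpmv <- matrix(3, 2, 6, dimnames = list(c("a", "b"), NULL))
    tcs <- TimeCourseSet(tpmv, rep(1:2, each = 3), rep(1:3, 2),
                         tpm = tpmv, geneLength = c(1, 1))
    de <- pairwiseDE(tcs)
    expect_true(all(deTable(de)$log2FC == 0))
    expect_false(any(de@degFlags))
})

test_that("adjusted p-values dominate raw p and DEG set is threshold-monotone", {
    set.seed(42)
    D <- 3; R <- 4
    cnt <- matrix(rnbinom(30 * D * R, mu = rep(c(50, 500), length.out = 30 * D * R),
                          size = 10), nrow = 30)
    tcs <- mkTCS(cnt, D, R)
    de <- pairwiseDE(tcs)
    tab <- deTable(de)
    expect_true(all(tab$padj >= tab$p - 1e-12))
    # DEG flag definition
    agg <- tapply(tab$significant, tab$gene, any)
    expect_identical(as.logical(agg[names(de@degFlags)]),
                     unname(de@degFlags))
    # lowering the FDR cutoff never adds genes
    de2 <- pairwiseDE(tcs, fdrCutoff = 0.01)
    expect_true(all(degGenes(de2) %in% degGenes(de)))
    de3 <- pairwiseDE(tcs, lfcCutoff = 2)
    expect_true(all(degGenes(de3) %in% degGenes(de)))
})

test_that("DE requires two replicates per time point", {
    cnt <- matrix(rpois(12, 10), 2, dimnames = list(c("g1", "g2"), NULL))
    tcs <- TimeCourseSet(cnt, timePoint = c(1, 1, 1, 2, 2, 3),
                         replicate = c(1, 2, 3, 1, 2, 1),
                         geneLength = c(1000, 1000))
    expect_error(pairwiseDE(tcs), "fewer than 2 replicates")
})

test_that("expressed-DEG selection applies the strict mean-TPM floor", {
    tpmv <- rbind(deg_low = c(0.2, 0.2, 0.6, 0.6),    # mean 0.4
                  deg_edge = c(0.4, 0.4, 0.6, 0.6),   # mean exactly 0.5
                  deg_ok  = c(2, 2, 40, 40),
                  flat    = c(100, 100, 100, 100))
    tcs <- TimeCourseSet(tpmv, rep(1:2, each = 2), rep(1:2, 2),
                         tpm = tpmv, geneLength = rep(1, 4))
    de <- pairwiseDE(tcs)
    fake <- de
    fake@degFlags[] <- c(TRUE, TRUE, TRUE, FALSE)   # force known DEG flags
    sel <- selectExpressedDEGs(tcs, fake)
    expect_identical(sel, "deg_ok")   # 0.4 out, 0.5 out (strict), non-DEG out
    # idempotent / order independent
    tcs2 <- tcs[rev(seq_len(nrow(tcs))), ]
    fake2 <- fake
    fake2@degFlags <- fake@degFlags[rev(names(fake@degFlags))]
    expect_setequal(selectExpressedDEGs(tcs2, fake2), sel)
})

test_that("seed-TF ranking demands a strict monotone decrease", {
    tpmv <- rbind(good = rep(c(10, 8, 6, 4, 2), each = 2),
                  up   = rep(c(2, 4, 6, 8, 10), each = 2),
                  tie  = rep(c(10, 10, 6, 4, 2), each = 2))
    tcs <- TimeCourseSet(tpmv, rep(1:5, each = 2), rep(1:2, 5),
                         tpm = tpmv, geneLength = rep(1, 3))
    out <- selectSeedTFs(tcs, c("good", "up", "tie"))
    expect_identical(out$gene[out$eligible], "good")
    expect_equal(out$score[out$gene == "good"], 10)
    expect_false(out$eligible[out$gene == "up"])
    expect_false(out$eligible[out$gene == "tie"])  # tie breaks monotonicity
    expect_error(selectSeedTFs(tcs, character(0)), "no TF ids")
})
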