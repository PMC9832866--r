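# shared fixture builders -----------------------------------------------

# TimeCourseSet from a genes x (D*R) matrix laid out T1_R1..T1_RR, T2_R1, ...
mkTCS <- function(mat, D, R, lengths = rep(1000, nrow(mat))) {
    mat <- as.matrix(mat)
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
    TimeCourseSet(mat, timePoint = rep(seq_len(D), each = R),
                  replicate = rep(seq_len(R), D), geneLength = lengths)
}

# CoexpressionEdgeSet from an explicit undirected edge list
esFromEdges <- function(pairs, tfs, nodes = NULL, r = 0.9, cutoff = 0.81) {
    a <- vapply(pairs, `[`, character(1), 1L)
    b <- vapply(pairs, `[`, character(1), 2L)
    swapNeeded <- !(a %in% tfs)
    tmp <- a[swapNeeded]; a[swapNeeded] <- b[swapNeeded]; b[swapNeeded] <- tmp
    bTF <- b %in% tfs
    swap <- bTF & b < a
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    if (is.null(nodes)) nodes <- union(a, b)
    e <- data.frame(a = a, b = b, r = rep_len(r, length(a)),
                    a_is_tf = TRUE, b_is_tf = bTF, stringsAsFactors = FALSE)
    new("CoexpressionEdgeSet", edges = e, nodes = nodes,
        tfNodes = intersect(nodes, tfs), cutoff = cutoff, mode = "C1+")
}

# TOGCN from explicit edges + a seed (levels derived by the package itself)
mkNet <- function(pairs, tfs, seed, nodes = NULL, r = 0.9) {
    es <- esFromEdges(pairs, tfs, nodes, r)
    lm <- assignLevels(es, seed)
    attachTargets(es, lm)
}

# small simulation configs used across tests
smallConfig <- function(seed, ...) {
    simulationConfig(seed = seed, nLevels = 3L, tfsPerLevel = 3L,
                     specificFraction = 1 / 3,
                     nEnzymeGenes = c(carotenoid = 2L, flavonol = 2L),
                     nHubEnzymes = 1L, nBackgroundGenes = 6L,
                     promoterLength = 200L, ...)
}

# brute-force Pearson correlation from first principles
corOracle <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    (n * sum(x * y) - sx * sy) /
        sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
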