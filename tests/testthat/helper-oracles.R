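# Independent oracles and fixture builders shared across test files.

# Edges on the path from a tip to the root, as row indices of tree$edge.
# Deliberately a per-leaf path walk, independent of the package's
# edge-incidence accumulation.
pathEdges <- function(tree, tipIdx) {
    out <- integer(0)
    node <- tipIdx
    root <- length(tree$tip.label) + 1L
    while (node != root) {
        e <- which(tree$edge[, 2L] == node)
        out <- c(out, e)
        node <- tree$edge[e, 1L]
    }
    out
}

bruteUnweightedUnifrac <- function(a, b, tree) {
    tips <- tree$tip.label
    setA <- unique(unlist(lapply(which(tips %in% names(a)[a > 0]),
                                 pathEdges, tree = tree)))
    setB <- unique(unlist(lapply(which(tips %in% names(b)[b > 0]),
                                 pathEdges, tree = tree)))
    uni <- sum(tree$edge.length[union(setdiff(setA, setB),
                                      setdiff(setB, setA))])
    tot <- sum(tree$edge.length[union(setA, setB)])
    if (tot == 0) 0 else uni / tot
}

bruteWeightedUnifrac <- function(a, b, tree, normalized = TRUE) {
    tips <- tree$tip.label
    fracUnder <- function(v) {
        A <- numeric(nrow(tree$edge))
        for (i in seq_along(tips)) {
            w <- if (tips[i] %in% names(v)) v[[tips[i]]] else 0
            A[pathEdges(tree, i)] <- A[pathEdges(tree, i)] + w
        }
        A
    }
    A <- fracUnder(a); B <- fracUnder(b)
    d <- sum(tree$edge.length * abs(A - B))
    if (!normalized) return(d)
    denom <- sum(tree$edge.length * (A + B))
    if (denom == 0) 0 else d / denom
}

# Random named abundance vector over a tree's tips (some zeros).
randomSampleOnTree <- function(tree, proportions = FALSE) {
    k <- length(tree$tip.label)
    v <- rexp(k) * rbinom(k, 1L, 0.7)
    if (sum(v) == 0) v[sample.int(k, 1L)] <- 1
    if (proportions) v <- v / sum(v)
    structure(v, names = tree$tip.label)
}

# Small valid random FeatureTable (counts) with taxonomy.
randomFeatureTable <- function(nSamples = 5L, nTaxa = 6L) {
    m <- matrix(rpois(nSamples * nTaxa, 8), nSamples, nTaxa,
                dimnames = list(paste0("S", seq_len(nSamples)),
                                paste0("t", seq_len(nTaxa))))
    m[1L, ] <- m[1L, ] + 1L   # no empty sample
    tax <- structure(sprintf(
        "k__Bacteria;p__P%d;c__C;o__O;f__F%d;g__G%d",
        seq_len(nTaxa) %% 3L, seq_len(nTaxa) %% 2L, seq_len(nTaxa)),
        names = colnames(m))
    FeatureTable(m, unit = "counts", taxonomy = tax)
}

# Four-leaf worked-example tree used throughout the beta-diversity tests.
cherryTree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

expect_identical_tables <- function(x, y) {
    expect_equal(abundances(x), abundances(y))
    expect_identical(abundanceUnit(x), abundanceUnit(y))
}
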