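test_that("unweighted UniFrac reproduces the worked branch-set examples", {
    tr <- cherryTree()
    expect_equal(unweightedUnifrac(c(A = 1), c(C = 1), tr), 1)
    expect_equal(unweightedUnifrac(c(A = 1, B = 1), c(A = 1, C = 2), tr),
                 0.6)
    expect_equal(unweightedUnifrac(c(A = 1, B = 2), c(A = 3, B = 1), tr), 0)
    expect_error(unweightedUnifrac(c(Z = 1), c(A = 1), tr), "missing from tree")
    expect_error(unweightedUnifrac(c(A = 0), c(B = 0), tr), "empty")
})

test_that("weighted UniFrac matches the star-tree closed form and is symmetric", {
    star <- ape::read.tree(text = "(X:1,Y:1);")
    expect_equal(weightedUnifrac(c(X = 1), c(Y = 1), star), 1)
    expect_equal(weightedUnifrac(c(X = 1), c(Y = 1), star,
                                 normalized = FALSE), 2)
    a <- c(X = 0.3, Y = 0.7); b <- c(X = 0.8, Y = 0.2)
    expect_equal(weightedUnifrac(a, b, star), weightedUnifrac(b, a, star))
    expect_equal(weightedUnifrac(a, a, star), 0)
})

test_that("both kernels equal the brute-force branch-set oracle on random trees", {
    set.seed(12)
    for (i in 1:25) {
        nl <- sample(3:16, 1)
        tr <- generateTree(paste0("t", seq_len(nl)), seed = 100 + i)
        a <- randomSampleOnTree(tr, proportions = TRUE)
        b <- randomSampleOnTree(tr, proportions = TRUE)
        expect_equal(unweightedUnifrac(a, b, tr),
                     bruteUnweightedUnifrac(a, b, tr))
        expect_equal(weightedUnifrac(a, b, tr),
                     bruteWeightedUnifrac(a, b, tr))
        d <- unweightedUnifrac(a, b, tr)
        expect_gte(d, 0); expect_lte(d, 1)
    }
})

test_that("unweighted UniFrac is zero iff presence sets agree and obeys the triangle inequality", {
    set.seed(13)
    tr <- generateTree(paste0("t", 1:10), seed = 77)
    for (i in 1:20) {
        a <- randomSampleOnTree(tr); b <- randomSampleOnTree(tr)
        cc <- randomSampleOnTree(tr)
        dab <- unweightedUnifrac(a, b, tr)
        expect_equal(dab == 0, identical(unname(a > 0), unname(b > 0)))
        expect_lte(dab, unweightedUnifrac(a, cc, tr) +
                        unweightedUnifrac(cc, b, tr) + 1e-12)
    }
})

test_that("the pairwise distance matrix matches per-pair kernel calls", {
    set.seed(14)
    tr <- generateTree(paste0("t", 1:8), seed = 5)
    m <- matrix(rpois(40, 6), 5, 8,
                dimnames = list(paste0("S", 1:5), tr$tip.label))
    m[2, ] <- m[1, ]                       # identical pair -> zero distance
    m[m == 0] <- 0
    ft <- FeatureTable(m, unit = "counts")
    rel <- toRelativeAbundance(ft)
    for (metric in c("unweighted_unifrac", "weighted_unifrac")) {
        dm <- distanceMatrix(rel, tr, metric)
        expect_equal(dm, t(dm))
        expect_equal(dm[1, 2], 0)
        kern <- if (metric == "unweighted_unifrac") unweightedUnifrac
                else weightedUnifrac
        for (i in 1:4) for (j in (i + 1):5)
            expect_equal(dm[i, j],
                         kern(abundances(rel)[i, ], abundances(rel)[j, ], tr),
                         tolerance = 1e-12)
        expect_equal(dm, distanceMatrix(rel, tr, metric))  # deterministic
    }
})

test_that("PCoA reproduces the hand-computed eigensystems", {
    d2 <- matrix(c(0, 2, 2, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    ord <- pcoa(d2)
    expect_equal(ord$eigenvalues, c(2, 0))
    expect_equal(abs(ord$coordinates[, 1]), c(a = 1, b = 1))

    deq <- matrix(1, 3, 3) - diag(3)
    dimnames(deq) <- list(letters[1:3], letters[1:3])
    orde <- pcoa(deq)
    expect_equal(orde$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-12)
    expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b")))),
                 "symmetric")
})

test_that("PCoA reconstructs Euclidean distances and matches cmdscale", {
    set.seed(15)
    for (i in 1:5) {
        n <- sample(4:9, 1)
        pts <- matrix(rnorm(n * 3), n)
        rownames(pts) <- paste0("S", 1:n)
        dm <- as.matrix(dist(pts))
        ord <- pcoa(dm)
        rec <- as.matrix(dist(ord$coordinates))
        expect_lt(max(abs(rec - dm)), 1e-8)
        # trace of the centred matrix equals the eigenvalue sum
        A <- -0.5 * dm^2
        J <- diag(n) - matrix(1 / n, n, n)
        expect_equal(sum(diag(J %*% A %*% J)), sum(ord$eigenvalues),
                     tolerance = 1e-8)
        # cross-check the eigenvalues against the classical-MDS reference
        ref <- cmdscale(dm, k = 2, eig = TRUE)
        expect_equal(ord$eigenvalues[seq_len(3)], ref$eig[seq_len(3)],
                     tolerance = 1e-8)
    }
})

test_that("distance-to-group means average over the reference samples", {
    dm <- matrix(0, 3, 3, dimnames = list(c("P", "C1", "C2"),
                                          c("P", "C1", "C2")))
    dm["P", "C1"] <- dm["C1", "P"] <- 0.2
    dm["P", "C2"] <- dm["C2", "P"] <- 0.4
    dm["C1", "C2"] <- dm["C2", "C1"] <- 0.1
    meta <- data.frame(sample_id = c("P", "C1", "C2"),
                       group = c("T2D", "control", "control"),
                       stringsAsFactors = FALSE)
    out <- distancesToGroup(dm, meta, "control")
    expect_equal(out$mean_distance[out$sample_id == "P"], 0.3)
    # reference samples use the other reference members only
    expect_equal(out$mean_distance[out$sample_id == "C1"], 0.1)
    # identical to every control -> zero
    dm0 <- dm; dm0["P", c("C1", "C2")] <- dm0[c("C1", "C2"), "P"] <- 0
    out0 <- distancesToGroup(dm0, meta, "control")
    expect_equal(out0$mean_distance[out0$sample_id == "P"], 0)
    expect_error(distancesToGroup(dm, meta, "AIS"), "empty")
})

test_that("PERMANOVA matches the exhaustive two-plus-two enumeration", {
    dm <- matrix(1, 4, 4) - diag(4)
    dm[1, 2] <- dm[2, 1] <- 0
    dm[3, 4] <- dm[4, 3] <- 0
    dimnames(dm) <- list(paste0("S", 1:4), paste0("S", 1:4))
    meta <- data.frame(sample_id = paste0("S", 1:4),
                       group = c("T2D", "T2D", "control", "control"),
                       stringsAsFactors = FALSE)
    # of the 3 distinct 2+2 partitions only the observed one attains F
    out <- permanova(dm, meta, nPermutations = 999, seed = 4)
    expect_lt(abs(out$p.value - 1 / 3), 0.05)
    expect_equal(out$p.value,
                 permanova(dm, meta, nPermutations = 999, seed = 4)$p.value)
})

test_that("PERMANOVA pseudo-F is relabeling invariant and matches vegan", {
    set.seed(16)
    n <- 12
    pts <- matrix(rnorm(n * 2), n)
    pts[7:12, ] <- pts[7:12, ] + 1.5
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("S", 1:n), paste0("S", 1:n))
    meta <- data.frame(sample_id = paste0("S", 1:n),
                       group = rep(c("control", "T2D"), each = 6),
                       stringsAsFactors = FALSE)
    out <- permanova(dm, meta, nPermutations = 99, seed = 1)
    ref <- vegan::adonis2(as.dist(dm) ~ group, data = meta,
                          permutations = 99)
    expect_equal(out$pseudoF, ref$F[1], tolerance = 1e-10)
    # permuting sample order (rows+cols together) leaves F unchanged
    perm <- sample(n)
    out2 <- permanova(dm[perm, perm], meta[perm, ], nPermutations = 99,
                      seed = 1)
    expect_equal(out2$pseudoF, out$pseudoF, tolerance = 1e-10)
    expect_error(permanova(dm, within(meta, group[1] <- "AIS")[], "group"),
                 "singleton")
})
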