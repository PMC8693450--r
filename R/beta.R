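# Beta diversity: UniFrac kernels from a rooted tree, pairwise distance
# matrices, PCoA ordination, distance-to-reference summaries and PERMANOVA.

# Edge/tip incidence of a rooted tree: one row per edge, TRUE where the tip
# descends from that edge. The root itself has no edge (a root edge, if set,
# is ignored: shared root length is uninformative for UniFrac).
.edgeTipIncidence <- function(tree) {
    key <- paste0("inc_", md5Of(ape::write.tree(tree)))
    cached <- .dysbCache[[key]]
    if (!is.null(cached)) return(cached)
    tre <- stats::reorder(tree, "postorder")
    nt <- length(tre$tip.label)
    nn <- nt + tre$Nnode
    M <- matrix(FALSE, nn, nt)
    M[cbind(seq_len(nt), seq_len(nt))] <- TRUE
    for (i in seq_len(nrow(tre$edge))) {
        p <- tre$edge[i, 1L]; ch <- tre$edge[i, 2L]
        M[p, ] <- M[p, ] | M[ch, ]
    }
    E <- M[tre$edge[, 2L], , drop = FALSE]
    colnames(E) <- tre$tip.label
    out <- list(incidence = E, lengths = tre$edge.length)
    .dysbCache[[key]] <- out
    out
}

# Map a named abundance vector onto the tree's tip order (absent tips = 0);
# any nonzero taxon missing from the tree is an error.
.tipVector <- function(a, tipLabels, what) {
    if (!is.numeric(a) || is.null(names(a)))
        stop(what, " must be a named numeric vector")
    nz <- names(a)[a > 0]
    missing <- setdiff(nz, tipLabels)
    if (length(missing))
        stop("nonzero taxon missing from tree: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    v <- structure(numeric(length(tipLabels)), names = tipLabels)
    common <- intersect(names(a), tipLabels)
    v[common] <- a[common]
    v
}

#' Unweighted UniFrac distance between two samples
#'
#' Fraction of total branch length leading to leaves present (abundance
#' strictly > 0) in exactly one of the two samples, over branch length
#' leading to leaves present in either; each branch counted once, the root
#' edge excluded.
#'
#' @param a,b named numeric abundance vectors (any unit; presence = > 0).
#' @param tree rooted [ape::phylo] with branch lengths; every taxon with
#'   nonzero abundance must be a tree leaf.
#' @return distance in \[0, 1\].
#' @export
unweightedUnifrac <- function(a, b, tree) {
    inc <- .edgeTipIncidence(tree)
    tips <- colnames(inc$incidence)
    va <- .tipVector(a, tips, "a") > 0
    vb <- .tipVector(b, tips, "b") > 0
    if (!any(va) && !any(vb)) stop("both samples empty")
    Ea <- as.vector(inc$incidence %*% va) > 0
    Eb <- as.vector(inc$incidence %*% vb) > 0
    l <- inc$lengths
    uni <- sum(l[xor(Ea, Eb)])
    tot <- sum(l[Ea | Eb])
    if (tot == 0) 0 else uni / tot
}

#' Weighted UniFrac distance between two samples
#'
#' `sum_e l_e * |A_e - B_e|` where `A_e` is the fraction of sample `a`
#' descending from edge `e`; if `normalized`, divided by the leaf-depth
#' normaliser `sum_e l_e * (A_e + B_e)` so the result lies in \[0, 1\].
#'
#' @param a,b named numeric vectors of proportions over tree leaves.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param normalized logical, default `TRUE`.
#' @return distance >= 0 (in \[0, 1\] when normalised).
#' @export
weightedUnifrac <- function(a, b, tree, normalized = TRUE) {
    inc <- .edgeTipIncidence(tree)
    tips <- colnames(inc$incidence)
    va <- .tipVector(a, tips, "a")
    vb <- .tipVector(b, tips, "b")
    for (nm in c("a", "b")) {
        s <- sum(if (nm == "a") va else vb)
        if (abs(s - 1) > 1e-6)
            stop(nm, " must be proportions summing to 1 over tree leaves")
    }
    A <- as.vector(inc$incidence %*% va)
    B <- as.vector(inc$incidence %*% vb)
    l <- inc$lengths
    d <- sum(l * abs(A - B))
    if (!normalized) return(d)
    denom <- sum(l * (A + B))
    if (denom == 0) 0 else d / denom
}

#' Pairwise UniFrac distance matrix for a feature table
#'
#' Computes all sample pairs with the chosen kernel, vectorised over the
#' tree's edge incidence; entries match per-pair kernel calls exactly and
#' the result is symmetric by construction.
#'
#' @param x a [FeatureTable-class] (any unit for unweighted; proportions
#'   required for weighted).
#' @param tree rooted [ape::phylo] covering all nonzero taxa.
#' @param metric `"unweighted_unifrac"` or `"weighted_unifrac"`.
#' @param normalized for the weighted metric, default `TRUE`.
#' @return symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
distanceMatrix <- function(x, tree,
                           metric = c("unweighted_unifrac",
                                      "weighted_unifrac"),
                           normalized = TRUE) {
    metric <- match.arg(metric)
    stopifnot(is(x, "FeatureTable"))
    v <- abundances(x)
    if (metric == "weighted_unifrac" && abundanceUnit(x) != "proportions")
        stop("weighted UniFrac requires proportions; ",
             "call toRelativeAbundance() first")
    inc <- .edgeTipIncidence(tree)
    tips <- colnames(inc$incidence)
    nz <- colnames(v)[colSums(v) > 0]
    missing <- setdiff(nz, tips)
    if (length(missing))
        stop("nonzero taxon missing from tree: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    tv <- matrix(0, length(tips), nrow(v), dimnames = list(tips, rownames(v)))
    common <- intersect(colnames(v), tips)
    tv[common, ] <- t(v[, common, drop = FALSE])
    EA <- inc$incidence %*% tv                     # edges x samples
    l <- inc$lengths
    n <- nrow(v)
    if (metric == "unweighted_unifrac") {
        B <- (EA > 0) * 1
        shared <- crossprod(B * l, B)              # sum l over both-present
        si <- colSums(B * l)
        union <- outer(si, si, "+") - shared
        uni <- outer(si, si, "+") - 2 * shared
        D <- ifelse(union > 0, uni / union, 0)
    } else {
        D <- matrix(0, n, n)
        for (i in seq_len(n))
            D[i, ] <- colSums(l * abs(EA - EA[, i]))
        if (normalized) {
            si <- colSums(l * EA)
            denom <- outer(si, si, "+")
            D <- ifelse(denom > 0, D / denom, 0)
        }
    }
    dimnames(D) <- list(rownames(v), rownames(v))
    D <- (D + t(D)) / 2
    D[D < 0] <- 0            # clip floating-point negatives near zero
    diag(D) <- 0
    D
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centring of `-D^2/2` followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by `sqrt(lambda)`
#' for positive eigenvalues; negative eigenvalues are reported and their
#' axes zeroed (no Cailliez/Lingoes correction).
#'
#' @param dm symmetric distance matrix (zero diagonal).
#' @param k number of axes to return (default: all positive axes).
#' @return list of class `"Ordination"`: `coordinates` (samples x k),
#'   `eigenvalues` (descending, length n), `proportionExplained` (per
#'   returned axis, over positive eigenvalues).
#' @export
pcoa <- function(dm, k = NULL) {
    .checkDistanceMatrix(dm)
    n <- nrow(dm)
    if (n < 2L) stop("need at least 2 samples")
    A <- -0.5 * dm^2
    J <- diag(n) - matrix(1 / n, n, n)
    B <- J %*% A %*% J
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    lambda <- e$values
    pos <- lambda > max(lambda[1L], 0) * 1e-12 & lambda > 0
    if (is.null(k)) k <- max(1L, sum(pos))
    k <- min(k, n)
    coords <- matrix(0, n, k,
                     dimnames = list(rownames(dm), paste0("PCo", seq_len(k))))
    usable <- which(pos)[which(pos) <= k]
    for (j in usable)
        coords[, j] <- e$vectors[, j] * sqrt(lambda[j])
    sumPos <- sum(lambda[pos])
    propExp <- ifelse(seq_len(k) %in% which(pos),
                      lambda[seq_len(k)] / sumPos, 0)
    structure(list(coordinates = coords, eigenvalues = lambda,
                   proportionExplained = propExp),
              class = "Ordination")
}

#' @export
print.Ordination <- function(x, ...) {
    cat(sprintf("PCoA ordination: %d samples, %d axes returned\n",
                nrow(x$coordinates), ncol(x$coordinates)))
    cat("  eigenvalues: ",
        paste(signif(utils::head(x$eigenvalues, 5L), 4L), collapse = ", "),
        if (length(x$eigenvalues) > 5L) ", ..." else "", "\n", sep = "")
    neg <- sum(x$eigenvalues < 0)
    if (neg) cat("  (", neg, " negative eigenvalues reported, axes zeroed)\n",
                 sep = "")
    invisible(x)
}

#' Mean distance of each sample to a reference group
#'
#' For each non-reference sample, the mean of its distances to all reference
#' samples; for reference samples, the mean distance to the *other*
#' reference samples.
#'
#' @param dm symmetric distance matrix.
#' @param meta metadata data.frame with `sample_id` and `group`.
#' @param reference reference group label (nonempty; >= 2 members for
#'   within-reference values).
#' @return data.frame with `sample_id`, `group`, `mean_distance`.
#' @export
distancesToGroup <- function(dm, meta, reference = "control") {
    .checkDistanceMatrix(dm)
    meta <- validateMetadata(meta)
    meta <- meta[meta$sample_id %in% rownames(dm), , drop = FALSE]
    refIds <- meta$sample_id[meta$group == reference]
    if (length(refIds) == 0L) stop("reference group is empty")
    out <- vapply(meta$sample_id, function(s) {
        others <- setdiff(refIds, s)
        if (length(others) == 0L)
            stop("reference group needs >= 2 members for within-reference ",
                 "distances")
        mean(dm[s, others])
    }, numeric(1L))
    data.frame(sample_id = meta$sample_id, group = meta$group,
               mean_distance = unname(out), stringsAsFactors = FALSE)
}

# Within-group sum of squared interpoint distances / group size, summed.
.permanovaSSW <- function(d2, groupIdx) {
    ssw <- 0
    for (g in groupIdx)
        ssw <- ssw + sum(d2[g, g]) / (2 * length(g))
    ssw
}

#' PERMANOVA (Adonis) one-way group test
#'
#' Pseudo-F from total versus within-group sums of squared distances;
#' the p-value counts label permutations with `F >= F_observed`, using the
#' `(count + 1) / (n_permutations + 1)` convention so p never returns 0.
#'
#' @param dm symmetric distance matrix.
#' @param meta metadata data.frame with `sample_id` and the grouping column.
#' @param grouping metadata column name, default `"group"`; >= 2 groups,
#'   each with >= 2 samples.
#' @param nPermutations number of label permutations, default 999.
#' @param seed integer seed for the permutation stream (reproducible p).
#' @return list with `pseudoF`, `p.value`, `nPermutations`.
#' @export
permanova <- function(dm, meta, grouping = "group", nPermutations = 999,
                      seed = 1) {
    .checkDistanceMatrix(dm)
    if (!grouping %in% names(meta)) stop("grouping column not in metadata")
    meta <- meta[match(rownames(dm), meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id)) stop("metadata missing samples of the matrix")
    labels <- as.character(meta[[grouping]])
    tabs <- table(labels)
    if (length(tabs) < 2L) stop("need >= 2 groups")
    if (any(tabs < 2L)) stop("singleton group: ",
                             paste(names(tabs)[tabs < 2L], collapse = ", "))
    n <- nrow(dm)
    a <- length(tabs)
    d2 <- dm^2
    sst <- sum(d2) / (2 * n)
    groupIdx <- split(seq_len(n), labels)
    ssw <- .permanovaSSW(d2, groupIdx)
    fObs <- ((sst - ssw) / (a - 1)) / (ssw / (n - a))
    count <- withSeed(seed, {
        hits <- 0L
        for (b in seq_len(nPermutations)) {
            perm <- sample.int(n)
            idx <- split(perm, labels)
            sswP <- .permanovaSSW(d2, idx)
            fP <- ((sst - sswP) / (a - 1)) / (sswP / (n - a))
            if (fP >= fObs - 1e-12) hits <- hits + 1L
        }
        hits
    })
    list(pseudoF = fObs, p.value = (count + 1) / (nPermutations + 1),
         nPermutations = nPermutations)
}
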