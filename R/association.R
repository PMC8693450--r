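# Spearman correlation engine (exact permutation p at small n),
# index-vs-clinical-score analysis, taxon-vs-outcome screens, Pearson
# chi-square and comparative-Ct relative expression.

# All permutations of 1..n as an n!-row matrix (n <= 9; 9! = 362880).
.permutationsMatrix <- function(n) {
    if (n == 1L) return(matrix(1L))
    p <- .permutationsMatrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        cbind(p[, seq_len(i - 1L), drop = FALSE],
              n,
              if (i <= n - 1L) p[, i:(n - 1L), drop = FALSE])
    }))
}

# Tabulated permutation-null distribution of S = sum((rank_x - rank_y)^2)
# for tie-free samples of size n; cached per n.
.spearmanNullS <- function(n) {
    key <- paste0("spearmanS_", n)
    cached <- .dysbCache[[key]]
    if (!is.null(cached)) return(cached)
    pm <- .permutationsMatrix(n)
    base <- matrix(seq_len(n), nrow(pm), n, byrow = TRUE)
    S <- rowSums((pm - base)^2)
    tab <- table(S)
    out <- list(values = as.numeric(names(tab)), counts = as.vector(tab),
                total = nrow(pm))
    .dysbCache[[key]] <- out
    out
}

#' Spearman rank correlation with exact small-n p-values
#'
#' `rho` is the Pearson correlation of (mid-)ranks. In `"exact"` mode
#' (tie-free ranks only, n <= 9) the two-sided p is the fraction of all n!
#' rank permutations with `|rho| >=` the observed value, computed from the
#' complete permutation distribution of the rank-difference statistic. In
#' `"asymptotic"` mode a t-approximation on mid-ranks is used
#' (`t = rho * sqrt((n-2) / (1-rho^2))`, df = n-2). `"auto"` picks exact
#' when n <= 9 and both vectors are tie-free.
#'
#' A constant input vector makes rho undefined: the result carries
#' `degenerate = TRUE` with `rho` and `p.value` `NA` (no NaN propagation).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param pMode `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @return list with `rho`, `p.value`, `n`, `mode`, `degenerate`.
#' @export
spearmanCorrelation <- function(x, y, pMode = c("auto", "exact",
                                                "asymptotic")) {
    pMode <- match.arg(pMode)
    stopIfNotNumericVector(x, "x")
    stopIfNotNumericVector(y, "y")
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (n < 3L) stop("need n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(rho = NA_real_, p.value = NA_real_, n = n,
                    mode = "degenerate", degenerate = TRUE))
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    tieFree <- anyDuplicated(x) == 0L && anyDuplicated(y) == 0L
    if (pMode == "auto")
        pMode <- if (n <= 9L && tieFree) "exact" else "asymptotic"
    if (pMode == "exact") {
        if (!tieFree) stop("exact mode requires tie-free x and y")
        if (n > 9L) stop("exact mode limited to n <= 9")
        S <- sum((rx - ry)^2)
        M <- n * (n^2 - 1) / 6          # null centre; rho = 1 - S/M... * 6
        null <- .spearmanNullS(n)
        hits <- sum(null$counts[abs(null$values - M) >= abs(S - M) - 1e-9])
        p <- hits / null$total
    } else {
        if (abs(rho) >= 1) {
            p <- .Machine$double.xmin
        } else {
            tstat <- rho * sqrt((n - 2) / (1 - rho^2))
            p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
        }
    }
    list(rho = rho, p.value = max(p, .Machine$double.xmin), n = n,
         mode = pMode, degenerate = FALSE)
}

#' Correlate index scores with clinical severity scores
#'
#' Spearman correlation (mid-ranks; clinical scores are heavily tied)
#' between per-sample dysbiosis index scores and each clinical score over
#' all stroke samples (groups AIS and AIS_T2D) carrying that score.
#'
#' @param scores data.frame from [computeIndexTable()].
#' @param meta metadata data.frame with `sample_id`, `group` and score
#'   columns.
#' @param targets score column names, default `c("NIHSS", "mRS", "Essen")`.
#' @param alpha significance level for the `significant` flag, default 0.05.
#' @return data.frame of correlation records (feature_id, target_name, rho,
#'   p_value, n, significant).
#' @export
scoreCorrelations <- function(scores, meta,
                              targets = c("NIHSS", "mRS", "Essen"),
                              alpha = 0.05) {
    meta <- validateMetadata(meta)
    stroke <- meta[meta$group %in% c("AIS", "AIS_T2D"), , drop = FALSE]
    s <- structure(scores$score, names = scores$sample_id)
    recs <- lapply(targets, function(tg) {
        if (!tg %in% names(stroke)) stop("score column missing: ", tg)
        v <- stroke[[tg]]
        ok <- !is.na(v) & stroke$sample_id %in% names(s)
        xs <- unname(s[stroke$sample_id[ok]])
        ys <- v[ok]
        if (length(xs) < 3L) stop("fewer than 3 usable samples for ", tg)
        r <- spearmanCorrelation(xs, ys, pMode = "auto")
        data.frame(feature_id = "dysbiosis_index", target_name = tg,
                   rho = r$rho, p_value = r$p.value, n = r$n,
                   significant = !r$degenerate & r$p.value < alpha,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
}

#' Screen taxa against numeric outcome columns
#'
#' Spearman correlation of every feature against every numeric outcome
#' column of the metadata (everything except `sample_id` and `group`),
#' pairwise-complete with per-record n. `level = "family"` aggregates
#' features by the family (`f__`) component of their lineage (summing
#' member abundances) before correlating. Constant features are excluded
#' with a message. Significance uses raw `p < alpha` by default; Bonferroni
#' over all tested pairs is available.
#'
#' @param x a [FeatureTable-class] (counts are converted to proportions).
#' @param meta metadata data.frame with `sample_id`, `group` and numeric
#'   outcome columns; >= 3 samples.
#' @param alpha significance level, default 0.05.
#' @param level `"otu"` (default, per feature) or `"family"`.
#' @param adjustment `"none"` (default) or `"bonferroni"`.
#' @return data.frame of correlation records.
#' @export
taxaOutcomeScreen <- function(x, meta, alpha = 0.05,
                              level = c("otu", "family"),
                              adjustment = c("none", "bonferroni")) {
    level <- match.arg(level)
    adjustment <- match.arg(adjustment)
    stopifnot(is(x, "FeatureTable"))
    meta <- validateMetadata(meta)
    if (abundanceUnit(x) == "counts") x <- toRelativeAbundance(x)
    outcomeCols <- setdiff(names(meta), c("sample_id", "group"))
    outcomeCols <- outcomeCols[vapply(meta[outcomeCols], is.numeric,
                                      logical(1L))]
    if (length(outcomeCols) == 0L) stop("no numeric outcome columns")
    v <- abundances(x)
    common <- intersect(rownames(v), meta$sample_id)
    if (length(common) < 3L) stop("need >= 3 samples with outcomes")
    v <- v[common, , drop = FALSE]
    meta <- meta[match(common, meta$sample_id), , drop = FALSE]
    if (level == "family") {
        tx <- taxonomy(x)
        if (!length(tx)) stop("family aggregation needs taxonomy")
        fam <- vapply(tx[colnames(v)], function(lin) {
            key <- .lineageKey(lin, match("family", names(.RANK_PREFIXES)))
            if (is.na(key)) lin else key
        }, character(1L))
        v <- t(rowsum(t(v), group = fam, reorder = TRUE))
    }
    recs <- list()
    skipped <- character(0)
    for (f in colnames(v)) {
        for (tg in outcomeCols) {
            ok <- !is.na(meta[[tg]])
            xs <- v[ok, f]
            ys <- meta[[tg]][ok]
            if (length(xs) < 3L) next
            if (stats::sd(xs) == 0) {
                skipped <- c(skipped, f)
                next
            }
            r <- spearmanCorrelation(xs, ys, pMode = "auto")
            if (r$degenerate) next
            recs[[length(recs) + 1L]] <-
                data.frame(feature_id = f, target_name = tg, rho = r$rho,
                           p_value = r$p.value, n = r$n,
                           stringsAsFactors = FALSE)
        }
    }
    if (length(skipped))
        message("taxaOutcomeScreen: excluded constant features: ",
                paste(unique(skipped), collapse = ", "))
    if (length(recs) == 0L) stop("no testable feature/outcome pairs")
    out <- do.call(rbind, recs)
    m <- nrow(out)
    out$significant <- if (adjustment == "bonferroni")
        pmin(1, m * out$p_value) <= alpha else out$p_value < alpha
    rownames(out) <- NULL
    out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default (df = 1); Yates correction is
#' available as a flag.
#'
#' @param contingency 2x2 matrix of non-negative integer counts with all
#'   row and column margins > 0.
#' @param correct apply the Yates continuity correction, default `FALSE`.
#' @return list with `chi2` and `p.value`.
#' @examples
#' chiSquare2x2(matrix(c(20, 10, 10, 20), 2, 2))$chi2  # 20/3
#' @export
chiSquare2x2 <- function(contingency, correct = FALSE) {
    m <- as.matrix(contingency)
    if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
    if (anyNA(m) || any(m < 0) || any(abs(m - round(m)) > 1e-9))
        stop("counts must be non-negative integers")
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
        stop("zero margin")
    ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
    list(chi2 = unname(ct$statistic), p.value = ct$p.value)
}

#' Comparative-Ct relative expression (2^-ddCt)
#'
#' `dCt = ct_target - ct_reference`, `ddCt = dCt - calibrator_delta`, fold
#' change `2^-ddCt` (one qPCR cycle = a doubling).
#'
#' @param ctTarget,ctReference finite Ct values (vectorised).
#' @param calibratorDelta the calibrator group's dCt, default 0.
#' @return fold change(s).
#' @examples
#' relativeExpression(21, 20, 0)   # ddCt = 1 -> 0.5
#' relativeExpression(20, 21, 0)   # ddCt = -1 -> 2
#' @export
relativeExpression <- function(ctTarget, ctReference, calibratorDelta = 0) {
    if (any(!is.finite(ctTarget)) || any(!is.finite(ctReference)) ||
        any(!is.finite(calibratorDelta)))
        stop("Ct values must be finite")
    2^(-((ctTarget - ctReference) - calibratorDelta))
}
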