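# Prevalence filtering, Wilcoxon rank-sum testing and index-model fitting.

#' Filter taxa by prevalence
#'
#' Keeps taxa whose prevalence (fraction of samples with nonzero abundance)
#' is at least `minPrevalence`; the boundary is inclusive, so a taxon seen
#' in exactly 10% of samples survives the default filter. Dropped taxa are
#' reported via `message()`.
#'
#' @param x a [FeatureTable-class].
#' @param minPrevalence fraction in \[0, 1\], default 0.10.
#' @return a [FeatureTable-class] with the same samples.
#' @export
prevalenceFilter <- function(x, minPrevalence = 0.10) {
    stopifnot(is(x, "FeatureTable"))
    if (!is.numeric(minPrevalence) || minPrevalence < 0 || minPrevalence > 1)
        stop("minPrevalence must be in [0, 1]")
    v <- abundances(x)
    if (nrow(v) == 0L || ncol(v) == 0L) stop("empty feature table")
    prev <- colMeans(v > 0)
    keep <- prev >= minPrevalence
    if (!any(keep)) stop("no taxa pass the prevalence filter")
    if (any(!keep))
        message("prevalenceFilter: dropped ", sum(!keep), " taxa: ",
                paste(utils::head(colnames(v)[!keep], 10L), collapse = ", "),
                if (sum(!keep) > 10L) ", ..." else "")
    tx <- taxonomy(x)
    FeatureTable(v[, keep, drop = FALSE], unit = abundanceUnit(x),
                 taxonomy = if (length(tx)) tx[colnames(v)[keep]] else NULL)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' The statistic is the rank sum of `x` within the pooled sample (mid-ranks
#' for ties). In `"exact"` mode the two-sided p-value comes from complete
#' enumeration of all `choose(n+m, n)` assignments of pooled ranks to the
#' first sample (`2 * min(P(W <= w), P(W >= w))`, capped at 1). In
#' `"asymptotic"` mode a tie-corrected normal approximation with continuity
#' correction is used. `"auto"` picks exact when `n + m <= 12` and the
#' pooled values are tie-free.
#'
#' @param x,y non-empty numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @return list with `statistic` (rank sum of `x`), `p.value` in (0, 1\],
#'   and `mode` actually used.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p.value  # 0.1
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
    mode <- match.arg(mode)
    stopIfNotNumericVector(x, "x")
    stopIfNotNumericVector(y, "y")
    n <- length(x); m <- length(y); N <- n + m
    pooled <- c(x, y)
    r <- rank(pooled)
    W <- sum(r[seq_len(n)])
    ties <- anyDuplicated(pooled) > 0L
    if (mode == "auto") mode <- if (N <= 12L && !ties) "exact" else "asymptotic"
    if (mode == "exact") {
        idx <- utils::combn(N, n)
        sums <- colSums(matrix(r[idx], nrow = n))
        pl <- mean(sums <= W + 1e-9)
        pg <- mean(sums >= W - 1e-9)
        p <- min(1, 2 * min(pl, pg))
    } else {
        mu <- n * (N + 1) / 2
        tcount <- table(r)
        sigma2 <- n * m / 12 * ((N + 1) -
                  sum(tcount^3 - tcount) / (N * (N - 1)))
        if (sigma2 <= 0) {
            p <- 1
        } else {
            z <- W - mu
            z <- (z - sign(z) * 0.5) / sqrt(sigma2)
            p <- min(1, 2 * stats::pnorm(-abs(z)))
        }
    }
    list(statistic = W, p.value = max(p, .Machine$double.xmin), mode = mode)
}

#' Differential-genus testing between two groups
#'
#' One Wilcoxon rank-sum test per taxon between the `case` and `control`
#' samples of a (prevalence-filtered) relative-abundance table. Direction is
#' `case_enriched` when the mean pooled rank of the case samples exceeds the
#' control mean rank, `control_enriched` when below, `tied` when equal. The
#' significance flag uses `p_adjusted <= alpha` under Bonferroni
#' (`p_adjusted = min(1, m * p)`) and raw `p_value < alpha` otherwise.
#'
#' @param x a [FeatureTable-class] with unit `"proportions"`.
#' @param meta metadata data.frame with `sample_id` and `group`.
#' @param case,control distinct group labels, each with >= 2 samples.
#' @param alpha significance level, default 0.05.
#' @param adjustment `"none"` (default) or `"bonferroni"`.
#' @return data.frame sorted by p ascending (ties broken by taxon id) with
#'   columns taxon_id, prevalence, p_value, p_adjusted, direction,
#'   mean_rank_case, mean_rank_control, significant.
#' @export
differentialGenera <- function(x, meta, case, control, alpha = 0.05,
                               adjustment = c("none", "bonferroni")) {
    adjustment <- match.arg(adjustment)
    stopifnot(is(x, "FeatureTable"))
    if (abundanceUnit(x) != "proportions")
        stop("differentialGenera expects proportions; ",
             "call toRelativeAbundance() first")
    if (identical(case, control)) stop("case and control must differ")
    meta <- validateMetadata(meta)
    caseIds <- meta$sample_id[meta$group == case]
    ctrlIds <- meta$sample_id[meta$group == control]
    if (length(caseIds) < 2L || length(ctrlIds) < 2L)
        stop("both groups need >= 2 samples (group absent from metadata?)")
    v <- abundances(x)
    missing <- setdiff(c(caseIds, ctrlIds), rownames(v))
    if (length(missing))
        stop("samples in metadata but not in table: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    vc <- v[caseIds, , drop = FALSE]
    vk <- v[ctrlIds, , drop = FALSE]
    nTaxa <- ncol(v)
    res <- lapply(seq_len(nTaxa), function(j) {
        xs <- vc[, j]; ys <- vk[, j]
        r <- rank(c(xs, ys))
        mrc <- mean(r[seq_along(xs)])
        mrk <- mean(r[-seq_along(xs)])
        w <- wilcoxonRankSum(xs, ys, mode = "auto")
        dir <- if (mrc > mrk) "case_enriched"
               else if (mrc < mrk) "control_enriched" else "tied"
        data.frame(taxon_id = colnames(v)[j],
                   prevalence = mean(c(xs, ys) > 0),
                   p_value = w$p.value,
                   direction = dir,
                   mean_rank_case = mrc,
                   mean_rank_control = mrk,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adjusted <- if (adjustment == "bonferroni")
        pmin(1, nTaxa * res$p_value) else res$p_value
    res$significant <- if (adjustment == "bonferroni")
        res$p_adjusted <= alpha else res$p_value < alpha
    res <- res[order(res$p_value, res$taxon_id), ,
               drop = FALSE]
    rownames(res) <- NULL
    res[, c("taxon_id", "prevalence", "p_value", "p_adjusted", "direction",
            "mean_rank_case", "mean_rank_control", "significant")]
}

#' Fit a dysbiosis index model from differential results
#'
#' Selects significant, non-tied taxa and weights each by `-log10(p_value)`
#' (p floored at 1e-300), so case-enriched taxa raise the index and
#' control-enriched taxa lower it. Tied-direction taxa are excluded with a
#' warning; no significant taxa is an explicit error.
#'
#' @param results data.frame from [differentialGenera()].
#' @param case,control group labels of the fitting comparison.
#' @param alpha significance level, default 0.05.
#' @param adjustment `"none"` (default, raw `p < alpha`) or `"bonferroni"`
#'   (`p_adjusted <= alpha`).
#' @return an [IndexModel-class].
#' @export
fitIndexModel <- function(results, case, control, alpha = 0.05,
                          adjustment = c("none", "bonferroni")) {
    adjustment <- match.arg(adjustment)
    need <- c("taxon_id", "p_value", "p_adjusted", "direction")
    if (!all(need %in% names(results)))
        stop("results must come from differentialGenera()")
    sig <- if (adjustment == "bonferroni")
        results$p_adjusted <= alpha else results$p_value < alpha
    tied <- results$direction == "tied"
    if (any(sig & tied))
        warning("excluding tied-direction taxa from the model: ",
                paste(results$taxon_id[sig & tied], collapse = ", "))
    keep <- sig & !tied
    if (!any(keep)) stop("empty model: no significant taxa at alpha = ", alpha)
    sel <- results[keep, , drop = FALSE]
    new("IndexModel",
        taxa = sel$taxon_id,
        weight = -log10(pmax(sel$p_value, 1e-300)),
        direction = sel$direction,
        caseLabel = as.character(case),
        controlLabel = as.character(control),
        alpha = alpha,
        adjustment = adjustment)
}

#' Serialise an IndexModel to JSON
#' @param model an [IndexModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIndexModel <- function(model, path) {
    stopifnot(is(model, "IndexModel"))
    obj <- list(case = model@caseLabel, control = model@controlLabel,
                alpha = model@alpha, adjustment = model@adjustment,
                entries = data.frame(taxon_id = model@taxa,
                                     weight = model@weight,
                                     direction = model@direction))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read an IndexModel from JSON
#' @param path JSON written by [writeIndexModel()].
#' @return an [IndexModel-class].
#' @export
readIndexModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("IndexModel",
        taxa = as.character(obj$entries$taxon_id),
        weight = as.numeric(obj$entries$weight),
        direction = as.character(obj$entries$direction),
        caseLabel = obj$case, controlLabel = obj$control,
        alpha = obj$alpha, adjustment = obj$adjustment)
}
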