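# Applying a fitted IndexModel: per-sample dysbiosis scores and group
# comparisons.

#' Compute the dysbiosis index for one sample
#'
#' `score = sum(w_g * a_g | case-enriched) - sum(w_g * a_g | control-enriched)`
#' over the model's taxa, on whole-community relative abundances. Model taxa
#' absent from the sample contribute 0.
#'
#' @param abundances named numeric vector of proportions for one sample.
#' @param model an [IndexModel-class].
#' @return a single finite score (unbounded, unitless).
#' @examples
#' m <- new("IndexModel", taxa = c("g1", "g2"), weight = c(2, 3),
#'          direction = c("case_enriched", "control_enriched"),
#'          caseLabel = "T2D", controlLabel = "control",
#'          alpha = 0.05, adjustment = "none")
#' computeIndex(c(g1 = 0.2, g2 = 0.1), m)  # 2*0.2 - 3*0.1 = 0.1
#' @export
computeIndex <- function(abundances, model) {
    stopifnot(is(model, "IndexModel"))
    if (!is.numeric(abundances) || is.null(names(abundances)))
        stop("abundances must be a named numeric vector of proportions")
    a <- abundances[model@taxa]
    a[is.na(a)] <- 0
    sgn <- ifelse(model@direction == "case_enriched", 1, -1)
    sum(sgn * model@weight * a)
}

#' Compute index scores for every sample of a table
#'
#' @param x a [FeatureTable-class] with unit `"proportions"` (counts must be
#'   normalised first).
#' @param model an [IndexModel-class].
#' @return data.frame with columns `sample_id` and `score`, one row per
#'   sample, carrying the md5 of the model JSON as attribute `modelHash`.
#' @export
computeIndexTable <- function(x, model) {
    stopifnot(is(x, "FeatureTable"), is(model, "IndexModel"))
    if (abundanceUnit(x) != "proportions")
        stop("computeIndexTable expects proportions; ",
             "call toRelativeAbundance() first")
    v <- abundances(x)
    present <- intersect(model@taxa, colnames(v))
    if (length(present) < length(model@taxa))
        message("computeIndexTable: ", length(model@taxa) - length(present),
                " model taxa absent from the table contribute 0")
    a <- matrix(0, nrow(v), length(model@taxa),
                dimnames = list(rownames(v), model@taxa))
    a[, present] <- v[, present]
    sgn <- ifelse(model@direction == "case_enriched", 1, -1)
    scores <- as.vector(a %*% (sgn * model@weight))
    out <- data.frame(sample_id = rownames(v), score = scores,
                      stringsAsFactors = FALSE)
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf))
    writeIndexModel(model, tf)
    attr(out, "modelHash") <- unname(tools::md5sum(tf))
    out
}

#' Compare index scores between two groups
#'
#' Wilcoxon rank-sum test (auto mode) on the per-sample scores of two
#' groups, reporting group medians.
#'
#' @param scores data.frame from [computeIndexTable()].
#' @param meta metadata data.frame with `sample_id` and `group`.
#' @param groupA,groupB group labels, each with >= 2 scored samples.
#' @return list with `medianA`, `medianB`, `p.value`.
#' @export
compareIndexGroups <- function(scores, meta, groupA, groupB) {
    meta <- validateMetadata(meta)
    s <- structure(scores$score, names = scores$sample_id)
    a <- s[meta$sample_id[meta$group == groupA]]
    b <- s[meta$sample_id[meta$group == groupB]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("both groups need >= 2 scored samples (group missing?)")
    w <- wilcoxonRankSum(unname(a), unname(b), mode = "auto")
    list(medianA = stats::median(a), medianB = stats::median(b),
         p.value = w$p.value)
}
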