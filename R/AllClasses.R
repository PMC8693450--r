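#' @import methods
NULL

#' FeatureTable: a samples-by-taxa abundance matrix
#'
#' The universal data carrier of the package: a non-negative numeric matrix
#' with samples as rows and taxa as columns, a declared unit (`"counts"` or
#' `"proportions"`), and an optional taxonomy map from taxon id to a
#' rank-delimited lineage string (Greengenes-style `k__...;p__...;...;g__...`).
#'
#' Invariants enforced by the validity method: all values finite and >= 0;
#' unique sample and taxon ids; in `"proportions"` unit every row sums to
#' 1 within 1e-9 (all-zero rows are forbidden).
#'
#' @slot values numeric matrix, samples x taxa, with dimnames.
#' @slot unit character, `"counts"` or `"proportions"`.
#' @slot taxonomy named character vector mapping taxon ids to lineage
#'   strings, or `character(0)` when absent.
#'
#' @seealso [FeatureTable()], [toRelativeAbundance()], [collapseTaxonomy()]
#' @exportClass FeatureTable
setClass("FeatureTable",
    representation(values = "matrix", unit = "character",
                   taxonomy = "character"))

setValidity("FeatureTable", function(object) {
    v <- object@values
    msgs <- character(0)
    if (!is.numeric(v))
        msgs <- c(msgs, "values must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msgs <- c(msgs, "values must have sample (row) and taxon (column) names")
    if (anyNA(v) || any(!is.finite(v)))
        msgs <- c(msgs, "values contain NA or non-finite entries")
    else if (any(v < 0))
        msgs <- c(msgs, "negative abundance")
    if (anyDuplicated(rownames(v)))
        msgs <- c(msgs, "duplicate sample ids")
    if (anyDuplicated(colnames(v)))
        msgs <- c(msgs, "duplicate taxon ids")
    if (!length(object@unit) == 1L || !object@unit %in% c("counts", "proportions"))
        msgs <- c(msgs, "unit must be 'counts' or 'proportions'")
    if (length(msgs) == 0L && identical(object@unit, "proportions")) {
        rs <- rowSums(v)
        if (any(rs <= 0) || any(rs > 1 + 1e-9))
            msgs <- c(msgs, paste("proportion rows must sum to 1 (within",
                                  "1e-9), or less for a taxon-filtered",
                                  "subcomposition; all-zero rows forbidden"))
    }
    if (length(object@taxonomy) > 0L) {
        if (is.null(names(object@taxonomy)) ||
            !all(colnames(v) %in% names(object@taxonomy)))
            msgs <- c(msgs, "taxonomy must name every taxon id")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix (samples x taxa) with dimnames.
#' @param unit `"counts"` or `"proportions"`.
#' @param taxonomy optional named character vector of lineage strings; names
#'   must cover all taxon ids.
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(10, 0, 3, 7), 2, 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), c("g1", "g2")))
#' ft <- FeatureTable(m, unit = "counts")
#' @export
FeatureTable <- function(values, unit = c("counts", "proportions"),
                         taxonomy = NULL) {
    unit <- match.arg(unit)
    if (is.data.frame(values)) values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(taxonomy)) taxonomy <- character(0)
    new("FeatureTable", values = values, unit = unit,
        taxonomy = taxonomy)
}

#' @describeIn FeatureTable-class Display a short summary.
#' @param object a `FeatureTable`.
#' @export
setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable: %d samples x %d taxa [%s]%s\n",
                nrow(object@values), ncol(object@values), object@unit,
                if (length(object@taxonomy)) ", taxonomy attached" else ""))
    cat("  samples: ", paste(utils::head(rownames(object@values), 4L),
                             collapse = ", "),
        if (nrow(object@values) > 4L) ", ..." else "", "\n", sep = "")
    cat("  taxa:    ", paste(utils::head(colnames(object@values), 4L),
                             collapse = ", "),
        if (ncol(object@values) > 4L) ", ..." else "", "\n", sep = "")
})

#' IndexModel: a fitted dysbiosis scorer
#'
#' Holds the taxa selected by a two-group differential-abundance comparison,
#' the enrichment direction of each taxon, and its weight
#' (-log10 of the Wilcoxon p-value of the fitting comparison, always > 0).
#'
#' @slot taxa character vector of taxon ids (no duplicates).
#' @slot weight positive numeric weights, parallel to `taxa`.
#' @slot direction character, `"case_enriched"` or `"control_enriched"`.
#' @slot caseLabel,controlLabel group labels of the fitting comparison.
#' @slot alpha significance level used in fitting.
#' @slot adjustment multiple-testing adjustment used (`"none"`/`"bonferroni"`).
#' @seealso [fitIndexModel()], [computeIndex()]
#' @exportClass IndexModel
setClass("IndexModel",
    representation(taxa = "character", weight = "numeric",
                   direction = "character", caseLabel = "character",
                   controlLabel = "character", alpha = "numeric",
                   adjustment = "character"))

setValidity("IndexModel", function(object) {
    msgs <- character(0)
    k <- length(object@taxa)
    if (k == 0L)
        msgs <- c(msgs, "empty model: no taxa")
    if (anyDuplicated(object@taxa))
        msgs <- c(msgs, "a taxon appears twice in the model")
    if (length(object@weight) != k || length(object@direction) != k)
        msgs <- c(msgs, "taxa, weight and direction lengths differ")
    if (any(!is.finite(object@weight)) || any(object@weight <= 0))
        msgs <- c(msgs, "weights must be finite and > 0")
    if (!all(object@direction %in% c("case_enriched", "control_enriched")))
        msgs <- c(msgs, "direction must be case_enriched or control_enriched")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn IndexModel-class Display a short summary.
#' @param object an `IndexModel`.
#' @export
setMethod("show", "IndexModel", function(object) {
    cat(sprintf("IndexModel: %s vs %s (alpha = %g, adjustment = %s)\n",
                object@caseLabel, object@controlLabel, object@alpha,
                object@adjustment))
    cat(sprintf("  %d taxa (%d case-enriched, %d control-enriched)\n",
                length(object@taxa),
                sum(object@direction == "case_enriched"),
                sum(object@direction == "control_enriched")))
})
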