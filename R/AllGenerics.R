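#' Sample identifiers
#' @param x an object with samples.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Taxon identifiers
#' @param x an object with taxa.
#' @return character vector of taxon ids.
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' Abundance matrix
#' @param x an object carrying abundances.
#' @return numeric matrix, samples x taxa.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' Abundance unit
#' @param x an object carrying abundances.
#' @return `"counts"` or `"proportions"`.
#' @export
setGeneric("abundanceUnit", function(x) standardGeneric("abundanceUnit"))

#' Taxonomy map
#' @param x an object carrying taxa.
#' @return named character vector of lineage strings (empty if absent).
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' Convert counts to relative abundances
#'
#' Divides every sample row by its total so rows sum to one. Idempotent on
#' proportion tables. A sample with zero total count is an error.
#'
#' @param x a [FeatureTable-class] with unit `"counts"` (or `"proportions"`,
#'   returned renormalised).
#' @return a [FeatureTable-class] with unit `"proportions"`.
#' @export
setGeneric("toRelativeAbundance",
           function(x) standardGeneric("toRelativeAbundance"))

#' Collapse taxa to a taxonomic rank
#'
#' Taxa sharing the same lineage prefix up to `rank` are summed; taxa whose
#' lineage lacks that rank keep their own (distinct) lineage string as an
#' unclassified bucket, so unclassified members of different parents stay
#' separate. Per-sample totals are conserved exactly.
#'
#' @param x a [FeatureTable-class] with taxonomy for all taxa.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return a [FeatureTable-class] whose taxon ids are lineage prefixes.
#' @export
setGeneric("collapseTaxonomy",
           function(x, rank) standardGeneric("collapseTaxonomy"))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "FeatureTable", function(x) rownames(x@values))

#' @rdname taxonIDs
#' @export
setMethod("taxonIDs", "FeatureTable", function(x) colnames(x@values))

#' @rdname abundances
#' @export
setMethod("abundances", "FeatureTable", function(x) x@values)

#' @rdname abundanceUnit
#' @export
setMethod("abundanceUnit", "FeatureTable", function(x) x@unit)

#' @rdname taxonomy
#' @export
setMethod("taxonomy", "FeatureTable", function(x) x@taxonomy)

#' Subset a FeatureTable
#'
#' @param x a [FeatureTable-class].
#' @param i sample index (character, integer or logical).
#' @param j taxon index.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @return a [FeatureTable-class]. Subsetting taxa of a proportion table
#'   yields a subcomposition: values stay on the whole-community scale and
#'   rows sum to less than one.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    tx <- x@taxonomy
    if (length(tx)) tx <- tx[colnames(v)]
    FeatureTable(v, unit = x@unit, taxonomy = if (length(tx)) tx else NULL)
})
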