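# Reading and writing the plain-text interchange formats: TSV feature
# tables (canonically samples-as-rows), TSV metadata, Newick trees, square
# labelled distance matrices and correlation-record tables.

.RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                    order = "o__", family = "f__", genus = "g__")

.GROUP_LEVELS <- c("control", "T2D", "AIS", "AIS_T2D",
                   "control_FMT", "T2D_FMT")

#' Read a feature table from TSV
#'
#' Parses a tab-delimited abundance table with an id header row and an id
#' first column. The unit is inferred: all-integral values are counts; rows
#' summing to 1 (within 1e-6) are proportions (then renormalised exactly);
#' anything else is an error unless `unit` is given explicitly, which always
#' wins over inference.
#'
#' @param path file path to a UTF-8 TSV.
#' @param orientation `"samples_as_rows"` (default, the canonical written
#'   orientation) or `"taxa_as_rows"`.
#' @param unit optional explicit `"counts"` or `"proportions"` override.
#' @param taxonomy optional named character vector of lineage strings.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(path,
                             orientation = c("samples_as_rows",
                                             "taxa_as_rows"),
                             unit = NULL, taxonomy = NULL) {
    orientation <- match.arg(orientation)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("feature table needs an id column and data")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate ids in first column")
    body <- df[, -1L, drop = FALSE]
    if (anyDuplicated(colnames(body))) stop("duplicate ids in header")
    if (!all(vapply(body, is.numeric, logical(1L))))
        stop("non-numeric cells in feature table body")
    m <- as.matrix(body)
    rownames(m) <- ids
    if (anyNA(m)) stop("missing values in feature table body")
    if (any(m < 0)) stop("negative abundance")
    if (orientation == "taxa_as_rows") m <- t(m)
    if (is.null(unit)) {
        if (all(abs(m - round(m)) < 1e-9)) {
            unit <- "counts"
        } else if (all(abs(rowSums(m) - 1) < 1e-6)) {
            unit <- "proportions"
        } else {
            stop("ambiguous unit: values neither integral nor row sums 1; ",
                 "pass unit= explicitly")
        }
    } else {
        unit <- match.arg(unit, c("counts", "proportions"))
    }
    if (unit == "proportions") {
        rs <- rowSums(m)
        if (any(rs <= 0)) stop("empty sample in proportion table")
        if (any(rs > 1 + 1e-6))
            stop("proportion row sums exceed 1")
        # snap rows that are 1 up to TSV rounding back to exactly 1; rows
        # summing to less are a taxon-filtered subcomposition, left alone
        whole <- abs(rs - 1) <= 1e-6
        m[whole, ] <- m[whole, , drop = FALSE] / rs[whole]
    }
    FeatureTable(m, unit = unit, taxonomy = taxonomy)
}

#' Write a feature table as TSV (samples as rows)
#'
#' @param x a [FeatureTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
    stopifnot(is(x, "FeatureTable"))
    df <- data.frame(sample_id = sampleIDs(x), abundances(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname toRelativeAbundance
#' @export
setMethod("toRelativeAbundance", "FeatureTable", function(x) {
    v <- abundances(x)
    rs <- rowSums(v)
    if (any(rs <= 0))
        stop("empty sample: zero total abundance in ",
             paste(rownames(v)[rs <= 0], collapse = ", "))
    FeatureTable(v / rs, unit = "proportions",
                 taxonomy = if (length(taxonomy(x))) taxonomy(x) else NULL)
})

# Lineage prefix through `rank`; NA when the rank is absent/empty there.
.lineageKey <- function(lineage, rankIdx) {
    parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
    if (length(parts) < rankIdx) return(NA_character_)
    leaf <- parts[rankIdx]
    pref <- .RANK_PREFIXES[rankIdx]
    label <- if (startsWith(leaf, pref)) substring(leaf, nchar(pref) + 1L) else leaf
    if (!nzchar(label)) return(NA_character_)
    paste(parts[seq_len(rankIdx)], collapse = ";")
}

#' @rdname collapseTaxonomy
#' @export
setMethod("collapseTaxonomy", "FeatureTable", function(x, rank) {
    rank <- match.arg(rank, names(.RANK_PREFIXES))
    tx <- taxonomy(x)
    if (!length(tx)) stop("missing taxonomy map")
    rankIdx <- match(rank, names(.RANK_PREFIXES))
    lin <- tx[taxonIDs(x)]
    keys <- vapply(lin, .lineageKey, character(1L), rankIdx = rankIdx)
    # taxa lacking the rank keep their full (distinct) lineage as an
    # unclassified bucket under their own parent
    keys[is.na(keys)] <- unname(lin[is.na(keys)])
    v <- abundances(x)
    collapsed <- t(rowsum(t(v), group = keys, reorder = TRUE))
    newTax <- structure(colnames(collapsed), names = colnames(collapsed))
    FeatureTable(collapsed, unit = abundanceUnit(x), taxonomy = newTax)
})

#' Read a rooted Newick tree
#'
#' Accepts unquoted labels, optional internal-node names, and requires the
#' `;` terminator. Absent branch lengths default to 0 with a warning.
#'
#' @param path Newick file with a single tree.
#' @return an [ape::phylo] tree.
#' @export
readTree <- function(path) {
    tr <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
    if (is.null(tr)) stop("malformed Newick: no tree parsed")
    if (inherits(tr, "multiPhylo")) stop("expected a single tree")
    if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names")
    if (is.null(tr$edge.length)) {
        warning("tree has no branch lengths; defaulting all to 0")
        tr$edge.length <- rep(0, nrow(tr$edge))
    } else if (anyNA(tr$edge.length)) {
        warning("missing branch lengths defaulted to 0")
        tr$edge.length[is.na(tr$edge.length)] <- 0
    }
    if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
        stop("branch lengths must be finite and >= 0")
    tr
}

# Range checks shared by readMetadata and the generators.
.checkScores <- function(df) {
    chk <- function(col, lo, hi) {
        if (col %in% names(df)) {
            v <- df[[col]]
            bad <- !is.na(v) & (v < lo | v > hi)
            if (any(bad))
                stop(col, " out of range ", lo, "-", hi)
        }
    }
    chk("NIHSS", 0, 42)
    chk("mRS", 0, 6)
    chk("mNSS", 0, 14)
    chk("infarct_ratio", 0, 1)
    if ("Essen" %in% names(df)) {
        v <- df$Essen
        if (any(!is.na(v) & v < 0)) stop("Essen out of range (must be >= 0)")
    }
    invisible(df)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id` and `group` (one of control, T2D, AIS,
#' AIS_T2D, control_FMT, T2D_FMT); clinical scores (NIHSS 0-42, mRS 0-6,
#' Essen >= 0) and numeric mouse outcomes (mNSS 0-14, infarct_ratio 0-1,
#' LBP, LPS, expression fold changes, ...) are optional columns, `NA`
#' allowed.
#'
#' @param path TSV file path.
#' @return a data.frame with one row per sample.
#' @export
readMetadata <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    validateMetadata(df)
}

#' Validate a metadata data.frame
#' @param df a data.frame with `sample_id` and `group` columns.
#' @return the validated data.frame, invisibly usable.
#' @export
validateMetadata <- function(df) {
    if (!all(c("sample_id", "group") %in% names(df)))
        stop("metadata needs 'sample_id' and 'group' columns")
    df$sample_id <- as.character(df$sample_id)
    df$group <- as.character(df$group)
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
    if (anyNA(df$group)) stop("group is required for every sample")
    unknown <- setdiff(unique(df$group), .GROUP_LEVELS)
    if (length(unknown))
        stop("unknown group label: ", paste(unknown, collapse = ", "))
    .checkScores(df)
    df
}

#' Write metadata as TSV
#' @param df metadata data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write correlation records as TSV
#' @param records data.frame of correlation records
#'   (feature_id, target_name, rho, p_value, n, significant).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorrelationRecords <- function(records, path) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read correlation records from TSV
#' @param path TSV written by [writeCorrelationRecords()].
#' @return data.frame of correlation records.
#' @export
readCorrelationRecords <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (any(abs(df$rho) > 1 + 1e-12)) stop("|rho| > 1 in records")
    df
}

#' Write a square labelled distance matrix as TSV
#' @param dm symmetric numeric matrix with zero diagonal and dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path) {
    .checkDistanceMatrix(dm)
    df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a square labelled distance matrix from TSV
#' @param path TSV written by [writeDistanceMatrix()].
#' @return symmetric numeric matrix.
#' @export
readDistanceMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    # tolerate TSV rounding, then restore exact symmetry
    if (max(abs(m - t(m))) > 1e-8) stop("distance matrix not symmetric")
    m <- (m + t(m)) / 2
    diag(m) <- 0
    .checkDistanceMatrix(m)
    m
}

.checkDistanceMatrix <- function(dm) {
    if (!is.matrix(dm) || nrow(dm) != ncol(dm))
        stop("distance matrix must be square")
    if (is.null(rownames(dm)) || !identical(rownames(dm), colnames(dm)))
        stop("distance matrix must carry matching sample labels")
    if (any(!is.finite(dm)) || any(dm < 0))
        stop("distances must be finite and >= 0")
    if (!isTRUE(all.equal(dm, t(dm), tolerance = 0)) &&
        max(abs(dm - t(dm))) > 0)
        stop("distance matrix must be exactly symmetric")
    if (any(diag(dm) != 0)) stop("distance matrix diagonal must be 0")
    invisible(dm)
}
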