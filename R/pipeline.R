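# Config-driven orchestration: simulate (or load) -> prevalence filter ->
# differential -> index fit/score/compare -> beta diversity -> correlations,
# with per-stage error reporting and a machine-readable manifest.

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Exactly one of `input` (paths
#' `table`, `metadata`, `tree`) or `simulate` (overrides for
#' [syntheticConfig()]) must be present. All validation errors are reported
#' at once, not first-fail. A missing seed is drawn once and recorded in
#' the returned config.
#'
#' @param config YAML path or list with fields `input`/`simulate`, `case`,
#'   `control`, `alpha`, `adjustment`, `metric`, `permutations`, `seed`,
#'   `out_dir`.
#' @return a normalised list of class `"RunConfig"`.
#' @export
validateConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a YAML file path or a list")
    errs <- character(0)
    known <- c("input", "simulate", "case", "control", "alpha", "adjustment",
               "metric", "permutations", "seed", "out_dir")
    unknown <- setdiff(names(config), known)
    if (length(unknown))
        errs <- c(errs, paste0("unknown keys: ",
                               paste(unknown, collapse = ", ")))
    hasInput <- !is.null(config$input)
    hasSim <- !is.null(config$simulate)
    if (hasInput == hasSim)
        errs <- c(errs,
                  "exactly one of 'input' and 'simulate' must be present")
    if (hasInput) {
        for (f in c("table", "metadata", "tree"))
            if (is.null(config$input[[f]]))
                errs <- c(errs, paste0("input.", f, " is required"))
    }
    if (is.null(config$case)) config$case <- "T2D"
    if (is.null(config$control)) config$control <- "control"
    if (is.null(config$alpha)) config$alpha <- 0.05
    if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
        errs <- c(errs, "alpha must be in (0,1)")
    if (is.null(config$adjustment)) config$adjustment <- "none"
    if (!config$adjustment %in% c("none", "bonferroni"))
        errs <- c(errs, "adjustment must be 'none' or 'bonferroni'")
    if (is.null(config$metric)) config$metric <- "unweighted_unifrac"
    if (!config$metric %in% c("unweighted_unifrac", "weighted_unifrac"))
        errs <- c(errs,
                  "metric must be unweighted_unifrac or weighted_unifrac")
    if (is.null(config$permutations)) config$permutations <- 999
    if (!is.numeric(config$permutations) || config$permutations < 1)
        errs <- c(errs, "permutations must be >= 1")
    if (is.null(config$seed)) {
        config$seed <- sample.int(.Machine$integer.max, 1L)
        message("validateConfig: no seed given; drew and recorded ",
                config$seed)
    }
    if (!is.numeric(config$seed) || config$seed != round(config$seed))
        errs <- c(errs, "seed must be an integer")
    if (is.null(config$out_dir)) config$out_dir <- "dysbindex_run"
    if (length(errs))
        stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
    structure(config, class = "RunConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> relative abundance -> prevalence filter ->
#' differential genera -> index fit -> per-sample scores -> group
#' comparisons -> UniFrac distance matrix, PCoA, distances-to-control,
#' PERMANOVA -> clinical-score correlations (and, for mouse metadata with
#' outcome columns, the taxon-outcome screen). Every intermediate is
#' written as TSV/JSON in `out_dir`; the returned (and written) manifest
#' records the seed, a config hash, package version and output checksums,
#' so identical (config, seed) runs are bit-identical.
#'
#' @param config a [validateConfig()]-accepted list, path or `RunConfig`.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "RunConfig")) config <- validateConfig(config)
    outDir <- config$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    put <- function(name) {
        f <- file.path(outDir, name)
        files <<- c(files, f)
        f
    }

    if (!is.null(config$simulate)) {
        data <- .stage("simulate", {
            simArgs <- config$simulate
            simArgs$seed <- config$seed
            if (!is.null(simArgs$effectSize)) {
                simArgs$effects <- defaultEffects(simArgs$effectSize)
                simArgs$effectSize <- NULL
            }
            if (!is.null(simArgs$nPerGroup))
                simArgs$nPerGroup <- unlist(simArgs$nPerGroup)
            cohort <- generateCohort(do.call(syntheticConfig, simArgs))
            tree <- generateTree(taxonIDs(cohort$table), seed = config$seed)
            writeFeatureTable(cohort$table, put("feature_table.tsv"))
            writeMetadata(cohort$metadata, put("metadata.tsv"))
            ape::write.tree(tree, put("tree.nwk"))
            jsonlite::write_json(
                list(latent = as.list(cohort$truth$latent),
                     effects = lapply(cohort$truth$effects, as.list),
                     note = cohort$truth$note),
                put("truth.json"), auto_unbox = TRUE, digits = NA)
            list(table = cohort$table, meta = cohort$metadata, tree = tree)
        })
    } else {
        data <- .stage("load", {
            list(table = readFeatureTable(config$input$table),
                 meta = readMetadata(config$input$metadata),
                 tree = readTree(config$input$tree))
        })
    }

    rel <- .stage("relative_abundance", toRelativeAbundance(data$table))
    filtered <- .stage("prevalence_filter", prevalenceFilter(rel, 0.10))
    diffRes <- .stage("differential", {
        d <- differentialGenera(filtered, data$meta, case = config$case,
                                control = config$control,
                                alpha = config$alpha,
                                adjustment = config$adjustment)
        utils::write.table(d, put("differential.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        d
    })
    model <- .stage("fit_index_model", {
        m <- fitIndexModel(diffRes, config$case, config$control,
                           alpha = config$alpha,
                           adjustment = config$adjustment)
        writeIndexModel(m, put("model.json"))
        m
    })
    scores <- .stage("score", {
        s <- computeIndexTable(rel, model)
        utils::write.table(s, put("scores.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        s
    })
    comparisons <- .stage("compare", {
        cmp <- list()
        cmp[[paste(config$case, "vs", config$control)]] <-
            compareIndexGroups(scores, data$meta, config$case,
                               config$control)
        grps <- unique(data$meta$group)
        if (all(c("AIS_T2D", "AIS") %in% grps))
            cmp[["AIS_T2D vs AIS"]] <-
                compareIndexGroups(scores, data$meta, "AIS_T2D", "AIS")
        jsonlite::write_json(cmp, put("comparisons.json"),
                             auto_unbox = TRUE, digits = NA)
        cmp
    })
    beta <- .stage("beta_diversity", {
        dm <- distanceMatrix(rel, data$tree, metric = config$metric)
        writeDistanceMatrix(dm, put("distance_matrix.tsv"))
        ord <- pcoa(dm, k = 3)
        utils::write.table(
            data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE),
            put("pcoa.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        ref <- if ("control" %in% data$meta$group) "control" else
               data$meta$group[1L]
        d2g <- distancesToGroup(dm, data$meta, reference = ref)
        utils::write.table(d2g, put("distance_to_control.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        pmv <- permanova(dm, data$meta, grouping = "group",
                         nPermutations = config$permutations,
                         seed = substreamSeed(config$seed, "permanova"))
        jsonlite::write_json(pmv, put("permanova.json"), auto_unbox = TRUE,
                             digits = NA)
        list(dm = dm, ordination = ord, distToRef = d2g, permanova = pmv)
    })
    scoreCols <- intersect(c("NIHSS", "mRS", "Essen"), names(data$meta))
    correlations <- NULL
    if (length(scoreCols) && any(!is.na(data$meta[, scoreCols])))
        correlations <- .stage("score_correlations", {
            r <- scoreCorrelations(scores, data$meta, targets = scoreCols,
                                   alpha = config$alpha)
            writeCorrelationRecords(r, put("score_correlations.tsv"))
            r
        })
    outcomeCols <- setdiff(names(data$meta),
                           c("sample_id", "group", "NIHSS", "mRS", "Essen"))
    screen <- NULL
    if (length(outcomeCols))
        screen <- .stage("outcome_screen", {
            r <- taxaOutcomeScreen(rel, data$meta, alpha = config$alpha)
            writeCorrelationRecords(r, put("outcome_screen.tsv"))
            r
        })

    manifest <- .stage("manifest", {
        cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                    digits = NA)
        man <- list(seed = config$seed,
                    config_hash = md5Of(as.character(cfgJson)),
                    package_version =
                        as.character(utils::packageVersion("dysbindex")),
                    files = as.list(structure(
                        unname(tools::md5sum(files)),
                        names = basename(files))))
        jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        man
    })
    manifest$results <- list(differential = diffRes, model = model,
                             scores = scores, comparisons = comparisons,
                             beta = beta, correlations = correlations,
                             screen = screen)
    invisible(manifest)
}
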