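smallConfig <- function(seed = 1, ...)
    syntheticConfig(nPerGroup = c(control = 8, AIS = 8, T2D = 8,
                                  AIS_T2D = 8),
                    seed = seed, ...)

test_that("cohort generation is deterministic and matches the design sizes", {
    a <- generateCohort(smallConfig(seed = 3))
    b <- generateCohort(smallConfig(seed = 3))
    expect_identical(abundances(a$table), abundances(b$table))
    expect_identical(a$metadata, b$metadata)
    cc <- generateCohort(smallConfig(seed = 4))
    expect_false(identical(abundances(a$table), abundances(cc$table)))

    full <- syntheticConfig()
    expect_equal(unname(full$nPerGroup[c("control", "AIS", "T2D",
                                         "AIS_T2D")]),
                 c(55, 90, 35, 60))
    expect_equal(table(a$metadata$group)[["AIS_T2D"]], 8)
    # stroke samples carry clinical scores, others do not
    stroke <- a$metadata$group %in% c("AIS", "AIS_T2D")
    expect_true(all(!is.na(a$metadata$NIHSS[stroke])))
    expect_true(all(is.na(a$metadata$NIHSS[!stroke])))
    expect_true(all(a$metadata$NIHSS[stroke] <= 15))
    expect_true(all(a$metadata$mRS[stroke] <= 6))
})

test_that("the comorbid log2 effect vector is exactly the sum of its parts", {
    coh <- generateCohort(smallConfig(seed = 5))
    lfc <- coh$truth$log2fcByGroup
    expect_identical(lfc$AIS_T2D, lfc$T2D + lfc$AIS)
    expect_identical(lfc$control, lfc$control * 0)
    # the planted 11-genus diabetes panel is present with signed effects
    t2d <- coh$truth$effects$T2D
    expect_equal(length(t2d), 11L)
    expect_true(all(c("Lactobacillus", "Lachnospira",
                      "Enterobacteriaceae_g1") %in% names(t2d)))
})

test_that("configuration validation rejects inconsistent settings", {
    expect_error(syntheticConfig(nPerGroup = c(control = 1, T2D = 5)),
                 ">= 2")
    expect_error(syntheticConfig(concentration = 0), "> 0")
    expect_error(syntheticConfig(effects = list(T2D = c(NotATaxon = 1))),
                 "unknown taxon")
})

test_that("score links are monotone without noise and null with zero slope", {
    meta <- data.frame(sample_id = sprintf("S%02d", 1:40),
                       group = rep(c("AIS", "control"), c(30, 10)),
                       stringsAsFactors = FALSE)
    latent <- structure(seq(-2, 2, length.out = 40), names = meta$sample_id)
    links0 <- lapply(defaultScoreLink(), function(l) {
        l$noise <- 0; l })
    m0 <- generateScores(meta, latent, links0, seed = 2)
    stroke <- m0$group == "AIS"
    expect_true(all(diff(m0$NIHSS[stroke]) >= 0))  # monotone in latent
    expect_gte(suppressWarnings(cor(latent[stroke], m0$NIHSS[stroke],
                                    method = "spearman")), 0.9)

    linksFlat <- lapply(defaultScoreLink(), function(l) {
        l$slope <- 0; l })
    rhos <- sapply(1:15, function(s) {
        m <- generateScores(meta, latent, linksFlat, seed = 100 + s)
        suppressWarnings(cor(latent[stroke], m$NIHSS[m$group == "AIS"],
                             method = "spearman"))
    })
    expect_lt(median(abs(rhos)), 0.2)

    expect_message(generateScores(meta, structure(rep(1, 40),
                                                  names = meta$sample_id),
                                  seed = 1), "constant")
    badLink <- defaultScoreLink(); badLink$NIHSS$slope <- Inf
    expect_error(generateScores(meta, latent, badLink, seed = 1), "finite")
})

test_that("random trees are binary, rooted, seeded and cover the taxa", {
    ids <- paste0("t", 1:17)
    tr <- generateTree(ids, seed = 9)
    expect_setequal(tr$tip.label, ids)
    expect_equal(tr$Nnode, length(ids) - 1L)   # binary rooted
    expect_true(ape::is.rooted(tr))
    expect_identical(ape::write.tree(generateTree(ids, seed = 9)),
                     ape::write.tree(tr))
    two <- generateTree(c("A", "B"), seed = 1)
    expect_equal(nrow(two$edge), 2L)
    expect_error(generateTree("A", seed = 1), ">= 2")
})

test_that("the mouse study couples outcomes to the planted community shift", {
    ms <- generateMouseStudy(seed = 6)
    expect_equal(nrow(abundances(ms$table)), 9L)
    expect_equal(table(ms$metadata$group)[["T2D_FMT"]], 4L)
    expect_true(all(ms$metadata$mNSS >= 0 & ms$metadata$mNSS <= 14))
    expect_true(all(ms$metadata$infarct_ratio >= 0 &
                    ms$metadata$infarct_ratio <= 1))
    ms2 <- generateMouseStudy(seed = 6)
    expect_identical(abundances(ms$table), abundances(ms2$table))
    expect_identical(ms$metadata, ms2$metadata)
    expect_error(generateMouseStudy(coupling = c(nope = 1), seed = 1),
                 "unknown outcome")
    # zero coupling leaves taxon-outcome correlations at small-n noise level
    med <- sapply(1:10, function(s) {
        m0 <- generateMouseStudy(coupling = 0, seed = 400 + s)
        scr <- suppressMessages(taxaOutcomeScreen(m0$table, m0$metadata))
        median(abs(scr$rho))
    })
    expect_lt(median(med), 0.4)
})

test_that("null cohorts keep the differential flag rate near the nominal level", {
    zero <- list(T2D = numeric(0), AIS = numeric(0))
    tot <- hits <- 0
    for (s in 1:25) {
        cfg <- syntheticConfig(nPerGroup = c(control = 20, T2D = 15),
                               effects = zero, seed = 500 + s)
        coh <- suppressMessages(generateCohort(cfg))
        rel <- toRelativeAbundance(coh$table)
        filt <- suppressMessages(prevalenceFilter(rel))
        d <- differentialGenera(filt, coh$metadata, "T2D", "control")
        tot <- tot + nrow(d); hits <- hits + sum(d$significant)
    }
    expect_gt(hits / tot, 0.02)
    expect_lt(hits / tot, 0.09)
})
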