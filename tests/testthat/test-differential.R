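test_that("exact rank-sum p-values match the worked enumerations", {
    expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6),
                                 mode = "exact")$p.value, 0.1)
    expect_equal(wilcoxonRankSum(1, 2, mode = "exact")$p.value, 1)
    # identical multisets are perfectly symmetric
    x <- c(2, 5, 9)
    expect_equal(wilcoxonRankSum(x, x, mode = "exact")$p.value, 1)
    expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
    expect_error(wilcoxonRankSum(c(1, NaN), 1:3), "NA")
})

test_that("exact mode agrees with the reference exact distribution", {
    set.seed(7)
    for (i in 1:60) {
        n <- sample(2:6, 1); m <- sample(2:6, 1)
        v <- sample(1000, n + m)   # tie-free
        x <- v[seq_len(n)]; y <- v[-seq_len(n)]
        ours <- wilcoxonRankSum(x, y, mode = "exact")$p.value
        ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
        expect_equal(ours, ref, tolerance = 1e-12)
    }
})

test_that("asymptotic p tracks exact p and is shift invariant", {
    set.seed(8)
    for (i in 1:6) {
        v <- sample(5000, 20)
        x <- v[1:10]; y <- v[11:20]
        pe <- wilcoxonRankSum(x, y, mode = "exact")$p.value
        pa <- wilcoxonRankSum(x, y, mode = "asymptotic")$p.value
        expect_lt(abs(pe - pa), 0.02)
        sh <- wilcoxonRankSum(x + 17.3, y + 17.3, mode = "asymptotic")
        expect_equal(sh$statistic,
                     wilcoxonRankSum(x, y, mode = "asymptotic")$statistic)
        expect_equal(sh$p.value, pa)
    }
})

test_that("tie-corrected asymptotic mode matches the reference implementation", {
    set.seed(9)
    for (i in 1:20) {
        x <- sample(0:4, 15, replace = TRUE)
        y <- sample(0:4, 20, replace = TRUE)
        if (sd(c(x, y)) == 0) next
        ours <- wilcoxonRankSum(x, y, mode = "asymptotic")$p.value
        ref <- suppressWarnings(
            wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
        expect_equal(ours, ref, tolerance = 1e-10)
    }
})

test_that("prevalence filter keeps the inclusive 10% boundary", {
    m <- matrix(0, 20, 3,
                dimnames = list(paste0("S", 1:20), c("keep", "edge", "drop")))
    m[, "keep"] <- 5
    m[1:2, "edge"] <- 3      # exactly 10% prevalence
    m[1, "drop"] <- 2        # 5%
    ft <- FeatureTable(m, unit = "counts")
    expect_message(out <- prevalenceFilter(ft, 0.10), "dropped")
    expect_setequal(taxonIDs(out), c("keep", "edge"))
    expect_equal(sampleIDs(out), sampleIDs(ft))
    # all-zero taxon never survives a positive threshold
    m2 <- cbind(m[, "keep", drop = FALSE], zero = 0)
    expect_message(out2 <- prevalenceFilter(FeatureTable(m2, unit = "counts"),
                                            0.01))
    expect_identical(taxonIDs(out2), "keep")
    expect_error(prevalenceFilter(ft, 1.2), "minPrevalence")
})

test_that("differential testing directions, sorting and Bonferroni are exact", {
    set.seed(10)
    n <- 12
    ids <- sprintf("S%02d", 1:(2 * n))
    meta <- data.frame(sample_id = ids,
                       group = rep(c("T2D", "control"), each = n),
                       stringsAsFactors = FALSE)
    up <- c(rexp(n) + 2, rexp(n))          # enriched in case
    down <- c(rexp(n), rexp(n) + 2)        # enriched in control
    # keep "flat" exactly constant across samples; up/down share the rest
    m <- cbind(up = 0.75 * up / (up + down),
               down = 0.75 * down / (up + down),
               flat = 0.25)
    rownames(m) <- ids
    ft <- FeatureTable(m, unit = "proportions")
    res <- differentialGenera(ft, meta, "T2D", "control")
    expect_equal(res$direction[res$taxon_id == "up"], "case_enriched")
    expect_equal(res$direction[res$taxon_id == "down"], "control_enriched")
    expect_equal(res$direction[res$taxon_id == "flat"], "tied")
    expect_equal(res$p_value[res$taxon_id == "flat"], 1)
    expect_true(all(diff(res$p_value) >= 0))
    expect_true(all(res$p_adjusted >= res$p_value))

    resB <- differentialGenera(ft, meta, "T2D", "control",
                               adjustment = "bonferroni")
    expect_equal(resB$p_adjusted, pmin(1, 3 * resB$p_value))
    expect_error(differentialGenera(ft, meta, "T2D", "T2D"), "differ")
    expect_error(differentialGenera(ft, meta, "T2D", "AIS"), ">= 2 samples")
})

test_that("index model fitting applies the -log10 weighting and thresholds", {
    res <- data.frame(taxon_id = c("a", "b", "c"),
                      p_value = c(0.01, 0.2, 0.04),
                      p_adjusted = c(0.03, 0.6, 0.12),
                      direction = c("case_enriched", "case_enriched",
                                    "control_enriched"),
                      stringsAsFactors = FALSE)
    m <- fitIndexModel(res, "T2D", "control", alpha = 0.05)
    expect_setequal(m@taxa, c("a", "c"))
    expect_equal(m@weight[m@taxa == "a"], 2)
    mB <- fitIndexModel(res, "T2D", "control", alpha = 0.05,
                        adjustment = "bonferroni")
    expect_identical(mB@taxa, "a")

    resT <- res
    resT$direction[1] <- "tied"
    expect_warning(mT <- fitIndexModel(resT, "T2D", "control"), "tied")
    expect_false("a" %in% mT@taxa)
    resNone <- res
    resNone$p_value <- c(0.5, 0.6, 0.7)
    expect_error(fitIndexModel(resNone, "T2D", "control"), "empty model")
})

test_that("index models survive a JSON round trip", {
    res <- data.frame(taxon_id = c("a", "c"), p_value = c(0.01, 0.04),
                      p_adjusted = c(0.02, 0.08),
                      direction = c("case_enriched", "control_enriched"),
                      stringsAsFactors = FALSE)
    m <- fitIndexModel(res, "T2D", "control")
    tf <- tempfile(fileext = ".json")
    writeIndexModel(m, tf)
    back <- readIndexModel(tf)
    expect_identical(back@taxa, m@taxa)
    expect_equal(back@weight, m@weight)
    expect_identical(back@direction, m@direction)
    unlink(tf)
})
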