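# Dirichlet-multinomial cohort simulator with planted enriched/depleted
# genera, clinical scores monotone in latent dysbiosis, random rooted trees
# and a germfree-mouse FMT outcome study generator.

.ACTIVE_DISEASES <- list(control = character(0), T2D = "T2D", AIS = "AIS",
                         AIS_T2D = c("T2D", "AIS"),
                         control_FMT = character(0), T2D_FMT = "T2D")

#' Default genus panel for simulated human cohorts
#'
#' Thirty-nine genus-level taxa with Greengenes-style lineages: the
#' dominant gut genera (Bacteroides, Prevotella, Faecalibacterium,
#' Parabacteroides lead the baseline composition), the eleven genera planted
#' as diabetes-associated (Porphyromonas, Lactobacillus, Blautia, Dorea,
#' Lachnospira, Roseburia, Megasphaera, Catenibacterium, Cetobacterium and
#' two placeholder Enterobacteriaceae genus buckets), stroke-associated
#' genera, and a tail of rare genera that exercise the prevalence filter.
#'
#' @return data.frame with columns `taxon_id`, `lineage`,
#'   `base` (baseline expected proportion, renormalised by the generator).
#' @export
defaultTaxonPanel <- function() {
    g <- function(phy, cls, ord, fam, gen)
        sprintf("k__Bacteria;p__%s;c__%s;o__%s;f__%s;g__%s",
                phy, cls, ord, fam, gen)
    tab <- rbind(
      c("Bacteroides",      g("Bacteroidetes","Bacteroidia","Bacteroidales","Bacteroidaceae","Bacteroides"),      0.22),
      c("Prevotella",       g("Bacteroidetes","Bacteroidia","Bacteroidales","Prevotellaceae","Prevotella"),       0.12),
      c("Parabacteroides",  g("Bacteroidetes","Bacteroidia","Bacteroidales","Porphyromonadaceae","Parabacteroides"), 0.06),
      c("Alistipes",        g("Bacteroidetes","Bacteroidia","Bacteroidales","Rikenellaceae","Alistipes"),         0.03),
      c("Porphyromonas",    g("Bacteroidetes","Bacteroidia","Bacteroidales","Porphyromonadaceae","Porphyromonas"), 5e-04),
      c("Faecalibacterium", g("Firmicutes","Clostridia","Clostridiales","Ruminococcaceae","Faecalibacterium"),    0.10),
      c("Ruminococcus",     g("Firmicutes","Clostridia","Clostridiales","Ruminococcaceae","Ruminococcus"),        0.03),
      c("Oscillospira",     g("Firmicutes","Clostridia","Clostridiales","Ruminococcaceae","Oscillospira"),        0.015),
      c("Roseburia",        g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Roseburia"),           0.005),
      c("Blautia",          g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Blautia"),             0.005),
      c("Dorea",            g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Dorea"),               0.005),
      c("Lachnospira",      g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Lachnospira"),         0.005),
      c("Coprococcus",      g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Coprococcus"),         0.006),
      c("Phascolarctobacterium", g("Firmicutes","Clostridia","Clostridiales","Veillonellaceae","Phascolarctobacterium"), 0.015),
      c("Dialister",        g("Firmicutes","Clostridia","Clostridiales","Veillonellaceae","Dialister"),           0.01),
      c("Megasphaera",      g("Firmicutes","Clostridia","Clostridiales","Veillonellaceae","Megasphaera"),         5e-04),
      c("Veillonella",      g("Firmicutes","Clostridia","Clostridiales","Veillonellaceae","Veillonella"),         0.005),
      c("Catenibacterium",  g("Firmicutes","Erysipelotrichi","Erysipelotrichales","Erysipelotrichaceae","Catenibacterium"), 4e-04),
      c("Lactobacillus",    g("Firmicutes","Bacilli","Lactobacillales","Lactobacillaceae","Lactobacillus"),       7e-04),
      c("Streptococcus",    g("Firmicutes","Bacilli","Lactobacillales","Streptococcaceae","Streptococcus"),       0.01),
      c("Clostridium",      g("Firmicutes","Clostridia","Clostridiales","Clostridiaceae","Clostridium"),          0.01),
      c("Enterobacteriaceae_g1", g("Proteobacteria","Gammaproteobacteria","Enterobacteriales","Enterobacteriaceae","Enterobacteriaceae_g1"), 7e-04),
      c("Enterobacteriaceae_g2", g("Proteobacteria","Gammaproteobacteria","Enterobacteriales","Enterobacteriaceae","Enterobacteriaceae_g2"), 4e-04),
      c("Haemophilus",      g("Proteobacteria","Gammaproteobacteria","Pasteurellales","Pasteurellaceae","Haemophilus"), 6e-04),
      c("Citrobacter",      g("Proteobacteria","Gammaproteobacteria","Enterobacteriales","Enterobacteriaceae","Citrobacter"), 5e-04),
      c("Klebsiella",       g("Proteobacteria","Gammaproteobacteria","Enterobacteriales","Enterobacteriaceae","Klebsiella"), 6e-04),
      c("Sutterella",       g("Proteobacteria","Betaproteobacteria","Burkholderiales","Alcaligenaceae","Sutterella"), 0.008),
      c("Desulfovibrio",    g("Proteobacteria","Deltaproteobacteria","Desulfovibrionales","Desulfovibrionaceae","Desulfovibrio"), 6e-04),
      c("Bilophila",        g("Proteobacteria","Deltaproteobacteria","Desulfovibrionales","Desulfovibrionaceae","Bilophila"), 6e-04),
      c("Fusobacterium",    g("Fusobacteria","Fusobacteriia","Fusobacteriales","Fusobacteriaceae","Fusobacterium"), 0.01),
      c("Cetobacterium",    g("Fusobacteria","Fusobacteriia","Fusobacteriales","Fusobacteriaceae","Cetobacterium"), 4e-04),
      c("Akkermansia",      g("Verrucomicrobia","Verrucomicrobiae","Verrucomicrobiales","Verrucomicrobiaceae","Akkermansia"), 0.008),
      # rare tail: most of these sit below 10% prevalence at default depth
      c("Slackia",          g("Actinobacteria","Coriobacteriia","Coriobacteriales","Coriobacteriaceae","Slackia"), 5e-05),
      c("Holdemania",       g("Firmicutes","Erysipelotrichi","Erysipelotrichales","Erysipelotrichaceae","Holdemania"), 8e-05),
      c("Anaerotruncus",    g("Firmicutes","Clostridia","Clostridiales","Ruminococcaceae","Anaerotruncus"),       1e-04),
      c("Anaerofustis",     g("Firmicutes","Clostridia","Clostridiales","Eubacteriaceae","Anaerofustis"),         4e-05),
      c("Succinivibrio",    g("Proteobacteria","Gammaproteobacteria","Aeromonadales","Succinivibrionaceae","Succinivibrio"), 5e-04),
      c("Paraprevotella",   g("Bacteroidetes","Bacteroidia","Bacteroidales","Prevotellaceae","Paraprevotella"),   1.2e-04),
      c("Mitsuokella",      g("Firmicutes","Clostridia","Clostridiales","Veillonellaceae","Mitsuokella"),         7e-05))
    data.frame(taxon_id = tab[, 1L], lineage = tab[, 2L],
               base = as.numeric(tab[, 3L]), stringsAsFactors = FALSE)
}

#' Default planted disease effects (log2 fold changes)
#'
#' The T2D effect plants the eleven diabetes-associated genera: enriched
#' Porphyromonas, Lactobacillus, Megasphaera, Catenibacterium, Cetobacterium
#' and the two Enterobacteriaceae buckets; depleted Blautia, Dorea,
#' Lachnospira and Roseburia. The AIS effect enriches Enterobacteriaceae and
#' a broader Proteobacteria bloom (Desulfovibrio, Bilophila, Haemophilus,
#' Citrobacter, Klebsiella, Succinivibrio) and depletes
#' Prevotella, Faecalibacterium, Lachnospira and Coprococcus. The comorbid
#' group applies the sum of both effect vectors.
#'
#' @param effectSize absolute log2 fold change, default 1.5.
#' @return list with named numeric vectors `T2D` and `AIS`.
#' @export
defaultEffects <- function(effectSize = 1.5) {
    e <- effectSize
    list(
      T2D = c(Porphyromonas = e, Lactobacillus = e, Megasphaera = e,
              Catenibacterium = e, Cetobacterium = e,
              Enterobacteriaceae_g1 = e, Enterobacteriaceae_g2 = e,
              Blautia = -e, Dorea = -e, Lachnospira = -e, Roseburia = -e),
      AIS = c(Enterobacteriaceae_g1 = e, Enterobacteriaceae_g2 = e,
              Desulfovibrio = e, Bilophila = e, Haemophilus = e,
              Citrobacter = e, Klebsiella = e, Succinivibrio = e,
              Prevotella = -e, Faecalibacterium = -e, Lachnospira = -e,
              Coprococcus = -e))
}

#' Default clinical score link
#'
#' Linear links from standardised latent dysbiosis to each clinical score,
#' on the score's own integer scale before clipping: NIHSS to \[0, 15\]
#' (admission criterion NIHSS < 16), mRS to \[0, 6\], Essen to \[0, 9\].
#'
#' @return list of per-score `intercept`, `slope`, `noise` (Gaussian sd).
#' @export
defaultScoreLink <- function() {
    list(NIHSS = list(intercept = 7, slope = 3,   noise = 2),
         mRS   = list(intercept = 2, slope = 1.2, noise = 1),
         Essen = list(intercept = 3, slope = 1.5, noise = 1.2))
}

#' Build and validate a synthetic cohort configuration
#'
#' Defaults reproduce the emulated study design: four cohorts of sizes
#' 55 (control) / 90 (AIS) / 35 (T2D) / 60 (AIS_T2D), a 37-genus panel,
#' Dirichlet-multinomial sampling, planted log2FC +/-1.5 effects whose
#' comorbid sum is additive by construction, and clinical scores monotone
#' in latent dysbiosis.
#'
#' @param nPerGroup named integer vector of group sizes (all >= 2).
#' @param panel taxon panel data.frame (`taxon_id`, `lineage`, `base`).
#' @param concentration Dirichlet precision > 0, default 100.
#' @param libraryMean,libraryDispersion negative-binomial library-size mean
#'   and size parameter, defaults 20000 and 10.
#' @param effects list of named log2FC vectors per disease (`T2D`, `AIS`).
#' @param scoreLink list from [defaultScoreLink()].
#' @param seed integer global seed; each generator stage draws from a named
#'   substream of it.
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nPerGroup = c(control = 55, AIS = 90, T2D = 35,
                                          AIS_T2D = 60),
                            panel = defaultTaxonPanel(),
                            concentration = 100,
                            libraryMean = 20000, libraryDispersion = 10,
                            effects = defaultEffects(),
                            scoreLink = defaultScoreLink(),
                            seed = 1) {
    if (is.null(names(nPerGroup)) ||
        !all(names(nPerGroup) %in% names(.ACTIVE_DISEASES)))
        stop("nPerGroup must be named with known group labels")
    if (any(nPerGroup < 2)) stop("all group sizes must be >= 2")
    if (!is.numeric(concentration) || concentration <= 0)
        stop("concentration must be > 0")
    if (libraryMean <= 0 || libraryDispersion <= 0)
        stop("library size parameters must be > 0")
    for (dis in names(effects)) {
        unknown <- setdiff(names(effects[[dis]]), panel$taxon_id)
        if (length(unknown))
            stop("effect references unknown taxon: ",
                 paste(unknown, collapse = ", "))
    }
    structure(list(nPerGroup = nPerGroup, panel = panel,
                   concentration = concentration,
                   libraryMean = libraryMean,
                   libraryDispersion = libraryDispersion,
                   effects = effects, scoreLink = scoreLink, seed = seed),
              class = "SyntheticConfig")
}

# Signed log2 effect vector active in a group (comorbid = exact sum).
.groupEffects <- function(config, group) {
    lfc <- structure(numeric(nrow(config$panel)),
                     names = config$panel$taxon_id)
    for (dis in .ACTIVE_DISEASES[[group]])
        if (!is.null(config$effects[[dis]])) {
            e <- config$effects[[dis]]
            lfc[names(e)] <- lfc[names(e)] + e
        }
    lfc
}

# Expected composition of a group: softmax(log base + log(2) * lfc).
.groupComposition <- function(config, group) {
    lfc <- .groupEffects(config, group)
    w <- log(config$panel$base) + log(2) * lfc
    p <- exp(w - max(w))
    structure(p / sum(p), names = config$panel$taxon_id)
}

#' Generate a synthetic patient cohort
#'
#' For each sample the true composition is drawn from
#' `Dirichlet(concentration * expected(group))` where the group expectation
#' is `softmax(log(base) + log(2) * lfc)` over the active disease effects
#' (the comorbid group's log2 effect vector is definitionally the sum of the
#' single-disease vectors), library size is negative binomial, and counts
#' are multinomial. Clinical severity scores are attached to stroke samples
#' via [generateScores()]. Deterministic given `config$seed`.
#'
#' @param config a [syntheticConfig()].
#' @return list with `table` (a counts [FeatureTable-class] with taxonomy),
#'   `metadata` (group labels and clinical scores), and `truth` (per-sample
#'   latent dysbiosis = planted-enriched minus planted-depleted true
#'   composition mass, per-group expected compositions, per-group signed
#'   log2 effect vectors, and the effect lists).
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    groups <- rep(names(config$nPerGroup), config$nPerGroup)
    n <- length(groups)
    ids <- sprintf("S%03d", seq_len(n))
    taxa <- config$panel$taxon_id
    k <- length(taxa)
    expected <- lapply(names(config$nPerGroup), function(g)
        .groupComposition(config, g))
    names(expected) <- names(config$nPerGroup)
    lfcByGroup <- lapply(names(config$nPerGroup), function(g)
        .groupEffects(config, g))
    names(lfcByGroup) <- names(config$nPerGroup)
    t2d <- config$effects$T2D
    enriched <- names(t2d)[t2d > 0]
    depleted <- names(t2d)[t2d < 0]
    sim <- withSeed(substreamSeed(config$seed, "cohort"), {
        counts <- matrix(0, n, k, dimnames = list(ids, taxa))
        latent <- structure(numeric(n), names = ids)
        libs <- pmax(1, stats::rnbinom(n, mu = config$libraryMean,
                                       size = config$libraryDispersion))
        for (i in seq_len(n)) {
            alpha <- config$concentration * expected[[groups[i]]]
            gam <- stats::rgamma(k, shape = alpha)
            if (sum(gam) == 0) gam <- alpha   # guard against total underflow
            comp <- structure(gam / sum(gam), names = taxa)
            counts[i, ] <- stats::rmultinom(1L, libs[i], comp)
            latent[i] <- sum(comp[enriched]) - sum(comp[depleted])
        }
        list(counts = counts, latent = latent)
    })
    taxonomyMap <- structure(config$panel$lineage, names = taxa)
    table <- FeatureTable(sim$counts, unit = "counts",
                          taxonomy = taxonomyMap)
    metadata <- data.frame(sample_id = ids, group = groups,
                           stringsAsFactors = FALSE)
    metadata <- generateScores(metadata, sim$latent, config$scoreLink,
                               seed = substreamSeed(config$seed, "scores"))
    list(table = table, metadata = metadata,
         truth = list(latent = sim$latent, expected = expected,
                      log2fcByGroup = lfcByGroup, effects = config$effects,
                      note = paste("Dirichlet-multinomial generative",
                                   "stand-in; abundance distributions are a",
                                   "modelling choice, not observed data")))
}

#' Attach clinical severity scores to stroke samples
#'
#' Standardises the latent dysbiosis of the stroke samples (AIS, AIS_T2D)
#' and maps it linearly (plus Gaussian noise) to each score, rounding and
#' clipping to the score's range: NIHSS 0-15 (admission criterion
#' NIHSS < 16), mRS 0-6, Essen 0-9. Non-stroke samples get `NA`. If all
#' latent values are equal the scores are constant up to noise and a message
#' flags that downstream correlations are undefined.
#'
#' @param metadata data.frame with `sample_id` and `group`.
#' @param latent named numeric vector of latent dysbiosis (one value per
#'   stroke sample at least).
#' @param scoreLink list from [defaultScoreLink()]; slopes and noise must be
#'   finite.
#' @param seed integer seed.
#' @return the metadata with `NIHSS`, `mRS`, `Essen` columns added.
#' @export
generateScores <- function(metadata, latent, scoreLink = defaultScoreLink(),
                           seed = 1) {
    metadata <- validateMetadata(metadata)
    stroke <- metadata$group %in% c("AIS", "AIS_T2D")
    ids <- metadata$sample_id[stroke]
    if (any(!ids %in% names(latent)))
        stop("latent value missing for some stroke samples")
    z <- latent[ids]
    if (length(z) > 0L) {
        sdz <- stats::sd(z)
        if (!is.finite(sdz) || sdz == 0) {
            message("generateScores: latent dysbiosis constant; scores are ",
                    "noise only and correlations with it are undefined")
            z <- rep(0, length(z))
        } else {
            z <- (z - mean(z)) / sdz
        }
    }
    ranges <- list(NIHSS = c(0, 15), mRS = c(0, 6), Essen = c(0, 9))
    withSeed(seed, {
        for (sc in names(ranges)) {
            link <- scoreLink[[sc]]
            if (is.null(link)) stop("scoreLink missing entry for ", sc)
            if (!all(is.finite(c(link$intercept, link$slope, link$noise))))
                stop("score link slope/intercept/noise must be finite")
            raw <- link$intercept + link$slope * z +
                   stats::rnorm(length(z), 0, link$noise)
            val <- pmin(ranges[[sc]][2L], pmax(ranges[[sc]][1L], round(raw)))
            col <- rep(NA_real_, nrow(metadata))
            col[stroke] <- val
            metadata[[sc]] <- col
        }
        metadata
    })
}

#' Generate a random rooted binary tree over taxa
#'
#' Sequential random joins: repeatedly merge two uniformly chosen subtrees,
#' assigning independent exponential(1) lengths to the two new edges, until
#' one tree remains. The root carries no edge. Deterministic given the seed.
#'
#' @param taxonIds >= 2 unique leaf names.
#' @param seed integer seed.
#' @return a rooted binary [ape::phylo] with `length(taxonIds)` leaves and
#'   `length(taxonIds) - 1` internal nodes.
#' @export
generateTree <- function(taxonIds, seed = 1) {
    taxonIds <- as.character(taxonIds)
    if (length(taxonIds) < 2L) stop("need >= 2 taxa")
    if (anyDuplicated(taxonIds)) stop("duplicate taxon ids")
    nwk <- withSeed(substreamSeed(seed, "tree"), {
        nodes <- as.list(taxonIds)
        while (length(nodes) > 1L) {
            pick <- sample.int(length(nodes), 2L)
            len <- stats::rexp(2L)
            merged <- sprintf("(%s:%.8f,%s:%.8f)",
                              nodes[[pick[1L]]], len[1L],
                              nodes[[pick[2L]]], len[2L])
            nodes[[pick[1L]]] <- merged
            nodes[[pick[2L]]] <- NULL
        }
        paste0(nodes[[1L]], ";")
    })
    ape::read.tree(text = nwk)
}

#' Taxon panel for the simulated germfree-mouse study
#'
#' OTU-style features: five Ruminococcaceae and two Lachnospira features
#' (the SCFA-producer block depleted under diabetic-donor FMT), one
#' S24-7 feature (LPS-producer, enriched), and a gut background.
#'
#' @return data.frame with columns `taxon_id`, `lineage`, `base`.
#' @export
mouseTaxonPanel <- function() {
    g <- function(phy, cls, ord, fam, gen)
        sprintf("k__Bacteria;p__%s;c__%s;o__%s;f__%s;g__%s",
                phy, cls, ord, fam, gen)
    rum <- function(i, base)
        c(sprintf("Ruminococcaceae_OTU%d", i),
          g("Firmicutes","Clostridia","Clostridiales","Ruminococcaceae",""),
          base)
    tab <- rbind(
      rum(1, 0.040), rum(2, 0.030), rum(3, 0.025), rum(4, 0.020),
      rum(5, 0.015),
      c("Lachnospira_OTU1", g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Lachnospira"), 0.025),
      c("Lachnospira_OTU2", g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Lachnospira"), 0.015),
      c("S24_7_OTU1",       g("Bacteroidetes","Bacteroidia","Bacteroidales","S24-7",""), 0.030),
      c("Bacteroides_OTU1", g("Bacteroidetes","Bacteroidia","Bacteroidales","Bacteroidaceae","Bacteroides"), 0.25),
      c("Prevotella_OTU1",  g("Bacteroidetes","Bacteroidia","Bacteroidales","Prevotellaceae","Prevotella"), 0.08),
      c("Parabacteroides_OTU1", g("Bacteroidetes","Bacteroidia","Bacteroidales","Porphyromonadaceae","Parabacteroides"), 0.05),
      c("Rikenellaceae_OTU1", g("Bacteroidetes","Bacteroidia","Bacteroidales","Rikenellaceae",""), 0.01),
      c("Faecalibacterium_OTU1", g("Firmicutes","Clostridia","Clostridiales","Ruminococcaceae","Faecalibacterium"), 0.08),
      c("Blautia_OTU1",     g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Blautia"), 0.03),
      c("Coprococcus_OTU1", g("Firmicutes","Clostridia","Clostridiales","Lachnospiraceae","Coprococcus"), 0.02),
      c("Clostridiales_OTU1", g("Firmicutes","Clostridia","Clostridiales","",""), 0.02),
      c("Oscillospira_OTU1", g("Firmicutes","Clostridia","Clostridiales","Ruminococcaceae","Oscillospira"), 0.015),
      c("Turicibacter_OTU1", g("Firmicutes","Bacilli","Turicibacterales","Turicibacteraceae","Turicibacter"), 0.005),
      c("Escherichia_OTU1", g("Proteobacteria","Gammaproteobacteria","Enterobacteriales","Enterobacteriaceae","Escherichia"), 0.01),
      c("Akkermansia_OTU1", g("Verrucomicrobia","Verrucomicrobiae","Verrucomicrobiales","Verrucomicrobiaceae","Akkermansia"), 0.01))
    data.frame(taxon_id = tab[, 1L], lineage = tab[, 2L],
               base = as.numeric(tab[, 3L]), stringsAsFactors = FALSE)
}

.MOUSE_OUTCOME_LINKS <- list(
    # slope is on standardised latent injury; positive couples the outcome
    # to S24-7 enrichment / SCFA depletion
    infarct_ratio = list(intercept = 0.25, slope = 0.08, noise = 0.04,
                         lo = 0.01, hi = 0.99, integer = FALSE),
    mNSS          = list(intercept = 7,    slope = 2.5,  noise = 0.8,
                         lo = 0, hi = 14, integer = TRUE),
    LBP           = list(intercept = 10,   slope = 2,    noise = 0.8,
                         lo = 0.1, hi = Inf, integer = FALSE),
    LPS           = list(intercept = 0.5,  slope = 0.1,  noise = 0.04,
                         lo = 0.01, hi = Inf, integer = FALSE),
    # tight-junction expression fold changes fall as injury rises;
    # chemokine expression rises
    Ocln_ileum  = list(log2 = TRUE, slope = -0.5, noise = 0.25),
    Cldn4_ileum = list(log2 = TRUE, slope = -0.5, noise = 0.25),
    Ocln_colon  = list(log2 = TRUE, slope = -0.5, noise = 0.25),
    Cldn4_colon = list(log2 = TRUE, slope = -0.5, noise = 0.25),
    Cxcl1_colon = list(log2 = TRUE, slope = 0.5,  noise = 0.25),
    Cxcl2_colon = list(log2 = TRUE, slope = 0.5,  noise = 0.25))

#' Generate a germfree-mouse FMT outcome study
#'
#' Mouse abundances come from the same Dirichlet-multinomial machinery with
#' the SCFA-producer features (Ruminococcaceae, Lachnospira) depleted and an
#' S24-7 feature enriched in the diabetic-donor group. A standardised latent
#' injury value (S24-7 mass minus SCFA-producer mass) drives the outcomes:
#' infarct ratio in \[0, 1\], mNSS on 0-14, serum LBP and LPS positively
#' coupled, and tight-junction expression fold changes (Ocln/Cldn4, as
#' 2^-ddCt values) negatively coupled, with Cxcl chemokine expression
#' positively coupled. `coupling` scales every outcome slope (0 = pure
#' noise); a named vector scales per outcome and must name known outcomes.
#'
#' @param nControl,nT2D group sizes (>= 2 each), defaults 5 and 4.
#' @param coupling scalar or named numeric slope multiplier, default 1.
#' @param seed integer seed.
#' @param effectSize absolute log2 fold change of the planted features,
#'   default 1.5.
#' @return list with `table` (counts [FeatureTable-class]), `metadata`
#'   (`group` control_FMT/T2D_FMT plus outcome columns), and `truth`
#'   (latent injury, planted effects).
#' @export
generateMouseStudy <- function(nControl = 5, nT2D = 4, coupling = 1,
                               seed = 1, effectSize = 1.5) {
    if (nControl < 2 || nT2D < 2) stop("need >= 2 mice per group")
    links <- .MOUSE_OUTCOME_LINKS
    if (!is.null(names(coupling)) && length(names(coupling))) {
        unknown <- setdiff(names(coupling), names(links))
        if (length(unknown))
            stop("coupling references unknown outcome: ",
                 paste(unknown, collapse = ", "))
        cp <- structure(rep(1, length(links)), names = names(links))
        cp[names(coupling)] <- coupling
    } else {
        if (length(coupling) != 1L || !is.finite(coupling))
            stop("coupling must be a finite scalar or a named vector")
        cp <- structure(rep(coupling, length(links)), names = names(links))
    }
    panel <- mouseTaxonPanel()
    scfa <- grep("^(Ruminococcaceae|Lachnospira)_OTU", panel$taxon_id,
                 value = TRUE)
    s247 <- "S24_7_OTU1"
    eff <- structure(rep(-effectSize, length(scfa)), names = scfa)
    eff[s247] <- effectSize
    cfg <- syntheticConfig(nPerGroup = c(control_FMT = nControl,
                                         T2D_FMT = nT2D),
                           panel = panel, concentration = 100,
                           libraryMean = 15000, libraryDispersion = 10,
                           effects = list(T2D = eff),
                           seed = substreamSeed(seed, "mouse"))
    groups <- rep(c("control_FMT", "T2D_FMT"), c(nControl, nT2D))
    n <- length(groups)
    ids <- sprintf("M%02d", seq_len(n))
    taxa <- panel$taxon_id
    k <- length(taxa)
    expected <- lapply(c("control_FMT", "T2D_FMT"), function(g)
        .groupComposition(cfg, g))
    names(expected) <- c("control_FMT", "T2D_FMT")
    out <- withSeed(substreamSeed(seed, "mouse_draws"), {
        counts <- matrix(0, n, k, dimnames = list(ids, taxa))
        latent <- structure(numeric(n), names = ids)
        libs <- pmax(1, stats::rnbinom(n, mu = cfg$libraryMean,
                                       size = cfg$libraryDispersion))
        for (i in seq_len(n)) {
            alpha <- cfg$concentration * expected[[groups[i]]]
            gam <- stats::rgamma(k, shape = alpha)
            if (sum(gam) == 0) gam <- alpha
            comp <- structure(gam / sum(gam), names = taxa)
            counts[i, ] <- stats::rmultinom(1L, libs[i], comp)
            latent[i] <- comp[s247] - sum(comp[scfa])
        }
        z <- latent
        sdz <- stats::sd(z)
        z <- if (is.finite(sdz) && sdz > 0) (z - mean(z)) / sdz else z * 0
        meta <- data.frame(sample_id = ids, group = groups,
                           stringsAsFactors = FALSE)
        for (oc in names(links)) {
            ln <- links[[oc]]
            slope <- cp[[oc]] * ln$slope
            if (isTRUE(ln$log2)) {
                val <- 2^(slope * z + stats::rnorm(n, 0, ln$noise))
            } else {
                raw <- ln$intercept + slope * z + stats::rnorm(n, 0, ln$noise)
                if (ln$integer) raw <- round(raw)
                val <- pmin(ln$hi, pmax(ln$lo, raw))
            }
            meta[[oc]] <- val
        }
        list(counts = counts, latent = latent, meta = meta)
    })
    taxonomyMap <- structure(panel$lineage, names = taxa)
    list(table = FeatureTable(out$counts, unit = "counts",
                              taxonomy = taxonomyMap),
         metadata = out$meta,
         truth = list(latent = out$latent, effects = eff,
                      scfaFeatures = scfa, s247Feature = s247))
}
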