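# Synthetic-data generator: design balance, generative structure, determinism.

test_that("design assigns balanced replicates and Bernoulli environments", {
    d <- simulateDesign(simulationSpec(nWorms = 4, nReplicates = 2, nGenes = 10,
                                       seed = 1))
    expect_equal(nrow(d), 4)
    expect_equal(as.integer(table(d$replicate)), c(2L, 2L))
    expect_true(all(d$parental_age %in% 0:1))
    expect_true(all(d$early_temp %in% 0:1))

    d180 <- simulateDesign(simulationSpec(seed = 2, nGenes = 10))
    expect_equal(nrow(d180), 180)
    expect_equal(as.integer(table(d180$replicate)), rep(36L, 5))
    # environments are assigned per worm, not per replicate block
    expect_gt(sd(tapply(d180$parental_age, d180$replicate, mean)), 0)

    expect_error(simulationSpec(nWorms = 8, nReplicates = 5, nGenes = 10),
                 "2 \\* nReplicates")
})

test_that("generator is deterministic given the spec seed", {
    spec <- simulationSpec(nWorms = 24, nReplicates = 3, nGenes = 40, seed = 9)
    a <- simulateStudy(spec)
    b <- simulateStudy(spec)
    expect_identical(counts(a), counts(b))
    expect_identical(phenotype(a), phenotype(b))
    expect_identical(groundTruth(a)$causalBrood, groundTruth(b)$causalBrood)
    sc1 <- simulateSiteCalls(5, 50, seed = 4)
    sc2 <- simulateSiteCalls(5, 50, seed = 4)
    expect_identical(as.data.frame(sc1), as.data.frame(sc2))
    an1 <- simulateChromatinAnnotation(letters, seed = 5)
    expect_identical(an1, simulateChromatinAnnotation(letters, seed = 5))
})

test_that("library sizes are the realized column sums", {
    we <- smallStudy()
    expect_identical(unname(libSizes(we)), unname(colSums(counts(we))))
})

test_that("a planted parental-age log-fold-change is recovered in the means", {
    spec <- simulationSpec(nWorms = 180, nReplicates = 5, nGenes = 80,
                           fracEnvGenes = 0, fracTraitGenes = 0,
                           nbDispersion = 5, seed = 21)
    d <- simulateDesign(spec)
    we <- simulateExpression(d, spec,
                             bAge = c(gene_0005 = log(2), gene_0010 = 0))
    cpm <- cpmValues(cpmNormalize(we))
    age <- phenotype(we)$parental_age
    ratio <- mean(cpm["gene_0005", age == 1]) / mean(cpm["gene_0005", age == 0])
    # analytic NB mean ratio is exactly 2; allow Monte-Carlo slack at n = 180
    expect_gt(ratio, 1.6)
    expect_lt(ratio, 2.5)
    ratioNull <- mean(cpm["gene_0010", age == 1]) /
        mean(cpm["gene_0010", age == 0])
    expect_lt(abs(ratioNull - 1), 0.35)
})

test_that("traits carry the planted causal effect and the target brood SD", {
    spec <- simulationSpec(nWorms = 180, nReplicates = 5, nGenes = 200,
                           fracTraitGenes = 0, fracEnvGenes = 0, seed = 31)
    d <- simulateDesign(spec)
    we <- simulateExpression(d, spec)
    we <- simulateTraits(we, spec,
                         causalBrood = c(gene_0007 = 0.4),
                         causalElo = c(gene_0002 = 0.3))
    ph <- phenotype(we)
    expect_lt(abs(sd(ph$early_brood) - 20.3) / 20.3, 0.10)
    expect_true(all(ph$elo_hours >= 66 & ph$elo_hours <= 74))
    expect_true(all(ph$early_brood >= 0))
    z <- scale(cpmValues(we)["gene_0007", ])[, 1]
    # closed-form: cor(z, trait) = beta / sd(latent) = 0.4 (unit variance)
    expect_lt(abs(cor(z, ph$early_brood) - 0.4), 0.15)
    expect_error(simulateTraits(we, spec, causalBrood = c(nope = 1)),
                 "absent")
})

test_that("null traits produce no Bonferroni hits beyond the nominal rate", {
    spec <- simulationSpec(nWorms = 90, nReplicates = 5, nGenes = 300,
                           fracTraitGenes = 0, fracEnvGenes = 0, seed = 41)
    we <- simulateStudy(spec)
    s <- scanTraitAssociations(we, "early_brood")
    expect_lte(sum(s$significant), 2)   # FWER 0.05: nearly always 0 hits
})

test_that("site-call simulation produces the planted patterns", {
    # error-free, variant-free: all sites unambiguous, identical across worms
    sc <- simulateSiteCalls(6, 100, depthMean = 40, errorRate = 0, seed = 7)
    cl <- classifySiteCalls(sc, minDepth = 1)
    expect_true(all(cl$class == "unambiguous"))
    expect_equal(unname(cl[, length(unique(base1)), by = "pos"]$V1),
                 rep(1L, 100))

    # planted het at high depth: both bases near 0.5
    sc <- simulateSiteCalls(4, 30, depthMean = 100, errorRate = 0,
                            hetSites = data.frame(pos = 5, worm = 2), seed = 8)
    cl <- classifySiteCalls(sc, minDepth = 20)
    h <- cl[cl$pos == 5 & cl$worm_id == "worm_002", ]
    expect_equal(h$class, "ambiguous2")
    expect_lt(abs(h$freq1 - 0.5), 0.2)

    # planted hom alt in one worm: that worm differs, others agree
    sc <- simulateSiteCalls(5, 30, depthMean = 40, errorRate = 0,
                            homSites = data.frame(pos = 3, worm = 4), seed = 9)
    cl <- classifySiteCalls(sc, minDepth = 1)
    atSite <- cl[cl$pos == 3, ]
    expect_true(all(atSite$class == "unambiguous"))
    expect_equal(length(unique(atSite$base1)), 2L)
    expect_equal(atSite$base1[atSite$worm_id == "worm_004"] ==
                 atSite$base1[atSite$worm_id == "worm_001"], FALSE)
})

test_that("chromatin annotation respects the label probabilities", {
    g <- sprintf("g%05d", 1:10000)
    annAll <- simulateChromatinAnnotation(g, pRegulated = 1, pOther = 0,
                                          seed = 2)
    expect_true(all(annAll$domain == "regulated"))
    ann <- simulateChromatinAnnotation(g, pRegulated = 0.5, pOther = 0,
                                       seed = 3)
    expect_lt(abs(mean(ann$domain == "regulated") - 0.5), 0.02)
    expect_true(all(ann$tissue %in% c("soma", "germline", "other")))
})
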