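# Random-intercept LMM engine, trait scan, NB environment scan, variance Z,
# RNAi effect test.

test_that("with one group the engine reduces to ordinary least squares", {
    set.seed(1)
    x <- rnorm(40)
    y <- 1.5 * x + rnorm(40)
    f <- fitLmm(y, x, groups = rep(1, 40))
    ols <- unname(coef(lm(y ~ x)))
    expect_equal(f$coefficients$estimate, ols, tolerance = 1e-8)
    expect_equal(f$sigma2_u, 0)
})

test_that("noise-free grouped data is interpolated exactly", {
    x <- c(1, 2, 3, 4, 1, 2, 3, 4)
    g <- rep(1:2, each = 4)
    y <- 2 * x + c(1, -1)[g]
    f <- fitLmm(y, x, g)
    expect_equal(f$coefficients$estimate[2], 2, tolerance = 1e-6)
    expect_lt(f$sigma2_e, 1e-6)
})

test_that("estimates agree with lme4 and with a grid-search oracle", {
    skip_if_not_installed("lme4")
    set.seed(42)
    for (rep in 1:5) {
        g <- rep(1:3, each = 20)
        x <- rnorm(60)
        y <- 0.7 * x + c(-1, 0, 1)[g] * 0.8 + rnorm(60)
        f <- fitLmm(y, x, g)
        m <- lme4::lmer(y ~ x + (1 | g), REML = TRUE)
        expect_equal(f$coefficients$estimate, unname(lme4::fixef(m)),
                     tolerance = 1e-5)
        vc <- as.data.frame(lme4::VarCorr(m))
        expect_equal(f$sigma2_u, vc$vcov[1], tolerance = 1e-4)
        expect_equal(f$sigma2_e, vc$vcov[2], tolerance = 1e-4)
        # independent brute-force profiled-likelihood oracle
        o <- gridSearchReml(y, cbind(1, x), g)
        expect_equal(f$coefficients$estimate, o$b, tolerance = 1e-4)
    }
})

test_that("the vectorized scan path matches the general engine", {
    we <- smallStudy()
    ph <- phenotype(we)
    s <- scanTraitAssociations(we, "early_brood")
    for (g in s$gene[seq(1, nrow(s), by = 17)]) {
        f <- fitLmm(ph$early_brood, cpmValues(we)[g, ], ph$replicate)
        i <- match(g, s$gene)
        expect_equal(s$estimate[i], f$coefficients$estimate[2],
                     tolerance = 1e-4)
        expect_equal(s$se[i], f$coefficients$se[2], tolerance = 1e-4)
    }
    # determinism: identical inputs, identical results
    expect_identical(s, scanTraitAssociations(we, "early_brood"))
})

test_that("the Bonferroni flag threshold is alpha / G exactly", {
    expect_equal(bonferroniThreshold(0.05, 8824), 0.05 / 8824)
    expect_equal(signif(bonferroniThreshold(0.05, 8824), 3), 5.67e-6)
    for (ag in list(c(0.05, 500), c(0.01, 7938), c(0.1, 11))) {
        expect_equal(bonferroniThreshold(ag[1], ag[2]), ag[1] / ag[2])
    }
    we <- smallStudy()
    s <- scanTraitAssociations(we, "early_brood", alpha = 0.05)
    expect_equal(attr(s, "nominalThreshold"), 0.05 / nrow(s))
    expect_identical(s$significant, s$p < 0.05 / nrow(s))
})

test_that("scan p-values are calibrated under the null", {
    # trait independent of all genes: p approximately uniform
    spec <- simulationSpec(nWorms = 120, nReplicates = 5, nGenes = 300,
                           fracTraitGenes = 0, fracEnvGenes = 0, seed = 77)
    we <- simulateStudy(spec)
    s <- scanTraitAssociations(we, "early_brood")
    frac <- mean(s$p < 0.05)
    se <- sqrt(0.05 * 0.95 / nrow(s))
    expect_lt(frac, 0.05 + 4 * se)
    ks <- suppressWarnings(ks.test(s$p, "punif"))
    expect_gt(ks$p.value, 0.001)
})

test_that("NB environment scan recovers a planted fold change", {
    spec <- simulationSpec(nWorms = 120, nReplicates = 5, nGenes = 30,
                           fracEnvGenes = 0, fracTraitGenes = 0,
                           nbDispersion = 5, seed = 13)
    d <- simulateDesign(spec)
    we <- cpmNormalize(simulateExpression(d, spec,
                                          bAge = c(gene_0003 = log(2))))
    e <- scanEnvironmentDE(we)
    i <- match("gene_0003", e$gene)
    seApprox <- abs(e$age_coef[i]) / abs(qnorm(e$age_p[i] / 2))
    expect_lt(abs(e$age_coef[i] - log(2)), 3 * seApprox)
    # null genes stay mostly non-significant at per-gene alpha
    nullP <- e$age_p[e$gene != "gene_0003"]
    expect_lt(mean(nullP < 0.05), 0.25)
    expect_true(all(e$dispersion > 0))
})

test_that("constant counts give zero coefficients and p of 1", {
    cts <- matrix(50L, 3, 12,
                  dimnames = list(paste0("g", 1:3), paste0("w", 1:12)))
    ph <- data.frame(worm_id = paste0("w", 1:12),
                     replicate = rep(1:3, each = 4),
                     parental_age = rep(c(0, 1), 6),
                     early_temp = rep(c(0, 0, 1, 1), 3))
    we <- cpmNormalize(WormExperiment(cts, ph))
    e <- scanEnvironmentDE(we)
    expect_equal(e$age_coef, rep(0, 3))
    expect_equal(e$age_p, rep(1, 3))
})

test_that("variance Z-scores measure departure from the mean-variance trend", {
    # genes exactly on a power-law trend: all Z = 0
    env <- data.frame(gene = sprintf("g%03d", 1:100),
                      mean_cpm = 10^seq(0, 3, length.out = 100))
    env$unexplained_var <- 10^(0.5 * log10(env$mean_cpm) - 1)
    vz <- varianceZscores(env)
    expect_lt(max(abs(vz$z)), 1e-8)

    # one inflated gene among on-trend genes has the maximum Z
    env2 <- env
    env2$unexplained_var[37] <- env2$unexplained_var[37] * 100
    vz2 <- varianceZscores(env2)
    expect_equal(which.max(vz2$z), 37L)

    # residual z-scoring: mean is zero by construction
    set.seed(5)
    env3 <- env
    env3$unexplained_var <- env3$unexplained_var * 10^rnorm(100, 0, 0.3)
    vz3 <- varianceZscores(env3)
    expect_lt(abs(mean(vz3$z)), 1e-6)

    # zero-variance genes are excluded, not fatal
    env4 <- env
    env4$unexplained_var[1] <- 0
    expect_equal(attr(varianceZscores(env4), "excluded"), "g001")
})

test_that("RNAi effect test detects a planted knockdown effect", {
    set.seed(8)
    nPer <- 30
    reps <- rep(1:3, length.out = 2 * nPer)
    treatment <- rep(c("ev", "puf-5"), each = nPer)
    brood <- ifelse(treatment == "ev", 100, 80) + rnorm(2 * nPer, 0, 5)
    r <- rnaiEffectTest(brood, treatment, reps)
    expect_equal(r$treatment, "puf-5")
    expect_lt(abs(r$estimate + 20), 5)
    expect_lt(r$p, 0.001)

    # single replicate reduces to the two-sample linear model
    r1 <- rnaiEffectTest(brood, treatment, rep(1, 2 * nPer))
    lmfit <- summary(lm(brood ~ relevel(factor(treatment), "ev")))
    expect_equal(r1$estimate, unname(coef(lmfit)[2, 1]), tolerance = 1e-8)

    # tiny treatment arms are excluded
    r2 <- rnaiEffectTest(c(brood, 55, 57), c(treatment, "tiny", "tiny"),
                         c(reps, 1, 2))
    expect_equal(attr(r2, "excluded"), "tiny")
    expect_error(rnaiEffectTest(brood, treatment, reps, control = "none"),
                 "control")
})
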