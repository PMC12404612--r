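# Tissue x domain ANOVA, regulated-proportion KS test, variance Wilcoxon.

makeAnnotation <- function(genes, domain, tissue) {
    data.frame(gene = genes, domain = domain, tissue = tissue,
               stringsAsFactors = FALSE)
}

test_that("ANOVA detects a single shifted tissue-domain cell", {
    set.seed(1)
    nPer <- 50
    cells <- expand.grid(tissue = c("soma", "germline"),
                         domain = c("active", "regulated"))
    genes <- sprintf("g%03d", seq_len(4 * nPer))
    ann <- makeAnnotation(genes,
                          rep(cells$domain, each = nPer),
                          rep(cells$tissue, each = nPer))
    beta <- rnorm(4 * nPer, 0, 0.1)
    shifted <- ann$tissue == "soma" & ann$domain == "regulated"
    beta[shifted] <- beta[shifted] - 0.3
    rep <- tissueDomainAnova(data.frame(gene = genes, beta1 = beta), ann)
    pInt <- rep$anova$p[rep$anova$term == "tissue:domain"]
    expect_lt(pInt, 1e-6)
    ct <- rep$cellTests
    sig <- ct$p < 0.01 & ct$mean < -0.1
    expect_identical(sig, ct$tissue == "soma" & ct$domain == "regulated")
    # Tukey adjusted p-values are valid probabilities
    expect_true(all(rep$tukey$p_adj >= 0 & rep$tukey$p_adj <= 1))
})

test_that("constant effect sizes give F = 0 and p = 1 by convention", {
    genes <- sprintf("g%02d", 1:40)
    ann <- makeAnnotation(genes, rep(c("active", "regulated"), 20),
                          rep(c("soma", "germline"), each = 20))
    rep <- tissueDomainAnova(data.frame(gene = genes, beta1 = rep(0.2, 40)),
                             ann)
    expect_equal(rep$anova$F, rep(0, 3))
    expect_equal(rep$anova$p, rep(1, 3))
})

test_that("balanced ANOVA sums of squares decompose additively", {
    set.seed(2)
    nPer <- 20
    genes <- sprintf("g%03d", seq_len(4 * nPer))
    ann <- makeAnnotation(
        genes, rep(rep(c("active", "regulated"), each = nPer), 2),
        rep(c("soma", "germline"), each = 2 * nPer))
    beta <- rnorm(4 * nPer)
    d <- merge(data.frame(gene = genes, beta1 = beta), ann, by = "gene")
    fit <- aov(beta1 ~ tissue * domain, data = d)
    sm <- summary(fit)[[1]]
    ssTotal <- sum((d$beta1 - mean(d$beta1))^2)
    expect_equal(sum(sm[, "Sum Sq"]), ssTotal, tolerance = 1e-8)
})

test_that("empty cells are reported by name", {
    genes <- sprintf("g%02d", 1:30)
    ann <- makeAnnotation(genes, rep("active", 30),
                          rep(c("soma", "germline"), 15))
    expect_error(
        tissueDomainAnova(data.frame(gene = genes, beta1 = rnorm(30)), ann),
        "regulated")
})

test_that("KS test separates fully regulated sets from a mixed background", {
    background <- sprintf("g%04d", 1:1000)
    ann <- makeAnnotation(background,
                          rep(c("active", "regulated"), 500),
                          "soma")
    regulated <- background[seq(2, 1000, by = 2)]
    setsReg <- lapply(1:100, function(i) sample(regulated, 10))
    r <- regulatedProportionTest(setsReg, background, ann, nRandom = 200,
                                 seed = 2)
    expect_equal(unname(stats::median(r$observed)), 1)
    expect_lt(r$ks[["p"]], 0.001)

    # identical observed and control collections: statistic 0
    same <- lapply(1:50, function(i) background[(10 * i - 9):(10 * i)])
    r2 <- regulatedProportionTest(same, background, ann, nRandom = 50,
                                  seed = 3)
    r2b <- suppressWarnings(stats::ks.test(r2$observed, r2$observed))
    expect_equal(unname(r2b$statistic), 0)
})

test_that("'other'-domain genes are dropped from proportion denominators", {
    background <- paste0("g", 1:100)
    dom <- rep(c("active", "regulated", "other"), length.out = 100)
    ann <- makeAnnotation(background, dom, "soma")
    # a set of 9: 3 active, 3 regulated, 3 other -> proportion 3/6
    set <- background[1:9]
    r <- regulatedProportionTest(list(set), background, ann, nRandom = 20,
                                 seed = 1)
    expect_equal(unname(r$observed), 0.5)
    expect_equal(unname(r$medianAnnotated), 6)
    # a set with only 'other' genes is dropped
    onlyOther <- background[dom == "other"][1:5]
    r2 <- regulatedProportionTest(list(set, onlyOther), background, ann,
                                  nRandom = 20, seed = 1)
    expect_equal(r2$droppedSets, 1)
})

test_that("KS results are deterministic given the seed", {
    background <- paste0("g", 1:200)
    ann <- makeAnnotation(background, rep(c("active", "regulated"), 100),
                          "soma")
    sets <- lapply(1:20, function(i) background[(i * 5):(i * 5 + 9)])
    r1 <- regulatedProportionTest(sets, background, ann, nRandom = 100,
                                  seed = 7)
    r2 <- regulatedProportionTest(sets, background, ann, nRandom = 100,
                                  seed = 7)
    expect_identical(r1$ks, r2$ks)
    expect_identical(r1$random, r2$random)
})

test_that("the variance-by-domain Wilcoxon detects a shift and is symmetric", {
    set.seed(4)
    genes <- sprintf("g%03d", 1:400)
    ann <- makeAnnotation(genes, rep(c("regulated", "active"), each = 200),
                          "soma")
    z <- c(rnorm(200, 1), rnorm(200, 0))   # regulated shifted +1
    vz <- data.frame(gene = genes, z = z)
    r <- varianceByDomainTest(vz, ann)
    expect_lt(r$p, 1e-10)
    expect_gt(r$medianRegulated, r$medianActive)
    # swapping the labels leaves the two-sided p unchanged
    annSwap <- ann
    annSwap$domain <- ifelse(ann$domain == "regulated", "active", "regulated")
    expect_equal(varianceByDomainTest(vz, annSwap)$p, r$p)
    expect_error(varianceByDomainTest(
        vz, makeAnnotation(genes, "regulated", "soma")), "non-empty")
})
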