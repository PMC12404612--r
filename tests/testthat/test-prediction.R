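# PCA scores, cumulative-PC regression, greedy selection, resampling,
# elastic-net LOOCV.

test_that("PCA scores are orthogonal and capture a rank-1 structure", {
    set.seed(2)
    u <- rnorm(30)
    v <- rnorm(15)
    rank1 <- outer(v, u)             # genes x worms, rank 1
    pc <- pcaScores(rank1)
    expect_gt(pc$varExplained[1], 1 - 1e-10)
    sc <- pc$scores
    off <- crossprod(sc[, 1:5])
    expect_lt(max(abs(off[upper.tri(off)])), 1e-8)
    # sign convention: largest-magnitude loading is positive
    expect_gt(pc$rotation[which.max(abs(pc$rotation[, 1])), 1], 0)
    expect_error(pcaScores(rank1[, 1, drop = FALSE]), "2 worms")
})

test_that("cumulative PC regression reaches the exact and null limits", {
    set.seed(4)
    mat <- matrix(rnorm(40 * 25), 40, 25)   # genes x worms
    pc <- pcaScores(mat)
    # trait = PC1 exactly: R2 = 1 at k = 1
    cc <- cumulativePcR2(pc$scores, pc$scores[, 1], kMax = 3, nPerm = 10)
    expect_equal(cc$r2[1], 1, tolerance = 1e-10)
    expect_true(all(diff(cc$r2) >= -1e-12))
    # k = n - 1: R2 = 1 even for a shuffled trait
    y <- rnorm(25)
    cc2 <- cumulativePcR2(pc$scores, sample(y), kMax = 24, nPerm = 5)
    expect_equal(cc2$r2[24], 1, tolerance = 1e-8)
    expect_gt(cc2$null_mean[24], 1 - 1e-8)
})

test_that("the shuffled-trait R2 matches the k/(n-1) null", {
    set.seed(6)
    n <- 100
    scores <- pcaScores(matrix(rnorm(150 * n), 150, n))$scores
    y <- rnorm(n)
    nPerm <- 400
    cc <- cumulativePcR2(scores, y, kMax = 20, nPerm = nPerm, seed = 3)
    for (k in c(1, 5, 20)) {
        expected <- k / (n - 1)
        mcse <- cc$null_sd[k] / sqrt(nPerm)
        expect_lt(abs(cc$null_mean[k] - expected), 3 * mcse + 1e-3)
    }
})

test_that("greedy selection equals exhaustive best-subset on small fixtures", {
    for (seed in 1:10) {
        set.seed(seed)
        n <- 30
        X <- matrix(rnorm(n * 8), n, 8,
                    dimnames = list(NULL, paste0("g", 1:8)))
        y <- X[, 3] * 0.8 + X[, 6] * 0.5 + rnorm(n)
        gs <- greedyForwardSelection(X, y, kMax = 2)
        r2 <- function(vars) summary(lm(y ~ X[, vars]))$r.squared
        best1 <- which.max(vapply(1:8, function(j) r2(j), numeric(1)))
        expect_equal(gs$genes[1], colnames(X)[best1])
        expect_equal(gs$r2[1], r2(best1), tolerance = 1e-10)
        rest <- setdiff(1:8, best1)
        best2 <- rest[which.max(vapply(rest, function(j)
            r2(c(best1, j)), numeric(1)))]
        expect_equal(gs$genes[2], colnames(X)[best2])
        expect_equal(gs$r2[2], r2(c(best1, best2)), tolerance = 1e-10)
        expect_true(all(diff(gs$r2) >= -1e-12))
    }
})

test_that("greedy handles perfect predictors, duplicates and ties", {
    set.seed(9)
    n <- 25
    noise <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("n", 1:5)))
    y <- rnorm(n)
    X <- cbind(noise, exact = y, dup = y)
    gs <- greedyForwardSelection(X, y, kMax = 3)
    # the trait-identical gene is picked first (dup ties broken by id)
    expect_equal(gs$genes[1], "dup")   # "dup" < "exact" lexicographically
    expect_equal(gs$r2[1], 1, tolerance = 1e-10)
    # the duplicate adds nothing and is never selected next
    expect_false("exact" %in% gs$genes[-1])
})

test_that("train/test resampling recovers planted signal and is reproducible", {
    set.seed(12)
    n <- 60
    X <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(NULL, sprintf("g%02d", 1:30)))
    y <- X[, 1] + 0.8 * X[, 2] + 0.6 * X[, 3]   # noiseless 3-gene trait
    rs <- trainTestResampling(X, y, nIter = 50, k = 5, seed = 2)
    expect_gte(rs$summary[["median_test_r2"]], 0.99)
    # determinism: same seed, same gene sets
    rs2 <- trainTestResampling(X, y, nIter = 50, k = 5, seed = 2)
    expect_identical(rs$geneSets, rs2$geneSets)
    expect_equal(rs$iterations$test_r2, rs2$iterations$test_r2)
    # splits are disjoint halves
    expect_true(all(abs(rs$iterations$train_r2 - 1) < 1e-10))
})

test_that("pure-noise traits do not survive the test split", {
    set.seed(13)
    n <- 100
    X <- matrix(rnorm(n * 200), n, 200,
                dimnames = list(NULL, sprintf("g%03d", 1:200)))
    y <- rnorm(n)
    rs <- trainTestResampling(X, y, nIter = 40, k = 10, seed = 5)
    # train R2 is inflated by selection; test R2 collapses
    expect_gt(median(rs$iterations$train_r2), 0.5)
    expect_lt(rs$summary[["median_test_r2"]], 0.1)
})

test_that("elastic-net LOOCV predicts strong signal and never leaks", {
    set.seed(20)
    n <- 40
    X <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(NULL, sprintf("g%02d", 1:30)))
    y <- 2 * X[, 5] + rnorm(n, 0, 0.1)
    fit <- elasticNetLoocv(X, y, seed = 3)
    expect_gte(fit$r2, 0.95)

    # leakage guard: perturbing a held-out trait cannot change its prediction
    y2 <- y
    y2[7] <- y2[7] + 1000
    fit2 <- elasticNetLoocv(X, y2, seed = 3)
    expect_identical(fit$predicted[7], fit2$predicted[7])

    # infinite-penalty limit: predictions shrink to the training mean
    fit3 <- elasticNetLoocv(X, y, seed = 3, lambda = 1e9)
    expect_lt(sd(fit3$predicted), 0.05 * sd(y))
    expect_lt(abs(mean(fit3$predicted) - mean(y)), 0.05 * sd(y))

    # zero-variance predictors are dropped with a warning
    X2 <- cbind(X, flat = rep(1, n))
    expect_warning(elasticNetLoocv(X2, y, seed = 3), "zero-variance")
})
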