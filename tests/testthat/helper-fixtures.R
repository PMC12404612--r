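# Shared fixtures, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

# Small complete study: 60 worms, 5 replicates, 120 genes.
smallStudy <- function() {
    if (is.null(.fixtureCache$small)) {
        .fixtureCache$small <- simulateStudy(
            simulationSpec(nWorms = 60, nReplicates = 5, nGenes = 120,
                           seed = 11))
    }
    .fixtureCache$small
}

# A WormExperiment built directly from a given counts matrix, with equal
# library sizes enforced by a balancing pseudo-gene so CPM is proportional
# to the counts row.
wormExperimentFromRows <- function(rows, replicate = NULL, parental_age = NULL,
                                   early_temp = NULL, traits = NULL) {
    rows <- as.matrix(rows)
    n <- ncol(rows)
    total <- max(colSums(rows)) + 1000
    balance <- total - colSums(rows)
    cts <- rbind(rows, balance = balance)
    rownames(cts) <- c(rownames(rows), "balance_gene")
    colnames(cts) <- sprintf("w%02d", seq_len(n))
    ph <- data.frame(
        worm_id = colnames(cts),
        replicate = if (is.null(replicate)) rep(1L, n) else replicate,
        parental_age = if (is.null(parental_age))
            rep(c(0L, 1L), length.out = n) else parental_age,
        early_temp = if (is.null(early_temp))
            rep(c(0L, 0L, 1L, 1L), length.out = n) else early_temp)
    if (!is.null(traits)) ph <- cbind(ph, traits)
    cpmNormalize(WormExperiment(cts, ph))
}

# Independent GLS fit of the random-intercept model at a fixed variance
# ratio lambda, by direct dense-matrix algebra (oracle path).
glsAtLambda <- function(y, X, groups, lambda) {
    gi <- as.integer(factor(groups))
    Z <- outer(gi, seq_len(max(gi)), "==") + 0
    V <- diag(length(y)) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    A <- t(X) %*% Vi %*% X
    b <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    wrss <- as.numeric(t(r) %*% Vi %*% r)
    list(b = as.numeric(b), wrss = wrss,
         logdetV = as.numeric(determinant(V)$modulus),
         logdetA = as.numeric(determinant(A)$modulus))
}

# Brute-force profiled REML over a lambda grid with local refinement;
# independent of the package's engine.
gridSearchReml <- function(y, X, groups) {
    n <- length(y); p <- ncol(X)
    crit <- function(lam) {
        g <- glsAtLambda(y, X, groups, lam)
        (n - p) * log(g$wrss / (n - p)) + g$logdetV + g$logdetA
    }
    ll <- seq(-12, 8, length.out = 201)
    vals <- vapply(ll, function(l) crit(exp(l)), numeric(1))
    i <- which.min(vals)
    lo <- ll[max(1, i - 1)]; hi <- ll[min(length(ll), i + 1)]
    for (k in 1:40) {    # golden-section refinement
        m1 <- lo + 0.382 * (hi - lo); m2 <- lo + 0.618 * (hi - lo)
        if (crit(exp(m1)) < crit(exp(m2))) hi <- m2 else lo <- m1
    }
    lam <- exp((lo + hi) / 2)
    if (crit(1e-12) < crit(lam)) lam <- 0
    g <- glsAtLambda(y, X, groups, lam)
    list(b = g$b, lambda = lam)
}
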