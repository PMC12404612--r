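#' Principal-component scores of the expression matrix
#'
#' PCA of the mean-normalized, log2-transformed CPM matrix (see
#' [logTransformForPca()]): per-gene centred singular value decomposition,
#' components ordered by decreasing variance explained.  The sign of each
#' component is fixed so its largest-magnitude gene loading is positive,
#' making scores reproducible across platforms.
#'
#' @param logMat genes x worms matrix from [logTransformForPca()].
#' @return list with `scores` (worms x components), `varExplained`
#'   (proportion per component) and `rotation` (gene loadings).
#' @export
pcaScores <- function(logMat) {
    if (ncol(logMat) < 2) stop("need at least 2 worms")
    if (any(!is.finite(logMat))) stop("matrix must be finite")
    pc <- stats::prcomp(t(logMat), center = TRUE, scale. = FALSE)
    flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    scores <- sweep(pc$x, 2, flip, "*")
    rotation <- sweep(pc$rotation, 2, flip, "*")
    list(scores = scores,
         varExplained = pc$sdev^2 / sum(pc$sdev^2),
         rotation = rotation)
}

#' Cumulative-PC regression R2 with a permutation null
#'
#' Adds principal components to a multiple linear regression of the trait,
#' in order of variance explained, and records the total R2 at each step.
#' The null band is the same curve on the trait vector shuffled `nPerm`
#' times: because any k linearly independent regressors explain about
#' k/(n-1) of an unrelated trait's variance — rising to 1 at k = n-1 even
#' for randomized data — the observed curve is only meaningful relative to
#' this band.
#'
#' @param scores worms x components score matrix from [pcaScores()].
#' @param trait numeric trait vector.
#' @param kMax largest number of components (default: all columns).
#' @param nPerm number of trait permutations (default 100).
#' @param seed integer RNG seed for the permutations.
#' @return data.frame of `R2Curve` rows: k, r2, null_mean, null_sd.
#' @export
cumulativePcR2 <- function(scores, trait, kMax = ncol(scores), nPerm = 100,
                           seed = 1) {
    stopifnot(kMax >= 1, kMax <= ncol(scores), nrow(scores) == length(trait))
    # PC scores are centred and orthogonal, so cumulative regression R2 is
    # the cumulative sum of squared correlations with the trait
    curve <- function(y) {
        yc <- y - mean(y)
        tss <- sum(yc^2)
        if (tss == 0) return(rep(NA_real_, kMax))
        num <- (crossprod(scores[, seq_len(kMax), drop = FALSE], yc))^2
        den <- colSums(scores[, seq_len(kMax), drop = FALSE]^2)
        pmin(1, cumsum(as.numeric(num) / den / tss))
    }
    obs <- curve(trait)
    set.seed(.stageSeed(seed, 6L))
    nullR2 <- vapply(seq_len(nPerm),
                     function(i) curve(sample(trait)), numeric(kMax))
    data.frame(k = seq_len(kMax), r2 = obs,
               null_mean = rowMeans(nullR2),
               null_sd = apply(nullR2, 1, stats::sd))
}

#' Greedy forward gene selection by explained variance
#'
#' Selects genes one at a time for a multiple linear regression of the
#' trait: at each step, the gene that most increases the model R2 given the
#' genes already selected is added (equivalently, the gene whose residual —
#' after projecting out the selected genes — best explains the residual
#' trait).  Because the candidate pool is residualized by Gram–Schmidt
#' after each addition, each step costs one pass over the pool, and the
#' result is exactly the step-wise best-subset path.  ΔR2 ties within
#' 1e-12 are broken lexicographically by gene id.
#'
#' @param exprMat worms x genes predictor matrix (rows = worms).
#' @param trait numeric trait vector.
#' @param kMax number of genes to select.
#' @return `GreedySelection`: list with `genes` (ordered ids) and `r2`
#'   (cumulative R2 after each addition).  Stops early (with fewer than
#'   `kMax` genes) if no remaining gene adds variance.
#' @export
greedyForwardSelection <- function(exprMat, trait, kMax) {
    stopifnot(kMax >= 1, nrow(exprMat) == length(trait))
    if (stats::var(trait) == 0) stop("trait has zero variance")
    ids <- colnames(exprMat)
    if (is.null(ids)) ids <- paste0("g", seq_len(ncol(exprMat)))
    ord <- order(ids)                      # lexicographic tie-break order
    Xr <- scale(exprMat[, ord, drop = FALSE], center = TRUE, scale = FALSE)
    ids <- ids[ord]
    yr <- trait - mean(trait)
    tss <- sum(yr^2)
    sel <- integer(0)
    r2 <- numeric(0)
    active <- rep(TRUE, ncol(Xr))
    for (step in seq_len(min(kMax, ncol(Xr)))) {
        ssx <- colSums(Xr^2)
        cand <- active & ssx > tss * 1e-12
        if (!any(cand)) break
        gain <- rep(-Inf, ncol(Xr))
        gain[cand] <- (crossprod(Xr[, cand, drop = FALSE], yr))^2 / ssx[cand]
        best <- max(gain)
        pick <- which(gain >= best - 1e-12 * max(tss, 1))[1]  # first = lexicographic
        u <- Xr[, pick] / sqrt(ssx[pick])
        yr <- yr - u * sum(u * yr)
        Xr <- Xr - u %o% as.numeric(crossprod(Xr, u))
        active[pick] <- FALSE
        sel <- c(sel, pick)
        r2 <- c(r2, 1 - sum(yr^2) / tss)
    }
    structure(list(genes = ids[sel], r2 = r2), class = "GreedySelection")
}

#' @export
print.GreedySelection <- function(x, ...) {
    cat("Greedy forward selection:", length(x$genes), "genes\n")
    print(data.frame(gene = x$genes, cumulative_r2 = round(x$r2, 4)))
    invisible(x)
}

#' Train/test resampling of top-k predictive gene sets
#'
#' Randomly splits the worms into equal train and test halves `nIter`
#' times.  In each train half, the top `k` genes are selected by
#' [greedyForwardSelection()] and their multiple-regression coefficients
#' refit; test-set performance is the squared Pearson correlation of
#' predicted versus observed trait.  `r2Method = "sse"` gives 1 - SSE/SST
#' of the train-fitted predictions instead, and `r2Method = "refit"` gives
#' the in-sample R2 of the selected genes' multiple regression refit on
#' the test half (the quantity a "total R2 of the same genes used in a
#' test set" plot shows; note it is inflated by k/(n_test - 1) even for
#' unrelated genes, where prediction-based R2 is not).  Iteration i is
#' seeded as `seed + i`, so any single iteration can be reproduced in
#' isolation.
#'
#' @param exprMat worms x genes predictor matrix.
#' @param trait numeric trait vector.
#' @param nIter number of random splits (default 500).
#' @param k genes per set (default 10).
#' @param seed base RNG seed.
#' @param r2Method `"cor"` (default), `"sse"` or `"refit"`.
#' @return list with `iterations` (data.frame: iter, train_r2, test_r2,
#'   genes as comma-joined string), `geneSets` (list of character vectors),
#'   `summary` (median and range of test R2).
#' @export
trainTestResampling <- function(exprMat, trait, nIter = 500, k = 10,
                                seed = 1, r2Method = c("cor", "sse",
                                                       "refit")) {
    r2Method <- match.arg(r2Method)
    n <- nrow(exprMat)
    stopifnot(n >= 4, length(trait) == n)
    half <- n %/% 2
    iters <- vector("list", nIter)
    sets <- vector("list", nIter)
    for (i in seq_len(nIter)) {
        set.seed(.stageSeed(seed, 7L) + i)
        tr <- sort(sample.int(n, half))
        te <- setdiff(seq_len(n), tr)
        yTr <- trait[tr]
        if (stats::var(yTr) == 0 || stats::var(trait[te]) == 0) next
        gs <- greedyForwardSelection(exprMat[tr, , drop = FALSE], yTr, k)
        g <- gs$genes
        d <- data.frame(y = yTr, exprMat[tr, g, drop = FALSE])
        fit <- stats::lm(y ~ ., data = d)
        predTe <- stats::predict(
            fit, newdata = data.frame(exprMat[te, g, drop = FALSE]))
        yTe <- trait[te]
        testR2 <- switch(r2Method,
            cor = if (stats::sd(predTe) == 0) 0
                  else stats::cor(predTe, yTe)^2,
            sse = 1 - sum((yTe - predTe)^2) / sum((yTe - mean(yTe))^2),
            refit = summary(stats::lm(
                y ~ ., data = data.frame(y = yTe,
                                         exprMat[te, g, drop = FALSE])))$r.squared)
        iters[[i]] <- data.frame(
            iter = i, train_r2 = utils::tail(gs$r2, 1), test_r2 = testR2,
            genes = paste(g, collapse = ","))
        sets[[i]] <- g
    }
    done <- !vapply(iters, is.null, logical(1))
    iterations <- do.call(rbind, iters[done])
    list(iterations = iterations, geneSets = sets[done],
         summary = c(median_test_r2 = stats::median(iterations$test_r2),
                     min_test_r2 = min(iterations$test_r2),
                     max_test_r2 = max(iterations$test_r2),
                     n_iter = sum(done)))
}

#' Elastic-net prediction with leave-one-out cross-validation
#'
#' For each worm, an elastic net (mixing parameter `alpha`, default 0.5) is
#' trained on all other worms and used to predict the held-out worm's
#' trait; the penalty weight is chosen by `nfolds`-fold cross-validation
#' inside each training fold (lambda.min; predictors standardized within
#' the training fold by glmnet).  The held-out worm contributes nothing to
#' its own prediction — not its trait, its expression profile, nor the
#' fold assignment (folds are seeded independently of the data).  The
#' reported R2 is that of the linear fit of observed on predicted traits.
#'
#' @param exprMat worms x genes predictor matrix (typically the
#'   log-transformed CPM layer).
#' @param trait numeric trait vector (length >= 10).
#' @param alpha elastic-net mixing parameter in [0, 1].
#' @param seed RNG seed for the inner fold assignments.
#' @param nfolds inner cross-validation folds (default 5).
#' @param lambda optional fixed penalty weight; skips the inner
#'   cross-validation when given.
#' @return `LoocvPrediction`: list with `predicted`, `observed` (per worm)
#'   and `r2`.
#' @export
elasticNetLoocv <- function(exprMat, trait, alpha = 0.5, seed = 1,
                            nfolds = 5, lambda = NULL) {
    n <- nrow(exprMat)
    stopifnot(n >= 10, length(trait) == n)
    v <- apply(exprMat, 2, stats::var)
    if (any(v == 0)) {
        warning(sum(v == 0), " zero-variance gene(s) dropped")
        exprMat <- exprMat[, v > 0, drop = FALSE]
    }
    pred <- numeric(n)
    for (i in seq_len(n)) {
        xTr <- exprMat[-i, , drop = FALSE]
        yTr <- trait[-i]
        if (is.null(lambda)) {
            set.seed(.stageSeed(seed, 8L) + i)
            foldid <- sample(rep(seq_len(nfolds), length.out = n - 1))
            cv <- glmnet::cv.glmnet(xTr, yTr, alpha = alpha, foldid = foldid)
            lam <- cv$lambda.min
            fit <- cv$glmnet.fit
        } else {
            lam <- lambda
            fit <- glmnet::glmnet(xTr, yTr, alpha = alpha)
        }
        pred[i] <- as.numeric(stats::predict(
            fit, newx = exprMat[i, , drop = FALSE], s = lam, exact = FALSE))
    }
    r2 <- if (stats::sd(pred) == 0) 0 else
        summary(stats::lm(trait ~ pred))$r.squared
    structure(list(predicted = pred, observed = trait, r2 = r2,
                   alpha = alpha),
              class = "LoocvPrediction")
}

#' @export
print.LoocvPrediction <- function(x, ...) {
    cat(sprintf("Elastic-net LOOCV (alpha = %.2f): %d worms, R2 = %.3f\n",
                x$alpha, length(x$predicted), x$r2))
    invisible(x)
}
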