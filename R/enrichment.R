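#' Two-way ANOVA of effect sizes by tissue and chromatin domain
#'
#' Restricts genes to those expressed in the soma or germline and sitting in
#' an active or regulated chromatin domain, then fits a two-way ANOVA with
#' interaction of the per-gene trait effect sizes (`beta1`) on tissue x
#' domain, followed by Tukey HSD pairwise comparisons of the four cell means
#' and a one-sample t-test of each cell's mean against zero.  If all effect
#' sizes are identical the F statistics are reported as 0 with p = 1 (by
#' convention; there is no variation to partition).
#'
#' @param effects data.frame with columns `gene` and `beta1` (e.g. from
#'   [decomposeGenes()], or `std_beta` from a scan renamed accordingly).
#' @param annotation data.frame with `gene`, `domain`, `tissue`.
#' @param minPerCell minimum genes required in each tissue x domain cell.
#' @return list of class `EnrichmentAnova`: `anova` (data.frame: term, df,
#'   F, p), `tukey` (pairwise adjusted p), `cellTests` (one-sample t per
#'   cell), `n` (genes used).
#' @export
tissueDomainAnova <- function(effects, annotation, minPerCell = 3) {
    d <- merge(effects, annotation, by = "gene")
    d <- d[d$tissue %in% c("soma", "germline") &
           d$domain %in% c("active", "regulated"), ]
    d$tissue <- factor(d$tissue, levels = c("soma", "germline"))
    d$domain <- factor(d$domain, levels = c("active", "regulated"))
    tab <- table(d$tissue, d$domain)
    if (any(tab == 0)) {
        empty <- which(tab == 0, arr.ind = TRUE)
        stop("empty tissue x domain cell: ",
             paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
                   sep = "/", collapse = ", "))
    }
    if (any(tab < minPerCell))
        stop("fewer than ", minPerCell, " genes in some tissue x domain cell")

    fit <- stats::aov(beta1 ~ tissue * domain, data = d)
    sm <- summary(fit)[[1]]
    terms <- trimws(rownames(sm))
    keep <- terms != "Residuals"
    Fv <- sm[keep, "F value"]
    pv <- sm[keep, "Pr(>F)"]
    # no variation to partition: F = 0, p = 1 by convention
    bad <- !is.finite(Fv) | stats::var(d$beta1) == 0
    Fv[bad] <- 0; pv[bad] <- 1
    anovaTab <- data.frame(term = terms[keep], df = sm[keep, "Df"],
                           F = Fv, p = pv, row.names = NULL)

    tk <- stats::TukeyHSD(fit, "tissue:domain")[["tissue:domain"]]
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL)
    cells <- expand.grid(tissue = levels(d$tissue),
                         domain = levels(d$domain))
    cellTests <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        v <- d$beta1[d$tissue == cells$tissue[i] &
                     d$domain == cells$domain[i]]
        tt <- if (stats::sd(v) == 0)
            list(statistic = 0, p.value = if (mean(v) == 0) 1 else 0)
        else stats::t.test(v, mu = 0)
        data.frame(tissue = cells$tissue[i], domain = cells$domain[i],
                   n = length(v), mean = mean(v),
                   t = unname(tt$statistic), p = tt$p.value)
    }))
    structure(list(anova = anovaTab, tukey = tukey, cellTests = cellTests,
                   n = nrow(d)),
              class = "EnrichmentAnova")
}

#' @export
print.EnrichmentAnova <- function(x, ...) {
    cat("Two-way ANOVA of effect sizes (", x$n, " genes)\n", sep = "")
    print(x$anova, digits = 4)
    invisible(x)
}

#' Regulated-domain enrichment of predictive gene sets
#'
#' For each predictive gene set (e.g. the 500 top-10 sets from
#' [trainTestResampling()]), computes the proportion of its annotated
#' members (genes labelled active or regulated; `other` is dropped from the
#' denominator) that sit in a regulated domain.  The observed distribution
#' of proportions is compared with that of `nRandom` random same-size sets
#' drawn from the background, using a two-sample Kolmogorov–Smirnov test.
#'
#' @param geneSets list of character vectors (the predictive sets).
#' @param background character vector of background gene ids (the expressed
#'   set the random draws come from).
#' @param annotation data.frame with `gene`, `domain`.
#' @param nRandom number of random control sets (default 500).
#' @param seed RNG seed for the random sets.
#' @param exact passed to [stats::ks.test()] (default NULL = asymptotic for
#'   larger samples).
#' @return list of class `RegulatedProportionTest`: `observed` and `random`
#'   proportion vectors, `ks` (statistic, p), `medianAnnotated` (median
#'   number of annotated genes per observed set), `droppedSets`.
#' @export
regulatedProportionTest <- function(geneSets, background, annotation,
                                    nRandom = 500, seed = 1, exact = NULL) {
    dom <- annotation$domain[match(background, annotation$gene)]
    names(dom) <- background
    prop <- function(genes) {
        d <- dom[intersect(genes, background)]
        d <- d[!is.na(d) & d %in% c("active", "regulated")]
        if (length(d) == 0) return(NA_real_)
        mean(d == "regulated")
    }
    obs <- vapply(geneSets, prop, numeric(1))
    nAnn <- vapply(geneSets, function(g) {
        d <- dom[intersect(g, background)]
        sum(!is.na(d) & d %in% c("active", "regulated"))
    }, numeric(1))
    dropped <- sum(is.na(obs))
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) stop("no gene set with annotated members")
    setSize <- max(lengths(geneSets))
    set.seed(.stageSeed(seed, 9L))
    rand <- vapply(seq_len(nRandom), function(i)
        prop(sample(background, setSize)), numeric(1))
    rand <- rand[!is.na(rand)]
    ks <- suppressWarnings(stats::ks.test(obs, rand, exact = exact))
    structure(list(observed = obs, random = rand,
                   ks = c(statistic = unname(ks$statistic),
                          p = ks$p.value),
                   medianAnnotated = stats::median(nAnn[nAnn > 0]),
                   droppedSets = dropped),
              class = "RegulatedProportionTest")
}

#' @export
print.RegulatedProportionTest <- function(x, ...) {
    cat(sprintf(
        "Regulated-proportion KS test: D = %.3f, p = %.3g\n  median proportion %.2f (observed) vs %.2f (random); %d sets dropped\n",
        x$ks["statistic"], x$ks["p"], stats::median(x$observed),
        stats::median(x$random), x$droppedSets))
    invisible(x)
}

#' Wilcoxon test of variance Z-scores by chromatin domain
#'
#' Two-sided two-sample rank-sum test comparing the variance Z-scores
#' ([varianceZscores()]) of regulated-domain genes with those of
#' active-domain genes: a positive shift for regulated genes means they are
#' more variable than expected for their expression level.
#'
#' @param varZ data.frame from [varianceZscores()].
#' @param annotation data.frame with `gene`, `domain`.
#' @return list of class `VarianceDomainTest`: `statistic`, `p`,
#'   `medianRegulated`, `medianActive`, group sizes.
#' @export
varianceByDomainTest <- function(varZ, annotation) {
    dom <- annotation$domain[match(varZ$gene, annotation$gene)]
    zr <- varZ$z[!is.na(dom) & dom == "regulated"]
    za <- varZ$z[!is.na(dom) & dom == "active"]
    if (length(zr) == 0 || length(za) == 0)
        stop("both regulated and active groups must be non-empty")
    wt <- stats::wilcox.test(zr, za, alternative = "two.sided")
    structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                   medianRegulated = stats::median(zr),
                   medianActive = stats::median(za),
                   nRegulated = length(zr), nActive = length(za)),
              class = "VarianceDomainTest")
}

#' @export
print.VarianceDomainTest <- function(x, ...) {
    cat(sprintf(
        "Variance-Z Wilcoxon (regulated vs active): W = %.0f, p = %.3g\n  medians %.2f vs %.2f (n = %d, %d)\n",
        x$statistic, x$p, x$medianRegulated, x$medianActive,
        x$nRegulated, x$nActive))
    invisible(x)
}
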