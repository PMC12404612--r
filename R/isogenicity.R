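#' Classify per-site per-worm base calls
#'
#' Observations with depth below `minDepth` (default 20 reads) are dropped;
#' the rest are classified by the number of distinct bases observed:
#' `unambiguous` (all reads the same base), `ambiguous2` (exactly two bases,
#' with their frequencies), or `multi` (more than two bases; never a variant
#' candidate).
#'
#' @param calls site-call table (data.frame/data.table with worm_id, chrom,
#'   pos, depth, A, C, G, T).
#' @param minDepth minimum read depth to retain an observation.
#' @return a `data.table` with columns worm_id, chrom, pos, depth, class,
#'   base1, base2, freq1, freq2 (base1 is the majority base; for
#'   unambiguous calls base2/freq2 are NA and freq1 = 1).
#' @export
classifySiteCalls <- function(calls, minDepth = 20) {
    need <- c("worm_id", "chrom", "pos", "depth", "A", "C", "G", "T")
    stopifnot(all(need %in% colnames(calls)))
    if (any(calls$A < 0 | calls$C < 0 | calls$G < 0 | calls$T < 0))
        stop("negative base counts")
    keep <- which(calls$depth >= minDepth)
    depth <- calls$depth[keep]
    n <- length(keep)
    m <- cbind(A = calls$A[keep], C = calls$C[keep],
               G = calls$G[keep], T = calls$T[keep])
    bases <- c("A", "C", "G", "T")
    nb <- (m[, 1] > 0L) + (m[, 2] > 0L) + (m[, 3] > 0L) + (m[, 4] > 0L)
    cls <- rep("multi", n)
    cls[nb == 1L] <- "unambiguous"
    cls[nb == 2L] <- "ambiguous2"
    # top two bases per observation (order within ties: A,C,G,T)
    i1 <- max.col(m, ties.method = "first")
    top1 <- m[cbind(seq_len(n), i1)]
    m[cbind(seq_len(n), i1)] <- -1L
    i2 <- max.col(m, ties.method = "first")
    top2 <- m[cbind(seq_len(n), i2)]
    b2 <- bases[i2]
    b2[nb < 2L] <- NA_character_
    f1 <- top1 / depth                 # exactly 1 for unambiguous calls
    f2 <- top2 / depth
    f2[nb < 2L] <- NA_real_
    out <- list(worm_id = calls$worm_id[keep], chrom = calls$chrom[keep],
                pos = calls$pos[keep], depth = depth, class = cls,
                base1 = bases[i1], base2 = b2, freq1 = f1, freq2 = f2)
    data.table::setDT(out)
    out[]
}

# Integer site index + coverage over a classified call table.  All the
# candidate rules reduce to tabulations over this index, which keeps the
# site-level logic O(n) with no joins.
.siteIndex <- function(calls, minWormsCovered) {
    chrom <- calls$chrom
    key <- if (length(chrom) == 0L || !anyNA(chrom) &&
               all(chrom == chrom[1L])) calls$pos
    else (as.integer(factor(chrom)) - 1) * (max(calls$pos) + 1) + calls$pos
    uk <- unique(key)
    id <- match(key, uk)
    nSites <- length(uk)
    cov <- tabulate(id, nSites)
    keep <- cov[id] >= minWormsCovered
    baseIdx <- match(calls$base1, c("A", "C", "G", "T"))
    un <- calls$class == "unambiguous" & keep
    cnt <- matrix(tabulate((id[un] - 1L) * 4L + baseIdx[un], 4L * nSites),
                  ncol = 4, byrow = TRUE)
    list(id = id, keep = keep, nSites = nSites,
         siteKept = cov >= minWormsCovered,
         baseIdx = baseIdx, unamb = un, cnt = cnt)
}

#' Candidate homozygous variants
#'
#' A site enters the analysis when at least `minWormsCovered` worms have
#' sufficient coverage there.  At such a site, candidate homozygous-variant
#' observations are the unambiguous calls whose base differs from the site's
#' modal unambiguous base — i.e. the minority observations at a discordant
#' site (a site where at least `minDiscordantWorms` worms disagree with the
#' rest).  Ties for the modal base are broken alphabetically.
#'
#' @param calls classified calls from [classifySiteCalls()].
#' @param minWormsCovered minimum covered worms per site (default 10).
#' @param minDiscordantWorms minimum discordant worms for candidacy
#'   (default 1).
#' @param si precomputed site index (internal; used by [isogenicityCheck()]).
#' @return data.table of candidate (chrom, pos, worm_id, base) rows.
#' @export
candidateHomozygous <- function(calls, minWormsCovered = 10,
                                minDiscordantWorms = 1, si = NULL) {
    if (!data.table::is.data.table(calls))
        calls <- data.table::as.data.table(calls)
    if (is.null(si)) si <- .siteIndex(calls, minWormsCovered)
    # modal base per site among unambiguous calls; max.col with bases in
    # A,C,G,T order makes ties resolve alphabetically
    modal <- max.col(si$cnt, ties.method = "first")
    isCand <- si$unamb & si$baseIdx != modal[si$id]
    nDisc <- tabulate(si$id[isCand], si$nSites)
    isCand <- isCand & nDisc[si$id] >= minDiscordantWorms
    out <- calls[isCand, c("chrom", "pos", "worm_id", "base1")]
    data.table::setnames(out, "base1", "base")
    out[]
}

#' Candidate heterozygous variants
#'
#' A (site, worm) observation is a candidate heterozygous variant when the
#' worm's call is `ambiguous2` with both base frequencies inside
#' `[freqLo, freqHi]` (default 0.3--0.7, the balanced-allele window that
#' excludes rare-sequencing-error patterns) and at least
#' `minUnambiguousOthers` other worms at the site are unambiguously called
#' for a single shared base.  Sites with fewer than `minWormsCovered`
#' covered worms are excluded.  The singleton fraction is the proportion of
#' candidate sites whose candidate is found in exactly one worm.
#'
#' @param calls classified calls from [classifySiteCalls()].
#' @param freqLo,freqHi inclusive allele-frequency window.
#' @param minUnambiguousOthers minimum other worms unambiguous for one
#'   shared base (default 10).
#' @param minWormsCovered minimum covered worms per site (default 10).
#' @param si precomputed site index (internal; used by [isogenicityCheck()]).
#' @return list: `candidates` (data.table chrom, pos, worm_id, base1, base2,
#'   freq1, freq2) and `singletonFraction`.
#' @export
candidateHeterozygous <- function(calls, freqLo = 0.3, freqHi = 0.7,
                                  minUnambiguousOthers = 10,
                                  minWormsCovered = 10, si = NULL) {
    if (!data.table::is.data.table(calls))
        calls <- data.table::as.data.table(calls)
    if (is.null(si)) si <- .siteIndex(calls, minWormsCovered)
    # per-site unambiguous consensus: count of unambiguous worms and number
    # of distinct bases among them ("other worms" is exact because the
    # ambiguous worm is never in the unambiguous tally)
    nUn <- rowSums(si$cnt)
    nBase <- rowSums(si$cnt > 0)
    isCand <- si$keep & calls$class == "ambiguous2" &
        calls$freq1 >= freqLo & calls$freq1 <= freqHi &
        calls$freq2 >= freqLo & calls$freq2 <= freqHi &
        nUn[si$id] >= minUnambiguousOthers & nBase[si$id] == 1
    cand <- calls[isCand, c("chrom", "pos", "worm_id", "base1", "base2",
                            "freq1", "freq2")]
    if (nrow(cand) == 0)
        return(list(candidates = cand[], singletonFraction = NA_real_))
    perSite <- tabulate(match(si$id[isCand], unique(si$id[isCand])))
    list(candidates = cand[], singletonFraction = mean(perSite == 1))
}

#' Variant rates from candidate counts
#'
#' Rates are candidates per retained site-by-worm observation: the
#' denominator counts every observation that passed the depth filter at a
#' site retained by the coverage rule, summed over worms (the study-scale
#' analogue is the 7.7e8 sites-across-all-worms denominator behind the
#' reported homozygous 2.21e-8 and heterozygous 9.86e-7 rates).
#'
#' @param nHom,nHet candidate counts.
#' @param totalObservations retained site x worm observations (> 0).
#' @return list with `homRate`, `hetRate` and the inputs.
#' @export
variantRates <- function(nHom, nHet, totalObservations) {
    if (totalObservations <= 0) stop("zero denominator")
    list(nHom = nHom, nHet = nHet,
         totalObservations = totalObservations,
         homRate = nHom / totalObservations,
         hetRate = nHet / totalObservations)
}

#' Full isogenicity check
#'
#' Runs [classifySiteCalls()], both candidate rules and [variantRates()] on
#' a raw site-call table; this is the check that trait-expression
#' associations in an isogenic population are not driven by segregating
#' mutations.
#'
#' @param calls raw site-call table (see [readSiteCalls()]).
#' @param minDepth minimum depth per observation (default 20).
#' @param minWormsCovered minimum covered worms per site (default 10).
#' @param freqLo,freqHi heterozygous allele-frequency window.
#' @param minUnambiguousOthers see [candidateHeterozygous()].
#' @return `VariantRateReport`: list with `sitesConsidered`,
#'   `totalObservations`, `homCandidates`, `hetCandidates`, `homRate`,
#'   `hetRate`, `singletonFraction`, and the candidate tables.
#' @examples
#' sc <- simulateSiteCalls(12, 200, depthMean = 30, seed = 2)
#' isogenicityCheck(sc)$homRate  # 0 for a variant-free simulation
#' @export
isogenicityCheck <- function(calls, minDepth = 20, minWormsCovered = 10,
                             freqLo = 0.3, freqHi = 0.7,
                             minUnambiguousOthers = 10) {
    cl <- classifySiteCalls(calls, minDepth = minDepth)
    si <- .siteIndex(cl, minWormsCovered)
    hom <- candidateHomozygous(cl, minWormsCovered, si = si)
    het <- candidateHeterozygous(cl, freqLo, freqHi, minUnambiguousOthers,
                                 minWormsCovered, si = si)
    rates <- variantRates(nrow(hom), nrow(het$candidates), sum(si$keep))
    structure(list(
        sitesConsidered = sum(si$siteKept),
        totalObservations = rates$totalObservations,
        homCandidates = rates$nHom, hetCandidates = rates$nHet,
        homRate = rates$homRate, hetRate = rates$hetRate,
        singletonFraction = het$singletonFraction,
        homTable = hom, hetTable = het$candidates),
        class = "VariantRateReport")
}

#' @export
print.VariantRateReport <- function(x, ...) {
    cat(sprintf(
        "Isogenicity check: %d sites, %s observations\n  homozygous: %d candidates (rate %.3g)\n  heterozygous: %d candidates (rate %.3g; singleton fraction %s)\n",
        x$sitesConsidered, format(x$totalObservations, big.mark = ","),
        x$homCandidates, x$homRate, x$hetCandidates, x$hetRate,
        ifelse(is.na(x$singletonFraction), "NA",
               sprintf("%.2f", x$singletonFraction))))
    invisible(x)
}
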