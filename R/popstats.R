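## Population-genetic statistics supporting the drift/isolation argument:
## heterozygosity, Wright's and Weir-Cockerham's F_ST, the exact
## Hardy-Weinberg test, per-individual inbreeding F, and Mantel tests.

#' Observed and expected heterozygosity per locus
#'
#' H_obs is the fraction of called genotypes that are heterozygous; H_exp =
#' 2p(1-p) from the within-population allele frequency.  Means across loci
#' exclude loci with no calls.
#'
#' @param x a \linkS4class{GenotypeData}, or an integer 0/1/2/NA matrix
#'   with loci as rows.
#' @return list: \code{perLocus} (data.frame locus, n, Ho, He),
#'   \code{meanHo}, \code{meanHe}.
#' @examples
#' gd <- simulateHWEPopulation(100, rep(0.4, 20), seed = 1)
#' heterozygosity(gd)$meanHe
#' @export
heterozygosity <- function(x) {
    g <- if (methods::is(x, "GenotypeData")) genoMatrix(x) else as.matrix(x)
    n <- rowSums(!is.na(g))
    ho <- rowSums(g == 1L, na.rm = TRUE) / n
    p <- rowSums(g, na.rm = TRUE) / (2 * n)
    he <- 2 * p * (1 - p)
    per <- data.frame(locus = rownames(g) %||% seq_len(nrow(g)),
                      n = n, Ho = ho, He = he)
    called <- n > 0
    list(perLocus = per,
         meanHo = mean(ho[called]), meanHe = mean(he[called]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wright's F_ST from population allele frequencies
#'
#' Per locus, H_T = 2 pbar (1 - pbar) with pbar the unweighted mean of the
#' population frequencies, H_S the unweighted mean of the within-population
#' 2 p_k (1 - p_k); F_ST = (H_T - H_S)/H_T, defined as 0 when H_T = 0.
#' Guaranteed to lie in [0, 1] by concavity of 2p(1-p).
#'
#' @param popFreqs loci-by-populations matrix of alternate-allele
#'   frequencies (a vector is taken as one locus), at least two
#'   populations.
#' @return list: \code{perLocus} F_ST values, \code{mean} across loci.
#' @examples
#' wrightFst(matrix(c(0.5, 0), 1))$perLocus   # 1/3
#' @export
wrightFst <- function(popFreqs) {
    if (is.null(dim(popFreqs))) popFreqs <- matrix(popFreqs, nrow = 1)
    if (ncol(popFreqs) < 2) stop("need at least two populations")
    .checkFreqs(popFreqs[is.finite(popFreqs)])
    pbar <- rowMeans(popFreqs, na.rm = TRUE)
    ht <- 2 * pbar * (1 - pbar)
    hs <- rowMeans(2 * popFreqs * (1 - popFreqs), na.rm = TRUE)
    fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
    list(perLocus = as.numeric(fst), mean = mean(fst, na.rm = TRUE))
}

#' Pairwise multilocus Wright's F_ST between populations
#'
#' @param popFreqs loci-by-populations frequency matrix.
#' @return symmetric matrix of multilocus (mean over loci) F_ST.
#' @export
pairwiseWrightFst <- function(popFreqs) {
    P <- ncol(popFreqs)
    out <- matrix(0, P, P, dimnames = list(colnames(popFreqs),
                                           colnames(popFreqs)))
    for (i in seq_len(P - 1)) for (j in (i + 1):P)
        out[i, j] <- out[j, i] <-
            wrightFst(popFreqs[, c(i, j), drop = FALSE])$mean
    out
}

#' Weir and Cockerham's theta (1984 variance-components estimator)
#'
#' Per locus, the among-population (a), among-individual-within-population
#' (b) and within-individual (c) components are computed from sample
#' sizes, allele frequencies and observed heterozygote frequencies;
#' theta = a/(a+b+c), and the global estimate is sum(a)/sum(a+b+c) across
#' loci.  Loci with a zero denominator are excluded and reported.
#' Populations with fewer than two called individuals at a locus are
#' excluded for that locus (with a warning the first time).
#'
#' @param x a \linkS4class{GenotypeData} with population labels.
#' @return list: \code{perLocus} data.frame (locus, a, b, c, theta),
#'   \code{theta} (global), \code{excluded} locus ids with undefined
#'   estimates.
#' @export
weirCockerhamFst <- function(x) {
    g <- genoMatrix(x)
    pops <- populations(x)
    if (is.null(pops)) stop("population labels are required")
    popIds <- unique(pops)
    if (length(popIds) < 2) stop("need at least two populations")
    warned <- FALSE
    res <- data.frame(locus = rownames(g), a = NA_real_, b = NA_real_,
                      c = NA_real_, theta = NA_real_)
    for (l in seq_len(nrow(g))) {
        gl <- g[l, ]
        ni <- vapply(popIds, function(k) sum(!is.na(gl[pops == k])),
                     numeric(1))
        keep <- ni >= 2
        if (any(!keep) && !warned) {
            warning("population(s) with < 2 called individuals excluded ",
                    "at some loci")
            warned <- TRUE
        }
        if (sum(keep) < 2) next
        ks <- popIds[keep]
        n <- ni[keep]                                  # individuals per pop
        p <- vapply(ks, function(k)
            mean(gl[pops == k], na.rm = TRUE) / 2, numeric(1))
        h <- vapply(ks, function(k)
            mean(gl[pops == k] == 1L, na.rm = TRUE), numeric(1))
        r <- length(ks)
        nbar <- mean(n)
        nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
        pbar <- sum(n * p) / (r * nbar)
        s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(n * h) / (r * nbar)
        a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                    (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        res$a[l] <- a; res$b[l] <- b; res$c[l] <- cc
        denom <- a + b + cc
        res$theta[l] <- if (abs(denom) > 0) a / denom else NA_real_
    }
    ok <- !is.na(res$theta)
    globalTheta <- sum(res$a[ok]) / sum((res$a + res$b + res$c)[ok])
    list(perLocus = res, theta = globalTheta,
         excluded = res$locus[!ok])
}

#' Exact test for Hardy-Weinberg equilibrium (biallelic)
#'
#' The exact conditional test on genotype counts: given n individuals and
#' nA alternate alleles, heterozygote counts of matching parity are
#' enumerated under P(nAB | nA, n) = n! / (nAA! nAB! naa!) * 2^nAB *
#' nA! na! / (2n)!; the p-value sums the probabilities of all
#' configurations no more probable than the observed one (the plain, not
#' mid-p, variant).
#'
#' @param nHomRef,nHet,nHomAlt observed genotype counts.
#' @return the exact p-value, in (0, 1].
#' @examples
#' hweExactTest(2, 6, 4)   # 1: the observed heterozygote count is modal
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
    if (any(c(nHomRef, nHet, nHomAlt) < 0))
        stop("genotype counts must be non-negative")
    n <- nHomRef + nHet + nHomAlt
    if (n < 1) stop("need at least one genotype")
    nA <- nHet + 2 * nHomAlt        # alternate allele count
    probs <- .hweEnumerate(n, nA)
    pObs <- probs[as.character(nHet)]
    if (is.na(pObs)) stop("heterozygote count has impossible parity")
    p <- sum(probs[probs <= pObs + 1e-12])
    min(p, 1)
}

## all possible het counts and their conditional probabilities, log-space
.hweEnumerate <- function(n, nA) {
    nB <- 2 * n - nA
    m <- min(nA, nB)
    hets <- seq(m %% 2, m, by = 2)
    lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
        lfactorial((nB - hets) / 2) + hets * log(2) +
        lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
    stats::setNames(exp(lp), hets)
}

#' Per-individual inbreeding coefficient F
#'
#' F = (O_hom - E_hom) / (L - E_hom), with E_hom the sample-size-corrected
#' expected homozygosity summed over the individual's called loci:
#' 1 - 2p(1-p) * 2n/(2n-1) per locus, p the reference frequency and n the
#' number of individuals genotyped at the locus.  Negative values (excess
#' heterozygosity) are not clamped.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param refFreqs per-locus frequencies; defaults to the frequencies
#'   stored in \code{x}, falling back to observed frequencies.
#' @return data.frame: sample_id, O_hom, E_hom, L (called loci), F
#'   (NA when all loci are uninformative).
#' @export
inbreedingF <- function(x, refFreqs = NULL) {
    g <- genoMatrix(x)
    if (is.null(refFreqs)) refFreqs <- refAlleleFreqs(x)
    if (is.null(refFreqs)) refFreqs <- observedAlleleFreqs(x)
    stopifnot(length(refFreqs) == nrow(g))
    nPerLocus <- rowSums(!is.na(g))
    corr <- ifelse(nPerLocus > 0, 2 * nPerLocus / (2 * nPerLocus - 1), NA)
    eHomLocus <- 1 - 2 * refFreqs * (1 - refFreqs) * corr
    out <- lapply(seq_len(ncol(g)), function(j) {
        called <- !is.na(g[, j])
        L <- sum(called)
        oHom <- sum(g[called, j] != 1L)
        eHom <- sum(eHomLocus[called])
        f <- if (L - eHom > 0) (oHom - eHom) / (L - eHom) else NA_real_
        data.frame(sample_id = colnames(g)[j], O_hom = oHom, E_hom = eHom,
                   L = L, F = f)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of lower-triangle entries with row/column joint
#' permutation (via \code{vegan::mantel}); p = (1 + #\{permuted r >=
#' observed\}) / (permutations + 1).
#'
#' @param dGen,dGeo conformable symmetric distance matrices (or dist
#'   objects).
#' @param permutations number of permutations (>= 99).
#' @return a \linkS4class{MantelResult}.
#' @export
mantelTest <- function(dGen, dGeo, permutations = 999) {
    stopifnot(permutations >= 99)
    dGen <- as.matrix(dGen); dGeo <- as.matrix(dGeo)
    if (!all(dim(dGen) == dim(dGeo)))
        stop("distance matrices are not conformable")
    if (stats::sd(dGen[lower.tri(dGen)]) == 0 ||
        stats::sd(dGeo[lower.tri(dGeo)]) == 0)
        stop("constant distance matrix: Mantel r undefined")
    fit <- vegan::mantel(stats::as.dist(dGen), stats::as.dist(dGeo),
                         method = "pearson", permutations = permutations)
    methods::new("MantelResult", statistic = unname(fit$statistic),
                 p = unname(fit$signif), permutations = permutations,
                 classes = data.frame())
}

#' Mantel correlogram (distance-class-wise Mantel tests)
#'
#' Wraps \code{vegan::mantel.correlog}: for each geographic distance class
#' the genetic distances are tested against membership of that class with
#' the same permutation scheme, showing how the distance-divergence
#' correlation decays (isolation by distance breaking down beyond some
#' range).
#'
#' @param dGen genetic distance matrix.
#' @param dGeo geographic distance matrix.
#' @param nClasses number of distance classes (default: Sturges' rule).
#' @param permutations permutations per class.
#' @return a \linkS4class{MantelResult} whose \code{classes} slot holds
#'   one row per class (midpoint, n, r, p); the overall statistic/p are
#'   from the plain Mantel test.
#' @export
mantelCorrelogram <- function(dGen, dGeo, nClasses = NULL,
                              permutations = 999) {
    overall <- mantelTest(dGen, dGeo, permutations)
    fit <- vegan::mantel.correlog(stats::as.dist(as.matrix(dGen)),
                                  stats::as.dist(as.matrix(dGeo)),
                                  n.class = if (is.null(nClasses)) 0
                                            else nClasses,
                                  nperm = permutations, mult = "none")
    m <- as.data.frame(fit$mantel.res)
    classes <- data.frame(midpoint = m[, "class.index"],
                          n = m[, "n.dist"],
                          r = m[, "Mantel.cor"],
                          p = m[, "Pr(Mantel)"])
    methods::new("MantelResult", statistic = overall@statistic,
                 p = overall@p, permutations = permutations,
                 classes = classes)
}

#' @export
setMethod("show", "MantelResult", function(object) {
    cat(sprintf("Mantel r = %.3f, p = %.4g (%d permutations)\n",
                object@statistic, object@p, object@permutations))
    if (nrow(object@classes)) {
        cat("correlogram classes:\n")
        print(object@classes, row.names = FALSE)
    }
})

#' Rank of one locus among per-locus F_ST values
#'
#' Small utility for asking whether a focal site is an outlier: returns the
#' rank (1 = largest) of \code{locus} within \code{values}.
#'
#' @param values named per-locus F_ST values.
#' @param locus the focal locus id.
#' @return integer rank.
#' @export
fstRank <- function(values, locus) {
    if (!locus %in% names(values)) stop("locus not found: ", locus)
    as.integer(rank(-values, ties.method = "min")[locus])
}
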