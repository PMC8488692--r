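## Individual identification from noninvasive samples: the locus/sample
## filter cascade, PLINK-style method-of-moments PI-HAT relatedness,
## recapture clustering at the calibrated thresholds, and probability of
## identity.

#' Construct a FilterSpec
#'
#' @param maxLocusMissing,minLociPerSample,minMAC,dropMonomorphic,hweAlpha,hweMinPops
#'   see \linkS4class{FilterSpec}.
#' @return a \linkS4class{FilterSpec}.
#' @export
filterSpec <- function(maxLocusMissing = 0.10, minLociPerSample = 50,
                       minMAC = 2, dropMonomorphic = TRUE, hweAlpha = 0.05,
                       hweMinPops = 2) {
    methods::new("FilterSpec", maxLocusMissing = maxLocusMissing,
                 minLociPerSample = minLociPerSample, minMAC = minMAC,
                 dropMonomorphic = dropMonomorphic, hweAlpha = hweAlpha,
                 hweMinPops = hweMinPops)
}

.locusFilterPass <- function(g, pops, spec) {
    ## returns data.frame(locus, reason) of removals for one pass
    reasons <- list()
    miss <- rowMeans(is.na(g))
    bad <- miss > spec@maxLocusMissing
    if (any(bad))
        reasons$miss <- data.frame(item = rownames(g)[bad], type = "locus",
                                   reason = "missingness")
    alt <- rowSums(g, na.rm = TRUE)
    tot <- 2 * rowSums(!is.na(g))
    mac <- pmin(alt, tot - alt)
    if (spec@dropMonomorphic) {
        mono <- !bad & tot > 0 & (alt == 0 | alt == tot)
        if (any(mono))
            reasons$mono <- data.frame(item = rownames(g)[mono],
                                       type = "locus",
                                       reason = "monomorphic")
    } else mono <- rep(FALSE, nrow(g))
    low <- !bad & !mono & mac > 0 & mac < spec@minMAC
    if (any(low))
        reasons$mac <- data.frame(item = rownames(g)[low], type = "locus",
                                  reason = "MAC")
    ## HWE: a locus fails when out of HWE in >= hweMinPops populations
    if (!is.null(pops) && length(unique(pops)) >= 1) {
        done <- bad | mono | low
        hweBad <- vapply(seq_len(nrow(g)), function(l) {
            if (done[l]) return(FALSE)
            nFail <- 0L
            for (k in unique(pops)) {
                gl <- g[l, pops == k]
                gl <- gl[!is.na(gl)]
                if (length(gl) < 2) next
                p <- hweExactTest(sum(gl == 0L), sum(gl == 1L),
                                  sum(gl == 2L))
                if (p < spec@hweAlpha) nFail <- nFail + 1L
            }
            nFail >= spec@hweMinPops
        }, logical(1))
        if (any(hweBad))
            reasons$hwe <- data.frame(item = rownames(g)[hweBad],
                                      type = "locus", reason = "HWE")
    }
    do.call(rbind, unname(reasons))
}

#' Apply the locus/sample filter cascade
#'
#' Locus filters (missingness, monomorphism, minor allele count, HWE
#' failure in \code{hweMinPops}+ populations) are applied first, then
#' samples with too few called loci are removed, and the locus filters are
#' recomputed on the reduced matrix until the result is stable.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param spec a \linkS4class{FilterSpec}.
#' @return list: \code{genotypes} (filtered \linkS4class{GenotypeData}),
#'   \code{report} (data.frame item, type, reason for every removal).
#'   An empty result is returned with a warning, not an error.
#' @export
applyFilters <- function(x, spec = filterSpec()) {
    g <- genoMatrix(x)
    pops <- populations(x)
    report <- data.frame(item = character(), type = character(),
                         reason = character())
    repeat {
        if (nrow(g) == 0 || ncol(g) == 0) break
        rem <- .locusFilterPass(g, pops, spec)
        changed <- FALSE
        if (!is.null(rem) && nrow(rem)) {
            g <- g[setdiff(rownames(g), rem$item), , drop = FALSE]
            report <- rbind(report, rem)
            changed <- TRUE
        }
        called <- colSums(!is.na(g))
        badS <- called < spec@minLociPerSample
        if (any(badS)) {
            report <- rbind(report, data.frame(
                item = colnames(g)[badS], type = "sample",
                reason = "too few called loci"))
            keep <- !badS
            g <- g[, keep, drop = FALSE]
            if (!is.null(pops)) pops <- pops[keep]
            changed <- TRUE
        }
        if (!changed) break
    }
    if (nrow(g) == 0 || ncol(g) == 0)
        warning("no loci or samples survive filtering")
    rownames(report) <- NULL
    freqs <- refAlleleFreqs(x)
    list(genotypes = GenotypeData(g, population = pops,
                                  alleleFreqs = freqs[rownames(g)]),
         report = report)
}

#' Pairwise relatedness (PI-HAT) by method of moments
#'
#' For each sample pair, observed counts of identity-by-state classes
#' (IBS 0/1/2) over co-called loci are combined with their expected
#' probabilities under IBD 0/1/2 (computed from the supplied reference
#' allele frequencies, treated as known) to solve for P(IBD = 0/1/2);
#' PI-HAT = P(IBD=2) + P(IBD=1)/2, with the probabilities clamped to
#' [0, 1] and renormalized.  Pairs sharing fewer than \code{minLoci}
#' co-called loci are flagged unreliable.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param refFreqs per-locus alternate-allele frequencies; when NULL the
#'   frequencies stored in \code{x} are used, or, with a warning about
#'   bias, the within-sample observed frequencies.
#' @param minLoci minimum co-called loci for a reliable estimate.
#' @return symmetric matrix of PI-HAT values (diagonal 1) with attribute
#'   \code{"unreliable"}: a logical matrix marking low-overlap pairs.
#' @export
estimateRelatedness <- function(x, refFreqs = NULL, minLoci = 10) {
    g <- genoMatrix(x, samplesAsRows = TRUE)   # samples x loci
    if (is.null(refFreqs)) refFreqs <- refAlleleFreqs(x)
    if (is.null(refFreqs)) {
        warning("no reference allele frequencies supplied; using ",
                "within-sample frequencies (biased toward relatives)")
        refFreqs <- observedAlleleFreqs(x)
    }
    stopifnot(length(refFreqs) == ncol(g))
    inf <- is.finite(refFreqs) & refFreqs > 0 & refFreqs < 1
    g <- g[, inf, drop = FALSE]
    n <- nrow(g)
    out <- diag(1, n); dimnames(out) <- list(rownames(g), rownames(g))
    unrel <- matrix(FALSE, n, n, dimnames = dimnames(out))
    p <- refFreqs[inf]; q <- 1 - p
    e0 <- cbind(2 * p^2 * q^2, 4 * p^3 * q + 4 * p * q^3,
                p^4 + q^4 + 4 * p^2 * q^2)
    e1 <- cbind(0, 2 * p^2 * q + 2 * p * q^2,
                p^3 + q^3 + p^2 * q + p * q^2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        co <- !is.na(g[i, ]) & !is.na(g[j, ])
        L <- sum(co)
        if (L < minLoci) {
            unrel[i, j] <- unrel[j, i] <- TRUE
            out[i, j] <- out[j, i] <- NA_real_
            next
        }
        ibs <- 2 - abs(g[i, co] - g[j, co])
        ## hom-opposite pairs are IBS 0, not IBS 0 from |0-2| alone:
        ## |0-2| = 2 -> ibs 0; |0-1|=1 -> ibs 1; equal -> ibs 2.  Correct.
        N <- c(sum(ibs == 0), sum(ibs == 1), sum(ibs == 2))
        Ee0 <- colSums(e0[co, , drop = FALSE])
        Ee1 <- colSums(e1[co, , drop = FALSE])
        P0 <- if (Ee0[1] > 0) N[1] / Ee0[1] else 0
        P1 <- if (Ee1[2] > 0) (N[2] - P0 * Ee0[2]) / Ee1[2] else 0
        P2 <- (N[3] - P0 * Ee0[3] - P1 * Ee1[3]) / L
        pr <- pmax(c(P0, P1, P2), 0)
        pr <- pr / sum(pr)
        pihat <- pr[3] + pr[2] / 2
        out[i, j] <- out[j, i] <- min(max(pihat, 0), 1)
    }
    attr(out, "unreliable") <- unrel
    out
}

#' Cluster samples into individuals by relatedness thresholds
#'
#' Pairs with PI-HAT above \code{recaptureThreshold} are recaptures of one
#' individual; single-linkage closure of those pairs defines the
#' individuals.  For pairs from different clusters falling in the
#' ambiguous zone (\code{ambiguousLow}, \code{recaptureThreshold}], the
#' member with more missing data is dropped (ties broken toward the
#' lexicographically later id) so a possible recapture is never counted as
#' a separate individual.  Everything else remains a singleton individual.
#'
#' @param rel symmetric PI-HAT matrix (from
#'   \code{\link{estimateRelatedness}}).
#' @param nMissing optional named per-sample missing-call counts used by
#'   the ambiguous-zone drop rule (default: all zero, so ties are broken
#'   by id).
#' @param recaptureThreshold PI-HAT above which a pair is a recapture.
#' @param ambiguousLow lower edge of the ambiguous zone.
#' @return list: \code{assignment} (data.frame sample_id, individual),
#'   \code{dropped} (ambiguous samples removed), \code{nIndividuals}.
#' @export
clusterIndividuals <- function(rel, nMissing = NULL,
                               recaptureThreshold = 0.78,
                               ambiguousLow = 0.6) {
    stopifnot(ambiguousLow < recaptureThreshold)
    rel <- as.matrix(rel)
    if (!isSymmetric(unname(ifelse(is.na(rel), -1, rel))))
        stop("relatedness matrix must be symmetric")
    ids <- rownames(rel) %||% sprintf("S%03d", seq_len(nrow(rel)))
    dimnames(rel) <- list(ids, ids)
    if (is.null(nMissing)) nMissing <- rep(0, length(ids))
    if (is.null(names(nMissing))) names(nMissing) <- ids
    ## single-linkage closure over recapture pairs (union-find)
    parent <- stats::setNames(seq_along(ids), ids)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    n <- length(ids)
    mergeConflict <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        v <- rel[i, j]
        if (!is.na(v) && v > recaptureThreshold) {
            ri <- findRoot(i); rj <- findRoot(j)
            if (ri != rj) parent[ri] <- rj
        }
    }
    cluster <- vapply(seq_len(n), function(i) findRoot(i), numeric(1))
    ## transitivity conflicts: members of one cluster with sub-threshold link
    for (cl in unique(cluster)) {
        mem <- which(cluster == cl)
        if (length(mem) > 1) {
            sub <- rel[mem, mem]
            if (any(sub[lower.tri(sub)] <= recaptureThreshold, na.rm = TRUE))
                mergeConflict <- TRUE
        }
    }
    if (mergeConflict)
        warning("recapture clusters merged through intermediate samples ",
                "(some within-cluster PI-HAT below the threshold)")
    ## ambiguous zone between clusters: drop the less informative sample
    dropped <- character()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        v <- rel[i, j]
        if (is.na(v) || cluster[i] == cluster[j]) next
        if (v > ambiguousLow && v <= recaptureThreshold) {
            a <- ids[i]; b <- ids[j]
            if (a %in% dropped || b %in% dropped) next
            drop <- if (nMissing[a] > nMissing[b]) a
                    else if (nMissing[b] > nMissing[a]) b
                    else max(a, b)           # tie: lexicographically later
            dropped <- c(dropped, drop)
        }
    }
    keep <- !(ids %in% dropped)
    cl <- cluster[keep]
    indIdx <- match(cl, unique(cl))
    assignment <- data.frame(sample_id = ids[keep],
                             individual = sprintf("IND-%02d", indIdx))
    list(assignment = assignment, dropped = dropped,
         nIndividuals = length(unique(indIdx)))
}

#' Probability of identity for a locus panel
#'
#' Per biallelic locus with alternate frequency p (allele frequencies
#' p1 = 1-p, p2 = p): PID = sum(pi^4) + sum_\{i<j\} (2 pi pj)^2 and
#' PID-sibs = 0.25 + 0.5 sum(pi^2) + 0.5 (sum(pi^2))^2 - 0.25 sum(pi^4).
#' Across loci the per-locus values multiply.  A fixed locus contributes 1
#' (uninformative).
#'
#' @param freqs per-locus alternate-allele frequencies in [0, 1].
#' @return list: \code{PID}, \code{PIDsibs}, and per-locus vectors
#'   \code{perLocusPID}, \code{perLocusPIDsibs}.
#' @examples
#' probabilityOfIdentity(0.5)$PID   # 0.375
#' @export
probabilityOfIdentity <- function(freqs) {
    .checkFreqs(freqs)
    p <- freqs; q <- 1 - p
    s2 <- p^2 + q^2
    s4 <- p^4 + q^4
    pid <- s4 + (2 * p * q)^2
    pidsib <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
    list(PID = prod(pid), PIDsibs = prod(pidsib),
         perLocusPID = pid, perLocusPIDsibs = pidsib)
}
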