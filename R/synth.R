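## Synthetic-data generators.  Everything downstream (consensus calling,
## individual identification, population statistics) is exercised against
## data produced here with known ground truth.

.checkFreqs <- function(alleleFreqs) {
    bad <- which(!is.finite(alleleFreqs) | alleleFreqs < 0 | alleleFreqs > 1)
    if (length(bad))
        stop("allele frequency outside [0, 1] at locus ",
             paste(bad, collapse = ", "))
    invisible(alleleFreqs)
}

#' Simulate a population in Hardy-Weinberg equilibrium
#'
#' Genotypes at each locus are drawn independently with probabilities
#' (q^2, 2pq, p^2) for (hom-ref, het, hom-alt), p the alternate-allele
#' frequency.
#'
#' @param nIndividuals number of diploid individuals.
#' @param alleleFreqs per-locus alternate-allele frequency in [0, 1].
#' @param population optional single population label applied to all
#'   samples.
#' @param seed integer seed (optional; fixed seed gives identical output).
#' @return a \linkS4class{GenotypeData} carrying the generating frequencies
#'   in \code{refAlleleFreqs()}.
#' @examples
#' gd <- simulateHWEPopulation(50, rep(0.5, 10), seed = 1)
#' observedAlleleFreqs(gd)
#' @export
simulateHWEPopulation <- function(nIndividuals, alleleFreqs,
                                  population = NULL, seed = NULL) {
    stopifnot(nIndividuals >= 1, length(alleleFreqs) >= 1)
    .checkFreqs(alleleFreqs)
    if (!is.null(seed)) set.seed(seed)
    L <- length(alleleFreqs)
    ## each genotype is the sum of two Bernoulli(p) gametes
    g <- matrix(rbinom(L * nIndividuals, 2L, rep(alleleFreqs, nIndividuals)),
                nrow = L)
    rownames(g) <- sprintf("L%03d", seq_len(L))
    colnames(g) <- sprintf("S%03d", seq_len(nIndividuals))
    pop <- if (is.null(population)) NULL else rep(population, nIndividuals)
    GenotypeData(g, population = pop, alleleFreqs = alleleFreqs)
}

#' Build a simple nuclear-family pedigree table
#'
#' \code{nPairs} unrelated founder pairs, each with \code{nOffspring}
#' children.  The returned data.frame (id, mother, father; founders have NA
#' parents) is the input format of \code{\link{simulatePedigree}}.
#'
#' @param nPairs number of founder pairs.
#' @param nOffspring offspring per pair (recycled across pairs).
#' @return pedigree data.frame.
#' @export
nuclearPedigree <- function(nPairs, nOffspring = 2) {
    nOffspring <- rep_len(nOffspring, nPairs)
    rows <- list()
    for (i in seq_len(nPairs)) {
        mo <- sprintf("F%d_mother", i); fa <- sprintf("F%d_father", i)
        rows[[length(rows) + 1L]] <-
            data.frame(id = c(mo, fa), mother = NA, father = NA)
        if (nOffspring[i] > 0)
            rows[[length(rows) + 1L]] <- data.frame(
                id = sprintf("F%d_child%d", i, seq_len(nOffspring[i])),
                mother = mo, father = fa)
    }
    do.call(rbind, rows)
}

.checkPedigree <- function(ped) {
    stopifnot(all(c("id", "mother", "father") %in% colnames(ped)))
    if (anyDuplicated(ped$id)) stop("pedigree ids must be unique")
    founder <- is.na(ped$mother) & is.na(ped$father)
    half <- xor(is.na(ped$mother), is.na(ped$father))
    if (any(half)) stop("every non-founder needs exactly two parents")
    parents <- c(ped$mother[!founder], ped$father[!founder])
    if (!all(parents %in% ped$id)) stop("parent not found in pedigree")
    ## parents must precede children (acyclicity in table order)
    pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
    for (i in which(!founder))
        if (pos[ped$mother[i]] >= i || pos[ped$father[i]] >= i)
            stop("pedigree must list parents before offspring (acyclic)")
    invisible(ped)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders are drawn under HWE at the supplied frequencies; each offspring
#' receives one uniformly chosen allele from each parent at every locus
#' (Mendelian segregation).  True pairwise relationship classes are
#' returned for validating relatedness estimators: "parent_offspring",
#' "full_sib", and "unrelated" (founder pairs and cross-family pairs).
#'
#' @param ped pedigree data.frame (id, mother, father); see
#'   \code{\link{nuclearPedigree}}.
#' @param alleleFreqs per-locus alternate-allele frequency.
#' @param seed integer seed.
#' @return list with \code{genotypes} (a \linkS4class{GenotypeData}) and
#'   \code{relationships} (data.frame id1, id2, class).
#' @export
simulatePedigree <- function(ped, alleleFreqs, seed = NULL) {
    .checkPedigree(ped)
    .checkFreqs(alleleFreqs)
    if (!is.null(seed)) set.seed(seed)
    L <- length(alleleFreqs)
    n <- nrow(ped)
    ## haplotype pair per individual, alleles coded 0/1
    hapA <- matrix(NA_integer_, L, n); hapB <- matrix(NA_integer_, L, n)
    colnames(hapA) <- colnames(hapB) <- ped$id
    for (i in seq_len(n)) {
        if (is.na(ped$mother[i])) {
            hapA[, i] <- rbinom(L, 1L, alleleFreqs)
            hapB[, i] <- rbinom(L, 1L, alleleFreqs)
        } else {
            mo <- ped$mother[i]; fa <- ped$father[i]
            pickA <- runif(L) < 0.5
            hapA[, i] <- ifelse(pickA, hapA[, mo], hapB[, mo])
            pickB <- runif(L) < 0.5
            hapB[, i] <- ifelse(pickB, hapA[, fa], hapB[, fa])
        }
    }
    g <- hapA + hapB
    rownames(g) <- sprintf("L%03d", seq_len(L))
    rel <- .pedigreeRelationships(ped)
    list(genotypes = GenotypeData(g, alleleFreqs = alleleFreqs),
         relationships = rel)
}

.pedigreeRelationships <- function(ped) {
    ids <- ped$id
    mo <- stats::setNames(ped$mother, ids); fa <- stats::setNames(ped$father, ids)
    pairs <- t(utils::combn(ids, 2))
    cls <- apply(pairs, 1, function(p) {
        a <- p[1]; b <- p[2]
        if ((!is.na(mo[b]) && a %in% c(mo[b], fa[b])) ||
            (!is.na(mo[a]) && b %in% c(mo[a], fa[a])))
            return("parent_offspring")
        if (!is.na(mo[a]) && !is.na(mo[b]) &&
            mo[a] == mo[b] && fa[a] == fa[b])
            return("full_sib")
        "unrelated"
    })
    data.frame(id1 = pairs[, 1], id2 = pairs[, 2], class = cls)
}

#' Simulate noisy multi-method genotype calls for noninvasive samples
#'
#' Emulates the error structure of degraded noninvasive samples at a single
#' diagnostic site: each genotyping method independently fails to return a
#' call with its method-specific failure probability, and a heterozygote is
#' mis-called as one of the two homozygotes (equal odds) with probability
#' \code{dropoutRate} per call.  Homozygotes are never mis-called as
#' heterozygotes.  Method failure-rate defaults complement the printed
#' success rates of Sanger sequencing (0.52), NGS panel genotyping (0.6)
#' and allele-specific PCR (0.68).
#'
#' @param truth a \linkS4class{GenotypeData} with a single locus (the
#'   diagnostic site), or an integer vector of true 0/1/2 genotypes.
#' @param dropoutRate probability a heterozygote is observed homozygous,
#'   per call.
#' @param failureRates named per-method missing-call probabilities.
#' @param aspcrReplicates number of AS-PCR replicate calls to simulate per
#'   sample (the multiple-tube rule consults these when methods disagree).
#' @param seed integer seed.
#' @return long-format call table: sample_id, method, call (genotype string
#'   "+/+", "+/m", "m/m" or "x/x"), replicate (0 = primary call, 1..k =
#'   AS-PCR replicates).
#' @export
simulateNoninvasiveCalls <- function(truth, dropoutRate = 0.1,
                                     failureRates = c(sanger = 0.48,
                                                      ngs = 0.40,
                                                      aspcr = 0.32),
                                     aspcrReplicates = 3, seed = NULL) {
    if (methods::is(truth, "GenotypeData")) {
        g <- genoMatrix(truth)
        if (nrow(g) != 1)
            stop("expected a single diagnostic locus")
        truthVec <- stats::setNames(as.integer(g[1, ]), colnames(g))
    } else truthVec <- truth
    if (is.null(names(truthVec)))
        names(truthVec) <- sprintf("S%03d", seq_along(truthVec))
    stopifnot(dropoutRate >= 0, dropoutRate <= 1,
              all(failureRates >= 0 & failureRates <= 1))
    if (!is.null(seed)) set.seed(seed)

    callOnce <- function(geno, failP) {
        if (runif(1) < failP) return("x/x")
        if (geno == 1L && runif(1) < dropoutRate)
            return(if (runif(1) < 0.5) "+/+" else "m/m")
        c("+/+", "+/m", "m/m")[geno + 1L]
    }
    out <- list()
    for (s in names(truthVec)) {
        for (m in names(failureRates))
            out[[length(out) + 1L]] <- data.frame(
                sample_id = s, method = m,
                call = callOnce(truthVec[s], failureRates[m]), replicate = 0L)
        for (k in seq_len(aspcrReplicates))
            out[[length(out) + 1L]] <- data.frame(
                sample_id = s, method = "aspcr",
                call = callOnce(truthVec[s], failureRates["aspcr"]),
                replicate = k)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Simulate noisy recaptures of known individuals at many loci
#'
#' Ground truth for the individual-identification pipeline: each true
#' individual is observed \code{recaptures[i]} times; every observation is
#' the true multilocus genotype degraded by per-call allelic dropout (hets
#' to a random homozygote) and missingness.
#'
#' @param truth a \linkS4class{GenotypeData} of true individuals.
#' @param recaptures integer vector, observations per individual (recycled).
#' @param dropoutRate per-call heterozygote dropout probability.
#' @param missingRate per-call missing probability.
#' @param seed integer seed.
#' @return list with \code{samples} (a \linkS4class{GenotypeData} of noisy
#'   observations) and \code{truthMap} (data.frame sample_id, individual).
#' @export
simulateRecaptureSamples <- function(truth, recaptures = 2,
                                     dropoutRate = 0.05, missingRate = 0.05,
                                     seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    g <- genoMatrix(truth)
    nInd <- ncol(g)
    recaptures <- rep_len(recaptures, nInd)
    cols <- list(); map <- list()
    for (i in seq_len(nInd)) {
        for (k in seq_len(recaptures[i])) {
            obs <- g[, i]
            het <- which(!is.na(obs) & obs == 1L)
            drop <- het[runif(length(het)) < dropoutRate]
            if (length(drop))
                obs[drop] <- ifelse(runif(length(drop)) < 0.5, 0L, 2L)
            obs[runif(length(obs)) < missingRate] <- NA_integer_
            sid <- sprintf("%s_obs%d", colnames(g)[i], k)
            cols[[sid]] <- obs
            map[[sid]] <- colnames(g)[i]
        }
    }
    gm <- do.call(cbind, cols)
    rownames(gm) <- rownames(g)
    list(samples = GenotypeData(gm, alleleFreqs = refAlleleFreqs(truth)),
         truthMap = data.frame(sample_id = names(map),
                               individual = unlist(map), row.names = NULL))
}

#' Simulate spatially structured populations (isolation by distance)
#'
#' Population allele frequencies diverge from a common ancestral frequency
#' by correlated Gaussian deviates on the logit scale with correlation
#' exp(-d/decay) between populations at geographic distance d, so
#' divergence grows with distance.  Genotypes are drawn under HWE within
#' populations.
#'
#' @param coords numeric matrix of population coordinates (rows =
#'   populations).
#' @param nPerPop individuals per population (recycled).
#' @param nLoci number of loci.
#' @param ancestralFreqs per-locus ancestral frequency (default: uniform on
#'   [0.2, 0.8]).
#' @param sigma standard deviation of the logit-scale deviates (controls
#'   overall differentiation).
#' @param decay correlation length of the spatial process; larger values
#'   give stronger isolation by distance at a given map scale, and
#'   \code{decay = Inf} makes all populations equally correlated (no
#'   distance signal).
#' @param seed integer seed.
#' @return list: \code{genotypes} (\linkS4class{GenotypeData} with
#'   population labels), \code{geoDist} (population distance matrix),
#'   \code{popFreqs} (loci x populations frequency matrix).
#' @export
simulateIBDLandscape <- function(coords, nPerPop = 20, nLoci = 100,
                                 ancestralFreqs = NULL, sigma = 0.5,
                                 decay = 1, seed = NULL) {
    stopifnot(decay > 0)
    if (!is.null(seed)) set.seed(seed)
    coords <- as.matrix(coords)
    P <- nrow(coords)
    if (is.null(rownames(coords)))
        rownames(coords) <- sprintf("P%02d", seq_len(P))
    if (is.null(ancestralFreqs))
        ancestralFreqs <- runif(nLoci, 0.2, 0.8)
    .checkFreqs(ancestralFreqs)
    nLoci <- length(ancestralFreqs)
    D <- as.matrix(dist(coords))
    C <- exp(-D / decay)
    ## correlated deviates: one multivariate normal draw per locus
    ch <- chol(C + diag(1e-10, P))
    Z <- matrix(stats::rnorm(nLoci * P), nLoci, P) %*% ch
    logit <- function(p) log(p / (1 - p))
    popFreqs <- 1 / (1 + exp(-(outer(logit(ancestralFreqs), rep(1, P)) +
                               sigma * Z)))
    colnames(popFreqs) <- rownames(coords)
    rownames(popFreqs) <- sprintf("L%03d", seq_len(nLoci))
    nPerPop <- rep_len(nPerPop, P)
    mats <- lapply(seq_len(P), function(k) {
        matrix(rbinom(nLoci * nPerPop[k], 2L,
                      rep(popFreqs[, k], nPerPop[k])), nrow = nLoci)
    })
    g <- do.call(cbind, mats)
    rownames(g) <- rownames(popFreqs)
    colnames(g) <- unlist(lapply(seq_len(P), function(k)
        sprintf("%s_S%02d", rownames(coords)[k], seq_len(nPerPop[k]))))
    pop <- rep(rownames(coords), nPerPop)
    list(genotypes = GenotypeData(g, population = pop),
         geoDist = D, popFreqs = popFreqs)
}

#' Simulate populations under an island model with known F_ST
#'
#' Per-locus population frequencies follow the Balding-Nichols model: given
#' ancestral frequency p and differentiation F, each population's frequency
#' is Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance
#' F p (1-p) — i.e. expected F_ST = F.  Used to check that the
#' Weir-Cockerham estimator recovers a known truth.
#'
#' @param nPops number of populations.
#' @param fst the generating differentiation.
#' @param nPerPop diploid individuals per population.
#' @param nLoci number of loci.
#' @param ancestralFreqs per-locus ancestral frequency (default uniform on
#'   [0.2, 0.8]).
#' @param seed integer seed.
#' @return a \linkS4class{GenotypeData} with population labels.
#' @export
simulateIslandModel <- function(nPops = 2, fst = 0.1, nPerPop = 100,
                                nLoci = 200, ancestralFreqs = NULL,
                                seed = NULL) {
    stopifnot(fst > 0, fst < 1)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(ancestralFreqs))
        ancestralFreqs <- runif(nLoci, 0.2, 0.8)
    .checkFreqs(ancestralFreqs)
    nLoci <- length(ancestralFreqs)
    a <- ancestralFreqs * (1 - fst) / fst
    b <- (1 - ancestralFreqs) * (1 - fst) / fst
    g <- matrix(NA_integer_, nLoci, nPops * nPerPop)
    for (k in seq_len(nPops)) {
        pk <- stats::rbeta(nLoci, a, b)
        idx <- (k - 1) * nPerPop + seq_len(nPerPop)
        g[, idx] <- rbinom(nLoci * nPerPop, 2L, rep(pk, nPerPop))
    }
    rownames(g) <- sprintf("L%03d", seq_len(nLoci))
    colnames(g) <- sprintf("pop%d_S%03d", rep(seq_len(nPops), each = nPerPop),
                           rep(seq_len(nPerPop), nPops))
    GenotypeData(g, population = rep(sprintf("pop%d", seq_len(nPops)),
                                     each = nPerPop))
}
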