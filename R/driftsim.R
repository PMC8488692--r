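## Forward-in-time neutral Wright-Fisher drift simulator.  A bottleneck of
## n0 founders recovers under the logistic map toward carrying capacity K;
## each generation the new gene-copy pool is a binomial draw from the
## parental allele frequency.  The same machinery runs to absorption for
## future-trajectory (time to fixation) simulations, optionally with
## wild-type migrant copies joining the parental gamete pool each
## generation (genetic rescue).  An exact absorbing-Markov-chain oracle
## validates the simulator for constant pool sizes.

#' Construct drift-simulation parameters
#'
#' @param n0 founding population size (individuals).
#' @param copiesPerIndividual gene copies per individual in the gamete
#'   pool: 2 for the bottleneck/grid simulations (diploid pool), 1 by
#'   convention for the fixation simulations.
#' @param generations horizon of bottleneck simulations.
#' @param r logistic growth rate per generation.
#' @param K carrying capacity (individuals).
#' @param reps replicate count.
#' @param founderMode "forced_het" or "sampled".
#' @param pSource source allele frequency (sampled mode only).
#' @param p0 starting frequency for fixation simulations.
#' @param threshold frequency cutoff for the probability grid.
#' @param migrantCopies wild-type gene copies added to the parental pool
#'   each generation.
#' @param maxGenerations cap for fixation runs (capped replicates are
#'   reported separately).
#' @param seed integer seed (NA for none).
#' @return a \linkS4class{DriftParams}.
#' @export
driftParams <- function(n0 = 2, copiesPerIndividual = 2, generations = 44,
                        r = 0.15, K = 104, reps = 1000,
                        founderMode = c("forced_het", "sampled"),
                        pSource = NA_real_, p0 = NA_real_, threshold = 0.5,
                        migrantCopies = 0, maxGenerations = 1e5,
                        seed = NA_real_) {
    founderMode <- match.arg(founderMode)
    methods::new("DriftParams", n0 = n0,
                 copiesPerIndividual = copiesPerIndividual,
                 generations = generations, r = r, K = K, reps = reps,
                 founderMode = founderMode, pSource = pSource, p0 = p0,
                 threshold = threshold, migrantCopies = migrantCopies,
                 maxGenerations = maxGenerations, seed = seed)
}

#' @export
setMethod("show", "DriftParams", function(object) {
    cat(sprintf(
        "DriftParams: n0=%g x%g copies, r=%g, K=%g, G=%g, reps=%g%s\n",
        object@n0, object@copiesPerIndividual, object@r, object@K,
        object@generations, object@reps,
        if (object@migrantCopies > 0)
            sprintf(", %g migrant copies/gen", object@migrantCopies)
        else ""))
})

#' One step of the logistic growth map
#'
#' n' = n + r n (1 - n/K).  The population size is kept real-valued: with
#' integer rounding every generation, small sizes (n = 2, 3 at r = 0.15)
#' are fixed points of the rounded map and a severe bottleneck could never
#' recover.  Only the sampled gene-copy pool is rounded (see
#' \code{\link{simulateBottleneck}}).  K is a fixed point.
#'
#' @param n population size (individuals; real-valued).
#' @param r per-generation growth rate.
#' @param K carrying capacity.
#' @return the updated size, floored at 1.
#' @examples
#' logisticStep(10, 0.15, 104)   # 11.356
#' logisticStep(104, 0.15, 104)  # 104: carrying capacity is a fixed point
#' @export
logisticStep <- function(n, r, K) {
    stopifnot(n >= 1, K > 0)
    pmax(1, n + r * n * (1 - n / K))
}

#' Binomial resampling of the gene-copy pool
#'
#' @param p parental mutant-allele frequency (vectorized).
#' @param nCopies pool size in gene copies.
#' @return list: \code{count} (mutant copies, Binomial(nCopies, p)) and
#'   \code{freq} (count / nCopies).
#' @export
nextGeneration <- function(p, nCopies) {
    stopifnot(all(p >= 0 & p <= 1), nCopies >= 1)
    k <- rbinom(length(p), nCopies, p)
    list(count = k, freq = k / nCopies)
}

#' Founding allele frequency
#'
#' In "forced_het" mode the founders include exactly one heterozygote, so
#' p0 = 1/(copiesPerIndividual * n0) deterministically.  In "sampled" mode
#' the founder pool is a binomial draw from the source frequency.
#'
#' @param params a \linkS4class{DriftParams}.
#' @param n number of independent founding draws (sampled mode).
#' @return vector of founding frequencies (length n, or 1 in forced mode
#'   recycled as needed).
#' @examples
#' founderFrequency(driftParams(n0 = 2))   # 0.25
#' @export
founderFrequency <- function(params, n = 1) {
    pool <- round(params@copiesPerIndividual * params@n0)
    if (params@founderMode == "forced_het")
        return(rep(1 / pool, n))
    if (is.na(params@pSource))
        stop("sampled founding requires pSource")
    rbinom(n, pool, params@pSource) / pool
}

.poolSize <- function(params, n) max(1L, round(params@copiesPerIndividual * n))

#' Simulate bottleneck founding and logistic recovery
#'
#' Starting from \code{n0} founders at the founding frequency, each
#' generation the population size advances one logistic step and the new
#' pool of \code{round(copiesPerIndividual * size)} gene copies is drawn
#' binomially from the parental frequency.  All replicates share the
#' (deterministic) size trajectory.
#'
#' @param params a \linkS4class{DriftParams} with \code{migrantCopies = 0}.
#' @return a \linkS4class{TrajectorySet}.
#' @examples
#' ts <- simulateBottleneck(driftParams(n0 = 2, reps = 100, seed = 1))
#' mean(finalFrequencies(ts) >= 0.5)
#' @export
simulateBottleneck <- function(params) {
    methods::validObject(params)
    if (params@migrantCopies != 0)
        stop("bottleneck simulation is migration-free; use ",
             "simulateToFixation for genetic rescue")
    if (!is.na(params@seed)) set.seed(params@seed)
    G <- params@generations
    reps <- params@reps
    size <- numeric(G + 1)
    size[1] <- params@n0
    for (g in seq_len(G))
        size[g + 1] <- if (params@r > 0)
            logisticStep(size[g], params@r, params@K) else size[g]
    freq <- matrix(NA_real_, reps, G + 1)
    freq[, 1] <- founderFrequency(params, reps)
    p <- freq[, 1]
    for (g in seq_len(G)) {
        pool <- .poolSize(params, size[g + 1])
        p <- rbinom(reps, pool, p) / pool
        freq[, g + 1] <- p
    }
    methods::new("TrajectorySet", size = size, freq = freq, params = params)
}

#' @rdname finalFrequencies
#' @export
setGeneric("finalFrequencies", function(x) standardGeneric("finalFrequencies"))

#' Final-generation allele frequencies of a trajectory set
#'
#' @param x a \linkS4class{TrajectorySet}.
#' @return numeric vector, one entry per replicate.
#' @export
setMethod("finalFrequencies", "TrajectorySet", function(x)
    x@freq[, ncol(x@freq)])

#' @export
setMethod("show", "TrajectorySet", function(object) {
    cat(sprintf(
        "TrajectorySet: %d replicates x %d generations; final freq %s\n",
        nrow(object@freq), ncol(object@freq) - 1,
        paste(sprintf("%.3f", stats::quantile(finalFrequencies(object),
                                              c(0.25, 0.5, 0.75))),
              collapse = "/")))
})

#' Probability grid P(final frequency >= threshold)
#'
#' For every (bottleneck size, drift time) cell, \code{params@reps}
#' independent replicates are run and the fraction whose final-generation
#' frequency reaches the threshold is recorded — the probability that
#' drift alone carries the allele to the observed level.
#'
#' @param n0Range bottleneck sizes (row axis).
#' @param genRange drift times in generations (column axis).
#' @param params template \linkS4class{DriftParams} (n0 and generations are
#'   overridden per cell; the seed, if set, is used once for the whole
#'   grid).
#' @param threshold frequency cutoff (default from \code{params}).
#' @return a \linkS4class{ProbabilityGrid}.
#' @export
probabilityGrid <- function(n0Range = 2:20, genRange = 10:50,
                            params = driftParams(),
                            threshold = params@threshold) {
    if (!length(n0Range) || !length(genRange))
        stop("axis ranges must be non-empty")
    if (!is.na(params@seed)) set.seed(params@seed)
    prob <- matrix(NA_real_, length(n0Range), length(genRange),
                   dimnames = list(n0Range, genRange))
    cellParams <- params
    cellParams@seed <- NA_real_   # one stream for the whole grid
    for (i in seq_along(n0Range)) for (j in seq_along(genRange)) {
        cellParams@n0 <- n0Range[i]
        cellParams@generations <- genRange[j]
        ts <- simulateBottleneck(cellParams)
        prob[i, j] <- mean(finalFrequencies(ts) >= threshold)
    }
    methods::new("ProbabilityGrid", prob = prob, n0 = n0Range,
                 generations = genRange, reps = params@reps,
                 threshold = threshold)
}

#' @export
setMethod("show", "ProbabilityGrid", function(object) {
    cat(sprintf(
        "ProbabilityGrid: %d bottleneck sizes x %d drift times, %g reps/cell\n",
        length(object@n0), length(object@generations), object@reps))
    cat(sprintf("P(p >= %g) range: %.3f to %.3f (max at n0=%s, G=%s)\n",
                object@threshold, min(object@prob), max(object@prob),
                rownames(object@prob)[which(object@prob == max(object@prob),
                                            arr.ind = TRUE)[1, 1]],
                colnames(object@prob)[which(object@prob == max(object@prob),
                                            arr.ind = TRUE)[1, 2]]))
})

#' Convert a probability grid to a long data.frame
#'
#' @param x a \linkS4class{ProbabilityGrid}.
#' @param row.names,optional,... unused.
#' @return data.frame: n0, generations, prob, reps.
#' @export
setMethod("as.data.frame", "ProbabilityGrid",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(n0 = rep(x@n0, times = length(x@generations)),
               generations = rep(x@generations, each = length(x@n0)),
               prob = as.vector(x@prob), reps = x@reps)
})

#' Simulate to fixation, optionally with genetic rescue
#'
#' Each replicate starts at frequency \code{p0} (default 0.5) in a
#' population of \code{n0} individuals and runs until the mutant allele is
#' fixed or lost.  Per generation, \code{migrantCopies} wild-type gene
#' copies join the parental gamete pool before offspring sampling, so the
#' effective parental frequency is p*c/(c + m) with c the parental pool
#' size; the population-size trajectory itself is unchanged.  With
#' migration the all-mutant state is not absorbing (migrants keep arriving)
#' and the mutant is eventually lost.  Replicates hitting
#' \code{maxGenerations} are reported as "capped".
#'
#' @param params a \linkS4class{DriftParams}; \code{p0} defaults to 0.5
#'   when NA.
#' @return a \linkS4class{FixationSummary}.
#' @examples
#' fs <- simulateToFixation(driftParams(n0 = 10, copiesPerIndividual = 1,
#'                                      r = 0, reps = 200, p0 = 0.5,
#'                                      seed = 1))
#' meanAbsorption(fs)
#' fixationProportion(fs, "mutant")
#' @export
simulateToFixation <- function(params) {
    methods::validObject(params)
    if (!is.na(params@seed)) set.seed(params@seed)
    p0 <- if (is.na(params@p0)) 0.5 else params@p0
    m <- params@migrantCopies
    if (m > .poolSize(params, params@n0))
        stop("migrantCopies exceeds the founding gene-copy pool")
    reps <- params@reps
    p <- rep(p0, reps)
    gen <- rep(NA_real_, reps)
    allele <- rep(NA_character_, reps)
    active <- rep(TRUE, reps)
    n <- params@n0
    g <- 0
    repeat {
        fixedWild <- active & p == 0
        fixedMut <- active & p == 1 & m == 0
        gen[fixedWild | fixedMut] <- g
        allele[fixedWild] <- "wild"
        allele[fixedMut] <- "mutant"
        active <- active & !(fixedWild | fixedMut)
        if (!any(active)) break
        if (g >= params@maxGenerations) {
            gen[active] <- g
            allele[active] <- "capped"
            break
        }
        cParent <- .poolSize(params, n)
        n <- if (params@r > 0) logisticStep(n, params@r, params@K) else n
        pool <- .poolSize(params, n)
        pEff <- p[active] * cParent / (cParent + m)
        p[active] <- rbinom(sum(active), pool, pEff) / pool
        g <- g + 1
    }
    methods::new("FixationSummary",
                 replicates = data.frame(rep = seq_len(reps),
                                         generations = gen,
                                         allele = allele),
                 params = params)
}

#' @rdname meanAbsorption
#' @export
setGeneric("meanAbsorption", function(x, allele = "any")
    standardGeneric("meanAbsorption"))

#' Mean absorption time of a fixation simulation
#'
#' @param x a \linkS4class{FixationSummary}.
#' @param allele "any" (all uncapped replicates), "mutant" or "wild"
#'   (conditional on which allele fixed).
#' @return mean absorption generation.
#' @export
setMethod("meanAbsorption", "FixationSummary", function(x, allele = "any") {
    d <- x@replicates
    keep <- if (allele == "any") d$allele != "capped" else d$allele == allele
    mean(d$generations[keep])
})

#' @rdname fixationProportion
#' @export
setGeneric("fixationProportion", function(x, allele = "mutant")
    standardGeneric("fixationProportion"))

#' Proportion of uncapped replicates fixing a given allele
#'
#' @param x a \linkS4class{FixationSummary}.
#' @param allele "mutant" or "wild".
#' @return proportion in [0, 1].
#' @export
setMethod("fixationProportion", "FixationSummary",
          function(x, allele = "mutant") {
    d <- x@replicates[x@replicates$allele != "capped", ]
    mean(d$allele == allele)
})

#' @export
setMethod("show", "FixationSummary", function(object) {
    d <- object@replicates
    capped <- sum(d$allele == "capped")
    cat(sprintf(
        "FixationSummary: %d replicates; mean absorption %.1f (sd %.1f)\n",
        nrow(d), meanAbsorption(object),
        stats::sd(d$generations[d$allele != "capped"])))
    cat(sprintf("fixed mutant %.1f%%, wild %.1f%%%s\n",
                100 * fixationProportion(object, "mutant"),
                100 * fixationProportion(object, "wild"),
                if (capped) sprintf(" (%d capped)", capped) else ""))
})

#' Exact absorbing-Markov-chain oracle for a constant gene-copy pool
#'
#' Builds the full binomial transition matrix over mutant copy counts
#' 0..nCopies (with the migration adjustment to the parental frequency)
#' and solves the absorbing-chain linear systems for the fixation
#' probability of the mutant and the expected time to absorption from
#' p0.  Without migration both boundaries absorb and the fixation
#' probability equals p0 (neutral martingale); with migration only loss
#' absorbs.
#'
#' @param nCopies pool size in gene copies (<= 200; dense linear algebra).
#' @param p0 starting frequency; round(p0 * nCopies) must be a valid copy
#'   count.
#' @param migrantCopies wild-type copies added per generation.
#' @return list: \code{fixMutant}, \code{fixWild}, \code{expectedTime}.
#' @examples
#' markovOracle(10, 0.5)$fixMutant      # exactly 0.5
#' markovOracle(2, 0.5)$expectedTime    # exactly 2
#' @export
markovOracle <- function(nCopies, p0, migrantCopies = 0) {
    stopifnot(nCopies >= 1, nCopies <= 200, p0 >= 0, p0 <= 1,
              migrantCopies >= 0)
    states <- 0:nCopies
    pEff <- (states / nCopies) * nCopies / (nCopies + migrantCopies)
    P <- t(vapply(pEff, function(pe) dbinom(states, nCopies, pe),
                  numeric(nCopies + 1)))
    absorbing <- if (migrantCopies == 0) c(1L, nCopies + 1L) else 1L
    trans <- setdiff(seq_len(nCopies + 1L), absorbing)
    i0 <- round(p0 * nCopies) + 1L
    if (abs(p0 * nCopies - round(p0 * nCopies)) > 1e-8)
        stop("p0 * nCopies must be an integer copy count")
    Q <- P[trans, trans, drop = FALSE]
    if (max(abs(eigen(Q, only.values = TRUE)$values)) >= 1 - 1e-12)
        stop("chain is not absorbing for these parameters")
    IQ <- diag(length(trans)) - Q
    ## expected absorption time
    tvec <- solve(IQ, rep(1, length(trans)))
    et <- numeric(nCopies + 1L)
    et[trans] <- tvec
    ## mutant fixation probability
    if (migrantCopies == 0) {
        h <- numeric(nCopies + 1L)
        h[nCopies + 1L] <- 1
        h[trans] <- solve(IQ, P[trans, nCopies + 1L])
        fixMut <- h[i0]
    } else fixMut <- 0
    list(fixMutant = fixMut, fixWild = 1 - fixMut,
         expectedTime = et[i0])
}
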