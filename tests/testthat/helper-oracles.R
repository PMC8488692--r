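## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths.

## Monte Carlo oracle for the exact HWE test: shuffle the allele pool into
## random diploid pairings and build the conditional distribution of
## heterozygote counts empirically.
mcHweOracle <- function(nHomRef, nHet, nHomAlt, draws = 2e5) {
    n <- nHomRef + nHet + nHomAlt
    pool <- rep(c(1L, 0L), c(nHet + 2L * nHomAlt, nHet + 2L * nHomRef))
    hets <- vapply(seq_len(draws), function(i) {
        x <- sample(pool)
        sum(x[seq(1, 2 * n, 2)] != x[seq(2, 2 * n, 2)])
    }, numeric(1))
    tab <- table(hets) / draws
    pObs <- tab[as.character(nHet)]
    sum(tab[tab <= pObs + 1e-9])
}

## ANOVA-route oracle for Weir-Cockerham theta at one locus: allele-copy
## indicator variables, mean squares among populations / among individuals
## within populations / within individuals.
anovaThetaOracle <- function(genos, pops) {
    keep <- !is.na(genos)
    genos <- genos[keep]; pops <- pops[keep]
    y <- unlist(lapply(genos, function(g) switch(g + 1L, c(0, 0), c(0, 1),
                                                 c(1, 1))))
    ind <- rep(seq_along(genos), each = 2)
    pop <- rep(pops, each = 2)
    ni <- tapply(ind, pop, function(x) length(unique(x)))
    r <- length(ni)
    ybarP <- tapply(y, pop, mean)
    ybar <- mean(y)
    ybarI <- tapply(y, ind, mean)
    nInd <- tapply(pop, ind, function(x) x[1])
    SSP <- sum(2 * ni * (ybarP - ybar)^2)
    SSI <- sum(2 * (ybarI - ybarP[nInd])^2)
    SSG <- sum((y - ybarI[as.character(ind)])^2)
    MSP <- SSP / (r - 1)
    MSI <- SSI / (sum(ni) - r)
    MSG <- SSG / sum(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    s2g <- MSG
    s2i <- (MSI - MSG) / 2
    s2p <- (MSP - MSI) / (2 * nc)
    s2p / (s2p + s2i + s2g)
}

## exact absorption moments for a constant Wright-Fisher pool, independent
## of the package's markovOracle: first-step recursion solved by fixed-point
## iteration on expected times.
iterativeAbsorptionTime <- function(nCopies, p0, tol = 1e-10) {
    states <- 0:nCopies
    P <- t(vapply(states / nCopies,
                  function(p) dbinom(states, nCopies, p),
                  numeric(nCopies + 1)))
    t0 <- rep(0, nCopies + 1)
    repeat {
        t1 <- 1 + as.vector(P %*% t0)
        t1[c(1, nCopies + 1)] <- 0
        if (max(abs(t1 - t0)) < tol) break
        t0 <- t1
    }
    t0[round(p0 * nCopies) + 1]
}
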