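test_that("filter cascade removes loci and samples for the stated reasons", {
    ## forced missingness threshold
    g <- genoMatrix(simulateHWEPopulation(30, rep(0.4, 15), seed = 51))
    g[1, 1:5] <- NA
    f <- applyFilters(GenotypeData(g), filterSpec(minLociPerSample = 5))
    expect_true(any(f$report$item == "L001" &
                    f$report$reason == "missingness"))
    expect_false("L001" %in% rownames(genoMatrix(f$genotypes)))

    ## a singleton (MAC = 1) locus is removed
    g2 <- matrix(0L, 4, 20, dimnames = list(paste0("L", 1:4), NULL))
    g2[1, ] <- rbinom(20, 2, 0.5); g2[2, ] <- rbinom(20, 2, 0.5)
    g2[3, ] <- rbinom(20, 2, 0.5)
    g2[4, 1] <- 1L   # exactly one alternate allele overall
    f2 <- applyFilters(GenotypeData(g2), filterSpec(minLociPerSample = 2))
    expect_true(any(f2$report$item == "L4" & f2$report$reason == "MAC"))
    ## monomorphic loci flagged as such, not as MAC
    g3 <- rbind(g2[1:3, ], L5 = rep(0L, 20))
    f3 <- applyFilters(GenotypeData(g3), filterSpec(minLociPerSample = 2))
    expect_true(any(f3$report$item == "L5" &
                    f3$report$reason == "monomorphic"))

    ## clean matrix passes through untouched
    clean <- simulateHWEPopulation(40, rep(0.5, 10), seed = 52)
    fc <- applyFilters(clean, filterSpec(minLociPerSample = 5))
    expect_equal(nrow(fc$report), 0)
    expect_identical(genoMatrix(fc$genotypes), genoMatrix(clean))

    ## gross HWE violation in two populations drops the locus
    gh <- genoMatrix(simulateHWEPopulation(60, rep(0.5, 6), seed = 53))
    gh[1, ] <- 1L   # all heterozygous in both populations
    pops <- rep(c("A", "B"), each = 30)
    fh <- applyFilters(GenotypeData(gh, population = pops),
                       filterSpec(minLociPerSample = 2))
    expect_true(any(fh$report$item == "L001" & fh$report$reason == "HWE"))

    ## over-aggressive thresholds empty the matrix with a warning
    expect_warning(
        applyFilters(clean, filterSpec(maxLocusMissing = 0,
                                       minLociPerSample = 1e6)),
        "survive")
})

test_that("PI-HAT recovers pedigree expectations and flags sparse pairs", {
    sim <- simulatePedigree(nuclearPedigree(6, 2), rep(0.5, 500), seed = 61)
    rel <- estimateRelatedness(sim$genotypes)
    r <- sim$relationships
    for (cls in c("parent_offspring", "full_sib", "unrelated")) {
        pairs <- r[r$class == cls, ]
        vals <- mapply(function(a, b) rel[a, b], pairs$id1, pairs$id2)
        target <- c(parent_offspring = 0.5, full_sib = 0.5, unrelated = 0)[cls]
        expect_lt(abs(mean(vals) - target), 0.1)
    }
    ## identical genotype vectors give PI-HAT 1
    g <- genoMatrix(sim$genotypes)
    dup <- GenotypeData(cbind(g[, 1, drop = FALSE], copy = g[, 1]),
                        alleleFreqs = refAlleleFreqs(sim$genotypes))
    relDup <- estimateRelatedness(dup)
    expect_equal(relDup[1, 2], 1)
    ## a pair sharing < 10 co-called loci is flagged unreliable
    gs <- g[1:12, 1:3]
    gs[1:8, 2] <- NA
    gs[9:12, 3] <- NA   # samples 2 and 3 share no co-called loci
    relS <- suppressWarnings(estimateRelatedness(
        GenotypeData(gs, alleleFreqs = refAlleleFreqs(sim$genotypes)[1:12])))
    expect_true(attr(relS, "unreliable")[2, 3])
    expect_true(is.na(relS[2, 3]))
})

test_that("recapture clustering follows the threshold rules", {
    ## four samples, all pairwise 0.95: one individual
    m <- matrix(0.95, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(m) <- 1
    cl <- clusterIndividuals(m)
    expect_equal(cl$nIndividuals, 1)
    expect_equal(length(cl$dropped), 0)

    ## two clusters linked by one ambiguous pair: one sample dropped
    ids <- c("a", "b", "c", "d")
    m2 <- diag(1, 4); dimnames(m2) <- list(ids, ids)
    m2[1, 2] <- m2[2, 1] <- 0.9      # a~b recapture
    m2[3, 4] <- m2[4, 3] <- 0.9      # c~d recapture
    m2[2, 3] <- m2[3, 2] <- 0.7      # ambiguous cross-cluster pair
    cl2 <- clusterIndividuals(m2)
    expect_equal(cl2$nIndividuals, 2)
    expect_equal(cl2$dropped, "c")   # tie on missingness: later id dropped
    ## the drop prefers the sample with more missing data
    cl3 <- clusterIndividuals(m2, nMissing = c(a = 0, b = 5, c = 0, d = 0))
    expect_equal(cl3$dropped, "b")

    ## clustering is invariant to sample order
    perm <- c(3, 1, 4, 2)
    cl4 <- clusterIndividuals(m2[perm, perm])
    expect_equal(cl4$nIndividuals, cl2$nIndividuals)
    expect_setequal(cl4$dropped, cl2$dropped)

    expect_error(clusterIndividuals(matrix(c(1, 0.2, 0.5, 1), 2)),
                 "symmetric")
    expect_warning(clusterIndividuals({
        mm <- diag(1, 3); dimnames(mm) <- list(c("x", "y", "z"),
                                               c("x", "y", "z"))
        mm[1, 2] <- mm[2, 1] <- 0.9
        mm[2, 3] <- mm[3, 2] <- 0.9
        mm[1, 3] <- mm[3, 1] <- 0.2   # transitivity conflict
        mm
    }), "merged")
})

test_that("probability of identity has its closed forms and orderings", {
    expect_equal(probabilityOfIdentity(0.5)$PID, 0.375)
    expect_equal(probabilityOfIdentity(0.5)$PIDsibs, 0.59375)
    ## fixed loci are uninformative
    expect_equal(probabilityOfIdentity(c(0, 1))$PID, 1)
    ## product rule
    expect_equal(probabilityOfIdentity(rep(0.5, 7))$PID, 0.375^7)
    ## PID <= PID-sibs locus-wise, and PID non-increasing in panel size
    p <- runif(50, 0.05, 0.95)
    pid <- probabilityOfIdentity(p)
    expect_true(all(pid$perLocusPID <= pid$perLocusPIDsibs + 1e-12))
    cum <- cumprod(pid$perLocusPID)
    expect_true(all(diff(cum) <= 1e-15))
    expect_error(probabilityOfIdentity(c(0.5, 1.4)), "locus 2")
})

test_that("the pipeline recovers the true number of individuals", {
    ## 12 individuals, 1-9 recaptures, realistic dropout/missingness
    runs <- 30
    ok <- vapply(seq_len(runs), function(s) {
        truth <- simulateHWEPopulation(12, runif(60, 0.2, 0.8),
                                       seed = 700 + s)
        rc <- simulateRecaptureSamples(truth,
                                       recaptures = c(1:9, 2, 3, 4),
                                       dropoutRate = 0.05,
                                       missingRate = 0.05, seed = 800 + s)
        rel <- estimateRelatedness(rc$samples)
        cl <- suppressWarnings(clusterIndividuals(rel, nMissing = colSums(
            is.na(genoMatrix(rc$samples)))))
        cl$nIndividuals == 12
    }, logical(1))
    expect_gte(sum(ok), ceiling(0.95 * runs))
})
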