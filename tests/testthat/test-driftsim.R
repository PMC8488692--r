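test_that("logistic map and founder frequencies follow their formulas", {
    expect_equal(logisticStep(10, 0.15, 104), 10 + 1.5 * (1 - 10 / 104))
    expect_equal(logisticStep(104, 0.15, 104), 104)   # fixed point at K
    expect_equal(logisticStep(2, 0.15, 104), 2 + 0.3 * (1 - 2 / 104))
    expect_equal(founderFrequency(driftParams(n0 = 2)), 0.25)
    expect_equal(founderFrequency(driftParams(n0 = 20)), 0.025)
    set.seed(81)
    p <- founderFrequency(driftParams(n0 = 5, founderMode = "sampled",
                                      pSource = 0), n = 20)
    expect_true(all(p == 0))
    expect_error(driftParams(founderMode = "sampled"), "pSource")
    expect_error(driftParams(n0 = 10, r = 0.15, K = 5), "K must be")
})

test_that("binomial resampling hits its boundary cases and moments", {
    set.seed(82)
    expect_true(all(nextGeneration(rep(0, 100), 20)$count == 0))
    expect_true(all(nextGeneration(rep(1, 100), 20)$count == 20))
    k <- nextGeneration(rep(0.5, 10000), 20)$count
    expect_lt(abs(mean(k) - 10), 3 * sqrt(20 * 0.25 / 10000))
})

test_that("absorbing states stay absorbed and seeds reproduce trajectories", {
    ## p0 = 0 stays at zero throughout
    ts0 <- simulateBottleneck(driftParams(n0 = 2, founderMode = "sampled",
                                          pSource = 0, reps = 20, seed = 83))
    expect_true(all(ts0@freq == 0))
    ## once a replicate hits 0 or 1 it never leaves
    ts <- simulateBottleneck(driftParams(n0 = 2, generations = 30,
                                         reps = 500, seed = 84))
    for (i in seq_len(nrow(ts@freq))) {
        f <- ts@freq[i, ]
        hit <- which(f %in% c(0, 1))[1]
        if (!is.na(hit)) expect_true(all(f[hit:length(f)] == f[hit]))
    }
    ## r = 0 with n0 = K reduces to a constant-size chain
    tsc <- simulateBottleneck(driftParams(n0 = 10, r = 0, K = 10,
                                          generations = 5, reps = 3,
                                          seed = 85))
    expect_true(all(tsc@size == 10))
    ## determinism
    p <- driftParams(n0 = 3, generations = 20, reps = 50, seed = 86)
    expect_identical(simulateBottleneck(p)@freq, simulateBottleneck(p)@freq)
    p2 <- driftParams(n0 = 10, copiesPerIndividual = 1, r = 0, K = 10,
                      reps = 100, p0 = 0.5, seed = 87)
    expect_identical(simulateToFixation(p2)@replicates,
                     simulateToFixation(p2)@replicates)
})

test_that("neutrality: fixation probability equals the founding frequency", {
    for (cfg in list(c(pool = 10, p0 = 0.5), c(pool = 20, p0 = 0.25))) {
        fs <- simulateToFixation(driftParams(
            n0 = cfg[["pool"]], copiesPerIndividual = 1, r = 0,
            K = cfg[["pool"]], reps = 2000, p0 = cfg[["p0"]],
            seed = 88 + cfg[["pool"]]))
        se <- sqrt(cfg[["p0"]] * (1 - cfg[["p0"]]) / 2000)
        expect_lt(abs(fixationProportion(fs, "mutant") - cfg[["p0"]]),
                  3 * se)
    }
    ## p0 = 1 absorbs immediately as mutant
    fs1 <- simulateToFixation(driftParams(n0 = 10, copiesPerIndividual = 1,
                                          r = 0, K = 10, reps = 10, p0 = 1,
                                          seed = 89))
    expect_true(all(fs1@replicates$generations == 0))
    expect_true(all(fs1@replicates$allele == "mutant"))
})

test_that("the Markov oracle is exact and the simulator matches it", {
    ## neutral martingale: P(fix) = p0 exactly
    for (n in c(4, 10, 24))
        expect_equal(markovOracle(n, 0.5)$fixMutant, 0.5, tolerance = 1e-10)
    expect_equal(markovOracle(20, 0.25)$fixMutant, 0.25, tolerance = 1e-10)
    ## two-copy chain from p0 = 0.5 absorbs with probability 1/2 per step
    expect_equal(markovOracle(2, 0.5)$expectedTime, 2, tolerance = 1e-10)
    ## independent fixed-point recursion agrees
    expect_equal(markovOracle(10, 0.5)$expectedTime,
                 iterativeAbsorptionTime(10, 0.5), tolerance = 1e-8)
    ## simulation within 3 SE of the exact mean for pools <= 30
    for (n in c(10, 30)) {
        fs <- simulateToFixation(driftParams(
            n0 = n, copiesPerIndividual = 1, r = 0, K = n, reps = 3000,
            p0 = 0.5, seed = 90 + n))
        tms <- fs@replicates$generations
        se <- sd(tms) / sqrt(length(tms))
        expect_lt(abs(mean(tms) - markovOracle(n, 0.5)$expectedTime), 3 * se)
    }
    expect_error(markovOracle(10, 0.47), "integer copy count")
})

test_that("migration drives the mutant to loss and speeds absorption", {
    fs <- simulateToFixation(driftParams(n0 = 10, copiesPerIndividual = 1,
                                         r = 0, K = 10, reps = 1000,
                                         p0 = 0.5, migrantCopies = 2,
                                         seed = 91))
    expect_true(all(fs@replicates$allele == "wild"))
    ## matches the exact migration-adjusted chain
    tms <- fs@replicates$generations
    se <- sd(tms) / sqrt(length(tms))
    expect_lt(abs(mean(tms) - markovOracle(10, 0.5, 2)$expectedTime), 3 * se)
    expect_error(simulateToFixation(driftParams(
        n0 = 2, copiesPerIndividual = 1, r = 0, K = 2, p0 = 0.5,
        migrantCopies = 5)), "exceeds")
})

test_that("drift probability is non-increasing in bottleneck size", {
    set.seed(92)
    n0s <- c(2, 4, 8, 16)
    probs <- vapply(n0s, function(n0) {
        ts <- simulateBottleneck(driftParams(n0 = n0, generations = 30,
                                             reps = 4000))
        mean(finalFrequencies(ts) >= 0.5)
    }, numeric(1))
    se <- sqrt(pmax(probs * (1 - probs), 1e-4) / 4000)
    for (i in seq_len(length(n0s) - 1))
        expect_lte(probs[i + 1], probs[i] + 2 * (se[i] + se[i + 1]))
})

test_that("probability grids are well-formed and threshold-consistent", {
    grid <- probabilityGrid(c(2, 6), c(5, 15), driftParams(reps = 200,
                                                           seed = 93))
    expect_s4_class(grid, "ProbabilityGrid")
    expect_true(all(grid@prob >= 0 & grid@prob <= 1))
    df <- as.data.frame(grid)
    expect_equal(nrow(df), 4)
    ## threshold 0 is always reached
    g0 <- probabilityGrid(2, 10, driftParams(reps = 100, seed = 94),
                          threshold = 0)
    expect_equal(unname(g0@prob[1, 1]), 1)
    expect_error(probabilityGrid(numeric(), 5), "non-empty")
})
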