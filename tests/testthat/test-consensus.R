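toyCalls <- function(sample, calls, reps = character()) {
    rbind(
        data.frame(sample_id = sample, method = names(calls),
                   call = unname(calls), replicate = 0L),
        if (length(reps))
            data.frame(sample_id = sample, method = "aspcr", call = reps,
                       replicate = seq_along(reps)))
}

test_that("genotype call parsing normalizes and rejects garbage", {
    expect_equal(parseGenotypeCall(c("+/+", "M/+", "+/M", "X/X", "", NA)),
                 c("+/+", "+/m", "+/m", "x/x", "x/x", "x/x"))
    expect_error(parseGenotypeCall("A/T", sample = "S1", method = "ngs"),
                 "S1.*ngs")
})

test_that("sample consensus follows the agreement and multiple-tube rules", {
    ## unanimous three-method call
    r <- sampleConsensus(toyCalls("STRF18-19", c(sanger = "+/m", ngs = "+/m",
                                                 aspcr = "+/m")))
    expect_equal(r$consensus, "+/m")
    expect_equal(r$support, 3L)
    expect_false(r$flagged_conflict)
    ## all missing
    r <- sampleConsensus(toyCalls("S0", c(sanger = "x/x", ngs = "x/x",
                                          aspcr = "x/x")))
    expect_equal(r$consensus, "x/x")
    ## method conflict resolved by unanimous AS-PCR triplicate
    r <- sampleConsensus(toyCalls("STRF18-81", c(sanger = "+/+",
                                                 aspcr = "+/m"),
                                  reps = c("+/m", "+/m", "+/m")))
    expect_equal(r$consensus, "+/m")
    expect_true(r$flagged_conflict)
    ## conflict without a unanimous triplicate stays missing
    r <- sampleConsensus(toyCalls("S1", c(sanger = "+/+", aspcr = "+/m"),
                                  reps = c("+/m", "+/m", "m/m")))
    expect_equal(r$consensus, "x/x")
    expect_true(r$flagged_conflict)
    r <- sampleConsensus(toyCalls("S2", c(sanger = "+/+", aspcr = "+/m")))
    expect_equal(r$consensus, "x/x")
    ## consensus is invariant to method order
    calls <- toyCalls("S3", c(sanger = "+/+", ngs = "+/+", aspcr = "m/m"),
                      reps = c("m/m", "m/m", "m/m"))
    perm <- calls[c(4, 2, 6, 1, 5, 3), ]
    expect_equal(sampleConsensus(calls)$consensus,
                 sampleConsensus(perm)$consensus)
})

test_that("individual genotypes are the recapture mode, ties conservative", {
    cons <- data.frame(
        individual = c("INDV-6", "INDV-6", "INDV-6", "INDV-6"),
        consensus = c("m/m", "+/m", "+/m", "+/m"))
    expect_equal(individualGenotype(cons)$genotype, "+/m")
    cons <- data.frame(individual = "INDV-4",
                       consensus = rep("m/m", 7))
    expect_equal(individualGenotype(cons)$genotype, "m/m")
    ## missing ignored; single informative record passes through
    cons <- data.frame(individual = "A", consensus = c("+/+", "x/x"))
    expect_equal(individualGenotype(cons)$genotype, "+/+")
    ## a tie is reported missing with a conflict flag
    cons <- data.frame(individual = "B", consensus = c("+/+", "m/m"))
    r <- individualGenotype(cons)
    expect_equal(r$genotype, "x/x")
    expect_true(r$conflict)
    expect_error(individualGenotype(cons[0, ]), "empty")
})

test_that("allele frequency bookkeeping conserves allele counts", {
    af <- alleleFrequency(rep(c("+/+", "+/m", "m/m"), c(2, 6, 4)))
    expect_equal(af$frequency, 14 / 24)
    expect_equal(unname(af$counts), c(2, 6, 4))
    expect_equal(alleleFrequency(rep("+/+", 5))$frequency, 0)
    expect_equal(alleleFrequency(rep("m/m", 5))$frequency, 1)
    expect_error(alleleFrequency(c("x/x", "x/x")), "missing")
    ## conservation: alt + ref copies = 2n
    g <- sample(c("+/+", "+/m", "m/m"), 50, replace = TRUE)
    af <- alleleFrequency(g)
    alt <- af$counts[["het"]] + 2 * af$counts[["hom_alt"]]
    ref <- af$counts[["het"]] + 2 * af$counts[["hom_ref"]]
    expect_equal(alt + ref, 2 * af$n)
})

test_that("census HWE prediction is sqrt of the phenotype fraction", {
    expect_equal(hwePredictedFrequency(3, 8), sqrt(0.375))
    expect_equal(round(hwePredictedFrequency(3, 8), 1), 0.6)
    expect_equal(hwePredictedFrequency(0, 8), 0)
    expect_equal(hwePredictedFrequency(8, 8), 1)
    expect_error(hwePredictedFrequency(1, 0), "positive")
})

test_that("consensus equals truth without noise and beats single methods with it", {
    truth <- simulateHWEPopulation(400, 0.5, seed = 41)
    tv <- c("+/+", "+/m", "m/m")[genoMatrix(truth)[1, ] + 1L]
    names(tv) <- colnames(truth)
    clean <- simulateNoninvasiveCalls(truth, dropoutRate = 0,
                                      failureRates = c(sanger = 0, ngs = 0,
                                                       aspcr = 0), seed = 42)
    cons <- sampleConsensus(clean)
    expect_true(all(cons$consensus == tv[cons$sample_id]))

    ## paired comparison over >= 1,000 simulated samples with dropout
    truth2 <- simulateHWEPopulation(1200, 0.5, seed = 43)
    tv2 <- c("+/+", "+/m", "m/m")[genoMatrix(truth2)[1, ] + 1L]
    names(tv2) <- colnames(truth2)
    noisy <- simulateNoninvasiveCalls(truth2, dropoutRate = 0.15, seed = 44)
    cons2 <- sampleConsensus(noisy)
    consErr <- mean(cons2$consensus != "x/x" &
                    cons2$consensus != tv2[cons2$sample_id])
    single <- noisy[noisy$method == "aspcr" & noisy$replicate == 0, ]
    singleErr <- mean(single$call != "x/x" &
                      single$call != tv2[single$sample_id])
    expect_lt(consErr, singleErr)
})

test_that("the packaged Similipal call table reproduces the printed genotypes", {
    calls <- similipalCalls()
    expect_equal(length(unique(calls$sample_id)), 37)
    cons <- sampleConsensus(calls)
    cons$individual <- calls$individual[match(cons$sample_id,
                                              calls$sample_id)]
    ## conflicted samples are resolved by the multiple-tube rule, not lost
    expect_equal(sort(cons$sample_id[cons$flagged_conflict]),
                 c("STRF18-09", "STRF18-81", "STRF18-94"))
    expect_equal(cons$consensus[cons$sample_id == "STRF18-81"], "+/m")
    expect_equal(cons$consensus[cons$sample_id == "STRF18-09"], "m/m")
    ind <- individualGenotype(cons)
    expect_equal(nrow(ind), 12)
    counts <- table(factor(ind$genotype, c("+/+", "+/m", "m/m")))
    expect_equal(unname(c(counts)), c(2, 6, 4))
    ## the single discordant recapture of INDV-6 is outvoted
    expect_equal(ind$genotype[ind$individual == "INDV-6"], "+/m")
})
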