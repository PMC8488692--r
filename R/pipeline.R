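## End-to-end orchestration: the packaged Similipal demo runs consensus
## genotyping on the printed call table, summarizes the allele frequency,
## tests HWE, and runs compact drift simulations.  Every output file starts
## with a provenance header (package version, seed, parameters).

.provenanceHeader <- function(seed, what, extra = "") {
    sprintf("# PseudoDrift %s | %s | seed=%s%s\n",
            as.character(utils::packageVersion("PseudoDrift")), what,
            ifelse(is.na(seed), "none", seed),
            if (nzchar(extra)) paste0(" | ", extra) else "")
}

.writeWithHeader <- function(df, path, seed, what, extra = "") {
    con <- file(path, "w")
    on.exit(close(con))
    cat(.provenanceHeader(seed, what, extra), file = con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the packaged Similipal demonstration pipeline
#'
#' Applies the consensus rules to the packaged per-sample call table,
#' aggregates recaptures into the 12 individual genotypes, computes the
#' mutant-allele frequency with its exact HWE test and the census-based
#' HWE prediction, and runs compact drift simulations (the headline
#' bottleneck cell and a constant-pool fixation run).  All outputs are
#' TSVs with provenance headers plus a summary list returned invisibly.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the stochastic stages.
#' @param reps replicates for the demonstration simulations (reduced by
#'   default to keep the demo quick).
#' @return invisibly, a list with \code{consensus}, \code{individuals},
#'   \code{alleleFrequency}, \code{hweP}, \code{censusPrediction},
#'   \code{bottleneckP}, \code{fixation}.
#' @export
runSimilipalDemo <- function(outDir, seed = 1, reps = 500) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    calls <- similipalCalls()
    if (!nrow(calls)) stop("empty call table")
    cons <- sampleConsensus(calls)
    cons$individual <- calls$individual[match(cons$sample_id,
                                              calls$sample_id)]
    ind <- individualGenotype(cons)
    af <- alleleFrequency(ind$genotype)
    hweP <- hweExactTest(af$counts[["hom_ref"]], af$counts[["het"]],
                         af$counts[["hom_alt"]])
    census <- hwePredictedFrequency(3, 8)

    .writeWithHeader(cons, file.path(outDir, "consensus.tsv"), NA,
                     "per-sample consensus genotypes")
    .writeWithHeader(ind, file.path(outDir, "individual_genotypes.tsv"), NA,
                     "per-individual genotypes")

    grid <- probabilityGrid(
        n0Range = 2, genRange = 44,
        params = driftParams(reps = reps, seed = seed))
    fix <- simulateToFixation(driftParams(
        n0 = 10, copiesPerIndividual = 1, r = 0, K = 10, reps = reps,
        p0 = 0.5, seed = seed + 1))
    .writeWithHeader(as.data.frame(grid),
                     file.path(outDir, "bottleneck_grid.tsv"), seed,
                     "P(p >= 0.5) bottleneck grid",
                     sprintf("reps=%d", reps))
    .writeWithHeader(fix@replicates,
                     file.path(outDir, "fixation_replicates.tsv"), seed + 1,
                     "constant-pool fixation replicates",
                     sprintf("reps=%d", reps))

    summary <- data.frame(
        quantity = c("n_hom_ref", "n_het", "n_hom_alt", "allele_frequency",
                     "hwe_exact_p", "census_hwe_prediction",
                     "bottleneck_P_ge_0.5", "mean_fixation_generations"),
        value = c(af$counts[["hom_ref"]], af$counts[["het"]],
                  af$counts[["hom_alt"]], round(af$frequency, 4), hweP,
                  round(census, 4), grid@prob[1, 1],
                  round(meanAbsorption(fix), 2)))
    .writeWithHeader(summary, file.path(outDir, "summary.tsv"), seed,
                     "demo summary")
    invisible(list(consensus = cons, individuals = ind,
                   alleleFrequency = af, hweP = hweP,
                   censusPrediction = census,
                   bottleneckP = grid@prob[1, 1], fixation = fix))
}
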