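#' @import methods
#' @importFrom stats rbinom runif dbinom pchisq setNames cor sd quantile dist
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GenotypeData: biallelic SNP genotypes with sample metadata
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding one assay named \code{"geno"}: an integer matrix of alternate
#' allele counts (0 = hom ref, 1 = het, 2 = hom alt, \code{NA} = missing)
#' with loci as rows and samples as columns.  Optional per-sample population
#' labels live in \code{colData()$population} and optional per-locus
#' reference alternate-allele frequencies in \code{rowData()$alleleFreq}.
#'
#' @slot .
#'   See \link[SummarizedExperiment]{SummarizedExperiment}; no extra slots.
#' @seealso \code{\link{GenotypeData}} (constructor),
#'   \code{\link{genoMatrix}}, \code{\link{populations}}
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
    if (!"geno" %in% SummarizedExperiment::assayNames(object))
        return("assay 'geno' is required")
    g <- SummarizedExperiment::assay(object, "geno")
    bad <- !(is.na(g) | g %in% c(0L, 1L, 2L))
    if (any(bad))
        return("genotype codes must be 0, 1, 2 or NA")
    if (anyDuplicated(rownames(object)))
        return("locus ids must be unique")
    TRUE
})

#' Filtering thresholds for the locus/sample filter cascade
#'
#' Defaults mirror the noninvasive-SNP filtering used for individual
#' identification: drop loci missing in more than 10\% of samples, samples
#' called at fewer than 50 loci, singleton loci (minor allele count 1),
#' monomorphic loci, and loci out of Hardy-Weinberg equilibrium at
#' \code{hweAlpha} in at least \code{hweMinPops} populations.
#'
#' @slot maxLocusMissing fraction of samples allowed missing per locus.
#' @slot minLociPerSample minimum called loci to keep a sample.
#' @slot minMAC minimum minor allele count (2 removes singletons).
#' @slot dropMonomorphic drop loci with no variation.
#' @slot hweAlpha significance level of the exact HWE test.
#' @slot hweMinPops number of populations failing HWE needed to drop a locus.
#' @export
setClass("FilterSpec", representation(
    maxLocusMissing = "numeric",
    minLociPerSample = "numeric",
    minMAC = "numeric",
    dropMonomorphic = "logical",
    hweAlpha = "numeric",
    hweMinPops = "numeric"))

setValidity("FilterSpec", function(object) {
    if (object@maxLocusMissing < 0 || object@maxLocusMissing > 1)
        return("maxLocusMissing must be in [0, 1]")
    if (object@hweAlpha <= 0 || object@hweAlpha > 1)
        return("hweAlpha must be in (0, 1]")
    if (object@minLociPerSample < 0 || object@minMAC < 0)
        return("counts must be non-negative")
    TRUE
})

#' Parameters of the forward drift simulations
#'
#' One parameter set drives both the bottleneck/recovery simulations and the
#' future time-to-fixation simulations.  The founding population has
#' \code{n0} individuals contributing \code{copiesPerIndividual} gene copies
#' each; population size then follows the logistic map
#' \code{n + r*n*(1 - n/K)} (kept real-valued; the sampled gene-copy pool is
#' rounded).  Each generation the new pool is drawn binomially from the
#' parental allele frequency.  \code{migrantCopies} wild-type copies join
#' the parental gamete pool each generation before sampling (genetic
#' rescue); with migration the mutant allele can only be lost.
#'
#' @slot n0 founding population size, individuals.
#' @slot copiesPerIndividual gene copies per individual in the pool (1 or 2).
#' @slot generations horizon of the bottleneck simulation.
#' @slot r logistic growth rate per generation (0.15 = 0.03/yr, 5-yr
#'   generations).
#' @slot K carrying capacity, individuals.
#' @slot reps replicate count.
#' @slot founderMode "forced_het" (one heterozygote among the founders,
#'   p0 = 1/(copies*n0)) or "sampled" (binomial draw at \code{pSource}).
#' @slot pSource source allele frequency for sampled founding.
#' @slot p0 starting frequency for fixation runs (default 0.5).
#' @slot threshold frequency cutoff for the probability grid.
#' @slot migrantCopies wild-type gene copies added per generation.
#' @slot maxGenerations cap guarding non-termination.
#' @slot seed integer seed or NA.
#' @export
setClass("DriftParams", representation(
    n0 = "numeric", copiesPerIndividual = "numeric", generations = "numeric",
    r = "numeric", K = "numeric", reps = "numeric", founderMode = "character",
    pSource = "numeric", p0 = "numeric", threshold = "numeric",
    migrantCopies = "numeric", maxGenerations = "numeric", seed = "numeric"))

setValidity("DriftParams", function(object) {
    if (object@n0 < 1) return("n0 must be >= 1")
    if (!object@copiesPerIndividual %in% c(1, 2))
        return("copiesPerIndividual must be 1 or 2")
    if (object@r < 0) return("r must be >= 0")
    if (object@r > 0 && object@K < object@n0)
        return("K must be >= n0 when growth is enabled (or set r = 0)")
    if (!object@founderMode %in% c("forced_het", "sampled"))
        return("founderMode must be 'forced_het' or 'sampled'")
    if (object@founderMode == "sampled" &&
        (is.na(object@pSource) || object@pSource < 0 || object@pSource > 1))
        return("sampled founding requires pSource in [0, 1]")
    if (!is.na(object@p0) && (object@p0 < 0 || object@p0 > 1))
        return("p0 must be in [0, 1]")
    if (object@migrantCopies < 0)
        return("migrantCopies must be >= 0")
    if (object@reps < 1) return("reps must be >= 1")
    TRUE
})

#' A set of simulated drift trajectories
#'
#' @slot size deterministic population-size trajectory (individuals,
#'   real-valued), length generations + 1.
#' @slot freq replicate-by-generation matrix of mutant-allele frequencies
#'   (reps rows, generations + 1 columns; column 1 is the founding
#'   frequency).
#' @slot params the \linkS4class{DriftParams} used.
#' @export
setClass("TrajectorySet", representation(
    size = "numeric", freq = "matrix", params = "DriftParams"))

#' Probability grid P(p >= threshold) over bottleneck size x generations
#'
#' @slot prob matrix of cell probabilities, bottleneck sizes as rows.
#' @slot n0 bottleneck sizes (row axis).
#' @slot generations drift times (column axis).
#' @slot reps replicates per cell.
#' @slot threshold the frequency cutoff.
#' @export
setClass("ProbabilityGrid", representation(
    prob = "matrix", n0 = "numeric", generations = "numeric",
    reps = "numeric", threshold = "numeric"))

setValidity("ProbabilityGrid", function(object) {
    if (any(object@prob < 0 | object@prob > 1, na.rm = TRUE))
        return("cell probabilities must be in [0, 1]")
    TRUE
})

#' Per-replicate absorption results of a fixation simulation
#'
#' @slot replicates data.frame with one row per replicate: \code{generations}
#'   (absorption generation) and \code{allele} ("mutant", "wild", or
#'   "capped" for replicates stopped at the generation cap).
#' @slot params the \linkS4class{DriftParams} used.
#' @export
setClass("FixationSummary", representation(
    replicates = "data.frame", params = "DriftParams"))

#' Mantel test result
#'
#' @slot statistic Mantel r (Pearson correlation of lower-triangle
#'   distances).
#' @slot p permutation p-value, never below 1/(permutations + 1).
#' @slot permutations number of permutations.
#' @slot classes per-distance-class correlogram results (or a 0-row
#'   data.frame for a plain Mantel test).
#' @export
setClass("MantelResult", representation(
    statistic = "numeric", p = "numeric", permutations = "numeric",
    classes = "data.frame"))

setValidity("MantelResult", function(object) {
    if (!is.na(object@p) && object@p < 1 / (object@permutations + 1) - 1e-12)
        return("p-value below 1/(permutations + 1) is impossible")
    TRUE
})
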