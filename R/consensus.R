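## Consensus genotyping at a single diagnostic site from up to three
## independent calling methods (Sanger, NGS panel, allele-specific PCR)
## plus AS-PCR replicates under the multiple-tube rule, and aggregation of
## recaptures into per-individual genotypes.

.GENO_LEVELS <- c("+/+", "+/m", "m/m", "x/x")

#' Parse and normalize a genotype call string
#'
#' Accepted states: "+/+" (wild-type homozygote), "+/m" (heterozygote,
#' "m/+" normalizes to it), "m/m" (mutant homozygote), "x/x" or "" or NA
#' (missing).  Parsing is case-insensitive.
#'
#' @param x character vector of calls.
#' @param sample,method context used in the error message for an
#'   unrecognized string.
#' @return character vector over \{"+/+", "+/m", "m/m", "x/x"\}.
#' @export
parseGenotypeCall <- function(x, sample = NULL, method = NULL) {
    y <- tolower(trimws(as.character(x)))
    y[is.na(y) | y == ""] <- "x/x"
    y[y == "m/+"] <- "+/m"
    bad <- !(y %in% .GENO_LEVELS)
    if (any(bad)) {
        ctx <- paste0(
            if (!is.null(sample)) paste0(" for sample ", sample[bad][1]),
            if (!is.null(method)) paste0(", method ", method[bad][1]))
        stop("unknown genotype string '", x[bad][1], "'", ctx)
    }
    y
}

#' Read a long-format call table
#'
#' @param path TSV with columns sample_id, method, call, replicate and
#'   optionally individual (known recapture grouping).
#' @return validated data.frame with normalized calls.
#' @export
readCallTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "method", "call", "replicate")
    stopifnot(all(need %in% colnames(df)))
    df$call <- parseGenotypeCall(df$call, df$sample_id, df$method)
    df
}

#' The packaged per-sample call table for the Similipal survey
#'
#' The printed three-method genotype calls for the 33 noninvasive samples
#' resolved to 12 individuals, in long format.  For the three samples whose
#' methods disagreed and were re-run under the multiple-tube rule, the
#' table encodes three unanimous AS-PCR replicate calls (replicate 1..3)
#' matching the accepted consensus; primary calls carry replicate 0.
#'
#' @return data.frame: sample_id, individual, method, call, replicate.
#' @examples
#' calls <- similipalCalls()
#' table(calls$method)
#' @export
similipalCalls <- function() {
    path <- system.file("extdata", "similipal_taqpep_calls.tsv",
                        package = "PseudoDrift", mustWork = TRUE)
    readCallTable(path)
}

.consensusOne <- function(calls, replicates) {
    calls <- calls[calls != "x/x"]
    if (!length(calls))
        return(list(consensus = "x/x", support = 0L, flagged = FALSE))
    u <- unique(calls)
    if (length(u) == 1L)
        return(list(consensus = u, support = length(calls), flagged = FALSE))
    ## methods disagree: multiple-tube rule on AS-PCR replicates
    reps <- replicates[replicates != "x/x"]
    if (length(replicates) == 3L && length(reps) == 3L &&
        length(unique(reps)) == 1L)
        return(list(consensus = reps[1], support = 3L, flagged = TRUE))
    list(consensus = "x/x", support = 0L, flagged = TRUE)
}

#' Per-sample consensus genotype across calling methods
#'
#' If all non-missing method calls agree, that genotype is the consensus
#' with support equal to the number of agreeing methods.  If methods
#' disagree, the AS-PCR replicate calls are consulted (multiple-tube rule):
#' the genotype is accepted, and flagged, only when exactly three
#' replicates are present and unanimous; otherwise the sample is flagged
#' missing.  Majority voting across methods is deliberately not used.
#'
#' @param calls long-format call table (sample_id, method, call, replicate;
#'   replicate 0 marks primary method calls, larger values AS-PCR
#'   replicates).
#' @return data.frame: sample_id, consensus, support, flagged_conflict.
#'   Row order follows first appearance in \code{calls}; the result is
#'   invariant to the order of methods within a sample.
#' @export
sampleConsensus <- function(calls) {
    stopifnot(all(c("sample_id", "method", "call", "replicate") %in%
                  colnames(calls)))
    calls$call <- parseGenotypeCall(calls$call, calls$sample_id, calls$method)
    ids <- unique(calls$sample_id)
    out <- lapply(ids, function(s) {
        cs <- calls[calls$sample_id == s, ]
        prim <- cs$call[cs$replicate == 0]
        if (!length(prim))
            stop("sample ", s, ": no primary method call attempted")
        reps <- cs$call[cs$method == "aspcr" & cs$replicate > 0]
        r <- .consensusOne(prim, reps)
        data.frame(sample_id = s, consensus = r$consensus,
                   support = r$support, flagged_conflict = r$flagged)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Final per-individual genotype from recapture consensus records
#'
#' The modal non-missing consensus genotype across an individual's
#' recaptures; ties yield missing with a conflict flag; a single record
#' passes through.
#'
#' @param consensus data.frame from \code{\link{sampleConsensus}} with an
#'   added \code{individual} column (recapture grouping from the
#'   identification step or from known truth).
#' @return data.frame: individual, genotype, n_samples, conflict.
#' @export
individualGenotype <- function(consensus) {
    stopifnot(all(c("individual", "consensus") %in% colnames(consensus)))
    if (!nrow(consensus)) stop("empty consensus table")
    out <- lapply(split(consensus, consensus$individual), function(d) {
        calls <- d$consensus[d$consensus != "x/x"]
        if (!length(calls)) {
            g <- "x/x"; conflict <- FALSE
        } else {
            tab <- sort(table(calls), decreasing = TRUE)
            tie <- length(tab) > 1 && tab[1] == tab[2]
            g <- if (tie) "x/x" else names(tab)[1]
            conflict <- tie
        }
        data.frame(individual = d$individual[1], genotype = g,
                   n_samples = nrow(d), conflict = conflict)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$individual), , drop = FALSE]
}

#' Allele frequency and genotype counts from genotype call strings
#'
#' frequency = (het + 2 hom-alt) / (2 n-called); missing calls are
#' excluded.
#'
#' @param genotypes character vector of "+/+", "+/m", "m/m", "x/x".
#' @return list: \code{frequency}, \code{counts} (named hom_ref/het/
#'   hom_alt), \code{n} called genotypes.
#' @examples
#' alleleFrequency(rep(c("+/+", "+/m", "m/m"), c(2, 6, 4)))$frequency
#' @export
alleleFrequency <- function(genotypes) {
    g <- parseGenotypeCall(genotypes)
    g <- g[g != "x/x"]
    if (!length(g)) stop("all genotypes missing")
    counts <- c(hom_ref = sum(g == "+/+"), het = sum(g == "+/m"),
                hom_alt = sum(g == "m/m"))
    n <- length(g)
    list(frequency = (counts[["het"]] + 2 * counts[["hom_alt"]]) / (2 * n),
         counts = counts, n = n)
}

#' Allele frequency predicted from phenotype census counts under HWE
#'
#' For a recessive trait, the phenotype frequency among census individuals
#' estimates q^2, so q = sqrt(nRecessive / nTotal).
#'
#' @param nRecessive individuals showing the recessive phenotype.
#' @param nTotal individuals censused.
#' @return the predicted allele frequency.
#' @examples
#' hwePredictedFrequency(3, 8)   # ~0.61
#' @export
hwePredictedFrequency <- function(nRecessive, nTotal) {
    if (nTotal <= 0) stop("nTotal must be positive")
    if (nRecessive < 0 || nRecessive > nTotal)
        stop("nRecessive must be between 0 and nTotal")
    sqrt(nRecessive / nTotal)
}
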