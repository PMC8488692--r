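#' Construct a GenotypeData object
#'
#' @param geno integer matrix of alternate-allele counts (0/1/2/NA), loci as
#'   rows and samples as columns.  A samples-by-loci matrix is accepted when
#'   dimnames make the orientation unambiguous; pass loci-by-samples to be
#'   safe.
#' @param population optional character vector of population labels, one per
#'   sample.
#' @param alleleFreqs optional per-locus reference alternate-allele
#'   frequency (e.g. the generating truth, or frequencies from an external
#'   reference panel).
#' @return a \linkS4class{GenotypeData}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'             dimnames = list(c("L1", "L2"), c("S1", "S2")))
#' gd <- GenotypeData(g, population = c("A", "A"))
#' genoMatrix(gd)
#' @export
GenotypeData <- function(geno, population = NULL, alleleFreqs = NULL) {
    geno <- as.matrix(geno)
    storage.mode(geno) <- "integer"
    if (is.null(rownames(geno)))
        rownames(geno) <- sprintf("L%03d", seq_len(nrow(geno)))
    if (is.null(colnames(geno)))
        colnames(geno) <- sprintf("S%03d", seq_len(ncol(geno)))
    cd <- S4Vectors::DataFrame(row.names = colnames(geno))
    if (!is.null(population)) {
        stopifnot(length(population) == ncol(geno))
        cd$population <- as.character(population)
    }
    rd <- S4Vectors::DataFrame(row.names = rownames(geno))
    if (!is.null(alleleFreqs)) {
        stopifnot(length(alleleFreqs) == nrow(geno))
        rd$alleleFreq <- as.numeric(alleleFreqs)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(geno = geno), colData = cd, rowData = rd)
    methods::new("GenotypeData", se)
}

#' @rdname genoMatrix
#' @export
setGeneric("genoMatrix", function(x, samplesAsRows = FALSE)
    standardGeneric("genoMatrix"))

#' Extract the genotype matrix
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param samplesAsRows return samples as rows (the orientation most
#'   pairwise statistics use internally).
#' @return integer matrix of 0/1/2/NA codes.
#' @export
setMethod("genoMatrix", "GenotypeData", function(x, samplesAsRows = FALSE) {
    g <- SummarizedExperiment::assay(x, "geno")
    if (samplesAsRows) t(g) else g
})

#' @rdname populations
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Per-sample population labels
#'
#' @param x a \linkS4class{GenotypeData}.
#' @return character vector of labels, or NULL when unset.
#' @export
setMethod("populations", "GenotypeData", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("population" %in% colnames(cd)) as.character(cd$population) else NULL
})

#' @rdname refAlleleFreqs
#' @export
setGeneric("refAlleleFreqs", function(x) standardGeneric("refAlleleFreqs"))

#' Per-locus reference alternate-allele frequencies stored with the object
#'
#' @param x a \linkS4class{GenotypeData}.
#' @return numeric vector named by locus, or NULL when unset.
#' @export
setMethod("refAlleleFreqs", "GenotypeData", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"alleleFreq" %in% colnames(rd)) return(NULL)
    stats::setNames(as.numeric(rd$alleleFreq), rownames(x))
})

#' Observed alternate-allele frequency per locus
#'
#' Computed from called genotypes only: (het + 2 hom-alt) / (2 n-called).
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param byPopulation split by \code{populations(x)} and return a
#'   loci-by-population matrix.
#' @return numeric vector (or matrix) of frequencies; NaN where a locus has
#'   no calls.
#' @export
observedAlleleFreqs <- function(x, byPopulation = FALSE) {
    g <- genoMatrix(x)
    if (!byPopulation)
        return(rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g))))
    pops <- populations(x)
    if (is.null(pops))
        stop("byPopulation = TRUE requires population labels")
    vapply(unique(pops), function(p) {
        gp <- g[, pops == p, drop = FALSE]
        rowSums(gp, na.rm = TRUE) / (2 * rowSums(!is.na(gp)))
    }, numeric(nrow(g)))
}

#' @export
setMethod("show", "GenotypeData", function(object) {
    g <- genoMatrix(object)
    miss <- mean(is.na(g))
    cat("GenotypeData:", nrow(g), "loci x", ncol(g), "samples;",
        sprintf("%.1f%% missing", 100 * miss), "\n")
    pops <- populations(object)
    if (!is.null(pops)) {
        tab <- table(pops)
        cat("populations:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    }
})

#' Write genotypes as TSV (samples as rows, loci as columns, codes 0/1/2/NA)
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTSV <- function(x, path) {
    g <- genoMatrix(x, samplesAsRows = TRUE)
    df <- data.frame(sample_id = rownames(g), g, check.names = FALSE)
    pops <- populations(x)
    if (!is.null(pops)) df <- cbind(df[1], population = pops, df[-1])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read genotypes from TSV written by \code{writeGenotypeTSV}
#'
#' @param path TSV with a \code{sample_id} column, an optional
#'   \code{population} column, and one 0/1/2/NA column per locus.
#' @return a \linkS4class{GenotypeData}.
#' @export
readGenotypeTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    stopifnot("sample_id" %in% colnames(df))
    pops <- if ("population" %in% colnames(df)) df$population else NULL
    loci <- setdiff(colnames(df), c("sample_id", "population"))
    g <- t(as.matrix(df[, loci, drop = FALSE]))
    colnames(g) <- df$sample_id
    GenotypeData(g, population = pops)
}

#' Minimal VCF import (GT field of biallelic records)
#'
#' Reads genotypes from a VCF using \pkg{vcfR}.  Only the GT field is used;
#' multiallelic records are dropped with a message; "./." and partial calls
#' become NA.
#'
#' @param path a VCF file (plain text or gzipped).
#' @return a \linkS4class{GenotypeData} (loci named CHROM:POS).
#' @export
readVCFGenotypes <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("readVCFGenotypes requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
    if (any(multi)) {
        message("dropping ", sum(multi), " non-biallelic record(s)")
        v <- v[!multi, ]
        fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- function(x) {
        x <- gsub("\\|", "/", x)
        out <- rep(NA_integer_, length(x))
        out[x %in% "0/0"] <- 0L
        out[x %in% c("0/1", "1/0")] <- 1L
        out[x %in% "1/1"] <- 2L
        out
    }
    g <- apply(gt, 2, code)
    if (is.null(dim(g))) g <- matrix(g, ncol = ncol(gt))
    rownames(g) <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
    colnames(g) <- colnames(gt)
    GenotypeData(g)
}
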