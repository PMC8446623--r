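# accessors, subsetting and show methods

#' @describeIn GeneCandidates number of candidates
#' @param x a GeneCandidates object.
#' @export
setMethod("length", "GeneCandidates", function(x) length(x@ranges))

#' @describeIn GeneCandidates subset candidates
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GeneCandidates", function(x, i, j, ..., drop = TRUE) {
  new("GeneCandidates", ranges = x@ranges[i],
      cds = x@cds[i], protein = x@protein[i])
})

#' Candidate genomic intervals
#' @param x a \code{\linkS4class{GeneCandidates}}.
#' @return GRanges (1-based) with metadata columns.
#' @export
candidateRanges <- function(x) x@ranges

#' Candidate CDS sequences (forward-coding orientation)
#' @param x a \code{\linkS4class{GeneCandidates}}.
#' @return DNAStringSet.
#' @export
candidateCDS <- function(x) x@cds

#' Candidate protein translations
#' @param x a \code{\linkS4class{GeneCandidates}}.
#' @return AAStringSet (terminal stop stripped).
#' @export
candidateProteins <- function(x) x@protein

#' Candidate ids
#' @param x a \code{\linkS4class{GeneCandidates}}.
#' @return character vector of gene ids.
#' @export
candidateIds <- function(x) S4Vectors::mcols(x@ranges)$gene_id

setMethod("show", "GeneCandidates", function(object) {
  n <- length(object@ranges)
  cat(sprintf("GeneCandidates with %d candidate(s)\n", n))
  if (n) {
    mc <- S4Vectors::mcols(object@ranges)
    intact <- sum(mc$starts_with_met & !mc$has_internal_stop &
                    mc$has_terminal_stop & !mc$frameshifted, na.rm = TRUE)
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(as.character(GenomicRanges::seqnames(object@ranges))),
                      collapse = ", ")))
    cat(sprintf("  intact ORFs: %d / %d\n", intact, n))
  }
  invisible(object)
})

#' @export
#' @method as.data.frame GeneCandidates
as.data.frame.GeneCandidates <- function(x, row.names = NULL, optional = FALSE, ...) {
  gr <- x@ranges
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,     # 0-based half-open export
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  df <- cbind(df, mc)
  df$cds <- as.character(x@cds)
  df$protein <- as.character(x@protein)
  rownames(df) <- NULL
  df
}
setMethod("as.data.frame", "GeneCandidates",
          function(x, ...) as.data.frame.GeneCandidates(x, ...))

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d sequence(s), %d codon site(s)\n",
              length(object),
              if (length(object)) Biostrings::width(object)[1L] %/% 3L else 0L))
  invisible(object)
})

setMethod("show", "SiteModelFit", function(object) {
  cat(sprintf("SiteModelFit [%s]  logLik = %.4f\n", object@model, object@logLik))
  cat("  ", paste(sprintf("%s=%.4g", names(object@params), object@params),
                  collapse = "  "), "\n", sep = "")
  if (!isTRUE(object@diagnostics$converged))
    cat("  WARNING: optimization did not converge in any start\n")
  invisible(object)
})

#' Log-likelihood of a fitted site model
#' @param object a \code{\linkS4class{SiteModelFit}}.
#' @param ... ignored.
#' @export
setMethod("logLik", "SiteModelFit", function(object, ...) object@logLik)

#' Parameter estimates of a fitted site model
#' @param x a \code{\linkS4class{SiteModelFit}}.
#' @return named numeric vector.
#' @export
modelParams <- function(x) x@params

setMethod("show", "EpitopeProfile", function(object) {
  cc <- object@counts
  cat(sprintf("EpitopeProfile: %d accession(s), %d locus(i), %d epitope(s); %d occurrence(s)\n",
              length(unique(cc$accession)), length(unique(cc$locus)),
              length(unique(cc$epitope)), sum(cc$occurrences)))
  invisible(object)
})

#' Profile counts as long data.frame
#' @param x an \code{\linkS4class{EpitopeProfile}}.
#' @export
profileCountsTable <- function(x) x@counts
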