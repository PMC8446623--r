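# Copy-number validation from long-read depth: copies whose mean coverage
# clearly deviates from the genome-wide median gene coverage are flagged as
# collapsed paralogs (~2x) or haplotype-specific assemblies of heterozygous
# alleles (~0.5x). Default thresholds 1.5x and 0.6x sit between the
# expectations with a noise margin.

#' Mean read depth per gene
#'
#' Accepts either a per-gene table (columns \code{gene_id},
#' \code{mean_depth}) which is validated and passed through, or a per-base
#' table (columns \code{chrom}, \code{pos} 0-based, \code{depth}) plus gene
#' intervals, in which case the mean per-base depth over each interval is
#' computed; bases absent from the table count as depth 0 with a warning.
#'
#' @param depth data.frame as above.
#' @param intervals data.frame(chrom, start, end, gene_id) with 0-based
#'   half-open coordinates (required for per-base input).
#' @return data.frame(gene_id, mean_depth).
#' @export
summarizeGeneCoverage <- function(depth, intervals = NULL) {
  if (all(c("gene_id", "mean_depth") %in% names(depth)))
    return(depth[, c("gene_id", "mean_depth")])
  if (!all(c("chrom", "pos", "depth") %in% names(depth)))
    stop("depth must have columns (gene_id, mean_depth) or (chrom, pos, depth)")
  if (is.null(intervals)) stop("per-base depth needs gene intervals")
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    if (iv$end <= iv$start) stop("empty interval for gene ", iv$gene_id)
    want <- seq(iv$start, iv$end - 1L)
    sel <- depth$chrom == iv$chrom & depth$pos %in% want
    d <- depth$depth[sel]
    if (length(d) < length(want)) {
      warning(sprintf("gene %s: %d base(s) missing from depth table, counted as 0",
                      iv$gene_id, length(want) - length(d)))
    }
    data.frame(gene_id = iv$gene_id,
               mean_depth = sum(d) / length(want),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify copy status from depth ratios
#'
#' Ratio = mean depth / median genome-wide gene coverage. Copies at or above
#' \code{highRatio} are collapsed paralogs, at or below \code{lowRatio}
#' haplotype-specific, otherwise normal. The summary attribute reports the
#' count and fraction of deviating copies.
#'
#' @param records data.frame(gene_id, mean_depth).
#' @param medianCov genome-wide median gene coverage (> 0); 32.23 genome
#'   equivalents is the published CDC Landmark ONT value.
#' @param highRatio,lowRatio thresholds with 0 < lowRatio < 1 < highRatio.
#' @return records with \code{ratio} and \code{status} columns;
#'   \code{attr(, "summary")} holds n, n_deviating, fraction_deviating.
#' @export
classifyCopyStatus <- function(records, medianCov = 32.23,
                               highRatio = 1.5, lowRatio = 0.6) {
  stopifnot(medianCov > 0, lowRatio > 0, lowRatio < 1, highRatio > 1)
  ratio <- records$mean_depth / medianCov
  status <- ifelse(ratio >= highRatio, "collapsed",
                   ifelse(ratio <= lowRatio, "haplotype_specific", "normal"))
  records$ratio <- ratio
  records$status <- status
  nDev <- sum(status != "normal")
  attr(records, "summary") <- list(
    n = nrow(records), n_deviating = nDev,
    fraction_deviating = if (nrow(records)) nDev / nrow(records) else 0)
  records
}
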