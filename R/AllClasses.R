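#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString AAString
NULL

#' Simulation configuration for synthetic gliadin-array assemblies
#'
#' Describes a synthetic "accession": chromosome lengths, sublocus anchor
#' positions carrying tandem arrays of gliadin-like single-exon genes, the
#' per-copy substitution process, pseudogenization, epitope planting, and
#' copy-status flags used by the depth simulator. All stochastic behaviour is
#' driven by the mandatory \code{seed}.
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot loci data.frame with columns \code{chrom}, \code{anchor} (bp, 1-based
#'   start of the first copy), \code{copies}, \code{spacing} (bp between
#'   consecutive copies).
#' @slot template character, the base gene CDS (starts with ATG, length a
#'   multiple of 3, ends with a stop codon).
#' @slot subRate numeric, per-site substitution probability applied
#'   independently to every planted copy.
#' @slot pseudoProb numeric, probability a planted copy is pseudogenized by
#'   exactly one of: lost start codon, internal premature stop, or a 1--2 bp
#'   indel.
#' @slot minusStrandProb numeric, probability a copy is planted on the minus
#'   strand.
#' @slot collapsedGenes integer indices (in planting order) of copies flagged
#'   as collapsed paralogs (2x expected read depth).
#' @slot haplotypeGenes integer indices of copies flagged haplotype-specific
#'   (0.5x expected depth).
#' @slot epitopes data.frame with columns \code{gene} (planting-order index),
#'   \code{name}, \code{peptide}, \code{offsetAA} (0-based protein offset).
#' @slot seed integer random seed (mandatory).
#' @export
setClass("SimConfig", slots = c(
  chromLengths = "numeric",
  loci = "data.frame",
  template = "character",
  subRate = "numeric",
  pseudoProb = "numeric",
  minusStrandProb = "numeric",
  collapsedGenes = "integer",
  haplotypeGenes = "integer",
  epitopes = "data.frame",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  for (p in c("subRate", "pseudoProb", "minusStrandProb")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a probability in [0,1]", p))
  }
  tpl <- object@template
  if (nchar(tpl) %% 3L != 0L)
    msg <- c(msg, "template length must be a multiple of 3")
  if (substr(tpl, 1L, 3L) != "ATG")
    msg <- c(msg, "template must start with ATG")
  if (is.null(names(object@chromLengths)) || any(!nzchar(names(object@chromLengths))))
    msg <- c(msg, "chromLengths must be named by chromosome")
  loci <- object@loci
  need <- c("chrom", "anchor", "copies", "spacing")
  if (!all(need %in% names(loci))) {
    msg <- c(msg, "loci must have columns chrom, anchor, copies, spacing")
  } else if (nrow(loci)) {
    bad <- !(loci$chrom %in% names(object@chromLengths))
    if (any(bad)) msg <- c(msg, "loci reference unknown chromosomes")
    inside <- loci$anchor > 0 & loci$anchor < object@chromLengths[loci$chrom]
    if (any(!inside[!bad]))
      msg <- c(msg, "sublocus anchors must lie strictly inside their chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Discovered gliadin gene candidates
#'
#' Candidate gene copies found by \code{\link{findCandidates}}: genomic
#' intervals (1-based \code{GRanges}; BED export is 0-based half-open), the
#' forward-coding CDS, its translation, and per-candidate ORF/divergence
#' flags stored in the range metadata columns (\code{gene_id},
#' \code{query_id}, \code{identity}, \code{score}, \code{starts_with_met},
#' \code{has_internal_stop}, \code{has_terminal_stop}, \code{frameshifted},
#' \code{divergent}).
#'
#' @slot ranges GRanges of candidate intervals with metadata columns.
#' @slot cds DNAStringSet, forward-coding nucleotide sequences.
#' @slot protein AAStringSet, translations (terminal stop stripped).
#' @export
setClass("GeneCandidates", slots = c(
  ranges = "GRanges",
  cds = "DNAStringSet",
  protein = "AAStringSet"
))

setValidity("GeneCandidates", function(object) {
  n <- length(object@ranges)
  if (length(object@cds) != n || length(object@protein) != n)
    return("ranges, cds and protein must have equal length")
  if (n && !all(GenomicRanges::width(object@ranges) == Biostrings::width(object@cds)))
    return("interval width must equal CDS length")
  TRUE
})

#' Codon-aware multiple alignment
#'
#' A \code{DNAStringSet} whose rows all have equal width, whose width is a
#' multiple of 3, and whose gaps occur in whole-codon triplets, so that
#' column triples can be interpreted as codon sites.
#' @export
setClass("CodonAlignment", contains = "DNAStringSet")

setValidity("CodonAlignment", function(object) {
  if (length(object) == 0L) return(TRUE)
  w <- Biostrings::width(object)
  if (length(unique(w)) != 1L) return("all rows must have equal length")
  if (w[1L] %% 3L != 0L) return("alignment length must be a multiple of 3")
  m <- as.matrix(object)
  gaps <- m == "-"
  nc <- ncol(m) / 3L
  for (j in seq_len(nc)) {
    cols <- gaps[, (3L * j - 2L):(3L * j), drop = FALSE]
    if (any(rowSums(cols) %% 3L != 0L))
      return("gaps must occur in whole-codon triplets")
  }
  TRUE
})

#' Fitted codon site model (M7 or M8)
#'
#' Result of \code{\link{fitSiteModel}}: a Goldman--Yang codon model with a
#' beta-distributed omega mixture (M7) optionally augmented by a selected
#' class with omega >= 1 (M8), fitted by maximum likelihood on a fixed tree
#' with a single free branch-scale multiplier.
#'
#' @slot model "M7" or "M8".
#' @slot params named numeric: kappa, p, q, scale and (M8) p0, omega_s.
#' @slot logLik numeric log-likelihood at the optimum.
#' @slot catOmega numeric omega value of each mixture category.
#' @slot catWeight numeric mixture weight of each category.
#' @slot freqs numeric F3x4 codon frequencies (61 sense codons).
#' @slot siteCatLogLik matrix (sites x categories) of per-site per-category
#'   log-likelihoods, used for empirical-Bayes posteriors.
#' @slot diagnostics list: convergence codes, start table, best start,
#'   evaluation counts, boundary flags, data hash.
#' @export
setClass("SiteModelFit", slots = c(
  model = "character",
  params = "numeric",
  logLik = "numeric",
  catOmega = "numeric",
  catWeight = "numeric",
  freqs = "numeric",
  siteCatLogLik = "matrix",
  diagnostics = "list"
))

#' Epitope count profile
#'
#' Counts of celiac-disease epitope occurrences indexed by (accession, locus,
#' epitope), with zero cells retained so absences are visible, plus
#' occurrence and gene-level (genes-containing-epitope) counts.
#'
#' @slot counts data.frame with columns accession, locus, subgenome, epitope,
#'   occurrences, genes_with.
#' @export
setClass("EpitopeProfile", slots = c(counts = "data.frame"))

setValidity("EpitopeProfile", function(object) {
  need <- c("accession", "locus", "subgenome", "epitope", "occurrences", "genes_with")
  if (!all(need %in% names(object@counts)))
    return("counts must have columns accession, locus, subgenome, epitope, occurrences, genes_with")
  if (any(object@counts$occurrences < 0)) return("counts must be >= 0")
  TRUE
})
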