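# Positional clustering of gene candidates into Gli-2 loci and subloci.
#
# Candidates on one chromosome are sorted by midpoint and a new cluster
# starts whenever the gap between consecutive midpoints exceeds gapMb. The
# default of 5 Mb sits between the two regimes seen in real accessions:
# subloci are >= ~6.6 Mb apart while intra-sublocus spans are <= ~2.4 Mb.

#' Cluster candidates into loci/subloci by genomic position
#'
#' @param x candidates on a single chromosome: a
#'   \code{\linkS4class{GeneCandidates}}, or a data.frame with columns
#'   \code{chrom} and \code{mid_mb} (midpoints in Mb; optional
#'   \code{gene_id}, \code{start_mb}, \code{end_mb}).
#' @param gapMb gap threshold in Mb (> 0); consecutive midpoints further
#'   apart than this start a new sublocus.
#' @return data.frame with one row per locus: \code{name} (Gli-\{A|B|D\}2
#'   with -n sublocus suffix when there are >= 2 clusters), \code{chrom},
#'   \code{subgenome}, \code{n}, \code{members} (list column of gene ids),
#'   \code{start_mb}, \code{end_mb}, \code{mid_mb}. The per-gene assignment
#'   is in \code{attr(, "assignment")}.
#' @export
clusterLoci <- function(x, gapMb = 5) {
  stopifnot(gapMb > 0)
  if (is(x, "GeneCandidates")) {
    gr <- x@ranges
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      gene_id = S4Vectors::mcols(gr)$gene_id,
      start_mb = (GenomicRanges::start(gr) - 1L) / 1e6,
      end_mb = GenomicRanges::end(gr) / 1e6,
      stringsAsFactors = FALSE)
    df$mid_mb <- (df$start_mb + df$end_mb) / 2
  } else {
    df <- as.data.frame(x)
    if (!all(c("chrom", "mid_mb") %in% names(df)))
      stop("input must have columns chrom and mid_mb")
    if (is.null(df$gene_id)) df$gene_id <- sprintf("g%03d", seq_len(nrow(df)))
    if (is.null(df$start_mb)) df$start_mb <- df$mid_mb
    if (is.null(df$end_mb)) df$end_mb <- df$mid_mb
  }
  if (nrow(df) == 0L) {
    out <- data.frame(name = character(), chrom = character(),
                      subgenome = character(), n = integer(),
                      start_mb = numeric(), end_mb = numeric(),
                      mid_mb = numeric())
    out$members <- list()
    attr(out, "assignment") <- data.frame(gene_id = character(),
                                          locus = character())
    return(out)
  }
  if (length(unique(df$chrom)) != 1L)
    stop("all candidates must share a chromosome; got: ",
         paste(unique(df$chrom), collapse = ", "))

  df <- df[order(df$mid_mb), , drop = FALSE]
  grp <- cumsum(c(1, diff(df$mid_mb) > gapMb))
  nClust <- max(grp)
  letter <- subgenomeLetter(df$chrom[1L])
  base <- sprintf("Gli-%s2", letter)
  names <- if (nClust == 1L) base else sprintf("%s-%d", base, seq_len(nClust))

  out <- do.call(rbind, lapply(seq_len(nClust), function(g) {
    sel <- df[grp == g, , drop = FALSE]
    data.frame(name = names[g], chrom = sel$chrom[1L], subgenome = letter,
               n = nrow(sel), start_mb = min(sel$start_mb),
               end_mb = max(sel$end_mb),
               mid_mb = mean(range(sel$mid_mb)), stringsAsFactors = FALSE)
  }))
  out$members <- lapply(seq_len(nClust), function(g) df$gene_id[grp == g])
  attr(out, "assignment") <- data.frame(
    gene_id = df$gene_id, locus = names[grp], stringsAsFactors = FALSE)
  out
}

#' Pairwise separations between consecutive subloci
#'
#' Separation is the start of the later span minus the end of the earlier
#' span, in Mb, reported both exactly and rounded to the nearest integer Mb
#' (the convention used for quoted sublocus distances such as "7 Mb apart").
#' Overlapping spans give separation 0 with a warning.
#'
#' @param loci locus data.frame from \code{\link{clusterLoci}} (>= 2 rows,
#'   one chromosome).
#' @return data.frame(from, to, separation_mb, separation_round_mb).
#' @export
sublocusSeparation <- function(loci) {
  if (nrow(loci) < 2L) stop("need >= 2 loci on one chromosome")
  if (length(unique(loci$chrom)) != 1L) stop("loci must share a chromosome")
  loci <- loci[order(loci$start_mb), , drop = FALSE]
  n <- nrow(loci)
  sep <- loci$start_mb[-1L] - loci$end_mb[-n]
  if (any(sep < 0)) {
    warning("overlapping sublocus spans; separation reported as 0")
    sep[sep < 0] <- 0
  }
  data.frame(from = loci$name[-n], to = loci$name[-1L],
             separation_mb = sep, separation_round_mb = round(sep),
             stringsAsFactors = FALSE)
}

#' Assign unanchored (chrUn) copies to a locus
#'
#' Copies on unanchored scaffolds default to Gli-D2 (the literature
#' convention for bread wheat). When phylogenetic clade labels are available,
#' each chrUn copy is instead assigned to the locus of its clade, and a
#' conflict flag is raised when that differs from the default -- the analog
#' of chrUn copies that cluster with Gli-A2 or Gli-B2 members.
#'
#' @param chrUnIds character gene ids of chrUn copies.
#' @param cladeLabels optional named character vector (gene id -> dominant
#'   locus label of its clade) from \code{\link{cladeMembership}}.
#' @param default default locus assignment.
#' @return data.frame(gene_id, assigned, conflict).
#' @export
assignUnanchored <- function(chrUnIds, cladeLabels = NULL, default = "Gli-D2") {
  if (is.null(cladeLabels)) {
    if (length(chrUnIds))
      warning("no clade labels supplied; chrUn copies assigned to ", default)
    return(data.frame(gene_id = chrUnIds, assigned = rep(default, length(chrUnIds)),
                      conflict = rep(FALSE, length(chrUnIds)),
                      stringsAsFactors = FALSE))
  }
  assigned <- ifelse(chrUnIds %in% names(cladeLabels) &
                       !is.na(cladeLabels[chrUnIds]) &
                       cladeLabels[chrUnIds] != "chrUn",
                     unname(cladeLabels[chrUnIds]), default)
  data.frame(gene_id = chrUnIds, assigned = assigned,
             conflict = assigned != default, stringsAsFactors = FALSE)
}
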