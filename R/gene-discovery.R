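# Seed-and-extend discovery of gliadin-like single-exon gene copies.
#
# Exact k-mer seeds tiled along each query are located on both strands of the
# assembly; co-linear seed clusters are extended by banded global(-on-query)
# alignment with a fixed scheme (match +1, mismatch -1, gap open 4, gap
# extend 1 per gap position), and hits passing identity/length thresholds are
# reported as genomically contiguous candidates (the single-exon criterion:
# no intron modelling). Overlapping same-strand hits keep the best score.

checkDNAQueries <- function(queries) {
  if (length(queries) == 0L) stop("query set must be non-empty")
  qs <- as.character(queries)
  bad <- grepl("[^ACGT]", qs)
  if (any(bad))
    stop("query contains non-ACGT characters: ",
         paste(names(queries)[bad], collapse = ", "))
  invisible(TRUE)
}

translateNoStop <- function(cds) {
  aa <- translateCDS(cds)
  sub("\\*$", "", aa)
}

emptyCandidates <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = character(), query_id = character(),
    identity = numeric(), score = numeric(),
    starts_with_met = logical(), has_internal_stop = logical(),
    has_terminal_stop = logical(), frameshifted = logical(),
    divergent = logical())
  new("GeneCandidates", ranges = gr,
      cds = Biostrings::DNAStringSet(), protein = Biostrings::AAStringSet())
}

# seed matches of one query against one strand-oriented subject sequence;
# returns candidate windows as implied query-start positions on the subject
seedWindows <- function(query, subject, seedLen, minHits) {
  qlen <- nchar(query)
  offs <- unique(c(seq(1L, max(1L, qlen - seedLen + 1L), by = seedLen),
                   max(1L, qlen - seedLen + 1L)))
  seeds <- substring(query, offs, pmin(offs + seedLen - 1L, qlen))
  keep <- nchar(seeds) == seedLen
  seeds <- seeds[keep]; offs <- offs[keep]
  if (!length(seeds)) return(integer())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  hits <- Biostrings::matchPDict(pd, subject)
  proj <- integer()
  for (i in seq_along(hits)) {
    st <- BiocGenerics::start(hits[[i]])
    if (length(st)) proj <- c(proj, st - offs[i] + 1L)
  }
  if (!length(proj)) return(data.frame(from = integer(), to = integer()))
  proj <- sort(proj)
  grp <- cumsum(c(1L, diff(proj) > 100L))
  sizes <- tabulate(grp)
  keep <- sizes >= minHits
  # repeats inside the query (polyglutamine, repeat domain) shift individual
  # seed projections; the window must span the whole projected cluster
  data.frame(from = vapply(split(proj, grp), min, numeric(1))[keep],
             to = vapply(split(proj, grp), max, numeric(1))[keep] + qlen)
}

#' Find gliadin gene candidates in an assembly
#'
#' Seed-and-extend homology search of query CDS sequences against both
#' strands of an assembly. Replaces a BLAST "e-value = 0, single exon"
#' selection with reproducible identity and length thresholds on contiguous
#' genomic hits.
#'
#' @param assembly \code{DNAStringSet} of chromosome/scaffold sequences.
#' @param queries named \code{DNAStringSet} of query CDS sequences
#'   (ACGT only).
#' @param minIdentity minimum alignment identity (fraction of alignment
#'   columns that match), in (0.5, 1].
#' @param minLen minimum aligned genomic length in bp.
#' @param seedLen exact-match seed length (>= 8).
#' @param accession accession name recorded on the result.
#' @return a \code{\linkS4class{GeneCandidates}} in coordinate order, with
#'   ORF flags set (see \code{\link{classifyOrf}}).
#' @export
findCandidates <- function(assembly, queries, minIdentity = 0.9,
                           minLen = 300L, seedLen = 12L,
                           accession = "accession") {
  seedLen <- as.integer(seedLen)
  minLen <- as.integer(minLen)
  stopifnot(seedLen >= 8L, minIdentity > 0.5, minIdentity <= 1)
  checkDNAQueries(queries)
  if (length(assembly) == 0L) return(emptyCandidates())
  if (is.null(names(queries)))
    names(queries) <- sprintf("query%d", seq_along(queries))

  hits <- list()
  for (chrom in names(assembly)) {
    chromSeq <- assembly[[chrom]]
    L <- length(chromSeq)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") chromSeq else Biostrings::reverseComplement(chromSeq)
      for (qi in seq_along(queries)) {
        q <- as.character(queries[[qi]])
        qlen <- nchar(q)
        minHits <- min(2L, max(1L, qlen %/% seedLen))
        wins <- seedWindows(q, subj, seedLen, minHits)
        for (wi in seq_len(nrow(wins))) {
          wFrom <- max(1L, wins$from[wi] - 50L)
          wTo <- min(L, wins$to[wi] + 50L)
          win <- Biostrings::subseq(subj, wFrom, wTo)
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(q), win, type = "global-local",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
              match = 1, mismatch = -1),
            gapOpening = 4, gapExtension = 1)
          sFrom <- wFrom + BiocGenerics::start(Biostrings::subject(aln)) - 1L
          sTo <- wFrom + BiocGenerics::end(Biostrings::subject(aln)) - 1L
          alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
          ident <- Biostrings::nmatch(aln) / alnLen
          span <- sTo - sFrom + 1L
          if (ident < minIdentity || span < minLen) next
          if (strand == "+") {
            gFrom <- sFrom; gTo <- sTo
          } else {
            gFrom <- L - sTo + 1L; gTo <- L - sFrom + 1L
          }
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, start = gFrom, end = gTo, strand = strand,
            query_id = names(queries)[qi], identity = ident,
            score = Biostrings::score(aln),
            cds = as.character(Biostrings::subseq(subj, sFrom, sTo)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(emptyCandidates())
  hits <- do.call(rbind, hits)

  # merge overlapping same-strand hits, keeping the best score
  hits <- hits[order(-hits$score, hits$chrom, hits$start), , drop = FALSE]
  kept <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- kept & hits$chrom == hits$chrom[i] & hits$strand == hits$strand[i] &
      hits$start <= hits$end[i] & hits$end >= hits$start[i]
    if (!any(ov)) kept[i] <- TRUE
  }
  hits <- hits[kept, , drop = FALSE]
  hits <- hits[order(match(hits$chrom, names(assembly)), hits$start), , drop = FALSE]

  gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(hits$start, hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = sprintf("%s_c%03d", accession, seq_len(nrow(hits))),
    query_id = hits$query_id, identity = hits$identity, score = hits$score,
    starts_with_met = NA, has_internal_stop = NA, has_terminal_stop = NA,
    frameshifted = NA, divergent = NA)
  cds <- Biostrings::DNAStringSet(hits$cds)
  names(cds) <- S4Vectors::mcols(gr)$gene_id
  prot <- Biostrings::AAStringSet(vapply(hits$cds, translateNoStop, character(1),
                                         USE.NAMES = FALSE))
  names(prot) <- names(cds)
  classifyOrf(new("GeneCandidates", ranges = gr, cds = cds, protein = prot))
}

#' Set ORF flags on gene candidates
#'
#' Translates each candidate CDS with the standard nuclear code and sets
#' flags: \code{starts_with_met}, \code{has_internal_stop},
#' \code{has_terminal_stop}, \code{frameshifted} (length not a multiple of
#' 3). Candidates are never dropped here; the flags drive downstream
#' filtering (copies without an initial methionine are incomplete fragments;
#' premature stops and frameshifts mark pseudogenes).
#'
#' @param candidates a \code{\linkS4class{GeneCandidates}}.
#' @return the same object with flags and proteins filled in.
#' @export
classifyOrf <- function(candidates) {
  n <- length(candidates@ranges)
  if (n == 0L) return(candidates)
  cds <- as.character(candidates@cds)
  met <- substr(cds, 1L, 3L) == "ATG"
  frame <- nchar(cds) %% 3L != 0L
  term <- logical(n); intern <- logical(n); prot <- character(n)
  for (i in seq_len(n)) {
    cod <- splitCodons(cds[i])
    isStop <- cod %in% stopCodons
    term[i] <- length(cod) > 0L && isStop[length(cod)]
    intern[i] <- any(isStop[-length(cod)])
    aa <- GENCODE[cod]
    aa[is.na(aa)] <- "X"
    if (term[i]) aa <- aa[-length(aa)]
    prot[i] <- paste(aa, collapse = "")
  }
  mc <- S4Vectors::mcols(candidates@ranges)
  mc$starts_with_met <- met
  mc$has_internal_stop <- intern
  mc$has_terminal_stop <- term
  mc$frameshifted <- frame
  S4Vectors::mcols(candidates@ranges) <- mc
  pr <- Biostrings::AAStringSet(prot)
  names(pr) <- mc$gene_id
  candidates@protein <- pr
  candidates
}

# protein p-distance after global alignment with the fixed aa scheme
proteinPDist <- function(a, b) {
  if (!nchar(a) || !nchar(b)) return(NA_real_)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = aaScoreMatrix(), gapOpening = 10, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- pa != "-" & sa != "-"
  if (!any(ok)) return(NA_real_)
  sum(pa[ok] != sa[ok]) / sum(ok)
}

aaScoreMatrix <- function() {
  if (!is.null(.codonCache$aaMat)) return(.codonCache$aaMat)
  letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*", "X")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 4
  .codonCache$aaMat <- m
  m
}

#' Filter candidates too diverged from the query set
#'
#' Computes the protein p-distance of each candidate to its nearest query
#' (after pairwise global alignment) and moves candidates beyond
#' \code{maxPdist} -- the operational reading of "too diverged" -- to the
#' discarded set with the \code{divergent} flag set. Input order is
#' preserved in both outputs.
#'
#' @param candidates a \code{\linkS4class{GeneCandidates}} with proteins.
#' @param queries \code{DNAStringSet} of query CDS sequences.
#' @param maxPdist maximum protein p-distance to the nearest query.
#' @return list(kept, discarded, reasons): two \code{GeneCandidates} plus a
#'   character vector of discard reasons ("divergent" or "empty_protein").
#' @export
filterDivergent <- function(candidates, queries, maxPdist = 0.35) {
  n <- length(candidates@ranges)
  if (n == 0L)
    return(list(kept = candidates, discarded = candidates, reasons = character()))
  qprot <- vapply(as.character(queries), translateNoStop, character(1))
  prot <- as.character(candidates@protein)
  dist <- numeric(n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!nchar(prot[i])) { dist[i] <- NA; reason[i] <- "empty_protein"; next }
    dist[i] <- min(vapply(qprot, proteinPDist, numeric(1), a = prot[i]),
                   na.rm = TRUE)
    if (dist[i] > maxPdist) reason[i] <- "divergent"
  }
  mc <- S4Vectors::mcols(candidates@ranges)
  mc$divergent <- !is.na(reason) & reason == "divergent"
  mc$pdist <- dist
  S4Vectors::mcols(candidates@ranges) <- mc
  drop <- !is.na(reason)
  list(kept = candidates[!drop], discarded = candidates[drop],
       reasons = reason[drop])
}

#' Write candidate artifacts
#'
#' Writes a BED file (0-based half-open, score column = alignment score,
#' name = gene id), a tab-separated detail table, and the candidate proteins
#' as FASTA.
#'
#' @param candidates a \code{\linkS4class{GeneCandidates}}.
#' @param outPrefix path prefix for the three output files.
#' @return invisibly, the paths written.
#' @export
writeCandidates <- function(candidates, outPrefix) {
  df <- as.data.frame(candidates)
  paths <- c(bed = paste0(outPrefix, ".bed"),
             tsv = paste0(outPrefix, ".tsv"),
             faa = paste0(outPrefix, ".proteins.fasta"))
  bed <- data.frame(df$chrom, df$start, df$end, df$gene_id,
                    round(df$score), df$strand)
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(df, paths["tsv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  Biostrings::writeXStringSet(candidates@protein, paths["faa"])
  invisible(paths)
}
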