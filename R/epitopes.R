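# Overlap-aware scanning of alpha-gliadin proteins for celiac-disease (CD)
# T-cell epitopes, 33-mer detection, and per-accession x locus profiles.
# Matching is exact (canonical sequences): a single substitution, like the
# P->S change that breaks DQ2.5-glia-a2 in A-subgenome copies, abolishes the
# match.

#' Default CD epitope table
#'
#' The four well-established DQ2.5-glia-alpha 9-mers plus the immunotoxic
#' 33-mer. The full epitope set is configurable via a user table (see
#' \code{\link{readEpitopeTable}}); this default is a starting point, not an
#' exhaustive canon.
#'
#' @return data.frame(name, peptide, note).
#' @export
defaultEpitopeTable <- function() {
  data.frame(
    name = c("DQ2.5-glia-a1a", "DQ2.5-glia-a1b", "DQ2.5-glia-a2",
             "DQ2.5-glia-a3", "33mer"),
    peptide = c("PFPQPQLPY", "PYPQPQLPY", "PQPQLPYPQ", "FRPQQPYPQ",
                "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"),
    note = c("DQ2.5-restricted 9-mer, repeat domain",
             "DQ2.5-restricted 9-mer, repeat domain",
             "DQ2.5-restricted 9-mer, repeat domain",
             "DQ2.5-restricted 9-mer",
             "33-residue immunotoxic fragment containing six overlapping epitopes"),
    stringsAsFactors = FALSE)
}

.PROT_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

checkEpitopeTable <- function(table) {
  if (!all(c("name", "peptide") %in% names(table)))
    stop("epitope table needs columns name and peptide")
  if (any(duplicated(table$name))) stop("epitope names must be unique")
  if (any(!nzchar(table$peptide))) stop("epitope peptides must be non-empty")
  bad <- grepl(sprintf("[^%s]", "ACDEFGHIKLMNPQRSTVWY"), table$peptide)
  if (any(bad))
    stop("epitope peptide with invalid residues: ",
         paste(table$name[bad], collapse = ", "))
  invisible(TRUE)
}

#' Read an epitope table from a tab-separated file
#' @param path TSV with columns name, peptide and optionally note.
#' @return validated data.frame(name, peptide, note).
#' @export
readEpitopeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  checkEpitopeTable(tab)
  if (is.null(tab$note)) tab$note <- ""
  tab[, c("name", "peptide", "note")]
}

checkProteins <- function(proteins) {
  if (is(proteins, "AAStringSet")) proteins <- as.character(proteins)
  if (is.null(names(proteins)))
    names(proteins) <- sprintf("protein%d", seq_along(proteins))
  bad <- grepl(sprintf("[^%s]", paste(.PROT_ALPHABET, collapse = "")), proteins)
  if (any(bad))
    stop("protein with invalid characters (lowercase or non-amino-acid): ",
         paste(names(proteins)[bad], collapse = ", "))
  proteins
}

# all (overlapping) occurrence offsets, 0-based
occurrenceOffsets <- function(protein, peptide) {
  n <- nchar(protein); m <- nchar(peptide)
  if (m > n) return(integer())
  starts <- which(vapply(seq_len(n - m + 1L),
                         function(i) substr(protein, i, i + m - 1L) == peptide,
                         logical(1)))
  starts - 1L
}

#' Scan proteins for epitope occurrences
#'
#' Reports every exact occurrence of every table peptide, including
#' overlapping and repeated occurrences, in deterministic order (by protein,
#' then offset, then epitope name).
#'
#' @param proteins named character vector or \code{AAStringSet} of uppercase
#'   protein sequences (no stop symbol; "X" is tolerated and never matches).
#' @param table epitope table (data.frame with name, peptide).
#' @return data.frame(gene_id, epitope, offset) with 0-based offsets.
#' @export
scanEpitopes <- function(proteins, table = defaultEpitopeTable()) {
  proteins <- checkProteins(proteins)
  checkEpitopeTable(table)
  out <- list()
  for (g in names(proteins)) {
    for (r in seq_len(nrow(table))) {
      offs <- occurrenceOffsets(proteins[[g]], table$peptide[r])
      if (length(offs))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, epitope = table$name[r], offset = offs,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), epitope = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(match(res$gene_id, names(proteins)), res$offset, res$epitope), ]
  rownames(res) <- NULL
  res
}

.MER33 <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"
.REPEAT_EPITOPES <- c("PFPQPQLPY", "PYPQPQLPY", "PQPQLPYPQ")

#' Detect the immunotoxic 33-mer
#'
#' Counts exact occurrences of the 33-mer peptide and, independently,
#' applies the composite rule: a 33-residue window containing at least six
#' overlapping occurrences of the three repeat-domain epitopes. Overlapping
#' qualifying windows are collapsed into runs, so one planted 33-mer counts
#' once under either definition.
#'
#' @param proteins named character vector or \code{AAStringSet}.
#' @return data.frame(gene_id, exact, composite).
#' @export
detect33mer <- function(proteins) {
  proteins <- checkProteins(proteins)
  out <- lapply(names(proteins), function(g) {
    p <- proteins[[g]]
    exact <- length(occurrenceOffsets(p, .MER33))
    hits <- sort(unlist(lapply(.REPEAT_EPITOPES, occurrenceOffsets, protein = p)))
    composite <- 0L
    n <- nchar(p)
    if (n >= 33L && length(hits) >= 6L) {
      qual <- vapply(0:(n - 33L), function(w)
        sum(hits >= w & hits + 9L <= w + 33L) >= 6L, logical(1))
      composite <- sum(diff(c(FALSE, qual)) == 1L)
    }
    data.frame(gene_id = g, exact = exact, composite = composite,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

locusSubgenome <- function(locus) {
  m <- regmatches(locus, regexpr("Gli-([ABD])2", locus))
  ifelse(nzchar(m), substr(m, 5L, 5L), "Un")
}

#' Tabulate epitope counts per accession and locus
#'
#' Builds the full (accession x locus x epitope) index with zero cells
#' retained, reporting both total occurrences and the number of genes
#' containing each epitope (the two plausible readings of a per-cell count).
#'
#' @param hits data.frame(gene_id, epitope, offset) from
#'   \code{\link{scanEpitopes}}.
#' @param genes data.frame(gene_id, accession, locus): locus assignment of
#'   every scanned gene.
#' @param epitopeNames epitope names defining the profile rows (defaults to
#'   those present in \code{hits} plus the default table).
#' @return an \code{\linkS4class{EpitopeProfile}}.
#' @export
profileCounts <- function(hits, genes,
                          epitopeNames = union(defaultEpitopeTable()$name,
                                               hits$epitope)) {
  missing <- setdiff(hits$gene_id, genes$gene_id)
  if (length(missing))
    stop("hits reference genes without a locus assignment: ",
         paste(missing, collapse = ", "))
  idx <- expand.grid(accession = unique(genes$accession),
                     locus = unique(genes$locus),
                     epitope = epitopeNames,
                     stringsAsFactors = FALSE)
  hh <- merge(hits, genes, by = "gene_id")
  if (nrow(hh)) {
    occ <- stats::aggregate(offset ~ accession + locus + epitope, hh, length)
    names(occ)[4L] <- "occurrences"
    gw <- stats::aggregate(gene_id ~ accession + locus + epitope, hh,
                           function(x) length(unique(x)))
    names(gw)[4L] <- "genes_with"
    idx <- merge(merge(idx, occ, all.x = TRUE), gw, all.x = TRUE)
  } else {
    idx$occurrences <- 0L
    idx$genes_with <- 0L
  }
  idx$occurrences[is.na(idx$occurrences)] <- 0L
  idx$genes_with[is.na(idx$genes_with)] <- 0L
  idx$subgenome <- locusSubgenome(idx$locus)
  idx <- idx[order(idx$accession, idx$locus, idx$epitope), ]
  rownames(idx) <- NULL
  new("EpitopeProfile",
      counts = idx[, c("accession", "locus", "subgenome", "epitope",
                       "occurrences", "genes_with")])
}

#' Epitope x (accession, subgenome) count matrix
#'
#' @param profile an \code{\linkS4class{EpitopeProfile}}.
#' @param value which count to tabulate.
#' @return matrix with epitopes as rows.
#' @export
profileMatrix <- function(profile, value = c("occurrences", "genes_with")) {
  value <- match.arg(value)
  cc <- profile@counts
  cc$col <- paste(cc$accession, cc$subgenome, sep = ".")
  tab <- stats::xtabs(stats::as.formula(paste(value, "~ epitope + col")), cc)
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Subgenome marginal counts
#' @param profile an \code{\linkS4class{EpitopeProfile}}.
#' @return data.frame(subgenome, occurrences).
#' @export
subgenomeMarginals <- function(profile) {
  cc <- profile@counts
  out <- stats::aggregate(occurrences ~ subgenome, cc, sum)
  out[order(out$subgenome), ]
}
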