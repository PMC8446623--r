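# Codon-aware alignment, K2P(+gamma) distances, neighbor-joining with
# bootstrap, and clade labelling of gene copies.

#' Codon-aware progressive alignment
#'
#' Aligns CDS sequences at the protein level with a deterministic
#' center-star strategy (the center is the sequence with the highest total
#' 3-mer similarity to the others; all pairwise alignments are global with
#' fixed scores: match +4, mismatch -1, gap opening 10, gap extension 1) and
#' back-projects the protein alignment onto codons, so gaps always occur in
#' whole-codon triplets.
#'
#' @param cds named \code{DNAStringSet} or character vector of CDS sequences
#'   (length a multiple of 3, no internal stop codons; a terminal stop codon
#'   is allowed and aligned as a residue).
#' @return a \code{\linkS4class{CodonAlignment}}.
#' @export
alignCodons <- function(cds) {
  if (is(cds, "XStringSet")) cds <- as.character(cds)
  if (is.null(names(cds))) names(cds) <- sprintf("seq%d", seq_along(cds))
  badLen <- nchar(cds) %% 3L != 0L
  if (any(badLen))
    stop("CDS length not a multiple of 3 (frameshifts must be filtered upstream): ",
         paste(names(cds)[badLen], collapse = ", "))
  prot <- vapply(cds, translateCDS, character(1))
  hasInternal <- vapply(prot, function(p)
    grepl("\\*", sub("\\*$", "", p)), logical(1))
  if (any(hasInternal))
    stop("internal stop codons in: ", paste(names(cds)[hasInternal], collapse = ", "))

  n <- length(cds)
  if (n == 1L) {
    out <- Biostrings::DNAStringSet(cds)
    return(new("CodonAlignment", out))
  }

  # guide order / center from 3-mer similarity
  kmers <- lapply(prot, function(p) {
    if (nchar(p) < 3L) return(character())
    substring(p, seq_len(nchar(p) - 2L), seq_len(nchar(p) - 2L) + 2L)
  })
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sum(pmin(table(kmers[[i]])[intersect(names(table(kmers[[i]])),
                                              names(table(kmers[[j]])))],
                  table(kmers[[j]])[intersect(names(table(kmers[[i]])),
                                              names(table(kmers[[j]])))]))
    sim[i, j] <- sim[j, i] <- s
  }
  center <- which.max(rowSums(sim))

  others <- setdiff(seq_len(n), center)
  cAln <- list(); oAln <- list()
  for (j in others) {
    a <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot[center]), Biostrings::AAString(prot[j]),
      type = "global", substitutionMatrix = aaScoreMatrix(),
      gapOpening = 10, gapExtension = 1)
    cAln[[as.character(j)]] <- strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]]
    oAln[[as.character(j)]] <- strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]]
  }

  # merged gap counts before each center residue (and at the end)
  cLen <- nchar(prot[center])
  gapsBefore <- function(cChars) {
    g <- integer(cLen + 1L); slot <- 1L; run <- 0L
    for (ch in cChars) {
      if (ch == "-") run <- run + 1L
      else { g[slot] <- run; slot <- slot + 1L; run <- 0L }
    }
    g[cLen + 1L] <- run
    g
  }
  G <- rep(0L, cLen + 1L)
  for (j in names(cAln)) G <- pmax(G, gapsBefore(cAln[[j]]))

  # rebuild each row in merged coordinates (insertions right-aligned)
  centerRow <- character()
  for (i in seq_len(cLen))
    centerRow <- c(centerRow, rep("-", G[i]), substr(prot[center], i, i))
  centerRow <- c(centerRow, rep("-", G[cLen + 1L]))

  buildRow <- function(cChars, oChars) {
    out <- character(); buf <- character(); slot <- 1L
    for (k in seq_along(cChars)) {
      if (cChars[k] == "-") buf <- c(buf, oChars[k])
      else {
        out <- c(out, rep("-", G[slot] - length(buf)), buf, oChars[k])
        buf <- character(); slot <- slot + 1L
      }
    }
    c(out, rep("-", G[cLen + 1L] - length(buf)), buf)
  }

  rows <- vector("list", n)
  rows[[center]] <- centerRow
  for (j in others) rows[[j]] <- buildRow(cAln[[as.character(j)]],
                                          oAln[[as.character(j)]])

  # back-project protein rows onto codons
  codonRows <- vapply(seq_len(n), function(i) {
    cod <- splitCodons(cds[i])
    k <- 0L
    paste(vapply(rows[[i]], function(ch) {
      if (ch == "-") "---" else { k <<- k + 1L; cod[k] }
    }, character(1)), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(codonRows)
  names(out) <- names(cds)
  new("CodonAlignment", out)
}

#' Kimura 2-parameter distances with optional gamma correction
#'
#' Transition (P) and transversion (Q) proportions are computed per pair
#' over comparable sites; the plain K2P distance is
#' \code{-log(1-2P-Q)/2 - log(1-2Q)/4} and the gamma-corrected form is
#' \code{(a/2)[(1-2P-Q)^(-1/a)-1] + (a/4)[(1-2Q)^(-1/a)-1]} for shape
#' \code{a}. Saturated pairs (log/power argument <= 0) and pairs with no
#' comparable sites receive a ceiling distance with a flag, so neighbor
#' joining always sees a complete matrix.
#'
#' @param aln a \code{CodonAlignment} or equal-width \code{DNAStringSet}.
#' @param alpha gamma shape parameter (2.25 reproduces the published
#'   setting; \code{Inf} gives the plain K2P distance).
#' @param deletion "complete" removes every codon column containing a gap in
#'   any sequence before computing distances; "pairwise" drops gapped sites
#'   per pair.
#' @param ceiling distance assigned to saturated/incomparable pairs.
#' @return symmetric distance matrix with attributes \code{alpha} and
#'   \code{flagged} (logical matrix of ceiling-substituted pairs).
#' @export
k2pDistance <- function(aln, alpha = 2.25, deletion = c("complete", "pairwise"),
                        ceiling = 5) {
  deletion <- match.arg(deletion)
  m <- as.matrix(Biostrings::DNAStringSet(as.character(aln)))
  if (nrow(m) < 2L) stop("need >= 2 sequences")
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  if (deletion == "complete" && ncol(m)) {
    nCod <- ncol(m) %/% 3L
    if (nCod * 3L == ncol(m)) {
      codOK <- vapply(seq_len(nCod), function(j)
        all(ok[, (3L * j - 2L):(3L * j)]), logical(1))
      keep <- rep(codOK, each = 3L)
    } else keep <- colSums(!ok) == 0L
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(m)
  purine <- m == "A" | m == "G"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  flag <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L) { D[i, j] <- D[j, i] <- ceiling; flag[i, j] <- flag[j, i] <- TRUE; next }
    diff <- comp & (m[i, ] != m[j, ])
    ts <- sum(diff & (purine[i, ] == purine[j, ]))
    P <- ts / nc
    Q <- (sum(diff) - ts) / nc
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) {
      d <- ceiling; flag[i, j] <- flag[j, i] <- TRUE
    } else if (is.infinite(alpha)) {
      d <- -0.5 * log(w1) - 0.25 * log(w2)
    } else {
      d <- (alpha / 2) * (w1^(-1 / alpha) - 1) + (alpha / 4) * (w2^(-1 / alpha) - 1)
    }
    D[i, j] <- D[j, i] <- min(d, ceiling)
  }
  attr(D, "alpha") <- alpha
  attr(D, "flagged") <- flag
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining; negative branch-length estimates are clamped
#' to zero (with a message).
#'
#' @param D symmetric distance matrix (zero diagonal, >= 3 taxa).
#' @return an unrooted \code{ape} phylo.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need >= 3 taxa")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(D) < 0) || any(diag(D) > 1e-12)) stop("diagonal must be zero")
  tree <- ape::nj(D)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Bootstrap support for the NJ tree
#'
#' Resamples codon columns with replacement (codon-granular), recomputes
#' distances and the NJ tree per replicate, and reports for each internal
#' node of the original tree the percentage of successful replicates
#' containing its bipartition. Replicates with a degenerate distance matrix
#' are skipped and counted.
#'
#' @param aln a \code{CodonAlignment}.
#' @param B number of replicates (>= 1).
#' @param alpha gamma shape for the distances.
#' @param seed integer seed.
#' @param deletion gap handling, as in \code{\link{k2pDistance}}.
#' @return the original NJ tree with node labels set to support percentages;
#'   \code{attr(, "skipped")} counts failed replicates.
#' @export
bootstrapSupport <- function(aln, B = 1000L, alpha = 2.25, seed,
                             deletion = "pairwise") {
  stopifnot(B >= 1L)
  D0 <- k2pDistance(aln, alpha = alpha, deletion = deletion)
  tree0 <- njTree(D0)
  seqs <- as.character(aln)
  nCod <- nchar(seqs[1L]) %/% 3L
  trees <- list(); skipped <- 0L
  withSeed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(nCod, nCod, replace = TRUE)
      res <- vapply(seqs, function(s) {
        tri <- splitCodons(s)
        paste(tri[cols], collapse = "")
      }, character(1))
      aln_b <- Biostrings::DNAStringSet(res)
      names(aln_b) <- names(seqs)
      tb <- tryCatch({
        Db <- suppressMessages(k2pDistance(aln_b, alpha = alpha, deletion = deletion))
        if (any(!is.finite(Db))) stop("degenerate")
        suppressMessages(njTree(Db))
      }, error = function(e) NULL)
      if (is.null(tb)) skipped <- skipped + 1L
      else trees[[length(trees) + 1L]] <- tb
    }
  })
  if (!length(trees)) stop("all bootstrap replicates degenerate")
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree0, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / length(trees)
  tree0$node.label <- as.character(round(support, 1))
  attr(tree0, "skipped") <- skipped
  attr(tree0, "support") <- support
  tree0
}

#' Clade assignment of tree leaves from locus labels
#'
#' Finds maximal monophyletic groups dominated (> 50\%) by one locus label;
#' every leaf inherits its clade's dominant label. Leaves whose own label
#' disagrees with the clade label are flagged as outliers (the analog of
#' copies placed in a clade of another locus); "chrUn" leaves carry no vote
#' and simply inherit the clade label.
#'
#' @param tree an \code{ape} phylo.
#' @param labels named character vector: leaf name -> locus label (possibly
#'   "chrUn").
#' @return data.frame(leaf, label, clade, clade_label, conflict).
#' @export
cladeMembership <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("unlabeled leaves: ",
         paste(setdiff(tips, names(labels)), collapse = ", "))
  labels <- labels[tips]
  nTip <- length(tips)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  leavesUnder <- function(node) {
    if (node <= nTip) return(node)
    unlist(lapply(children[[as.character(node)]], leavesUnder))
  }
  assignment <- rep(NA_character_, nTip)
  cladeId <- rep(NA_integer_, nTip)
  nextId <- 0L
  descend <- function(node) {
    lv <- leavesUnder(node)
    voting <- labels[lv][labels[lv] != "chrUn"]
    if (length(voting)) {
      tab <- sort(table(voting), decreasing = TRUE)
      if (tab[1L] / length(voting) > 0.5 || node <= nTip) {
        nextId <<- nextId + 1L
        assignment[lv] <<- names(tab)[1L]
        cladeId[lv] <<- nextId
        return(invisible())
      }
    } else {
      nextId <<- nextId + 1L
      assignment[lv] <<- "chrUn"
      cladeId[lv] <<- nextId
      return(invisible())
    }
    for (ch in children[[as.character(node)]]) descend(ch)
  }
  descend(nTip + 1L)
  data.frame(leaf = tips, label = unname(labels), clade = cladeId,
             clade_label = assignment,
             conflict = labels != "chrUn" & labels != assignment,
             stringsAsFactors = FALSE)
}

#' Read a codon alignment from FASTA
#'
#' Validates that all rows have equal width, that the width is a multiple of
#' 3, and that gaps occur in whole-codon triplets.
#'
#' @param path FASTA file of aligned sequences.
#' @return a \code{\linkS4class{CodonAlignment}}.
#' @export
readCodonAlignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*", "", names(x))
  new("CodonAlignment", x)
}

#' Write a distance matrix as a PHYLIP-style square matrix
#' @param D distance matrix.
#' @param path output path.
#' @export
writeDistanceMatrix <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(rownames(D)[i], sprintf("%.6f", D[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}
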