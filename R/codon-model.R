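# Goldman-Yang (GY94) codon model machinery shared by the simulator and the
# M7/M8 site-model fitter. States are the 61 sense codons of the standard
# nuclear code; instantaneous rates are zero for multi-nucleotide changes and
# pi_j * {1, kappa, omega, omega*kappa} for synonymous transversions,
# synonymous transitions, nonsynonymous transversions and nonsynonymous
# transitions respectively.

.codonCache <- new.env(parent = emptyenv())

#' Sense codons of the standard nuclear code
#' @return character vector of the 61 non-stop codons.
#' @export
senseCodons <- function() {
  if (is.null(.codonCache$codons))
    .codonCache$codons <- names(GENCODE)[GENCODE != "*"]
  .codonCache$codons
}

# 61x61 integer matrix classifying codon pairs:
# 0 identical or multi-nucleotide change, 1 synonymous transversion,
# 2 synonymous transition, 3 nonsynonymous transversion, 4 nonsynonymous ts.
codonPairType <- function() {
  if (!is.null(.codonCache$pairType)) return(.codonCache$pairType)
  cod <- senseCodons()
  n <- length(cod)
  aa <- GENCODE[cod]
  cm <- do.call(rbind, strsplit(cod, ""))
  isTs <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  type <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    diffs <- t(cm) != cm[i, ]           # 3 x n logical
    ndiff <- colSums(diffs)
    one <- which(ndiff == 1L)
    for (j in one) {
      pos <- which(diffs[, j])
      ts <- isTs(cm[i, pos], cm[j, pos])
      syn <- aa[i] == aa[j]
      type[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
    }
  }
  dimnames(type) <- list(cod, cod)
  .codonCache$pairType <- type
  type
}

# Integer codon-state matrix (rows = sequences, cols = codon sites) from a
# CodonAlignment; gaps and ambiguous codons become NA (missing data).
# Stop codons in the data are an error: they must be cleaned upstream.
codonIndexMatrix <- function(aln) {
  seqs <- as.character(aln)
  cod <- senseCodons()
  nSites <- nchar(seqs[1L]) %/% 3L
  idx <- matrix(NA_integer_, length(seqs), nSites,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    tri <- splitCodons(seqs[i])
    m <- match(tri, cod)
    isStop <- tri %in% stopCodons
    if (any(isStop))
      stop(sprintf("stop codon in sequence '%s' (site %d); clean the alignment first",
                   names(seqs)[i], which(isStop)[1L]))
    idx[i, ] <- m
  }
  idx
}

#' Position-specific (F3x4) codon frequencies
#'
#' Estimates nucleotide frequencies at each codon position from the data and
#' forms codon frequencies as their product over the 61 sense codons,
#' renormalized. Frequencies are floored at 1e-8 to keep the rate matrix
#' irreducible when a nucleotide is absent at some position.
#'
#' @param aln a \code{CodonAlignment} (gaps ignored).
#' @return numeric vector of length 61, named by codon, summing to 1.
#' @export
f3x4Freqs <- function(aln) {
  seqs <- as.character(aln)
  counts <- matrix(0, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (s in seqs) {
    tri <- splitCodons(s)
    tri <- tri[!grepl("-", tri)]
    if (!length(tri)) next
    for (p in 1:3) {
      tb <- table(factor(substr(tri, p, p), levels = c("A", "C", "G", "T")))
      counts[p, ] <- counts[p, ] + as.numeric(tb)
    }
  }
  fr <- counts / pmax(rowSums(counts), 1)
  cod <- senseCodons()
  cm <- do.call(rbind, strsplit(cod, ""))
  pi <- fr[1, cm[, 1]] * fr[2, cm[, 2]] * fr[3, cm[, 3]]
  pi <- pmax(pi, 1e-8)
  pi <- pi / sum(pi)
  names(pi) <- cod
  pi
}

#' Discretize a beta distribution into equal-probability categories
#'
#' The standard CODEML-style discretization: K categories of weight 1/K whose
#' representative omega is the median of each probability slice.
#'
#' @param p,q beta shape parameters (> 0).
#' @param K number of categories.
#' @return numeric vector of K category values in (0, 1).
#' @export
discretizeBeta <- function(p, q, K = 10L) {
  stopifnot(p > 0, q > 0, K >= 1L)
  # extreme shapes explored by the optimizer can trip qbeta's accuracy
  # warning; 1e-4 quantile accuracy is immaterial for category medians
  suppressWarnings(stats::qbeta((seq_len(K) - 0.5) / K, p, q))
}

# omega categories + weights for a site-model parameter list.
omegaCategories <- function(model, K = 10L) {
  type <- toupper(model$type)
  if (type == "M7") {
    list(omega = discretizeBeta(model$p, model$q, K), weight = rep(1 / K, K))
  } else if (type == "M8") {
    stopifnot(model$p0 >= 0, model$p0 <= 1, model$omega_s >= 1)
    list(omega = c(discretizeBeta(model$p, model$q, K), model$omega_s),
         weight = c(rep(model$p0 / K, K), 1 - model$p0))
  } else stop("model$type must be 'M7' or 'M8'")
}

#' GY94 instantaneous rate matrix
#'
#' @param pi codon frequencies (length 61).
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param normalize if TRUE, scale so the expected rate at stationarity is 1
#'   substitution per codon per unit time.
#' @return 61x61 rate matrix with zero row sums.
#' @export
gy94Q <- function(pi, kappa, omega, normalize = TRUE) {
  type <- codonPairType()
  fac <- c(0, 1, kappa, omega, omega * kappa)[type + 1L]
  Q <- matrix(fac, nrow(type), ncol(type)) * rep(pi, each = nrow(type))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    rate <- -sum(pi * diag(Q))
    Q <- Q / rate
  }
  dimnames(Q) <- dimnames(type)
  Q
}

# Eigen machinery for a reversible Q: returns closures computing P(t) and
# P(t) rows, via the symmetrized decomposition A = D^{1/2} Q D^{-1/2}.
gy94Eigen <- function(pi, kappa, omega, normalize = TRUE) {
  Q <- gy94Q(pi, kappa, omega, normalize = normalize)
  sq <- sqrt(pi)
  A <- Q * (sq %o% (1 / sq))
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  U <- e$vectors
  lam <- e$values
  left <- (1 / sq) * U            # D^{-1/2} U
  right <- t(U) * rep(sq, each = ncol(U))  # U' D^{1/2}
  list(
    pmat = function(t) {
      P <- left %*% (exp(lam * t) * right)
      P[P < 0] <- 0
      P
    },
    prow = function(i, t) {
      v <- (left[i, ] * exp(lam * t)) %*% right
      v <- as.numeric(v)
      v[v < 0] <- 0
      v / sum(v)
    }
  )
}

# Prepare tree structures for the C++ pruning routine.
prepTree <- function(tree, tipNames) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  phy <- ape::reorder.phylo(tree, "postorder")
  tipMap <- match(phy$tip.label, tipNames)
  if (anyNA(tipMap))
    stop("tree leaves not present in alignment: ",
         paste(phy$tip.label[is.na(tipMap)], collapse = ", "))
  list(phy = phy, tipMap = tipMap)
}

# Log-likelihood of a codon alignment under a GY94 omega-mixture on a fixed
# tree. `scale` multiplies all branch lengths; categories are normalized by
# the mixture-average rate so branch lengths are expected substitutions per
# codon under the fitted mixture.
mixtureLogLik <- function(idx, weights, phy, tipMap, pi, kappa,
                          omega, catWeight, scale, wantSite = FALSE) {
  tips <- idx[tipMap, , drop = FALSE]
  tips[is.na(tips)] <- 0L            # 0 = missing for C++ (1-based states)
  res <- gy94_loglik_cpp(
    tips, as.numeric(weights),
    phy$edge, phy$edge.length, length(phy$tip.label),
    as.numeric(pi), codonPairType(),
    kappa, as.numeric(omega), as.numeric(catWeight), scale, wantSite)
  res
}
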