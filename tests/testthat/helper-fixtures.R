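# shared fixtures and independent oracles

# balanced 8-leaf tree used by the simulation harnesses (branch lengths in
# expected substitutions per codon under the mixture)
balancedTree8 <- function(len = 0.25) {
  ape::read.tree(text = sprintf(
    "((A:%1$g,B:%1$g):%1$g,(C:%1$g,D:%1$g):%1$g,((E:%1$g,F:%1$g):%1$g,(G:%1$g,H:%1$g):%1$g):%1$g);",
    len))
}

# independent overlap-aware substring scanner (regex lookahead route,
# distinct from the package's explicit all-substrings comparison)
oracleScan <- function(protein, peptide) {
  m <- gregexpr(paste0("(?=", gsub("([^A-Za-z])", "\\\\\\1", peptide), ")"),
                protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m) - 1L
}

# random gliadin-flavoured peptides (QP-rich so epitope hits actually occur)
randomProteins <- function(n, maxLen, seed) {
  aa <- c("Q", "P", "F", "Y", "L", "S", "A", "G", "V", "R")
  wt <- c(8, 8, 3, 3, 3, 1, 1, 1, 1, 1)
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    len <- sample(10:maxLen, 1L)
    paste(sample(aa, len, replace = TRUE, prob = wt), collapse = "")
  }, character(1)))
}

# matrix exponential by scaling-and-squaring of the truncated series
# (independent of the package's eigendecomposition route)
seriesPmat <- function(Q, t) {
  A <- Q * t / 2^10
  P <- diag(nrow(Q)); term <- diag(nrow(Q))
  for (k in 1:20) { term <- term %*% A / k; P <- P + term }
  for (k in 1:10) P <- P %*% P
  P
}

# exhaustive-sum mixture log-likelihood for a 3-leaf star tree
naiveStarLogLik <- function(idx, lens, pi, kappa, omegas, catw, scale) {
  rates <- vapply(omegas, function(w)
    -sum(pi * diag(gy94Q(pi, kappa, w, normalize = FALSE))), numeric(1))
  mr <- sum(catw * rates)
  nSite <- ncol(idx)
  ll <- 0
  for (s in seq_len(nSite)) {
    likc <- numeric(length(omegas))
    for (k in seq_along(omegas)) {
      Q <- gy94Q(pi, kappa, omegas[k], normalize = FALSE)
      Ps <- lapply(lens, function(b) seriesPmat(Q, b * scale / mr))
      tot <- 0
      for (x in 1:61)
        tot <- tot + pi[x] * Ps[[1]][x, idx[1, s]] * Ps[[2]][x, idx[2, s]] *
          Ps[[3]][x, idx[3, s]]
      likc[k] <- tot
    }
    ll <- ll + log(sum(catw * likc))
  }
  ll
}

# small two-sublocus accession on a 200 kb chromosome
smallSimConfig <- function(seed, subRate = 0.02, pseudoProb = 0.3,
                           minusStrandProb = 0,
                           epitopes = data.frame(
                             gene = 1L, name = "DQ2.5-glia-a1a",
                             peptide = "PFPQPQLPY", offsetAA = 24L)) {
  simConfig(
    chromLengths = c(chr6B = 200000),
    loci = data.frame(chrom = "chr6B", anchor = c(20000, 120000),
                      copies = c(5L, 2L), spacing = 2000),
    subRate = subRate, pseudoProb = pseudoProb,
    minusStrandProb = minusStrandProb,
    collapsedGenes = integer(), haplotypeGenes = integer(),
    epitopes = epitopes, seed = seed)
}

templateQuery <- function() {
  Biostrings::DNAStringSet(c(template = gliadinTemplateCDS()))
}

# scan the translated truth CDS set: the generator-side epitope oracle
truthEpitopeHits <- function(truth, table = defaultEpitopeTable()) {
  prot <- vapply(truth$cds, function(x)
    chartr("*", "X", gliascan:::translateCDS(x)), character(1))
  names(prot) <- truth$gene_id
  scanEpitopes(prot, table)
}
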