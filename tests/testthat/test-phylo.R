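test_that("codon-aware alignment handles identity, deletions and frameshifts", {
  tpl <- gliadinTemplateCDS()
  a2 <- alignCodons(c(x = tpl, y = tpl))
  expect_false(any(grepl("-", as.character(a2))))
  expect_equal(Biostrings::width(a2)[1], nchar(tpl))

  # a 3-nt in-frame deletion gives exactly one codon gap triple
  del <- paste0(substr(tpl, 1, 150), substr(tpl, 154, nchar(tpl)))
  ad <- alignCodons(c(full = tpl, del = del))
  rows <- as.character(ad)
  expect_equal(Biostrings::width(ad)[1] %% 3, 0)
  gapRuns <- gregexpr("-+", rows[["del"]])[[1]]
  expect_equal(length(gapRuns), 1L)
  expect_equal(attr(gapRuns, "match.length"), 3L)
  expect_false(grepl("-", rows[["full"]]))

  expect_error(alignCodons(c(bad = paste(rep("A", 100), collapse = ""))),
               "multiple of 3")
})

test_that("K2P matches its closed form and ape's implementation", {
  # P = 0.2, Q = 0.1 by construction
  a <- paste(rep("A", 120), collapse = "")
  b <- paste(c(rep("G", 24), rep("C", 12), rep("A", 84)), collapse = "")
  aln <- Biostrings::DNAStringSet(c(x = a, y = b))
  D <- k2pDistance(aln, alpha = Inf)
  expect_equal(round(D[1, 2], 4), 0.4024)
  expect_equal(D[1, 2], -0.5 * log(1 - 2 * 0.2 - 0.1) - 0.25 * log(1 - 2 * 0.1))

  # identical rows -> 0
  same <- Biostrings::DNAStringSet(c(x = a, y = a))
  expect_equal(k2pDistance(same, alpha = 2.25)[1, 2], 0)

  # gamma correction converges to plain K2P and grows as alpha decreases
  expect_lt(abs(k2pDistance(aln, alpha = 1e6)[1, 2] - D[1, 2]), 1e-4)
  alphas <- c(10, 5, 2.25, 1, 0.5)
  ds <- vapply(alphas, function(al) k2pDistance(aln, alpha = al)[1, 2],
               numeric(1))
  expect_true(all(diff(ds) > 0))

  # cross-check against the independent reference implementation
  tr <- balancedTree8()
  sim <- simulateCodonAlignment(tr, list(type = "M7", p = 2, q = 5), 80,
                                seed = 3)
  Dg <- k2pDistance(sim$alignment, alpha = 2.25, deletion = "pairwise")
  bin <- ape::as.DNAbin(as(sim$alignment, "DNAStringSet"))
  Dape <- as.matrix(ape::dist.dna(bin, model = "K80", gamma = 2.25,
                                  pairwise.deletion = TRUE))
  expect_equal(unname(Dg), unname(Dape[rownames(Dg), colnames(Dg)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("distance outputs satisfy the metric axioms and flag saturation", {
  tr <- balancedTree8()
  sim <- simulateCodonAlignment(tr, list(type = "M7", p = 2, q = 5), 60,
                                seed = 10)
  D <- k2pDistance(sim$alignment, alpha = 2.25)
  expect_true(all(D >= 0))
  expect_equal(diag(D), setNames(rep(0, nrow(D)), rownames(D)))
  expect_lt(max(abs(D - t(D))), 1e-12)

  # saturated pair: complementary sequences exceed the log domain
  sat <- Biostrings::DNAStringSet(c(x = "ACGTACGTACGT", y = "TGCATGCATGCA"))
  Ds <- k2pDistance(sat, alpha = Inf, ceiling = 5)
  expect_equal(Ds[1, 2], 5)
  expect_true(attr(Ds, "flagged")[1, 2])
})

test_that("NJ recovers additive trees exactly", {
  # fixed 4-taxon additive matrix from ((A:1,B:2):1,(C:3,D:4))
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(tr)
  out <- njTree(D)
  Dout <- ape::cophenetic.phylo(out)[rownames(D), colnames(D)]
  expect_lt(max(abs(Dout - D)), 1e-9)

  # 3 taxa: three-point formulas
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(D3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  # identical leaves -> zero-length cherry
  D0 <- matrix(c(0, 0, 2, 2, 0, 0, 2, 2, 2, 2, 0, 1, 2, 2, 1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  t0 <- suppressMessages(njTree(D0))
  cherry <- t0$edge[, 2] %in% which(t0$tip.label %in% c("a", "b"))
  expect_true(all(t0$edge.length[cherry] == 0))

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- matrix(runif(16), 4, 4); diag(bad) <- 0
  expect_error(njTree(bad), "symmetric")
})

test_that("bootstrap supports are deterministic, bounded and saturate for clean splits", {
  # two maximally separated 4-leaf clades: within-clade identical sequences,
  # every codon column carries the split signal
  blockA <- paste(rep("ATTGCT", 30), collapse = "")
  blockB <- paste(rep("GCAACG", 30), collapse = "")
  aln <- new("CodonAlignment", Biostrings::DNAStringSet(
    c(a1 = blockA, a2 = blockA,
      a3 = gsub("^ATT", "ATC", blockA), a4 = gsub("GCT$", "GCC", blockA),
      b1 = blockB, b2 = blockB,
      b3 = gsub("^GCA", "GCG", blockB), b4 = gsub("ACG$", "ACA", blockB))))
  tr <- bootstrapSupport(aln, B = 100, alpha = Inf, seed = 2)
  sup <- attr(tr, "support")
  # the central bipartition is present in every replicate
  expect_true(any(sup == 100))

  tr2 <- bootstrapSupport(aln, B = 100, alpha = Inf, seed = 2)
  expect_identical(attr(tr, "support"), attr(tr2, "support"))

  tr1 <- bootstrapSupport(aln, B = 1, alpha = Inf, seed = 5)
  expect_true(all(attr(tr1, "support") %in% c(0, 100)))
})

test_that("bootstrap support is invariant under consistent leaf relabeling", {
  trs <- balancedTree8()
  sim <- simulateCodonAlignment(trs, list(type = "M7", p = 2, q = 5), 60,
                                seed = 14)
  aln <- sim$alignment
  t1 <- bootstrapSupport(aln, B = 30, alpha = 2.25, seed = 8)
  perm <- setNames(paste0("x", seq_len(8)), names(aln))
  aln2 <- aln
  names(aln2) <- unname(perm[names(aln)])
  t2 <- bootstrapSupport(aln2, B = 30, alpha = 2.25, seed = 8)
  t2$tip.label <- names(perm)[match(t2$tip.label, perm)]
  # same topology, same supports on matching bipartitions
  counts <- ape::prop.clades(t1, t2, rooted = FALSE)
  expect_equal(sort(attr(t1, "support")), sort(attr(t2, "support")))
  expect_true(all(counts == 1, na.rm = TRUE))
})

test_that("clade membership flags locus outliers and absorbs chrUn leaves", {
  txt <- "(((a1:1,a2:1):1,(a3:1,a4:1):1):2,((b1:1,b2:1):1,(b3:1,b4:1):1):2,((d1:1,d2:1):1,(d3:1,d4:1):1):2);"
  tr <- ape::read.tree(text = txt)
  labs <- c(a1 = "Gli-A2", a2 = "Gli-A2", a3 = "Gli-A2", a4 = "Gli-A2",
            b1 = "Gli-B2", b2 = "Gli-B2", b3 = "Gli-B2", b4 = "Gli-B2",
            d1 = "Gli-D2", d2 = "Gli-D2", d3 = "Gli-D2", d4 = "Gli-D2")
  res <- cladeMembership(tr, labs)
  expect_false(any(res$conflict))
  expect_equal(length(unique(res$clade)), 3L)

  # one Gli-D2-labeled leaf inside the B clade is exactly the flagged one
  labs2 <- labs; labs2["b4"] <- "Gli-D2"
  res2 <- cladeMembership(tr, labs2)
  expect_equal(res2$leaf[res2$conflict], "b4")
  expect_equal(res2$clade_label[res2$leaf == "b4"], "Gli-B2")

  # a chrUn leaf inherits the clade of its neighbours
  labs3 <- labs; labs3["a4"] <- "chrUn"
  res3 <- cladeMembership(tr, labs3)
  expect_equal(res3$clade_label[res3$leaf == "a4"], "Gli-A2")
  expect_false(res3$conflict[res3$leaf == "a4"])

  expect_error(cladeMembership(tr, labs[-1]), "a1")
})
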