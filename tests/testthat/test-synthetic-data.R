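test_that("generator plants the configured copies with matching truth", {
  cfg <- smallSimConfig(seed = 7)
  sim <- generateAssembly(cfg)
  expect_equal(nrow(sim$truth), 7L)
  expect_equal(sort(unique(sim$truth$sublocus)), c("S1", "S2"))
  expect_equal(as.numeric(table(sim$truth$sublocus)), c(5, 2))
  # planted sequence sits at the truth coordinates
  for (i in seq_len(nrow(sim$truth))) {
    tt <- sim$truth[i, ]
    seg <- as.character(Biostrings::subseq(sim$assembly[[tt$chrom]],
                                           tt$start + 1L, tt$end))
    expect_identical(seg, tt$cds)
  }
  # intervals are non-overlapping and 0-based half-open
  expect_true(all(sim$truth$start < sim$truth$end))
})

test_that("identical config and seed give byte-identical artifacts", {
  cfg <- smallSimConfig(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(generateAssembly(cfg), d1)
  writeSimulation(generateAssembly(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("zero mutation and zero pseudogenization reproduce the template", {
  cfg <- smallSimConfig(seed = 3, subRate = 0, pseudoProb = 0,
                        epitopes = data.frame(gene = integer(),
                                              name = character(),
                                              peptide = character(),
                                              offsetAA = integer()))
  sim <- generateAssembly(cfg)
  expect_true(all(sim$truth$cds == gliadinTemplateCDS()))
  expect_true(all(sim$truth$intact_orf))
})

test_that("pseudogenized copies carry exactly one disruption type", {
  cfg <- smallSimConfig(seed = 19, subRate = 0, pseudoProb = 1)
  sim <- generateAssembly(cfg)
  expect_true(all(!sim$truth$intact_orf))
  tpl <- gliadinTemplateCDS()
  for (cds in sim$truth$cds) {
    cod <- gliascan:::splitCodons(cds)
    lostATG <- substr(cds, 1, 3) != "ATG"
    internalStop <- any(cod[-length(cod)] %in% gliascan:::stopCodons)
    indel <- nchar(cds) != nchar(tpl)
    if (indel) {
      # a 1-2 bp indel shifts the frame; downstream stops are a consequence
      expect_false(lostATG)
      expect_true(abs(nchar(cds) - nchar(tpl)) %in% 1:2)
    } else {
      expect_equal(sum(lostATG, internalStop), 1L)
    }
  }
})

test_that("overlapping planted intervals are rejected naming the genes", {
  cfg <- simConfig(chromLengths = c(chr6B = 50000),
                   loci = data.frame(chrom = "chr6B", anchor = c(10000, 10100),
                                     copies = c(1L, 1L), spacing = 1000),
                   collapsedGenes = integer(), haplotypeGenes = integer(),
                   epitopes = data.frame(gene = integer(), name = character(),
                                         peptide = character(),
                                         offsetAA = integer()),
                   seed = 1)
  expect_error(generateAssembly(cfg), "overlap.*g001.*g002")
})

test_that("anchors outside the chromosome are rejected", {
  expect_error(
    simConfig(chromLengths = c(chr6B = 1000),
              loci = data.frame(chrom = "chr6B", anchor = 5000, copies = 1L,
                                spacing = 100),
              seed = 1),
    "strictly inside")
})

test_that("planted epitopes are retrievable from the translated truth CDS", {
  cfg <- simConfig(seed = 23)   # default accession: a1a, a3, 33mer, a2 planted
  sim <- generateAssembly(cfg)
  for (i in which(nzchar(sim$truth$epitopes))) {
    tt <- sim$truth[i, ]
    prot <- gliascan:::translateCDS(tt$cds)
    for (nm in strsplit(tt$epitopes, ",")[[1]]) {
      pep <- defaultEpitopeTable()$peptide[defaultEpitopeTable()$name == nm]
      expect_true(grepl(pep, prot, fixed = TRUE),
                  label = sprintf("%s in %s", nm, tt$gene_id))
    }
  }
})

test_that("depth table reflects copy status with exact zero-noise limits", {
  truth <- data.frame(gene_id = sprintf("g%02d", 1:12),
                      copy_status = c(rep("normal", 10), "collapsed",
                                      "haplotype_specific"))
  d <- simulateDepthTable(truth, medianCov = 32.23, noiseSd = 0, seed = 1)
  expect_equal(d$mean_depth[1:10], rep(32.23, 10))
  expect_equal(d$mean_depth[11], 64.46)
  expect_equal(d$mean_depth[12], 16.115)
  d2 <- simulateDepthTable(truth, medianCov = 32.23, noiseSd = 3, seed = 9)
  d3 <- simulateDepthTable(truth, medianCov = 32.23, noiseSd = 3, seed = 9)
  expect_identical(d2, d3)
})

test_that("codon simulator respects model constraints and determinism", {
  tr <- balancedTree8()
  s1 <- simulateCodonAlignment(tr, list(type = "M7", p = 2, q = 5), 50, seed = 4)
  expect_length(s1$class, 50)
  expect_true(all(s1$class == "beta"))
  expect_true(all(s1$omega < 1))           # M7 forbids omega > 1
  # no stop codons can be emitted
  for (s in as.character(s1$alignment))
    expect_false(any(gliascan:::splitCodons(s) %in% gliascan:::stopCodons))
  s2 <- simulateCodonAlignment(tr, list(type = "M7", p = 2, q = 5), 50, seed = 4)
  expect_identical(as.character(s1$alignment), as.character(s2$alignment))
  # zero branch lengths: no evolution
  tr0 <- tr; tr0$edge.length[] <- 0
  s0 <- simulateCodonAlignment(tr0, list(type = "M7", p = 2, q = 5), 30, seed = 5)
  expect_length(unique(as.character(s0$alignment)), 1L)
  expect_error(simulateCodonAlignment(tr, list(type = "M7", p = 2, q = 5),
                                      0, seed = 1), "nSites")
  trNoLen <- ape::rtree(4); trNoLen$edge.length <- NULL
  expect_error(simulateCodonAlignment(trNoLen, list(type = "M7", p = 2, q = 5),
                                      10, seed = 1), "branch lengths")
})

test_that("M8 selected-class frequency matches the mixture weight", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  n <- 0L; sel <- 0L
  for (seed in 1:4) {
    s <- simulateCodonAlignment(
      tr, list(type = "M8", p0 = 0.9, p = 0.5, q = 2, omega_s = 3),
      500, seed = seed)
    n <- n + 500L
    sel <- sel + sum(s$class == "omega_s")
    expect_true(all(s$omega[s$class == "omega_s"] == 3))
    expect_true(all(s$omega[s$class == "beta"] < 1))
  }
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(sel / n - 0.1), 3 * se + 1e-12)
})
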