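test_that("alignment cleanup drops rule-violating rows and masks polyglutamine", {
  tpl <- gliadinTemplateCDS()          # ends in TAA, has a 12-Q and a 9-Q run
  stopRow <- paste0(substr(tpl, 1, 90), "TAA", substr(tpl, 94, nchar(tpl)))
  noStop <- paste0(substr(tpl, 1, nchar(tpl) - 3), "CAA")
  aln <- alignCodons(c(s1 = tpl, s2 = tpl, s3 = tpl, s4 = noStop, s5 = tpl))
  # inject the premature stop after alignment so alignCodons accepts input
  rows <- as.character(aln)
  rows["s2"] <- paste0(substr(rows["s2"], 1, 90), "TAA",
                       substr(rows["s2"], 94, nchar(rows["s2"])))
  aln <- new("CodonAlignment", Biostrings::DNAStringSet(rows))
  prep <- prepareSelectionAlignment(aln)
  expect_setequal(prep$report$rows$id, c("s2", "s4"))
  expect_setequal(prep$report$rows$reason, c("premature stop", "no terminal stop"))
  expect_false("s2" %in% names(prep$alignment))

  # the 12-codon glutamine run is masked; the 9-codon run too (>= 8)
  expect_gte(length(prep$report$maskedColumns), 20L)
  # masked columns translate to >= 75% Q/P
  orig <- gliascan:::splitCodons(tpl)
  for (j in prep$report$maskedColumns[1:5]) {
    aa <- gliascan:::GENCODE[orig[j]]
    expect_true(aa %in% c("Q", "P"))
  }
})

test_that("clean gap-free alignments pass through untouched", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  sim <- simulateCodonAlignment(tr, list(type = "M7", p = 2, q = 5), 60,
                                seed = 2)
  prep <- prepareSelectionAlignment(sim$alignment, requireTerminalStop = FALSE)
  expect_equal(as.character(prep$alignment), as.character(sim$alignment))
  expect_equal(nrow(prep$report$rows), 0L)
  expect_length(prep$report$maskedColumns, 0L)
})

test_that("the GY94 generator is time-reversible with unit-rate normalization", {
  withr::with_seed(6, {
    pi <- runif(61, 0.5, 2); pi <- pi / sum(pi)
  })
  Q <- gy94Q(pi, kappa = 3.1, omega = 0.7)
  expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)   # pi_i q_ij = pi_j q_ji
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1)
  # transition matrices are stochastic
  P <- gliascan:::gy94Eigen(pi, 3.1, 0.7)$pmat(0.3)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0))
})

test_that("M7 fit recovers simulated data within the likelihood envelope", {
  tr <- balancedTree8()
  sim <- simulateCodonAlignment(tr, list(type = "M7", p = 2, q = 5), 300,
                                seed = 17)
  fit <- fitSiteModel(sim$alignment, tr, "M7", starts = 2, seed = 1)
  expect_true(fit@diagnostics$converged)
  # log-likelihood at the generating parameters (same K=10 family)
  idx <- gliascan:::codonIndexMatrix(sim$alignment)
  pt <- gliascan:::prepTree(tr, rownames(idx))
  cats <- gliascan:::omegaCategories(list(type = "M7", p = 2, q = 5), 10L)
  llTrue <- gliascan:::mixtureLogLik(idx, rep(1, ncol(idx)), pt$phy, pt$tipMap,
                                     fit@freqs, 2, cats$omega, cats$weight,
                                     1)$loglik
  expect_gte(fit@logLik, llTrue - 1e-6)   # MLE dominates the true point
  expect_lt(fit@logLik - llTrue, 10)      # and does not run away
  # the beta shapes are weakly identified jointly, but their mean
  # E[omega] = p/(p+q) is: it must land near the generating 2/7
  meanW <- fit@params[["p"]] / (fit@params[["p"]] + fit@params[["q"]])
  expect_lt(abs(meanW - 2 / 7), 0.15)
  expect_true(all(is.finite(fit@params)))
})

test_that("M8 nests M7: warm-started M8 never loses likelihood", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);")
  sim <- simulateCodonAlignment(tr, list(type = "M7", p = 1, q = 3), 80,
                                seed = 23)
  f7 <- fitSiteModel(sim$alignment, tr, "M7", starts = 1, seed = 1)
  f8 <- fitSiteModel(sim$alignment, tr, "M8", starts = 1, seed = 1,
                     init = f7@params)
  expect_gte(f8@logLik, f7@logLik - 1e-4)
  lrt <- lrtM7M8(f7, f8)
  expect_gte(lrt$statistic, 0)
})

test_that("identical sequences drive the tree scale to its boundary", {
  one <- paste(rep("ATGGCTCAA", 10), collapse = "")
  aln <- new("CodonAlignment", Biostrings::DNAStringSet(
    c(A = one, B = one, C = one)))
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  fit <- fitSiteModel(aln, tr, "M7", starts = 1, seed = 1)
  expect_equal(fit@params[["scale"]], 1e-4, tolerance = 1e-6)
  expect_true("scale" %in% fit@diagnostics$boundary)
})

test_that("LRT arithmetic follows the chi-squared(2) convention", {
  mkFit <- function(model, ll) new("SiteModelFit", model = model,
    params = c(kappa = 2), logLik = ll, catOmega = 0.5, catWeight = 1,
    freqs = rep(1 / 61, 61), siteCatLogLik = matrix(0, 1, 1),
    diagnostics = list(converged = TRUE, dataHash = "abc"))
  lrt <- lrtM7M8(mkFit("M7", -1000), mkFit("M8", -995))
  expect_equal(lrt$statistic, 10)
  expect_equal(lrt$p_value, pchisq(10, 2, lower.tail = FALSE))
  expect_equal(round(lrt$p_value, 4), 0.0067)

  eq <- lrtM7M8(mkFit("M7", -1000), mkFit("M8", -1000))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  num <- lrtM7M8(mkFit("M7", -1000), mkFit("M8", -1000 - 1e-6))
  expect_equal(num$statistic, 0)
  expect_true(num$clamped)

  bad8 <- mkFit("M8", -995)
  bad8@diagnostics$dataHash <- "zzz"
  expect_error(lrtM7M8(mkFit("M7", -1000), bad8), "different data")
})

test_that("site posteriors are proper probabilities and vanish when p0 = 1", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);")
  sim <- simulateCodonAlignment(
    tr, list(type = "M8", p0 = 0.8, p = 0.5, q = 2, omega_s = 4), 100,
    seed = 31)
  f8 <- fitSiteModel(sim$alignment, tr, "M8", starts = 2, seed = 3)
  sp <- sitePosteriors(f8)
  expect_true(all(sp$posterior >= 0 & sp$posterior <= 1))
  expect_equal(sp$significant, sp$posterior > 0.95)

  # full responsibility matrix rows sum to 1
  lw <- log(f8@catWeight[f8@catWeight > 0])
  lp <- sweep(f8@siteCatLogLik[, f8@catWeight > 0, drop = FALSE], 2, lw, "+")
  pr <- exp(lp - apply(lp, 1, max))
  pr <- pr / rowSums(pr)
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-8)

  # a degenerate selected class gets zero posterior everywhere
  zero <- gliascan:::sitePosteriorFromCats(f8@siteCatLogLik,
                                           c(rep(0.1, 10), 0),
                                           f8@catOmega)
  expect_true(all(zero == 0))
})

test_that("coarse-grid BEB agrees with NEB on strong signal sites", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);")
  sim <- simulateCodonAlignment(
    tr, list(type = "M8", p0 = 0.8, p = 0.5, q = 2, omega_s = 4), 60,
    seed = 37)
  f8 <- fitSiteModel(sim$alignment, tr, "M8", starts = 1, seed = 3)
  neb <- sitePosteriors(f8)
  beb <- sitePosteriors(f8, method = "BEB-grid", aln = sim$alignment, tree = tr)
  # rank agreement on the clearest sites
  top <- order(-neb$posterior)[1:5]
  expect_gt(mean(beb$posterior[top]), mean(beb$posterior))
})
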