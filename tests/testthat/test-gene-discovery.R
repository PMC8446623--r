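test_that("an exact embedded copy is found with identity 1 at exact coordinates", {
  q <- gliadinTemplateCDS()           # 504 bp
  withr::with_seed(99, {
    bg <- gliascan:::randomDNA(30000)
  })
  asm <- Biostrings::DNAStringSet(
    c(chr1 = paste0(substr(bg, 1, 10000), q,
                    substr(bg, 10001 + nchar(q), 30000))))
  cand <- findCandidates(asm, templateQuery(), minIdentity = 0.9, minLen = 300)
  df <- as.data.frame(cand)
  expect_equal(nrow(df), 1L)
  expect_equal(df$start, 10000)       # 0-based half-open
  expect_equal(df$end, 10000 + nchar(q))
  expect_equal(df$strand, "+")
  expect_equal(df$identity, 1.0)
})

test_that("synthetic assembly recovery: intervals equal truth exactly", {
  cfg <- smallSimConfig(seed = 7)
  sim <- generateAssembly(cfg)
  cand <- findCandidates(sim$assembly, templateQuery(), minIdentity = 0.9,
                         minLen = 300)
  df <- as.data.frame(cand)
  tt <- sim$truth[order(sim$truth$start), ]
  expect_equal(nrow(df), nrow(tt))
  expect_equal(df$start, tt$start)
  expect_equal(df$end, tt$end)
  expect_equal(df$strand, tt$strand)
  expect_equal(df$cds, tt$cds)
})

test_that("pure random background yields no candidates", {
  withr::with_seed(5, {
    asm <- Biostrings::DNAStringSet(c(chr1 = gliascan:::randomDNA(100000)))
  })
  cand <- findCandidates(asm, templateQuery(), minIdentity = 0.9, minLen = 300)
  expect_equal(length(cand), 0L)
  # brute-force confirmation: no window within mismatch budget
  q <- Biostrings::DNAString(gliadinTemplateCDS())
  mm <- floor(0.1 * length(q))
  hits <- Biostrings::matchPattern(q, asm[[1]], max.mismatch = mm)
  expect_equal(length(hits), 0L)
})

test_that("find agrees with a brute-force window scan on small assemblies", {
  # ungapped world: every ~>=90% identity window found by enumerating all
  # offsets via matchPattern must be reported, and vice versa
  cfg <- smallSimConfig(seed = 13, subRate = 0.03, pseudoProb = 0)
  sim <- generateAssembly(cfg)
  q <- Biostrings::DNAString(gliadinTemplateCDS())
  mm <- floor(0.1 * length(q))
  oracle <- Biostrings::matchPattern(q, sim$assembly[[1]], max.mismatch = mm)
  cand <- findCandidates(sim$assembly, templateQuery(), minIdentity = 0.9,
                         minLen = 300)
  df <- as.data.frame(cand)
  expect_setequal(df$start, BiocGenerics::start(oracle) - 1L)
  expect_setequal(df$end, BiocGenerics::end(oracle))
})

test_that("reverse-complementing the assembly mirrors coordinates and strand", {
  cfg <- smallSimConfig(seed = 21)
  sim <- generateAssembly(cfg)
  L <- length(sim$assembly[[1]])
  rcAsm <- Biostrings::DNAStringSet(
    stats::setNames(as.character(Biostrings::reverseComplement(sim$assembly[[1]])),
                    "chr6B"))
  fw <- as.data.frame(findCandidates(sim$assembly, templateQuery()))
  rv <- as.data.frame(findCandidates(rcAsm, templateQuery()))
  expect_equal(nrow(fw), nrow(rv))
  rv <- rv[order(-rv$start), ]
  expect_equal(L - rv$end, fw$start)
  expect_equal(L - rv$start, fw$end)
  expect_true(all(rv$strand == "-"))
  expect_equal(rv$cds, fw$cds)        # forward-coding orientation preserved
})

test_that("minus-strand planted genes are recovered in coding orientation", {
  cfg <- smallSimConfig(seed = 31, minusStrandProb = 1)
  sim <- generateAssembly(cfg)
  expect_true(all(sim$truth$strand == "-"))
  df <- as.data.frame(findCandidates(sim$assembly, templateQuery()))
  tt <- sim$truth[order(sim$truth$start), ]
  expect_equal(df$start, tt$start)
  expect_equal(df$end, tt$end)
  expect_true(all(df$strand == "-"))
  expect_equal(df$cds, tt$cds)
})

test_that("ORF flags follow the translation rules", {
  mk <- function(cds) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, nchar(cds)), "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = "g", query_id = "q", identity = 1, score = 1,
      starts_with_met = NA, has_internal_stop = NA, has_terminal_stop = NA,
      frameshifted = NA, divergent = NA)
    cd <- Biostrings::DNAStringSet(cds); names(cd) <- "g"
    pr <- Biostrings::AAStringSet(""); names(pr) <- "g"
    classifyOrf(new("GeneCandidates", ranges = gr, cds = cd, protein = pr))
  }
  flags <- function(x) as.data.frame(S4Vectors::mcols(candidateRanges(x)))

  a <- mk("ATGCAATAG")
  expect_equal(as.character(candidateProteins(a)[[1]]), "MQ")
  f <- flags(a)
  expect_true(f$starts_with_met); expect_true(f$has_terminal_stop)
  expect_false(f$has_internal_stop); expect_false(f$frameshifted)

  b <- flags(mk("ATGTAACAATAG"))
  expect_true(b$has_internal_stop)

  cc <- flags(mk("ATGCAAA"))
  expect_true(cc$frameshifted)

  d <- flags(mk("CTGCAATAG"))
  expect_false(d$starts_with_met)
})

test_that("divergence filter separates paralogs by protein p-distance", {
  q <- templateQuery()
  cfg <- smallSimConfig(seed = 17, subRate = 0.02, pseudoProb = 0)
  sim <- generateAssembly(cfg)
  cand <- findCandidates(sim$assembly, q)
  flt <- filterDivergent(cand, q, maxPdist = 0.35)
  expect_equal(length(flt$kept), length(cand))   # 2% divergence all kept
  expect_equal(length(flt$discarded), 0L)

  # a candidate with ~50% mismatching residues is discarded at 0.35
  tpl <- gliadinTemplateCDS()
  prot <- gliascan:::translateCDS(tpl)
  half <- paste0(substr(tpl, 1, 3),
                 paste(rep("GGTTGGGGTTGG", 100), collapse = ""))
  half <- substr(half, 1, nchar(tpl) - 3)
  half <- paste0(half, "TAA")
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, nchar(half)), "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = "far", query_id = "q", identity = 1, score = 1,
    starts_with_met = NA, has_internal_stop = NA, has_terminal_stop = NA,
    frameshifted = NA, divergent = NA)
  cd <- Biostrings::DNAStringSet(half); names(cd) <- "far"
  bad <- classifyOrf(new("GeneCandidates", ranges = gr, cds = cd,
                         protein = Biostrings::AAStringSet("")))
  flt2 <- filterDivergent(bad, q, maxPdist = 0.35)
  expect_equal(length(flt2$discarded), 1L)
  expect_equal(flt2$reasons, "divergent")
})

test_that("non-ACGT queries and empty assemblies are handled", {
  expect_error(findCandidates(Biostrings::DNAStringSet(c(chr = "ACGT")),
                              Biostrings::DNAStringSet(c(bad = "ACGN"))),
               "bad")
  empty <- findCandidates(Biostrings::DNAStringSet(), templateQuery())
  expect_equal(length(empty), 0L)
})
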