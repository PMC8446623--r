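# Synthetic accession generator: chromosomes carrying tandem arrays of
# gliadin-like single-exon genes at known positions, with a per-site
# substitution process, pseudogenization, planted epitopes, and copy-status
# flags that only the depth simulator sees (collapsed copies are coverage
# evidence, not duplicated sequence). Background sequence is i.i.d. uniform
# ACGT: homology search must key on the planted genes, not background realism.

# fixed back-translation table (one common codon per amino acid)
.AA2CODON <- c(
  A = "GCT", R = "CGT", N = "AAC", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAC", I = "ATT", L = "CTT", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAC", V = "GTT", `*` = "TAA")

backTranslate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(.AA2CODON))
  if (length(bad)) stop("cannot back-translate residues: ", paste(bad, collapse = ","))
  paste(.AA2CODON[aa], collapse = "")
}

#' Gliadin-like template CDS
#'
#' A deterministic single-exon CDS with the domain architecture of an
#' alpha-gliadin: signal peptide, repetitive domain, polyglutamine run,
#' unique domain I, a second glutamine run, unique domain II and a C-terminal
#' segment, ending in a stop codon. The repetitive domain deliberately
#' contains no canonical CD epitope, so that epitope content is entirely
#' controlled by the planting specification.
#'
#' @return character CDS (length a multiple of 3, starts ATG, ends TAA).
#' @export
gliadinTemplateCDS <- function() {
  protein <- paste0(
    "MKTFLILALLAIVATTATTA",                      # signal peptide
    strrep("QPQNFPSQQPYA", 3L),                  # repetitive domain (epitope-free)
    strrep("Q", 12L),                            # polyglutamine I
    "VLQQSTYELLQELCCQHLWGIPEDSRCEAIHNVVHAIILH",  # unique domain I
    strrep("Q", 9L),                             # polyglutamine II
    "SEVLRDALSATYEVGIDAMGRVYELTNKLVTMECKHIFAG",  # unique domain II
    "SVDLMRRELS",                                # C-terminal
    "*")
  backTranslate(protein)
}

# default epitope plantings for the bundled synthetic accession: DQ2.5-glia
# 9-mers in the A-subgenome array, the immunotoxic 33-mer in a D-subgenome
# copy (the D-specific pattern seen in bread wheat).
defaultEpitopePlanting <- function() {
  data.frame(
    gene = c(1L, 2L, 10L, 11L),
    name = c("DQ2.5-glia-a1a", "DQ2.5-glia-a3", "33mer", "DQ2.5-glia-a2"),
    peptide = c("PFPQPQLPY", "FRPQQPYPQ",
                "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF", "PQPQLPYPQ"),
    offsetAA = c(24L, 24L, 21L, 24L),
    stringsAsFactors = FALSE)
}

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale hexaploid accession: three 12-Mb group-6
#' chromosomes, a single gliadin array on 6A and 6D, and a bipartite 6B locus
#' whose two subloci sit 7 Mb apart (the sublocus separation regime reported
#' for real accessions, at reduced chromosome scale). Copies diverge from the
#' template at 2\% per site; roughly a third are pseudogenized, matching the
#' intact/total copy ratios seen in real assemblies.
#'
#' @param chromLengths named chromosome lengths (bp).
#' @param loci data.frame(chrom, anchor, copies, spacing): sublocus anchors
#'   (1-based bp position of the first copy), copy counts and inter-copy
#'   spacing.
#' @param template base gene CDS.
#' @param subRate per-site substitution probability per copy.
#' @param pseudoProb pseudogenization probability per copy.
#' @param minusStrandProb probability a copy is planted on the minus strand.
#' @param collapsedGenes,haplotypeGenes planting-order indices flagged for
#'   2x / 0.5x expected read depth.
#' @param epitopes data.frame(gene, name, peptide, offsetAA) of planted
#'   epitopes.
#' @param seed mandatory integer seed.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
simConfig <- function(chromLengths = c(chr6A = 12e6, chr6B = 12e6, chr6D = 12e6),
                      loci = data.frame(
                        chrom = c("chr6A", "chr6B", "chr6B", "chr6D"),
                        anchor = c(3.0e6, 2.0e6, 9.0e6, 3.0e6),
                        copies = c(4L, 3L, 2L, 3L),
                        spacing = 3000,
                        stringsAsFactors = FALSE),
                      template = gliadinTemplateCDS(),
                      subRate = 0.02,
                      pseudoProb = 0.35,
                      minusStrandProb = 0,
                      collapsedGenes = 5L,
                      haplotypeGenes = 9L,
                      epitopes = defaultEpitopePlanting(),
                      seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimConfig", chromLengths = chromLengths, loci = loci,
      template = template, subRate = subRate, pseudoProb = pseudoProb,
      minusStrandProb = minusStrandProb,
      collapsedGenes = as.integer(collapsedGenes),
      haplotypeGenes = as.integer(haplotypeGenes),
      epitopes = epitopes, seed = as.integer(seed))
}

# substitute each site independently with probability `rate`
mutateSeq <- function(cds, rate) {
  if (rate <= 0) return(cds)
  chars <- strsplit(cds, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      alt <- bases[bases != chars[i]]
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(chars, collapse = "")
}

# overwrite codons with the back-translated epitope at a 0-based aa offset
plantEpitope <- function(cds, peptide, offsetAA) {
  epiCDS <- backTranslate(peptide)
  from <- 3L * offsetAA + 1L
  to <- from + nchar(epiCDS) - 1L
  if (to > nchar(cds) - 3L)
    stop("epitope does not fit inside the CDS at offset ", offsetAA)
  paste0(substr(cds, 1L, from - 1L), epiCDS, substr(cds, to + 1L, nchar(cds)))
}

# pseudogenize by exactly one of: lost start codon, internal premature stop,
# or a 1-2 bp indel; disruptions avoid planted epitope codons.
pseudogenize <- function(cds, protectAA) {
  mode <- sample(c("lost_atg", "internal_stop", "indel"), 1L)
  nCod <- nchar(cds) %/% 3L
  eligible <- setdiff(6:(nCod - 2L), protectAA + 1L)
  if (mode == "lost_atg") {
    cds <- paste0("CTG", substr(cds, 4L, nchar(cds)))
  } else if (mode == "internal_stop") {
    i <- eligible[sample.int(length(eligible), 1L)]
    cds <- paste0(substr(cds, 1L, 3L * (i - 1L)), "TAA",
                  substr(cds, 3L * i + 1L, nchar(cds)))
  } else {
    minPos <- 3L * (if (length(protectAA)) max(protectAA) + 1L else 5L) + 1L
    pos <- sample(seq(minPos, nchar(cds) - 6L), 1L)
    k <- sample(1:2, 1L)
    if (stats::runif(1) < 0.5) {
      cds <- paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + k, nchar(cds)))
    } else {
      ins <- paste(c("A", "C", "G", "T")[sample.int(4L, k, replace = TRUE)],
                   collapse = "")
      cds <- paste0(substr(cds, 1L, pos - 1L), ins, substr(cds, pos, nchar(cds)))
    }
  }
  cds
}

intactORF <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) return(FALSE)
  if (substr(cds, 1L, 3L) != "ATG") return(FALSE)
  cod <- splitCodons(cds)
  if (!(cod[length(cod)] %in% stopCodons)) return(FALSE)
  !any(cod[-length(cod)] %in% stopCodons)
}

#' Generate a synthetic assembly and its truth table
#'
#' Plants mutated (and possibly pseudogenized, epitope-carrying) copies of
#' the template gene at the configured sublocus anchors on i.i.d. random
#' background, and returns the assembly together with one truth record per
#' planted gene. Identical (config, seed) give byte-identical output.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return list with \code{assembly} (\code{DNAStringSet}, one record per
#'   chromosome) and \code{truth} (data.frame with gene_id, chrom, start,
#'   end -- 0-based half-open -- strand, intact_orf, epitopes, copy_status,
#'   sublocus, cds). The cds column is the forward-coding planted sequence.
#' @export
generateAssembly <- function(config) {
  validObject(config)
  loci <- config@loci
  withSeed(config@seed, {
    # plan gene placements first so collisions are detected before sequence work
    plan <- list()
    k <- 0L
    for (li in seq_len(nrow(loci))) {
      chrom <- loci$chrom[li]
      sub <- sum(loci$chrom[seq_len(li)] == chrom)  # sublocus index on chrom
      for (ci in seq_len(loci$copies[li])) {
        k <- k + 1L
        plan[[k]] <- list(
          gene = sprintf("g%03d", k), chrom = chrom, sub = sub,
          anchor = loci$anchor[li], spacing = loci$spacing[li], copy = ci)
      }
    }
    nGene <- k
    epi <- config@epitopes
    status <- rep("normal", nGene)
    status[config@collapsedGenes] <- "collapsed"
    status[config@haplotypeGenes] <- "haplotype_specific"

    truth <- vector("list", nGene)
    cdsList <- character(nGene)
    tplLen <- nchar(config@template)
    for (i in seq_len(nGene)) {
      p <- plan[[i]]
      cds <- mutateSeq(config@template, config@subRate)
      myEpi <- epi[epi$gene == i, , drop = FALSE]
      protect <- integer()
      for (j in seq_len(nrow(myEpi))) {
        cds <- plantEpitope(cds, myEpi$peptide[j], myEpi$offsetAA[j])
        protect <- c(protect, myEpi$offsetAA[j] +
                       seq_len(nchar(myEpi$peptide[j])) - 1L)
      }
      if (stats::runif(1) < config@pseudoProb) cds <- pseudogenize(cds, protect)
      strand <- if (stats::runif(1) < config@minusStrandProb) "-" else "+"
      start1 <- p$anchor + (p$copy - 1L) * (tplLen + p$spacing)
      truth[[i]] <- data.frame(
        gene_id = p$gene, chrom = p$chrom,
        start = start1 - 1L, end = start1 - 1L + nchar(cds),
        strand = strand, intact_orf = intactORF(cds),
        epitopes = paste(myEpi$name, collapse = ","),
        copy_status = status[i], sublocus = sprintf("S%d", p$sub),
        cds = cds, stringsAsFactors = FALSE)
      cdsList[i] <- cds
    }
    truth <- do.call(rbind, truth)

    # collision / bounds checks
    for (chrom in unique(truth$chrom)) {
      tt <- truth[truth$chrom == chrom, , drop = FALSE]
      tt <- tt[order(tt$start), , drop = FALSE]
      if (nrow(tt) > 1L) {
        bad <- which(tt$start[-1L] < tt$end[-nrow(tt)])
        if (length(bad))
          stop(sprintf("planted genes overlap on %s: %s and %s", chrom,
                       tt$gene_id[bad[1L]], tt$gene_id[bad[1L] + 1L]))
      }
      if (any(tt$end > config@chromLengths[chrom]))
        stop(sprintf("gene %s extends beyond %s",
                     tt$gene_id[which(tt$end > config@chromLengths[chrom])[1L]],
                     chrom))
    }

    chroms <- lapply(names(config@chromLengths), function(chrom) {
      s <- randomDNA(config@chromLengths[[chrom]])
      tt <- truth[truth$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(tt))) {
        ins <- if (tt$strand[i] == "-") reverseComplement1(tt$cds[i]) else tt$cds[i]
        substr(s, tt$start[i] + 1L, tt$end[i]) <- ins
      }
      s
    })
    assembly <- Biostrings::DNAStringSet(unlist(chroms))
    names(assembly) <- names(config@chromLengths)
    list(assembly = assembly, truth = truth)
  })
}

#' Truth table intervals as GRanges
#' @param truth truth data.frame from \code{\link{generateAssembly}}.
#' @return GRanges (1-based) with the truth metadata.
#' @export
truthToGRanges <- function(truth) {
  GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = truth$strand,
    gene_id = truth$gene_id, intact_orf = truth$intact_orf,
    epitopes = truth$epitopes, copy_status = truth$copy_status,
    sublocus = truth$sublocus)
}

#' Write simulation artifacts to disk
#'
#' Writes the assembly FASTA, the truth table (tab-separated, 0-based
#' half-open), a BED export of the truth intervals, and the planted CDS
#' sequences as FASTA.
#'
#' @param sim result of \code{\link{generateAssembly}}.
#' @param outDir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    assembly = file.path(outDir, "assembly.fasta"),
    truth = file.path(outDir, "truth.tsv"),
    bed = file.path(outDir, "truth.bed"),
    cds = file.path(outDir, "truth_cds.fasta"))
  Biostrings::writeXStringSet(sim$assembly, paths["assembly"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(sim$truth$chrom, sim$truth$start, sim$truth$end,
                    sim$truth$gene_id, 0L, sim$truth$strand)
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cds <- Biostrings::DNAStringSet(sim$truth$cds)
  names(cds) <- sim$truth$gene_id
  Biostrings::writeXStringSet(cds, paths["cds"])
  invisible(paths)
}

#' Simulate a per-gene read-depth table
#'
#' Normal copies draw their mean depth around \code{medianCov}, collapsed
#' paralogs around 2x and haplotype-specific copies around 0.5x, each plus
#' Gaussian noise. Negative draws are truncated at zero and flagged.
#'
#' @param truth truth data.frame from \code{\link{generateAssembly}} (or any
#'   data.frame with gene_id and copy_status columns).
#' @param medianCov genome-wide median gene coverage (genome equivalents);
#'   default 32.23, the value observed for CDC Landmark ONT data.
#' @param noiseSd standard deviation of the depth noise.
#' @param seed integer seed.
#' @return data.frame(gene_id, mean_depth, copy_status, truncated).
#' @export
simulateDepthTable <- function(truth, medianCov = 32.23, noiseSd = 2, seed) {
  stopifnot(medianCov > 0)
  mult <- c(normal = 1, collapsed = 2, haplotype_specific = 0.5)
  expected <- medianCov * mult[truth$copy_status]
  depth <- withSeed(seed, expected + stats::rnorm(nrow(truth), 0, noiseSd))
  truncated <- depth < 0
  if (any(truncated))
    message(sum(truncated), " negative depth draw(s) truncated at 0")
  depth[truncated] <- 0
  data.frame(gene_id = truth$gene_id, mean_depth = unname(depth),
             copy_status = truth$copy_status, truncated = truncated,
             stringsAsFactors = FALSE)
}

#' Simulate a codon alignment under an M7 or M8 site model
#'
#' Draws a per-site omega from the model (continuous beta for the beta
#' component), then evolves each codon site independently along the tree
#' under GY94. Rates are normalized by the mixture-average rate so faster
#' (higher-omega) sites accumulate proportionally more substitutions, as the
#' fitted mixture assumes. No stop codons can be emitted (states are the 61
#' sense codons).
#'
#' @param tree an \code{ape} phylo with branch lengths (expected
#'   substitutions per codon under the mixture).
#' @param model list: \code{type} ("M7" or "M8"), beta shapes \code{p},
#'   \code{q}, for M8 also \code{p0} and \code{omega_s}; optional
#'   \code{kappa} (default 2).
#' @param nSites number of codon sites (>= 1).
#' @param seed integer seed.
#' @param pi codon frequencies (default uniform over the 61 sense codons).
#' @return list: \code{alignment} (\code{CodonAlignment}), \code{class}
#'   (per-site "beta" or "omega_s"), \code{omega} (per-site true omega).
#' @export
simulateCodonAlignment <- function(tree, model, nSites, seed, pi = NULL) {
  if (nSites < 1L) stop("nSites must be >= 1")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (length(tree$tip.label) < 3L) stop("tree must have >= 3 leaves")
  kappa <- if (is.null(model$kappa)) 2 else model$kappa
  if (is.null(pi)) pi <- rep(1 / 61, 61)

  withSeed(seed, {
    type <- toupper(model$type)
    if (type == "M7") {
      omega <- stats::rbeta(nSites, model$p, model$q)
      cls <- rep("beta", nSites)
      meanOmega <- model$p / (model$p + model$q)
    } else if (type == "M8") {
      sel <- stats::runif(nSites) >= model$p0
      omega <- ifelse(sel, model$omega_s, stats::rbeta(nSites, model$p, model$q))
      cls <- ifelse(sel, "omega_s", "beta")
      meanOmega <- model$p0 * model$p / (model$p + model$q) +
        (1 - model$p0) * model$omega_s
    } else stop("model$type must be 'M7' or 'M8'")

    # stationarity rate is linear in omega: rate(w) = a + b w
    r0 <- -sum(pi * diag(gy94Q(pi, kappa, 0, normalize = FALSE)))
    r1 <- -sum(pi * diag(gy94Q(pi, kappa, 1, normalize = FALSE)))
    meanRate <- r0 + (r1 - r0) * meanOmega

    phy <- ape::reorder.phylo(tree, "cladewise")   # parent before child
    nTip <- length(phy$tip.label)
    nNode <- nTip + phy$Nnode
    root <- nTip + 1L
    states <- matrix(NA_integer_, nNode, nSites)
    for (s in seq_len(nSites)) {
      eg <- gy94Eigen(pi, kappa, omega[s], normalize = FALSE)
      states[root, s] <- sample.int(61L, 1L, prob = pi)
      for (e in seq_len(nrow(phy$edge))) {
        par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
        t <- phy$edge.length[e] / meanRate
        pr <- eg$prow(states[par, s], t)
        states[ch, s] <- sample.int(61L, 1L, prob = pr)
      }
    }
    cod <- senseCodons()
    seqs <- vapply(seq_len(nTip), function(i)
      paste(cod[states[i, ]], collapse = ""), character(1))
    aln <- Biostrings::DNAStringSet(seqs)
    names(aln) <- phy$tip.label
    list(alignment = new("CodonAlignment", aln), class = cls, omega = omega)
  })
}
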