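# Pipeline orchestration: run the discovery -> locus map -> epitopes ->
# phylogeny -> selection -> coverage stages from one configuration, with a
# JSON manifest (input hashes, parameters, seed) so a run is reproducible
# from a single seed.

#' Default pipeline parameters
#' @return named list of stage parameters.
#' @export
defaultPipelineParams <- function() {
  list(min_identity = 0.9, min_len = 300, seed_len = 12, max_pdist = 0.35,
       gap_mb = 5, alpha = 2.25, bootstrap = 100, starts = 2,
       median_cov = 32.23, high_ratio = 1.5, low_ratio = 0.6)
}

#' Bundled toy pipeline configuration
#'
#' A self-contained synthetic accession: the simulation stage generates the
#' assembly, truth table and depth table, and the template CDS serves as the
#' discovery query.
#'
#' @param outDir run directory.
#' @param seed global seed.
#' @param selection run the selection stage (slowest; off by default).
#' @return config list for \code{\link{runPipeline}}.
#' @export
toyPipelineConfig <- function(outDir, seed, selection = FALSE) {
  list(accession = "synthA", out_dir = outDir, seed = seed,
       simulate = TRUE,
       stages = list(discover = TRUE, loci = TRUE, epitopes = TRUE,
                     phylo = TRUE, selection = selection, coverage = TRUE),
       params = defaultPipelineParams())
}

#' Run the full pipeline
#'
#' Executes the configured stages in order (simulate -> discover -> map-loci
#' -> epitopes -> phylo -> selection -> coverage), writing every artifact
#' plus a JSON manifest of input hashes, parameters and the seed. A stage
#' failure halts the run; partial outputs are retained next to a FAILED
#' marker file. Reruns with identical config and seed reproduce identical
#' artifacts.
#'
#' @param config a config list or path to a JSON config file. Fields:
#'   \code{accession}, \code{out_dir}, \code{seed}, \code{stages} (named
#'   logical list), \code{params} (see
#'   \code{\link{defaultPipelineParams}}), either \code{simulate = TRUE} or
#'   \code{paths} with \code{assembly}, \code{queries} and optionally
#'   \code{epitope_table}, \code{depth}, \code{tree}.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outDir, "FAILED"))
  params <- utils::modifyList(defaultPipelineParams(),
                              as.list(config$params %||% list()))
  stages <- utils::modifyList(
    list(discover = TRUE, loci = TRUE, epitopes = TRUE, phylo = TRUE,
         selection = FALSE, coverage = TRUE),
    as.list(config$stages %||% list()))
  accession <- config$accession %||% "accession"
  seeds <- deriveSeeds(config$seed, 8L)
  manifest <- list(accession = accession, seed = config$seed,
                   params = params, stages = list(), files = list())
  currentStage <- "setup"

  finishFail <- function(e) {
    writeLines(c(currentStage, conditionMessage(e)), file.path(outDir, "FAILED"))
    manifest$status <- "FAILED"
    manifest$failed_stage <- currentStage
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop(e)
  }

  addFiles <- function(stage, paths) {
    manifest$stages[[stage]] <<- "run"
    for (p in paths)
      manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
  }

  tryCatch({
    # --- simulate -----------------------------------------------------
    depthTab <- NULL; truth <- NULL
    if (isTRUE(config$simulate)) {
      currentStage <- "simulate"
      simDir <- file.path(outDir, "simulate")
      cfg <- simConfig(seed = seeds[1L])
      sim <- generateAssembly(cfg)
      truth <- sim$truth
      paths <- writeSimulation(sim, simDir)
      depthTab <- simulateDepthTable(truth, medianCov = params$median_cov,
                                     noiseSd = 2, seed = seeds[2L])
      depthPath <- file.path(simDir, "depth.tsv")
      utils::write.table(depthTab, depthPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addFiles("simulate", c(paths, depthPath))
      assembly <- sim$assembly
      # like the real AS1-AS11 query panel, include an epitope-carrying
      # variant so 33-mer genes stay within the identity threshold
      queries <- Biostrings::DNAStringSet(c(
        template = cfg@template,
        template_33mer = plantEpitope(cfg@template, .MER33, 21L)))
    } else {
      assembly <- Biostrings::readDNAStringSet(config$paths$assembly)
      names(assembly) <- sub("\\s.*", "", names(assembly))
      queries <- Biostrings::readDNAStringSet(config$paths$queries)
      names(queries) <- sub("\\s.*", "", names(queries))
      if (!is.null(config$paths$depth))
        depthTab <- utils::read.delim(config$paths$depth)
    }

    # --- discover -----------------------------------------------------
    cand <- NULL
    if (isTRUE(stages$discover)) {
      currentStage <- "discover"
      cand <- findCandidates(assembly, queries,
                             minIdentity = params$min_identity,
                             minLen = params$min_len,
                             seedLen = params$seed_len,
                             accession = accession)
      flt <- filterDivergent(cand, queries, maxPdist = params$max_pdist)
      cand <- flt$kept
      paths <- writeCandidates(cand, file.path(outDir, "candidates"))
      addFiles("discover", paths)
    } else manifest$stages$discover <- "skipped"

    # --- map-loci -----------------------------------------------------
    loci <- NULL; assignment <- NULL
    if (isTRUE(stages$loci) && !is.null(cand)) {
      currentStage <- "map-loci"
      df <- as.data.frame(cand)
      lociList <- lapply(split(seq_len(nrow(df)), df$chrom), function(ii)
        clusterLoci(cand[ii], gapMb = params$gap_mb))
      loci <- do.call(rbind, lapply(lociList, function(l) {
        l$members <- NULL; l
      }))
      rownames(loci) <- NULL
      assignment <- do.call(rbind, lapply(lociList, attr, "assignment"))
      rownames(assignment) <- NULL
      mc <- S4Vectors::mcols(cand@ranges)
      intact <- mc$starts_with_met & !mc$has_internal_stop &
        mc$has_terminal_stop & !mc$frameshifted
      intactByGene <- stats::setNames(intact, mc$gene_id)
      loci$n_intact <- vapply(seq_len(nrow(loci)), function(i) {
        members <- assignment$gene_id[assignment$locus == loci$name[i]]
        sum(intactByGene[members])
      }, integer(1))
      loci$accession <- accession
      tabPath <- file.path(outDir, "locus_table.tsv")
      writeLocusTable(loci, tabPath)
      rawPath <- file.path(outDir, "loci.tsv")
      utils::write.table(loci, rawPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addFiles("map-loci", c(tabPath, rawPath))
    } else manifest$stages$loci <- "skipped"

    # --- epitopes -----------------------------------------------------
    if (isTRUE(stages$epitopes) && !is.null(cand)) {
      currentStage <- "epitopes"
      tab <- if (!is.null(config$paths$epitope_table))
        readEpitopeTable(config$paths$epitope_table) else defaultEpitopeTable()
      prot <- chartr("*", "X", as.character(cand@protein))
      hits <- scanEpitopes(prot, tab)
      genes <- data.frame(gene_id = candidateIds(cand), accession = accession,
                          locus = if (!is.null(assignment))
                            assignment$locus[match(candidateIds(cand),
                                                   assignment$gene_id)]
                          else "chrUn",
                          stringsAsFactors = FALSE)
      profile <- profileCounts(hits, genes, epitopeNames = tab$name)
      m33 <- detect33mer(prot)
      hitsPath <- file.path(outDir, "epitope_hits.tsv")
      utils::write.table(hits, hitsPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      matPath <- file.path(outDir, "epitope_matrix.tsv")
      writeEpitopeMatrix(profile, matPath)
      m33Path <- file.path(outDir, "mer33.tsv")
      utils::write.table(m33, m33Path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addFiles("epitopes", c(hitsPath, matPath, m33Path))
    } else manifest$stages$epitopes <- "skipped"

    # --- phylo --------------------------------------------------------
    codAln <- NULL; tree <- NULL
    if (isTRUE(stages$phylo) && !is.null(cand)) {
      currentStage <- "phylo"
      mc <- S4Vectors::mcols(cand@ranges)
      usable <- !mc$frameshifted & !mc$has_internal_stop
      if (sum(usable) >= 3L) {
        sub <- cand[usable]
        cds <- stats::setNames(as.character(sub@cds), candidateIds(sub))
        codAln <- alignCodons(cds)
        tree <- bootstrapSupport(codAln, B = params$bootstrap,
                                 alpha = params$alpha, seed = seeds[3L])
        labels <- stats::setNames(
          if (!is.null(assignment))
            assignment$locus[match(names(cds), assignment$gene_id)]
          else rep("chrUn", length(cds)), names(cds))
        labels[is.na(labels)] <- "chrUn"
        clades <- cladeMembership(tree, labels)
        treePath <- file.path(outDir, "tree.nwk")
        ape::write.tree(tree, treePath)
        alnPath <- file.path(outDir, "codon_alignment.fasta")
        Biostrings::writeXStringSet(as(codAln, "DNAStringSet"), alnPath)
        cladePath <- file.path(outDir, "clades.tsv")
        utils::write.table(clades, cladePath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        addFiles("phylo", c(treePath, alnPath, cladePath))
      } else manifest$stages$phylo <- "skipped (fewer than 3 usable copies)"
    } else manifest$stages$phylo <- "skipped"

    # --- selection ----------------------------------------------------
    if (isTRUE(stages$selection) && !is.null(codAln)) {
      currentStage <- "selection"
      prep <- prepareSelectionAlignment(codAln)
      keep <- intersect(tree$tip.label, names(prep$alignment))
      selTree <- ape::keep.tip(tree, keep)
      fit7 <- fitSiteModel(prep$alignment, selTree, "M7",
                           starts = params$starts, seed = seeds[4L])
      fit8 <- fitSiteModel(prep$alignment, selTree, "M8",
                           starts = params$starts, seed = seeds[5L],
                           init = fit7@params)
      lrt <- lrtM7M8(fit7, fit8)
      sites <- sitePosteriors(fit8)
      sites$original_column <- prep$report$columnMap[sites$site]
      selPath <- file.path(outDir, "selection.json")
      jsonlite::write_json(
        list(M7 = list(params = as.list(fit7@params), logLik = fit7@logLik),
             M8 = list(params = as.list(fit8@params), logLik = fit8@logLik),
             lrt = lrt), selPath, auto_unbox = TRUE, digits = NA)
      sitesPath <- file.path(outDir, "selection_sites.tsv")
      utils::write.table(sites, sitesPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      maskPath <- file.path(outDir, "selection_mask.tsv")
      utils::write.table(
        data.frame(type = c(rep("row", nrow(prep$report$rows)),
                            rep("masked_column", length(prep$report$maskedColumns)),
                            rep("all_gap_column", length(prep$report$allGapColumns))),
                   item = c(prep$report$rows$id,
                            as.character(prep$report$maskedColumns),
                            as.character(prep$report$allGapColumns)),
                   reason = c(prep$report$rows$reason,
                              rep("polyglutamine", length(prep$report$maskedColumns)),
                              rep("all gaps", length(prep$report$allGapColumns)))),
        maskPath, sep = "\t", quote = FALSE, row.names = FALSE)
      addFiles("selection", c(selPath, sitesPath, maskPath))
    } else manifest$stages$selection <- "skipped"

    # --- coverage -----------------------------------------------------
    if (isTRUE(stages$coverage) && !is.null(depthTab)) {
      currentStage <- "coverage"
      rec <- summarizeGeneCoverage(depthTab)
      rec <- classifyCopyStatus(rec, medianCov = params$median_cov,
                                highRatio = params$high_ratio,
                                lowRatio = params$low_ratio)
      covPath <- file.path(outDir, "coverage.tsv")
      utils::write.table(rec, covPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addFiles("coverage", covPath)
    } else manifest$stages$coverage <- "skipped"

    manifest$status <- "OK"
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = finishFail)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the per-accession locus table
#'
#' One row per accession; for each locus a positions column ("start-end" Mb,
#' 1 decimal; "chrUn" for unanchored assignments) and a copy-count column in
#' the "total (intact ORF)" convention, stated in the header.
#'
#' @param loci data.frame with columns accession, name, chrom, start_mb,
#'   end_mb, n, n_intact.
#' @param path output TSV path.
#' @return invisibly, the wide data.frame written.
#' @export
writeLocusTable <- function(loci, path) {
  fmtPos <- function(s, e, chrom) {
    ifelse(chrom == "chrUn", "chrUn",
           ifelse(sprintf("%.1f", s) == sprintf("%.1f", e),
                  sprintf("%.1f", s), sprintf("%.1f-%.1f", s, e)))
  }
  accs <- unique(loci$accession)
  lociNames <- unique(loci$name)
  out <- data.frame(accession = accs, stringsAsFactors = FALSE)
  for (ln in lociNames) {
    pos <- cnt <- rep("", length(accs))
    for (ai in seq_along(accs)) {
      sel <- loci[loci$accession == accs[ai] & loci$name == ln, , drop = FALSE]
      if (nrow(sel)) {
        pos[ai] <- paste(fmtPos(sel$start_mb, sel$end_mb, sel$chrom),
                         collapse = " and ")
        cnt[ai] <- sprintf("%d (%d)", sum(sel$n), sum(sel$n_intact))
      }
    }
    out[[paste0(ln, ".positions_mb")]] <- pos
    out[[paste0(ln, ".copies_total_intact")]] <- cnt
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write the epitope count matrix
#'
#' Epitope x (accession, subgenome) occurrence matrix with zero rows
#' retained, so epitope absences stay visible.
#'
#' @param profile an \code{\linkS4class{EpitopeProfile}}.
#' @param path output TSV path.
#' @return invisibly, the matrix written.
#' @export
writeEpitopeMatrix <- function(profile, path) {
  m <- profileMatrix(profile)
  df <- data.frame(epitope = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
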