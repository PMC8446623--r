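# Codon site-model analysis: alignment cleanup, M7/M8 maximum-likelihood
# fits on a fixed tree (single free branch-scale multiplier), the M7-vs-M8
# likelihood-ratio test, and empirical-Bayes per-site posteriors of
# positive selection.

#' Clean a codon alignment for site-model analysis
#'
#' Applies the conservative full-length rules: rows with a premature stop,
#' a frameshift (ungapped length not a multiple of 3) or no terminal stop
#' are dropped (the terminal stop is then stripped); all-gap codon columns
#' are removed; and codon columns inside any run of >= 8 consecutive
#' columns whose residues are >= 75\% Q/P (the hard-to-align polyglutamine
#' regions) are excluded.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param requireTerminalStop drop rows lacking a terminal stop codon.
#' @return list: \code{alignment} (cleaned \code{CodonAlignment}),
#'   \code{report} with \code{rows} (id, reason), \code{maskedColumns} and
#'   \code{allGapColumns} (original codon-column indices), and
#'   \code{columnMap} mapping cleaned codon columns to original ones.
#' @export
prepareSelectionAlignment <- function(aln, requireTerminalStop = TRUE) {
  seqs <- as.character(aln)
  ids <- names(seqs)
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keepRows <- character()
  for (i in seq_along(seqs)) {
    ung <- gsub("-", "", seqs[i])
    if (nchar(ung) %% 3L != 0L) {
      dropped <- rbind(dropped, data.frame(id = ids[i], reason = "frameshift"))
      next
    }
    cod <- splitCodons(ung)
    isStop <- cod %in% stopCodons
    if (any(isStop[-length(isStop)])) {
      dropped <- rbind(dropped, data.frame(id = ids[i], reason = "premature stop"))
      next
    }
    if (requireTerminalStop && !isStop[length(isStop)]) {
      dropped <- rbind(dropped, data.frame(id = ids[i], reason = "no terminal stop"))
      next
    }
    keepRows <- c(keepRows, ids[i])
  }
  seqs <- seqs[keepRows]
  if (length(seqs) < 3L)
    stop("fewer than 3 sequences survive cleanup; model unidentifiable")

  # codon-column matrix
  nCod <- nchar(seqs[[1L]]) %/% 3L
  codMat <- t(vapply(seqs, splitCodons, character(nCod)))

  # strip terminal stop (last non-gap codon of each row)
  if (requireTerminalStop) {
    for (i in seq_len(nrow(codMat))) {
      nz <- which(codMat[i, ] != "---")
      last <- nz[length(nz)]
      if (codMat[i, last] %in% stopCodons) codMat[i, last] <- "---"
    }
  }

  allGap <- which(apply(codMat == "---", 2L, all))

  # polyglutamine mask on the remaining columns
  resFrac <- vapply(seq_len(nCod), function(j) {
    cods <- codMat[, j]
    cods <- cods[cods != "---"]
    if (!length(cods)) return(0)
    aa <- GENCODE[cods]
    mean(aa %in% c("Q", "P"), na.rm = TRUE)
  }, numeric(1))
  qp <- resFrac >= 0.75
  qp[allGap] <- FALSE
  runs <- rle(qp)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  masked <- integer()
  for (r in seq_along(runs$values))
    if (runs$values[r] && runs$lengths[r] >= 8L)
      masked <- c(masked, starts[r]:ends[r])

  removed <- sort(unique(c(allGap, masked)))
  keepCols <- setdiff(seq_len(nCod), removed)
  if (length(keepCols) < 10L)
    stop("fewer than 10 codon columns survive cleanup; model unidentifiable")
  cleaned <- apply(codMat[, keepCols, drop = FALSE], 1L, paste, collapse = "")
  out <- Biostrings::DNAStringSet(cleaned)
  names(out) <- keepRows
  list(alignment = new("CodonAlignment", out),
       report = list(rows = dropped, maskedColumns = masked,
                     allGapColumns = allGap, columnMap = keepCols))
}

alignmentHash <- function(aln, tree) {
  contentHash(c(as.character(aln), names(aln), ape::write.tree(tree)))
}

#' Fit a GY94 site model (M7 or M8) by maximum likelihood
#'
#' The omega distribution is a K-category equal-probability discretized
#' Beta(p, q) (category values are slice medians); M8 adds a point mass at
#' omega_s >= 1 with weight 1 - p0. Codon frequencies are F3x4 estimated
#' from the data; branch lengths come from the input tree and are rescaled
#' by a single free multiplier. Optimization is bounded quasi-Newton
#' (L-BFGS-B) from \code{starts} seeded initial points; the best start is
#' returned with diagnostics (a fit that converges in no start is returned
#' with \code{converged = FALSE}, never as a silent success).
#'
#' @param aln cleaned \code{\linkS4class{CodonAlignment}} (no stop codons).
#' @param tree \code{ape} phylo with branch lengths; its leaves must all
#'   appear in the alignment.
#' @param model "M7" or "M8".
#' @param starts number of optimization starts.
#' @param seed integer seed for the start jitter.
#' @param K number of beta discretization categories.
#' @param init optional named vector of starting values (used as the first
#'   start; e.g. a converged M7 fit to warm-start M8).
#' @return a \code{\linkS4class{SiteModelFit}}.
#' @export
fitSiteModel <- function(aln, tree, model = c("M7", "M8"), starts = 5L,
                         seed = 1L, K = 10L, init = NULL) {
  model <- match.arg(model)
  idx <- codonIndexMatrix(aln)
  pt <- prepTree(tree, rownames(idx))
  if (length(pt$phy$tip.label) < 3L) stop("tree must have >= 3 leaves")
  pi <- f3x4Freqs(aln)

  # site-pattern compression
  key <- apply(idx, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  patIdx <- idx[, upat, drop = FALSE]
  patOf <- match(key, key[upat])
  w <- as.numeric(table(factor(patOf, levels = seq_len(sum(upat)))))

  parNames <- c("kappa", "p", "q", "scale", if (model == "M8") c("p0", "omega_s"))
  lower <- c(0.2, 0.02, 0.02, 1e-4, if (model == "M8") c(0, 1))
  upper <- c(50, 50, 50, 100, if (model == "M8") c(1, 50))
  base <- c(kappa = 2, p = 0.8, q = 2, scale = 1,
            if (model == "M8") c(p0 = 0.9, omega_s = 2))
  names(base) <- parNames

  nEval <- 0L
  negLL <- function(par) {
    nEval <<- nEval + 1L
    cats <- omegaCategories(
      c(list(type = model), as.list(par[setdiff(parNames, c("kappa", "scale"))])), K)
    res <- mixtureLogLik(patIdx, w, pt$phy, pt$tipMap, pi, par[["kappa"]],
                         cats$omega, cats$weight, par[["scale"]])
    ll <- res$loglik
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  jitters <- deriveSeeds(seed, starts)
  fits <- vector("list", starts)
  for (s in seq_len(starts)) {
    p0s <- if (s == 1L && !is.null(init)) {
      v <- base; v[names(init)[names(init) %in% parNames]] <-
        init[names(init) %in% parNames]
      if (model == "M8" && !("p0" %in% names(init))) {
        # an M7 warm start embeds the null at the p0 = 1 boundary, so the
        # M8 optimum can never fall below the M7 one
        v["p0"] <- 1; v["omega_s"] <- 1
      }
      v
    } else if (s == 1L) base else withSeed(jitters[s], {
      v <- base * exp(stats::runif(length(base), -1, 1))
      if (model == "M8") v["p0"] <- stats::runif(1, 0.5, 0.99)
      pmin(pmax(v, lower + 1e-6), upper - 1e-6)
    })
    fits[[s]] <- tryCatch(
      stats::optim(p0s, negLL, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 200, factr = 1e9)),
      error = function(e) list(value = Inf, convergence = 99L,
                               par = p0s, message = conditionMessage(e)))
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- which.min(vals)
  fit <- fits[[best]]
  par <- fit$par
  names(par) <- parNames
  converged <- any(vapply(fits, function(f)
    identical(f$convergence, 0L) && is.finite(f$value), logical(1)))

  cats <- omegaCategories(
    c(list(type = model), as.list(par[setdiff(parNames, c("kappa", "scale"))])), K)
  final <- mixtureLogLik(patIdx, w, pt$phy, pt$tipMap, pi, par[["kappa"]],
                         cats$omega, cats$weight, par[["scale"]],
                         wantSite = TRUE)
  siteCat <- final$site[patOf, , drop = FALSE]

  atBound <- par <= lower + 1e-6 | par >= upper - 1e-6
  new("SiteModelFit", model = model, params = par,
      logLik = final$loglik, catOmega = cats$omega, catWeight = cats$weight,
      freqs = pi, siteCatLogLik = siteCat,
      diagnostics = list(
        converged = converged, convergence = fit$convergence,
        startValues = -vals, bestStart = best, nEval = nEval,
        boundary = parNames[atBound],
        dataHash = alignmentHash(aln, tree)))
}

#' Likelihood-ratio test of M7 (null) vs M8 (positive selection)
#'
#' The statistic 2(l8 - l7), clamped at zero, is compared to a chi-squared
#' distribution with 2 degrees of freedom (M8 adds p0 and omega_s); the
#' boundary makes this conservative.
#'
#' @param fit7,fit8 \code{\linkS4class{SiteModelFit}} objects fitted to the
#'   same alignment and tree.
#' @return list(statistic, df, p_value, clamped).
#' @export
lrtM7M8 <- function(fit7, fit8) {
  if (fit7@model != "M7" || fit8@model != "M8")
    stop("expected an M7 fit and an M8 fit, in that order")
  if (!identical(fit7@diagnostics$dataHash, fit8@diagnostics$dataHash))
    stop("fits were produced from different data/tree")
  raw <- 2 * (fit8@logLik - fit7@logLik)
  clamped <- raw < 0
  stat <- max(0, raw)
  list(statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, df = 2L, lower.tail = FALSE),
       clamped = clamped)
}

#' Per-site posterior probability of positive selection
#'
#' Default NEB: at the M8 maximum-likelihood estimates, the posterior that a
#' site belongs to the selected (omega_s) class is its mixture
#' responsibility. The optional coarse-grid BEB averages that posterior over
#' a fixed grid on (p0, p, q, omega_s) weighted by the data likelihood at
#' each grid point (kappa and scale held at their MLEs). Sites with
#' posterior > \code{threshold} are flagged significant.
#'
#' @param fit8 a converged M8 \code{\linkS4class{SiteModelFit}}.
#' @param threshold significance cutoff on the posterior (default 0.95).
#' @param method "NEB" (default) or "BEB-grid".
#' @param aln,tree required for "BEB-grid" (the data to re-evaluate on).
#' @return data.frame(site, posterior, significant); sites indexed in the
#'   cleaned alignment's codon coordinates.
#' @export
sitePosteriors <- function(fit8, threshold = 0.95,
                           method = c("NEB", "BEB-grid"),
                           aln = NULL, tree = NULL) {
  method <- match.arg(method)
  if (fit8@model != "M8") stop("an M8 fit is required")
  if (!isTRUE(fit8@diagnostics$converged))
    stop("fit did not converge; refusing to compute posteriors")
  if (method == "NEB") {
    post <- sitePosteriorFromCats(fit8@siteCatLogLik, fit8@catWeight,
                                  fit8@catOmega)
  } else {
    if (is.null(aln) || is.null(tree))
      stop("BEB-grid needs the alignment and tree")
    post <- bebGridPosterior(fit8, aln, tree)
  }
  data.frame(site = seq_along(post), posterior = post,
             significant = post > threshold)
}

# mixture responsibilities of the omega>1 classes
sitePosteriorFromCats <- function(siteCat, catWeight, catOmega) {
  lw <- ifelse(catWeight > 0, log(catWeight), -Inf)
  lp <- sweep(siteCat, 2L, lw, "+")
  mx <- apply(lp, 1L, max)
  pr <- exp(lp - mx)
  pr <- pr / rowSums(pr)
  sel <- catOmega > 1
  if (!any(sel)) return(rep(0, nrow(pr)))
  rowSums(pr[, sel, drop = FALSE])
}

# coarse fixed grid over (p0, p, q, omega_s), likelihood-weighted
bebGridPosterior <- function(fit8, aln, tree) {
  grid <- expand.grid(p0 = c(0.6, 0.8, 0.9, 0.99),
                      p = c(0.3, 1, 2), q = c(0.5, 2, 5),
                      omega_s = c(1.5, 3, 6))
  idx <- codonIndexMatrix(aln)
  pt <- prepTree(tree, rownames(idx))
  pi <- fit8@freqs
  kappa <- fit8@params[["kappa"]]
  scale <- fit8@params[["scale"]]
  w <- rep(1, ncol(idx))
  K <- length(fit8@catOmega) - 1L
  nSite <- ncol(idx)
  postSum <- rep(0, nSite)
  wtSum <- 0
  logw <- numeric(nrow(grid))
  posts <- matrix(0, nSite, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cats <- omegaCategories(list(type = "M8", p0 = grid$p0[g], p = grid$p[g],
                                 q = grid$q[g], omega_s = grid$omega_s[g]), K)
    res <- mixtureLogLik(idx, w, pt$phy, pt$tipMap, pi, kappa,
                         cats$omega, cats$weight, scale, wantSite = TRUE)
    logw[g] <- res$loglik
    posts[, g] <- sitePosteriorFromCats(res$site, cats$weight, cats$omega)
  }
  wt <- exp(logw - max(logw))
  wt <- wt / sum(wt)
  as.numeric(posts %*% wt)
}
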