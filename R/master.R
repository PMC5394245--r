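#' Upper-tail binomial test for master-TF status
#'
#' P(X >= observed) with X ~ Binomial(nTargets, backgroundRate): does the
#' TF regulate more of the target universe than the background edge
#' density predicts?
#'
#' @param tfTargetCount number of targets the TF regulates in the pruned
#'   network.
#' @param nTargets size of the target universe.
#' @param backgroundRate background regulation probability, strictly
#'   between 0 and 1.
#' @return the p-value (1 when the TF has no targets).
#' @examples
#' binomialMasterTest(10, 20, 0.1)
#' @export
binomialMasterTest <- function(tfTargetCount, nTargets, backgroundRate) {
  if (!is.finite(backgroundRate) || backgroundRate <= 0 ||
      backgroundRate >= 1)
    stop("degenerate background rate: ", backgroundRate)
  if (tfTargetCount > nTargets)
    stop("a TF cannot regulate more targets than the universe holds")
  stats::pbinom(tfTargetCount - 1, nTargets, backgroundRate,
                lower.tail = FALSE)
}

#' One-sided Fisher test for shared targets between two TFs
#'
#' Tests enrichment of the overlap between two target sets against a
#' hypergeometric null over the target universe.
#'
#' @param targetsA,targetsB character vectors of target identifiers.
#' @param universe size of the target universe (positive integer).
#' @return the one-sided (enrichment) p-value.
#' @export
targetOverlapTest <- function(targetsA, targetsB, universe) {
  universe <- as.integer(universe)
  if (universe <= 0L) stop("empty target universe")
  a <- unique(targetsA); b <- unique(targetsB)
  if (length(a) > universe || length(b) > universe)
    stop("target set larger than the universe")
  ov <- length(intersect(a, b))
  tab <- matrix(c(ov, length(a) - ov,
                  length(b) - ov,
                  universe - length(a) - length(b) + ov),
                2L, byrow = TRUE)
  if (any(tab < 0)) stop("sets exceed the stated universe")
  fisherExact(tab, "greater")
}

#' Mutual exclusivity of two overexpression sample sets
#'
#' One-sided Fisher test for depletion of co-overexpression: are fewer
#' samples overexpressing both TFs than expected under independence?
#' The odds ratio is computed from the 2x2 table with a Haldane
#' correction (+0.5 to every cell) when any cell is zero; mutually
#' exclusive patterns give odds ratios below 1.
#'
#' @param overA,overB character vectors of samples overexpressing each
#'   TF.
#' @param nSamples cohort size (positive integer).
#' @return list with `p` (depletion p-value), `oddsRatio` and `table`
#'   (the 2x2 co-occurrence matrix).
#' @examples
#' mutualExclusivityTest(paste0("s", 1:8), paste0("s", 9:16), 20)$p
#' @export
mutualExclusivityTest <- function(overA, overB, nSamples) {
  nSamples <- as.integer(nSamples)
  if (nSamples <= 0L) stop("empty cohort")
  a <- unique(overA); b <- unique(overB)
  both <- length(intersect(a, b))
  tab <- matrix(c(both, length(a) - both,
                  length(b) - both,
                  nSamples - length(a) - length(b) + both),
                2L, byrow = TRUE,
                dimnames = list(c("A", "notA"), c("B", "notB")))
  if (any(tab < 0)) stop("sets exceed the stated cohort")
  p <- fisherExact(tab, "less")
  ct <- if (any(tab == 0)) tab + 0.5 else tab
  list(p = p, oddsRatio = (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1]),
       table = tab)
}

#' Bimodality index of a two-component equal-variance mixture
#'
#' BI = |mu1 - mu2| / sigma * sqrt(p (1 - p)); higher values indicate a
#' cleaner bimodal split. Unitless and invariant to affine rescaling of
#' the expression axis.
#'
#' @param p mixing proportion, strictly between 0 and 1.
#' @param mu1,mu2 component means.
#' @param sigma common standard deviation, positive.
#' @return the bimodality index.
#' @examples
#' bimodalityIndex(0.5, 0, 2, 1) # exactly 1
#' @export
bimodalityIndex <- function(p, mu1, mu2, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("mixing proportion must lie strictly between 0 and 1")
  abs(mu1 - mu2) / sigma * sqrt(p * (1 - p))
}

#' Two-component equal-variance fit and bimodality index for one gene
#'
#' @param values numeric vector of one gene's per-sample expression.
#' @return list with `p`, `mu1`, `mu2`, `sigma`, `bi` (0 for degenerate
#'   or effectively unimodal input).
#' @export
fitBimodality <- function(values) {
  values <- as.numeric(values)
  degenerate <- list(p = 0.5, mu1 = mean(values), mu2 = mean(values),
                     sigma = max(stats::sd(values), 1e-8), bi = 0)
  if (length(values) < 4L || stats::sd(values) < .Machine$double.eps)
    return(degenerate)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = 2, modelNames = "E",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(degenerate)
  mu <- as.numeric(fit$parameters$mean)
  sigma <- sqrt(fit$parameters$variance$sigmasq[1L])
  pr <- fit$parameters$pro[1L]
  if (!is.finite(sigma) || sigma <= 0 || pr <= 0 || pr >= 1)
    return(degenerate)
  list(p = pr, mu1 = mu[1L], mu2 = mu[2L], sigma = sigma,
       bi = bimodalityIndex(pr, mu[1L], mu[2L], sigma))
}

#' Screen a dataset and genes for mutual-exclusivity analysis
#'
#' A dataset qualifies only when it holds strictly more than
#' `minSamplesScreen` samples; a gene qualifies when its two-component
#' equal-variance fit yields a bimodality index strictly above
#' `bimodalityCutoff`.
#'
#' @param m numeric genes-by-samples matrix (or a `TFTargetExperiment`).
#' @param genes gene identifiers to screen (default: all rows).
#' @param config a [pipelineConfig()].
#' @return list with `datasetPass`, `nSamples` and `genes`, a data.frame
#'   of per-gene fits, `bi` values and pass flags (`pass` requires both
#'   the dataset and the gene to qualify).
#' @export
screenDataset <- function(m, genes = NULL, config = pipelineConfig()) {
  if (is(m, "TFTargetExperiment")) m <- exprMatrix(m)
  if (is.null(genes)) genes <- rownames(m)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  datasetPass <- ncol(m) > config$minSamplesScreen
  rows <- lapply(genes, function(g) {
    f <- fitBimodality(m[g, ])
    data.frame(gene = g, p = f$p, mu1 = f$mu1, mu2 = f$mu2,
               sigma = f$sigma, bi = f$bi,
               genePass = f$bi > config$bimodalityCutoff,
               pass = datasetPass && f$bi > config$bimodalityCutoff,
               stringsAsFactors = FALSE)
  })
  list(datasetPass = datasetPass, nSamples = ncol(m),
       genes = do.call(rbind, rows))
}

#' Validation rate of a completely random predictor
#'
#' The chance a randomly predicted target is true: 100 * nTrue / nTotal
#' percent. With 1,800 total candidate targets this baseline stays below
#' 13 percent even for the largest observed true-target set.
#'
#' @param nTrue number of true targets for the TF.
#' @param nTotal total number of candidate targets (default 1800).
#' @return validation rate in percent (vectorized over `nTrue`).
#' @examples
#' randomPredictorRate(c(226, 94, 129))
#' @export
randomPredictorRate <- function(nTrue, nTotal = 1800) {
  if (nTotal <= 0) stop("nTotal must be positive")
  100 * nTrue / nTotal
}

#' Master-TF, target-overlap and mutual-exclusivity statistics
#'
#' For every selected TF, an upper-tail binomial test of its target count
#' against the background edge density; for every pair of selected TFs, a
#' one-sided Fisher test on shared targets and a one-sided Fisher
#' depletion test on co-overexpression across the cohort. Overexpression
#' calls reuse the discretization's `over` aberration flags; TFs whose
#' aberration direction is not `over` contribute empty overexpression
#' sets. The optional low-abundance filter voids a call when the sample's
#' expression sits an order of magnitude below the competing TF's.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param ab the matching [AberrationCalls-class].
#' @param candidates the FDR-significant test table the network was
#'   pruned from; used for the default background rate (falls back to the
#'   network's own edges when `NULL`).
#' @param config a [pipelineConfig()].
#' @param exprMat expression matrix, required only when
#'   `config$lowAbundanceFilter` is `TRUE`.
#' @return a [MasterTFReport-class].
#' @export
masterTFReport <- function(net, ab, candidates = NULL,
                           config = pipelineConfig(), exprMat = NULL) {
  stopifnot(is(net, "RegulatoryNetwork"), is(ab, "AberrationCalls"))
  emptyTF <- data.frame(tf = character(), nTargets = integer(),
                        binomP = numeric(), isMaster = logical(),
                        stringsAsFactors = FALSE)
  emptyPair <- data.frame(tfA = character(), tfB = character(),
                          overlap = integer(), overlapP = numeric(),
                          bothOver = integer(), exclusivityP = numeric(),
                          oddsRatio = numeric(),
                          stringsAsFactors = FALSE)
  sel <- net@selected
  edges <- net@edges
  if (!length(sel) || !nrow(edges))
    return(new("MasterTFReport", perTF = emptyTF, perPair = emptyPair,
               backgroundRate = NA_real_))
  nEdgesBg <- if (!is.null(candidates)) nrow(candidates) else nrow(edges)
  rate <- if (!is.null(config$backgroundRate)) config$backgroundRate
          else nEdgesBg / (net@S * net@n)
  rate <- min(max(rate, .Machine$double.eps), 1 - .Machine$double.eps)
  perTF <- do.call(rbind, lapply(sel, function(tf) {
    k <- sum(edges$tf == tf)
    p <- binomialMasterTest(k, net@n, rate)
    data.frame(tf = tf, nTargets = k, binomP = p,
               isMaster = p < config$masterPCutoff,
               stringsAsFactors = FALSE)
  }))
  overSets <- lapply(sel, function(tf) {
    i <- match(tf, rownames(ab@flags))
    if (is.na(i) || ab@direction[i] != "over") return(character())
    s <- colnames(ab@flags)[ab@flags[i, ]]
    if (config$lowAbundanceFilter && !is.null(exprMat)) {
      others <- setdiff(sel, tf)
      if (length(others)) {
        comp <- apply(exprMat[others, s, drop = FALSE], 2, max)
        s <- s[exprMat[tf, s] > comp - log(10, base = config$logBase)]
      }
    }
    s
  })
  names(overSets) <- sel
  perPair <- emptyPair
  if (length(sel) >= 2L) {
    pairs <- utils::combn(sel, 2L)
    perPair <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      ta <- edges$target[edges$tf == a]
      tb <- edges$target[edges$tf == b]
      ex <- mutualExclusivityTest(overSets[[a]], overSets[[b]],
                                  ncol(ab@flags))
      data.frame(tfA = a, tfB = b,
                 overlap = length(intersect(ta, tb)),
                 overlapP = targetOverlapTest(ta, tb, net@n),
                 bothOver = ex$table[1L, 1L],
                 exclusivityP = ex$p, oddsRatio = ex$oddsRatio,
                 stringsAsFactors = FALSE)
    }))
  }
  new("MasterTFReport", perTF = perTF, perPair = perPair,
      backgroundRate = rate)
}
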