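#' Fit a per-gene Gaussian mixture and designate the normal component
#'
#' Fits univariate equal-variance Gaussian mixtures with 1..`kMax`
#' components (selected by BIC via \pkg{mclust}) and
#' designates the component holding the largest number of samples as the
#' normal cluster. The fit is deterministic for a given input vector.
#' Vectors shorter than `minSamples`, or with zero variance, fall back to
#' a single component; fitted standard deviations are floored at
#' `sigmaFloor` to keep downstream z-scores finite.
#'
#' @param values numeric vector of one gene's per-sample expression
#'   (log scale).
#' @param kMax maximum number of components (default 3).
#' @param minSamples single-component fallback threshold (default 8).
#' @param sigmaFloor standard-deviation floor; default 1e-3 times the
#'   gene's value range (an absolute floor of 1e-8 guards constant genes).
#' @return list with components `mu`, `sigma`, `pro` (numeric vectors over
#'   components), `classification` (hard assignment per sample), `normal`
#'   (index of the normal component) and `G` (number of components).
#' @examples
#' set.seed(1)
#' fit <- fitMixture(c(rnorm(80), rnorm(20, 5)))
#' fit$G
#' @export
fitMixture <- function(values, kMax = 3, minSamples = 8,
                       sigmaFloor = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (is.null(sigmaFloor))
    sigmaFloor <- max(1e-3 * diff(range(values)), 1e-8)
  single <- function() {
    list(mu = mean(values),
         sigma = max(stats::sd(values), sigmaFloor, na.rm = TRUE),
         pro = 1, classification = rep(1L, n), normal = 1L, G = 1L)
  }
  if (n < minSamples || stats::sd(values) < .Machine$double.eps)
    return(single())
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  # homoscedastic components only: an unequal-variance fit can park a
  # broad "background" component next to a narrow core, making the core
  # the normal cluster and exploding downstream z-scores
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = seq_len(kMax),
                                    modelNames = "E", verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(single())
  G <- fit$G
  mu <- as.numeric(fit$parameters$mean)
  var <- fit$parameters$variance$sigmasq
  if (length(var) == 1L) var <- rep(var, G)
  sigma <- pmax(sqrt(as.numeric(var)), sigmaFloor)
  cl <- as.integer(fit$classification)
  counts <- tabulate(cl, nbins = G)
  list(mu = mu, sigma = sigma, pro = as.numeric(fit$parameters$pro),
       classification = cl, normal = which.max(counts), G = G)
}

#' Z-scores and outlier flags relative to the normal component
#'
#' z = (x - mu_normal) / sigma_normal; a sample is an over (under)
#' outlier when z is strictly greater than `zThreshold` (strictly less
#' than `-zThreshold`). A sample sitting exactly at the threshold is not
#' flagged.
#'
#' @param fit a mixture fit from [fitMixture()].
#' @param values the same gene's per-sample expression (named).
#' @param zThreshold positive cutoff (default 2).
#' @return list with `z` (named numeric), `over`, `under` (named logical).
#' @examples
#' fit <- list(mu = 0, sigma = 1, normal = 1)
#' callOutliers(fit, c(a = 0, b = 2, c = -3))$under
#' @export
callOutliers <- function(fit, values, zThreshold = 2) {
  z <- (values - fit$mu[fit$normal]) / fit$sigma[fit$normal]
  list(z = z, over = z > zThreshold, under = z < -zThreshold)
}

#' Select the aberration direction by metastatic enrichment
#'
#' For each direction with at least one outlier, the one-sided
#' hypergeometric enrichment of metastatic samples among its outliers is
#' computed; the direction with the smaller enrichment p is returned when
#' that p falls below `pCutoff`. Ties break toward the direction with
#' more metastatic outliers, then toward `over`. `none` is returned when
#' neither direction qualifies.
#'
#' @param overSamples,underSamples character vectors of outlier sample
#'   identifiers in each direction.
#' @param sampleClass named character vector sample -> class; must contain
#'   at least one metastatic sample.
#' @param pCutoff enrichment significance cutoff (default 0.05).
#' @return list with `direction` ("over"/"under"/"none"), `p` (enrichment
#'   p of the chosen direction, NA when none), `pOver`, `pUnder`.
#' @export
selectDirection <- function(overSamples, underSamples, sampleClass,
                            pCutoff = 0.05) {
  met <- names(sampleClass)[sampleClass == "metastatic"]
  if (!length(met)) stop("cohort contains no metastatic samples")
  N <- length(sampleClass)
  M <- length(met)
  enrich <- function(s) {
    k <- length(s)
    if (!k) return(NA_real_)
    m <- length(intersect(s, met))
    stats::phyper(m - 1L, M, N - M, k, lower.tail = FALSE)
  }
  pOver <- enrich(overSamples)
  pUnder <- enrich(underSamples)
  metOver <- length(intersect(overSamples, met))
  metUnder <- length(intersect(underSamples, met))
  okOver <- !is.na(pOver) && pOver < pCutoff
  okUnder <- !is.na(pUnder) && pUnder < pCutoff
  direction <- "none"
  if (okOver && okUnder) {
    direction <- if (pOver < pUnder) "over"
      else if (pUnder < pOver) "under"
      else if (metOver > metUnder) "over"
      else if (metUnder > metOver) "under"
      else "over"
  } else if (okOver) direction <- "over"
    else if (okUnder) direction <- "under"
  list(direction = direction,
       p = switch(direction, over = pOver, under = pUnder, NA_real_),
       pOver = pOver, pUnder = pUnder)
}

#' Discretize an expression matrix into aberration calls
#'
#' Applies [fitMixture()], [callOutliers()] and [selectDirection()]
#' gene-wise. Genes whose outliers show no metastatic enrichment in
#' either direction are retained with direction `none` and all-`FALSE`
#' flags.
#'
#' @param x a [TFTargetExperiment-class].
#' @param config a [pipelineConfig()].
#' @return an [AberrationCalls-class].
#' @export
discretizeAberrations <- function(x, config = pipelineConfig()) {
  stopifnot(is(x, "TFTargetExperiment"))
  m <- exprMatrix(x)
  cls <- sampleClass(x)
  genes <- rownames(m)
  samples <- colnames(m)
  flags <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  z <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  direction <- character(nrow(m))
  enrichP <- rep(NA_real_, nrow(m))
  fits <- vector("list", nrow(m))
  names(fits) <- genes
  for (i in seq_along(genes)) {
    v <- stats::setNames(m[i, ], samples)
    fit <- fitMixture(v, kMax = config$kMax,
                      minSamples = config$minSamplesMixture,
                      sigmaFloor = max(config$sigmaFloorFrac *
                                         diff(range(v)), 1e-8))
    out <- callOutliers(fit, v, config$zThreshold)
    sel <- selectDirection(names(which(out$over)),
                           names(which(out$under)), cls,
                           pCutoff = config$directionPCutoff)
    z[i, ] <- out$z
    direction[i] <- sel$direction
    enrichP[i] <- sel$p
    if (sel$direction == "over") flags[i, ] <- out$over
    else if (sel$direction == "under") flags[i, ] <- out$under
    fits[[i]] <- fit
  }
  new("AberrationCalls", flags = flags, z = z, direction = direction,
      enrichP = enrichP, zThreshold = config$zThreshold, fits = fits)
}
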