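#' TF-based relaxed cutoff for a target gene
#'
#' Recomputes the target's outlier threshold from its expression within
#' the TF's outlier samples: the cutoff is the least-extreme target
#' z-score among those samples in the target's aberration direction,
#' clamped so it is never more permissive than |z| = `zMin` and never
#' stricter than the target's own |z| = `zThreshold` cutoff. Samples at
#' or beyond the cutoff in the aberration direction form the relaxed
#' outlier set (a superset of the target's own strict outlier set).
#'
#' @param targetZ named numeric vector of the target's z-scores over all
#'   samples.
#' @param tfOutlierSamples non-empty character vector of the TF's outlier
#'   samples.
#' @param direction the target's aberration direction, "over" or "under".
#' @param zThreshold the expression-based outlier cutoff (default 2).
#' @param zMin the permissiveness clamp (default 1).
#' @return list with `cutoffZ` (signed z cutoff) and `relaxed` (character
#'   vector of relaxed outlier samples).
#' @examples
#' z <- c(s1 = -3, s2 = -1.5, s3 = -0.2, s4 = -1.8)
#' tfBasedCutoff(z, c("s1", "s2"), "under")
#' @export
tfBasedCutoff <- function(targetZ, tfOutlierSamples, direction,
                          zThreshold = 2, zMin = 1) {
  if (!length(tfOutlierSamples)) stop("empty TF outlier set")
  if (!direction %in% c("over", "under"))
    stop("target has no aberration direction")
  bad <- setdiff(tfOutlierSamples, names(targetZ))
  if (length(bad))
    stop("TF outlier sample(s) missing from target z-scores: ",
         paste(bad, collapse = ", "))
  zSub <- targetZ[tfOutlierSamples]
  if (direction == "under") {
    cutoffZ <- max(min(max(zSub), -zMin), -zThreshold)
    relaxed <- names(targetZ)[targetZ <= cutoffZ]
  } else {
    cutoffZ <- min(max(min(zSub), zMin), zThreshold)
    relaxed <- names(targetZ)[targetZ >= cutoffZ]
  }
  list(cutoffZ = cutoffZ, relaxed = relaxed)
}

#' Modified contingency table for one TF-target pair
#'
#' True positives are counted against the target's own strict outlier
#' set (the TF gains no credit from the relaxed cutoff); the false
#' positive cell absorbs only the extra outliers the relaxed cutoff
#' admits, removing hidden-regulator effects from the association test.
#'
#' @param tfOutliers,exprOutliers,relaxedOutliers character sample sets:
#'   the TF's outliers, the target's strict expression-based outliers and
#'   the target's relaxed (TF-based) outliers. `exprOutliers` must be a
#'   subset of `relaxedOutliers`.
#' @param samples character vector of all cohort samples.
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @examples
#' buildContingency(c("s1","s2","s3"), c("s2","s3","s4"),
#'                  c("s2","s3","s4","s5"), paste0("s", 1:20))
#' @export
buildContingency <- function(tfOutliers, exprOutliers, relaxedOutliers,
                             samples) {
  for (s in list(tfOutliers, exprOutliers, relaxedOutliers))
    if (length(setdiff(s, samples)))
      stop("outlier set contains samples outside the cohort")
  if (length(setdiff(exprOutliers, relaxedOutliers)))
    stop("expression outliers must be a subset of the relaxed outliers")
  tp <- length(intersect(tfOutliers, exprOutliers))
  fp <- max(0L, length(relaxedOutliers) - length(exprOutliers))
  fn <- length(tfOutliers) - tp
  tn <- max(0L, length(samples) - tp - fp - fn)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional p-value by hypergeometric tail computation over all
#' tables with the observed margins. A table with a zero margin carries
#' no evidence and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative "greater" (default; enrichment of the top-left
#'   cell), "less", or "two.sided".
#' @return the p-value.
#' @examples
#' fisherExact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE), "greater") # 17/70
#' @export
fisherExact <- function(tab, alternative = c("greater", "less",
                                             "two.sided")) {
  alternative <- match.arg(alternative)
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table cells must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  a <- tab[1L, 1L]
  K <- sum(tab[1L, ])        # margin of the first row
  N <- sum(tab)
  k <- sum(tab[, 1L])        # margin of the first column
  p <- switch(alternative,
    greater = stats::phyper(a - 1, K, N - K, k, lower.tail = FALSE),
    less = stats::phyper(a, K, N - K, k),
    two.sided = stats::fisher.test(tab)$p.value)
  min(p, 1)
}

#' Infer pairwise TF -> target regulation candidates
#'
#' One modified Fisher's exact test per (aberrant TF, aberrant target)
#' pair: the TF's outlier samples are cross-classified against the
#' target's strict outliers, with the relaxed TF-based cutoff feeding the
#' false-positive cell (see [buildContingency()]). One-sided (enrichment)
#' p-values are corrected with Benjamini-Hochberg over all tested pairs
#' jointly. The regulation sign is `inhibition` when the TF and target
#' aberration directions disagree, `activation` otherwise.
#'
#' @param ab an [AberrationCalls-class] from [discretizeAberrations()].
#' @param x the matching [TFTargetExperiment-class].
#' @param config a [pipelineConfig()].
#' @return data.frame with one row per tested pair: `tf`, `target`,
#'   `cutoffZ`, `cutoff` (expression scale), `tp`, `fp`, `fn`, `tn`, `p`,
#'   `q`, `sign`, and a `tpSamples` list-column of the explained samples.
#'   Zero rows when no TF or no target is aberrant.
#' @export
inferPairwise <- function(ab, x, config = pipelineConfig()) {
  stopifnot(is(ab, "AberrationCalls"), is(x, "TFTargetExperiment"))
  dirs <- aberrationDirection(ab)
  flags <- aberrationFlags(ab)
  aberrant <- names(dirs)[dirs != "none" & rowSums(flags) > 0L]
  tfs <- intersect(tfNames(x), aberrant)
  tgts <- intersect(targetNames(x), aberrant)
  empty <- data.frame(tf = character(), target = character(),
                      cutoffZ = numeric(), cutoff = numeric(),
                      tp = integer(), fp = integer(), fn = integer(),
                      tn = integer(), p = numeric(), q = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  empty$tpSamples <- list()
  if (!length(tfs) || !length(tgts)) return(empty)
  samples <- colnames(flags)
  rows <- vector("list", length(tfs) * length(tgts))
  k <- 0L
  for (tf in tfs) {
    tfOut <- samples[flags[tf, ]]
    for (tg in tgts) {
      tgZ <- stats::setNames(ab@z[tg, ], samples)
      fit <- ab@fits[[tg]]
      relax <- tfBasedCutoff(tgZ, tfOut, dirs[[tg]],
                             zThreshold = config$zThreshold,
                             zMin = config$relaxZMin)
      exprOut <- samples[flags[tg, ]]
      tab <- buildContingency(tfOut, exprOut, relax$relaxed, samples)
      p <- fisherExact(matrix(tab[c("tp", "fp", "fn", "tn")], 2L,
                              byrow = TRUE), "greater")
      k <- k + 1L
      rows[[k]] <- data.frame(
        tf = tf, target = tg, cutoffZ = relax$cutoffZ,
        cutoff = fit$mu[fit$normal] +
          relax$cutoffZ * fit$sigma[fit$normal],
        tp = tab[["tp"]], fp = tab[["fp"]], fn = tab[["fn"]],
        tn = tab[["tn"]], p = p,
        sign = if (dirs[[tf]] == dirs[[tg]]) "activation"
               else "inhibition",
        stringsAsFactors = FALSE)
      rows[[k]]$tpSamples <- list(intersect(tfOut, exprOut))
    }
  }
  res <- do.call(rbind, rows[seq_len(k)])
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res[, c("tf", "target", "cutoffZ", "cutoff", "tp", "fp", "fn", "tn",
          "p", "q", "sign", "tpSamples")]
}
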