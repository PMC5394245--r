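#' Edge likelihood in bits from a Fisher p-value
#'
#' The description-length saving of encoding one TF -> target regulation,
#' -log2(p), capped to keep underflowed p-values finite.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param cap maximum likelihood in bits (default 300).
#' @return numeric vector of likelihoods.
#' @examples
#' edgeLikelihood(c(1, 0.25)) # 0 and 2 bits
#' @export
edgeLikelihood <- function(p, cap = 300) {
  out <- numeric(length(p))
  bad <- !is.finite(p) | p <= 0
  if (any(bad)) {
    warning("non-positive p-value(s); likelihood capped at ", cap,
            " bits")
    out[bad] <- cap
  }
  out[!bad] <- pmin(-log2(p[!bad]), cap)
  out
}

# Data-fit term of the objective with per-target novel-coverage
# weighting. For each target, its selected regulators are visited in
# canonical order (likelihood descending, then TF id); each edge is
# credited likelihood * (fraction of its explained samples not already
# covered for that target). Edges without recorded explained-sample sets
# are credited in full, so the term reduces to the plain sum of edge
# likelihoods whenever coverages are disjoint or unrecorded.
.networkFit <- function(edges) {
  if (!nrow(edges)) return(0)
  hasTp <- "tpSamples" %in% colnames(edges)
  fit <- 0
  for (tg in unique(edges$target)) {
    sub <- edges[edges$target == tg, , drop = FALSE]
    ord <- order(-sub$lik, sub$tf)
    covered <- character()
    for (i in ord) {
      tp <- if (hasTp) sub$tpSamples[[i]] else character()
      if (!length(tp)) {
        fit <- fit + sub$lik[i]
      } else {
        novel <- length(setdiff(tp, covered)) / length(tp)
        fit <- fit + sub$lik[i] * novel
        covered <- union(covered, tp)
      }
    }
  }
  fit
}

.objectiveFromEdges <- function(edges, m, S, n) {
  if (!nrow(edges) && m == 0L) return(0)
  .networkFit(edges) - m * log2(max(S, 1)) - nrow(edges) * log2(max(n, 1))
}

#' MDL objective of a regulatory network
#'
#' J = (data fit) - m * log2(S) - |E| * log2(n): the summed edge
#' likelihoods (novel-coverage weighted when several selected TFs explain
#' the same target, see the package vignette) minus the cost of naming
#' the m selected TFs among S candidates and each edge's target among n.
#' The empty network scores 0.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return the objective value in bits, recomputed from the network's
#'   parts.
#' @export
objectiveValue <- function(net) {
  stopifnot(is(net, "RegulatoryNetwork"))
  .objectiveFromEdges(net@edges, length(net@selected), net@S, net@n)
}

.prepareCandidates <- function(candidates, n, cap) {
  if (!nrow(candidates)) return(candidates)
  candidates$lik <- edgeLikelihood(candidates$p, cap = cap)
  # an edge costing more bits than it explains can never help
  candidates[candidates$lik >= log2(max(n, 1)), , drop = FALSE]
}

.makeNetwork <- function(selected, edges, S, n, cap) {
  edges <- edges[edges$tf %in% selected, , drop = FALSE]
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  new("RegulatoryNetwork", selected = sort(selected), edges = edges,
      S = as.integer(S), n = as.integer(n),
      objective = .objectiveFromEdges(edges, length(selected), S, n),
      likelihoodCap = cap)
}

#' Greedy forward MDL selection of driver TFs
#'
#' Starting from the empty network, repeatedly adds the candidate TF
#' (together with all its retained significant edges) yielding the
#' largest strictly positive objective gain; stops when no addition
#' gains. Ties break toward the lexicographically smaller TF id. Within
#' a TF, edges whose likelihood falls below log2(n) are dropped before
#' selection — they cost more to encode than they explain.
#'
#' @param candidates data.frame of FDR-significant regulation tests
#'   (columns `tf`, `target`, `p`; an optional `tpSamples` list-column
#'   enables redundancy-aware crediting).
#' @param S total number of candidate TFs.
#' @param n size of the target universe.
#' @param cap likelihood cap in bits (default 300).
#' @return a [RegulatoryNetwork-class].
#' @export
greedySelect <- function(candidates, S, n, cap = 300) {
  S <- as.integer(S); n <- as.integer(n)
  kept <- .prepareCandidates(candidates, n, cap)
  if (!nrow(kept)) return(.makeNetwork(character(), kept, S, n, cap))
  tfs <- sort(unique(kept$tf))
  selected <- character()
  Jcur <- 0
  repeat {
    remaining <- setdiff(tfs, selected)
    if (!length(remaining)) break
    gains <- vapply(remaining, function(t) {
      sel <- c(selected, t)
      e <- kept[kept$tf %in% sel, , drop = FALSE]
      .objectiveFromEdges(e, length(sel), S, n) - Jcur
    }, numeric(1))
    best <- remaining[order(-gains, remaining)][1L]
    if (gains[[best]] <= 1e-9) break
    selected <- c(selected, best)
    Jcur <- Jcur + gains[[best]]
  }
  .makeNetwork(selected, kept, S, n, cap)
}

#' Exhaustive MDL selection (test oracle)
#'
#' Enumerates all 2^k subsets of the candidate TFs and returns the
#' objective-maximal network; ties break toward fewer TFs, then
#' lexicographically. Refuses more than 15 candidate TFs.
#'
#' @inheritParams greedySelect
#' @return a [RegulatoryNetwork-class].
#' @export
exhaustiveSelect <- function(candidates, S, n, cap = 300) {
  S <- as.integer(S); n <- as.integer(n)
  if (S > 15L) stop("exhaustive search refused for S > 15")
  kept <- .prepareCandidates(candidates, n, cap)
  if (!nrow(kept)) return(.makeNetwork(character(), kept, S, n, cap))
  tfs <- sort(unique(kept$tf))
  if (length(tfs) > 15L) stop("exhaustive search refused for > 15 TFs")
  best <- list(J = 0, sel = character())
  for (mask in seq_len(2^length(tfs)) - 1L) {
    sel <- tfs[bitwAnd(mask, 2^(seq_along(tfs) - 1L)) > 0L]
    e <- kept[kept$tf %in% sel, , drop = FALSE]
    J <- .objectiveFromEdges(e, length(sel), S, n)
    replace <- J > best$J + 1e-12 ||
      (abs(J - best$J) <= 1e-12 &&
         (length(sel) < length(best$sel) ||
            (length(sel) == length(best$sel) &&
               paste(sort(sel), collapse = "\r") <
                 paste(sort(best$sel), collapse = "\r"))))
    if (replace) best <- list(J = J, sel = sel)
  }
  .makeNetwork(best$sel, kept, S, n, cap)
}
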