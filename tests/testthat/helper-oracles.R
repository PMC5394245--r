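# Independent brute-force oracles for the exact tests. These enumerate the
# hypergeometric support with choose() directly and never share code with
# the package implementation.

oracleTableProb <- function(a, K, N, k) {
  choose(K, a) * choose(N - K, k - a) / choose(N, k)
}

oracleFisher <- function(tab, alternative) {
  a <- tab[1, 1]
  K <- sum(tab[1, ]); N <- sum(tab); k <- sum(tab[, 1])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  lo <- max(0, k - (N - K)); hi <- min(K, k)
  support <- lo:hi
  probs <- vapply(support, oracleTableProb, 0, K = K, N = N, k = k)
  switch(alternative,
         greater = sum(probs[support >= a]),
         less = sum(probs[support <= a]),
         two.sided = sum(probs[probs <= probs[support == a] * (1 + 1e-7)]))
}

oracleBinomUpper <- function(x, n, p) {
  if (x <= 0) return(1)
  sum(choose(n, x:n) * p^(x:n) * (1 - p)^(n - (x:n)))
}

# random 2x2 table with all margins <= 30
randomTable <- function() {
  matrix(sample(0:7, 4, replace = TRUE), 2)
}
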