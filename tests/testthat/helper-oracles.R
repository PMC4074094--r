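# Independent oracles: direct enumeration / summation, never the library
# calls the implementation uses.

# Binomial upper tail by term-by-term summation of the mass function,
# written from the definition with explicit binomial coefficients.
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Hypergeometric upper tail by enumeration of the mass function
# choose(K, i) * choose(N-K, n-i) / choose(N, n).
oracleHyperUpper <- function(N, K, n, k) {
  i <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

oracleHyperLower <- function(N, K, n, k) {
  lo <- max(0, n - (N - K))
  if (k < lo) return(0)
  i <- lo:k
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exhaustive minimal-tail region search over ALL substrings of length >=
# minLen (no candidate pruning). Tie-break: lower P, then greater length,
# then smaller start.
oracleMinPRegion <- function(chars, residueSet, pSet, minLen) {
  L <- length(chars)
  flags <- chars %in% residueSet
  cs <- c(0L, cumsum(flags))
  starts <- integer(); ends <- integer()
  for (s in 1:(L - minLen + 1L)) {
    e <- (s + minLen - 1L):L
    starts <- c(starts, rep(s, length(e)))
    ends <- c(ends, e)
  }
  len <- ends - starts + 1L
  cnt <- cs[ends + 1L] - cs[starts]
  logp <- pbinom(cnt - 1L, len, pSet, lower.tail = FALSE, log.p = TRUE)
  best <- order(logp, -len, starts)[1L]
  list(start = starts[best], end = ends[best], count = cnt[best],
       length = len[best], pvalue = exp(logp[best]))
}

# Hand-stepped Holm procedure straight from its definition.
oracleHolm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

# Brute-force interaction-level contingency counts by a double loop over
# the pair list, straight from the counting definition.
oracleSetCounts <- function(pairs, sample, target) {
  N <- nrow(pairs); K <- 0L; n <- 0L; k <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    tT <- (a %in% target) || (b %in% target)
    tS <- (a %in% sample) || (b %in% sample)
    cross <- (a %in% sample && b %in% target) ||
             (b %in% sample && a %in% target)
    K <- K + tT; n <- n + tS; k <- k + cross
  }
  list(N = N, K = K, n = n, k = k)
}

# Random amino-acid sequence helper.
randomSeq <- function(L, freq = NULL) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  if (is.null(freq)) freq <- rep(1 / 20, 20)
  paste(sample(aa, L, replace = TRUE, prob = freq), collapse = "")
}

# Small uniform background shared by bias tests.
uniformBg <- stats::setNames(rep(1 / 20, 20),
  c("A","C","D","E","F","G","H","I","K","L",
    "M","N","P","Q","R","S","T","V","W","Y"))
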