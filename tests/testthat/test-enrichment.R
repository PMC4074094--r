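test_that("hypergeometric tails match direct enumeration", {
  expect_equal(hypergeomUpper(10, 4, 5, 3), 66 / 252)
  expect_equal(hypergeomLower(10, 4, 5, 1), 66 / 252)
  expect_equal(hypergeomUpper(100, 10, 5, 0), 1.0)
  expect_equal(hypergeomLower(100, 10, 5, 5), 1.0)
  set.seed(23)
  for (rep in 1:50) {
    N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomUpper(N, K, n, k), oracleHyperUpper(N, K, n, k),
                 tolerance = 1e-12)
    expect_equal(hypergeomLower(N, K, n, k), oracleHyperLower(N, K, n, k),
                 tolerance = 1e-12)
    # complement identity
    if (k >= 1)
      expect_equal(hypergeomUpper(N, K, n, k) + hypergeomLower(N, K, n, k - 1),
                   1, tolerance = 1e-12)
  }
  expect_error(hypergeomUpper(10, 11, 5, 2), "K <= N")
  expect_error(hypergeomUpper(10, 4, 5, 5), "min")
})

test_that("extreme tails stay representable in log space", {
  # population-scale depletion far below double underflow on the raw scale
  l10 <- hypergeomLower(36467, 19481, 4405, 0, log10p = TRUE)
  expect_true(is.finite(l10))
  expect_lt(l10, -1000)
})

test_that("published contingency cells reproduce their printed P-values", {
  expect_equal(hypergeomUpper(36467, 4405, 314, 63), 3.4e-5,
               tolerance = 0.02)
  expect_equal(hypergeomLower(36467, 19481, 314, 89), 9e-20,
               tolerance = 0.6)
  expect_equal(hypergeomUpper(36467, 4405, 20, 13), 4e-8, tolerance = 0.05)
})

test_that("Holm flags equal the hand-stepped procedure", {
  expect_equal(holmBonferroni(0.01, 0.05), TRUE)
  expect_equal(holmBonferroni(c(0.01, 0.03, 0.04), 0.05),
               c(TRUE, FALSE, FALSE))  # 0.03 > 0.05/2 stops the step-down
  expect_equal(holmBonferroni(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_length(holmBonferroni(numeric()), 0)
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.2)
    got <- holmBonferroni(p, alpha)
    expect_equal(got, oracleHolm(p, alpha))
    # sandwiched between Bonferroni and uncorrected rejections
    bonf <- p <= alpha / length(p)
    expect_true(all(got[bonf]))
    expect_true(all(p[got] <= alpha))
  }
})

test_that("Holm controls family-wise error on uniform null p-values", {
  set.seed(37)
  rej <- vapply(1:500, function(.)
    any(holmBonferroni(runif(72), 0.05)), logical(1))
  expect_lte(mean(rej), 0.07)
})

test_that("interaction enrichment counts match the brute-force oracle", {
  net <- interactionNetwork(
    a = c("A", "A", "B", "C", "X", "X", "Y", "A"),
    b = c("X", "Y", "X", "Z", "Z", "W", "Z", "B"))
  r <- interactorSetEnrichment(net, sample = "A", target = c("X", "Y"))
  want <- oracleSetCounts(net@pairs, "A", c("X", "Y"))
  expect_equal(r$N, want$N); expect_equal(r$K, want$K)
  expect_equal(r$n, want$n); expect_equal(r$k, want$k)

  set.seed(41)
  accs <- sprintf("P%02d", 1:25)
  net2 <- interactionNetwork(sample(accs, 80, TRUE), sample(accs, 80, TRUE))
  for (rep in 1:10) {
    s <- sample(accs, sample(1:12, 1)); t <- sample(accs, sample(1:12, 1))
    r <- interactorSetEnrichment(net2, s, t)
    w <- oracleSetCounts(net2@pairs, s, t)
    expect_equal(unlist(r[c("N", "K", "n", "k")], use.names = FALSE),
                 unlist(w, use.names = FALSE))
    expect_equal(r$p_raw,
                 if (r$direction == "enrichment")
                   oracleHyperUpper(w$N, w$K, w$n, w$k)
                 else oracleHyperLower(w$N, w$K, w$n, w$k),
                 tolerance = 1e-10)
  }
})

test_that("degenerate sample/target sets yield p = 1", {
  net <- interactionNetwork(c("A", "B"), c("B", "C"))
  r <- interactorSetEnrichment(net, "A", "ZZ")
  expect_equal(r$k, 0L)
  expect_equal(r$p_raw, 1)
  r2 <- interactorSetEnrichment(net, character(), "A")
  expect_equal(r2$n, 0L)
  expect_equal(r2$p_raw, 1)
})

test_that("sample = target counts set-internal interactions as k", {
  # the diagonal-cell semantics: k is internal pairs, not n
  net <- interactionNetwork(c("A", "A", "B", "C"), c("B", "X", "Y", "X"))
  r <- interactorSetEnrichment(net, c("A", "B"), c("A", "B"))
  expect_equal(r$n, 3L)   # A-B, A-X, B-Y
  expect_equal(r$k, 1L)   # only A-B is internal
})

test_that("restricted backgrounds reuse the same counting contract", {
  set.seed(43)
  accs <- sprintf("P%02d", 1:20)
  net <- interactionNetwork(sample(accs, 60, TRUE), sample(accs, 60, TRUE))
  bgset <- sample(accs, 8)
  bg <- restrictNetwork(net, bgset)
  expect_equal(numInteractions(bg), setInteractions(net, bgset)$n)
  s <- sample(accs, 5); t <- sample(accs, 5)
  r <- interactorSetEnrichment(net, s, t, background = bg)
  w <- oracleSetCounts(bg@pairs, s, t)
  expect_equal(unlist(r[c("N", "K", "n", "k")], use.names = FALSE),
               unlist(w, use.names = FALSE))
})

test_that("the enrichment grid corrects over its whole family", {
  set.seed(47)
  accs <- sprintf("P%02d", 1:30)
  net <- interactionNetwork(sample(accs, 100, TRUE), sample(accs, 100, TRUE))
  samples <- list(s1 = sample(accs, 6), s2 = sample(accs, 6))
  targets <- list(t1 = sample(accs, 6), t2 = sample(accs, 6))
  g <- enrichmentGrid(net, samples, targets)
  expect_equal(nrow(g), 4L)
  expect_equal(g$holm_significant, holmBonferroni(g$p_raw, 0.05))
  # extraP enlarges the family and can only lose rejections
  g2 <- enrichmentGrid(net, samples, targets, extraP = rep(1e-12, 68))
  expect_true(all(g2$holm_significant <= g$holm_significant))
})
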