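test_that("binomial tail matches term-by-term summation", {
  expect_equal(binomialTail(0, 10, 0.3), 1.0)
  expect_equal(binomialTail(3, 3, 0.5), 0.125)
  expect_equal(binomialTail(5, 10, 0.25), oracleBinomTail(5, 10, 0.25))
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(1:80, 1); k <- sample(0:n, 1); p <- runif(1, 0.01, 0.95)
    expect_equal(binomialTail(k, n, p), oracleBinomTail(k, n, p),
                 tolerance = 1e-10)
  }
  # monotonically non-increasing in k
  k <- 0:30
  expect_true(all(diff(binomialTail(k, 30, 0.2)) <= 0))
  expect_error(binomialTail(2, 5, 0), "p must be")
  expect_error(binomialTail(6, 5, 0.5), "0 <= k <= n")
})

test_that("minimal-tail region search is exact on canonical cases", {
  th <- biasThresholds()
  rec <- list(accession = "T1", sequence = strrep("Q", 20))
  r <- findMinPRegion(rec, "Q", uniformBg, th)
  expect_equal(c(r$start, r$end, r$count), c(1, 20, 20))

  # no N/Q at all: count 0, tail 1, longest region wins ties
  rec <- list(accession = "T2", sequence = strrep("A", 50))
  r <- findMinPRegion(rec, c("N", "Q"), uniformBg, th)
  expect_equal(r$count, 0)
  expect_equal(r$pvalue, 1.0)
  expect_equal(c(r$start, r$end), c(1, 50))

  rec <- list(accession = "T3", sequence = "MNQ")
  expect_message(r <- findMinPRegion(rec, "Q", uniformBg, th), "shorter")
  expect_null(r)
})

test_that("region search equals the exhaustive all-substrings oracle", {
  th <- biasThresholds()
  set.seed(17)
  for (rep in 1:30) {
    L <- sample(40:200, 1)
    # mix plain background sequences with planted N/Q-heavy stretches
    s <- randomSeq(L)
    if (rep %% 2 == 0) {
      dl <- sample(10:40, 1); st <- sample(1:(L - dl + 1), 1)
      dom <- paste(sample(c("N", "Q", "A"), dl, TRUE,
                          prob = c(.35, .35, .3)), collapse = "")
      substr(s, st, st + dl - 1) <- dom
    }
    chars <- strsplit(s, "")[[1]]
    got <- findMinPRegion(list(accession = "r", sequence = s),
                          c("N", "Q"), uniformBg, th)
    want <- oracleMinPRegion(chars, c("N", "Q"), 2 / 20,
                             th$minRegionLength)
    expect_equal(got[c("start", "end", "count", "length")],
                 want[c("start", "end", "count", "length")])
    expect_equal(got$pvalue, want$pvalue)
  }
})

test_that("poly-Q domains are accepted and exclusion rules reject", {
  th <- biasThresholds()
  # 60-residue poly-Q embedded in background: far below the main threshold
  rec <- list(accession = "P1",
              sequence = paste0(randomSeq(50), strrep("Q", 60), randomSeq(50)))
  res <- classifyNqp(rec, uniformBg, th)
  expect_true(res$accepted)
  expect_lt(res$region$pvalue, 1e-10)
  expect_equal(res$reason, "ok")

  # same bias with an embedded leucine run: the minimal-tail N/Q region
  # spans both Q blocks (60 of 75 residues), so the leucine bias inside it
  # triggers the exclusion rule
  lrun <- strrep("L", 15)  # P(15 L in 75 at p=1/20) ~ 2e-6 < 1e-4
  rec2 <- list(accession = "P2",
               sequence = paste0(randomSeq(50), strrep("Q", 30), lrun,
                                 strrep("Q", 30), randomSeq(50)))
  res2 <- classifyNqp(rec2, uniformBg, th)
  expect_false(res2$accepted)
  expect_equal(res2$reason, "excluded-residue bias")
  # confirm the sub-test with the summation oracle
  reg <- res2$region
  chars <- strsplit(toupper(rec2$sequence), "")[[1]]
  window <- chars[reg$start:reg$end]
  expect_lt(oracleBinomTail(sum(window == "L"), reg$length, 1 / 20), 1e-4)
})

test_that("sub-threshold N/Q bias is rejected at the main threshold", {
  th <- biasThresholds()
  # oracle-guided construction: spread k asparagines evenly through a
  # 60-residue window and pick the k whose MINIMAL region tail (over the
  # candidate residue sets and all subregions) lands in (1e-10, 1e-8)
  L <- 60
  minOracleP <- function(s) {
    chars <- strsplit(s, "")[[1]]
    min(oracleMinPRegion(chars, "N", 1 / 20, th$minRegionLength)$pvalue,
        oracleMinPRegion(chars, "Q", 1 / 20, th$minRegionLength)$pvalue,
        oracleMinPRegion(chars, c("N", "Q"), 2 / 20,
                         th$minRegionLength)$pvalue)
  }
  target <- NA; seqFound <- NULL
  for (k in 1:40) {
    chars <- rep("A", L)
    chars[round(seq(1, L, length.out = k))] <- "N"
    s <- paste(chars, collapse = "")
    p <- minOracleP(s)
    if (p > 1e-10 && p < 1e-8) { target <- k; seqFound <- s; break }
  }
  expect_false(is.na(target))
  res <- classifyNqp(list(accession = "B", sequence = seqFound),
                     uniformBg, th)
  expect_false(res$accepted)
  expect_equal(res$reason, "main threshold")
  expect_gt(res$region$pvalue, 1e-10)
  expect_lt(res$region$pvalue, 1e-8)
})

test_that("classification ignores case and trailing stops", {
  th <- biasThresholds()
  s <- paste0(randomSeq(40), strrep("Q", 50), randomSeq(40))
  a <- classifyNqp(list(accession = "C", sequence = s), uniformBg, th)
  b <- classifyNqp(list(accession = "C", sequence = tolower(s)), uniformBg, th)
  c3 <- classifyNqp(list(accession = "C", sequence = paste0(s, "*")),
                    uniformBg, th)
  expect_equal(a, b)
  expect_equal(a, c3)
})

test_that("stricter main thresholds never grow the NQP set", {
  set.seed(29)
  cfg <- synthConfig(nProteins = 40, plantedNqpFraction = 0.3,
                     lengthMeanlog = log(150), seed = 29)
  gp <- genProteome(cfg)
  bg <- proteomeComposition(gp$proteome)
  prev <- NULL
  for (mp in c(1e-8, 1e-10, 1e-12, 1e-14)) {
    nqp <- scanProteome(gp$proteome, bg,
                        biasThresholds(mainP = mp))$nqp
    if (!is.null(prev)) expect_true(all(nqp %in% prev))
    prev <- nqp
  }
})

test_that("reported region P-value falls as planted bias strengthens", {
  # paired seeds: same background sequence, stronger planted domain
  set.seed(31)
  worse <- 0
  for (rep in 1:25) {
    base <- randomSeq(150)
    st <- sample(1:90, 1)
    plant <- function(strength) {
      dom <- paste(ifelse(runif(60) < strength,
                          sample(c("N", "Q"), 60, TRUE), "A"), collapse = "")
      s <- base
      substr(s, st, st + 59) <- dom
      s
    }
    seedrep <- sample.int(1e6, 1)
    set.seed(seedrep); s1 <- plant(0.3)
    set.seed(seedrep); s2 <- plant(0.6)
    p1 <- findMinPRegion(list(accession = "w", sequence = s1), c("N", "Q"),
                         uniformBg)$pvalue
    p2 <- findMinPRegion(list(accession = "s", sequence = s2), c("N", "Q"),
                         uniformBg)$pvalue
    if (p2 > p1) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("proteome scan output is deterministic and well-formed", {
  cfg <- synthConfig(nProteins = 30, seed = 5)
  gp <- genProteome(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  s1 <- scanProteome(gp$proteome, file = f)
  s2 <- scanProteome(gp$proteome)
  expect_identical(s1, s2)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$start >= 1 & tab$end <= gp$proteome$length))
  expect_setequal(s1$nqp, tab$accession[tab$decision])
  # empty proteome
  expect_length(scanProteome(gp$proteome[0, ])$nqp, 0)
})
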