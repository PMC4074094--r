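chainDag <- function() {
  goDag(data.frame(id = c("GO:1", "GO:2", "GO:3"),
                   name = c("root", "mid", "leaf"),
                   namespace = "biological_process"),
        list("GO:1" = character(), "GO:2" = "GO:1", "GO:3" = "GO:2"))
}

test_that("annotation propagation closes chains and is idempotent", {
  dag <- chainDag()
  an <- goAnnotations(list(P1 = "GO:3"), dag)
  expect_setequal(an@propagated$P1, c("GO:1", "GO:2", "GO:3"))
  an2 <- goAnnotations(an@propagated, dag)
  expect_equal(lapply(an2@propagated, sort), lapply(an@propagated, sort))
})

test_that("OBO and GAF readers round-trip the generator output", {
  cfg <- synthConfig(nProteins = 40, nInteractions = 100, seed = 3)
  gp <- genProteome(cfg)
  obo <- withr::local_tempfile(fileext = ".obo")
  gaf <- withr::local_tempfile(fileext = ".gaf")
  ann <- genAnnotations(cfg, gp$proteome, oboFile = obo, gafFile = gaf)
  dag2 <- readGoOntology(obo)
  expect_equal(sort(dag2@terms$id), sort(ann$dag@terms$id))
  expect_equal(lapply(dag2@ancestors, sort),
               lapply(ann$dag@ancestors[names(dag2@ancestors)], sort))
  an2 <- readGoAnnotations(gaf, dag2)
  expect_equal(lapply(an2@direct[sort(names(an2@direct))], sort),
               lapply(ann$annot@direct[sort(names(ann$annot@direct))], sort))
})

test_that("NOT-qualified and unknown-term GAF rows are excluded", {
  dag <- chainDag()
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
    "UniProtKB\tP1\tP1\t\tGO:3\tPMID:1\tIEA\t\tP\t\t\tprotein\ttaxon:4932\t20200101\tDB\t\t",
    "UniProtKB\tP2\tP2\tNOT\tGO:3\tPMID:1\tIEA\t\tP\t\t\tprotein\ttaxon:4932\t20200101\tDB\t\t",
    "UniProtKB\tP3\tP3\t\tGO:999\tPMID:1\tIEA\t\tP\t\t\tprotein\ttaxon:4932\t20200101\tDB\t\t"),
    gaf)
  expect_warning(an <- readGoAnnotations(gaf, dag), "unknown")
  expect_named(an@direct, "P1")
})

test_that("cyclic ontologies are rejected", {
  expect_error(
    goDag(data.frame(id = c("GO:1", "GO:2"), name = c("a", "b"),
                     namespace = "biological_process"),
          list("GO:1" = "GO:2", "GO:2" = "GO:1")),
    "cyclic")
})

test_that("ancestor closure equals a matrix-power reachability oracle", {
  set.seed(53)
  for (rep in 1:3) {
    nT <- 50
    ids <- sprintf("GO:%03d", 1:nT)
    parents <- list(); parents[[ids[1]]] <- character()
    for (i in 2:nT)  # random DAG: up to 2 parents among earlier terms
      parents[[ids[i]]] <- ids[sample(seq_len(i - 1),
                                      min(i - 1, sample(1:2, 1)))]
    dag <- goDag(data.frame(id = ids, name = ids,
                            namespace = "biological_process"), parents)
    adj <- matrix(0, nT, nT, dimnames = list(ids, ids))
    for (id in ids) adj[id, parents[[id]]] <- 1
    reach <- (diag(nT) + adj) > 0  # (I + A)^(2^s) covers all path lengths
    for (s in 1:ceiling(log2(nT)))
      reach <- (reach %*% reach) > 0
    for (id in ids)
      expect_setequal(dag@ancestors[[id]],
                      setdiff(ids[reach[id, ] > 0], id))
  }
})

test_that("membership enrichment matches the hypergeometric oracle", {
  dag <- chainDag()
  universe <- sprintf("U%03d", 1:100)
  annotated <- universe[1:10]
  an <- goAnnotations(stats::setNames(as.list(rep("GO:3", 10)), annotated),
                      dag)
  res <- membershipEnrichment(annotated, an, universe)
  # all three chain terms annotate exactly those 10 proteins
  expect_equal(nrow(res), 3L)
  expect_equal(res$k, rep(10L, 3))
  expect_equal(res$p_raw, rep(oracleHyperUpper(100, 10, 10, 10), 3),
               tolerance = 1e-12)
  expect_true(all(res$holm_significant))

  # sample containing none of the annotated proteins: k=0, p=1
  res0 <- membershipEnrichment(universe[90:99], an, universe)
  expect_equal(res0$k, rep(0L, 3))
  expect_equal(res0$p_raw, rep(1, 3))

  # saturation: sample = universe gives k = K and p = 1
  resAll <- membershipEnrichment(universe, an, universe)
  expect_equal(resAll$k, resAll$K)
  expect_equal(resAll$p_raw, rep(1, 3))

  expect_equal(nrow(membershipEnrichment(character(), an, universe)), 0L)
})

test_that("high-membership collapse keeps the more specific term only when
           it improves the P-value", {
  dag <- chainDag()
  universe <- sprintf("U%03d", 1:60)
  # child GO:3 annotates 4 proteins, parent GO:2 a superset of 6
  direct <- c(stats::setNames(as.list(rep("GO:3", 4)), universe[1:4]),
              stats::setNames(as.list(rep("GO:2", 2)), universe[5:6]))
  an <- goAnnotations(direct, dag)
  sample <- universe[1:4]  # covers all of GO:3, 4/6 of GO:2
  res <- membershipEnrichment(sample, an, universe)
  high <- highMembershipReport(res, sample, an, dag, universe)
  # both terms have identical covered lists (the 4 sample proteins);
  # the child has the lower p (4/4 vs 4/6) so the parent collapses away
  expect_true("GO:3" %in% high$term)
  expect_false("GO:2" %in% high$term)
  expect_equal(high$fraction[high$term == "GO:3"], 1)

  # negative branch: make the child the WEAKER enrichment by annotating it
  # more broadly than the parent covers -- identical covered lists but
  # child p higher => both retained
  direct2 <- c(stats::setNames(as.list(rep("GO:3", 8)), universe[1:8]),
               stats::setNames(as.list(rep("GO:2", 0)), character()))
  an2 <- goAnnotations(direct2, dag)
  res2 <- membershipEnrichment(universe[1:8], an2, universe)
  # here child and parent have identical annotation sets and identical p;
  # p_child < p_parent is FALSE, so both survive
  high2 <- highMembershipReport(res2, universe[1:8], an2, dag, universe)
  expect_true(all(c("GO:2", "GO:3") %in% high2$term))

  # fraction filter: a term with 3/8 coverage is dropped at 0.5
  res3 <- membershipEnrichment(universe[1:3], an2, universe)
  high3 <- highMembershipReport(res3, universe[1:3], an2, dag, universe,
                                maxP = 1)
  expect_equal(nrow(high3), 0L)
})

test_that("interaction GO enrichment deduplicates protein-term pairs", {
  dag <- chainDag()
  # A interacts with B and C; both annotated only to GO:3
  net <- interactionNetwork(c("A", "A"), c("B", "C"))
  an <- goAnnotations(list(B = "GO:3", C = "GO:3"), dag)
  res <- interactionGoEnrichment(net, "A", an)
  # A contributes exactly one pair per term of the chain
  rowA <- res[res$term == "GO:3", ]
  expect_equal(rowA$k, 1L)

  expect_equal(nrow(interactionGoEnrichment(interactionNetwork(), "A", an)),
               0L)
})

test_that("interaction GO counts equal a brute-force pair construction", {
  dag <- chainDag()
  set.seed(59)
  prots <- sprintf("Q%d", 1:6)
  net <- interactionNetwork(sample(prots, 10, TRUE), sample(prots, 10, TRUE))
  direct <- lapply(stats::setNames(nm = prots), function(.)
    sample(c("GO:1", "GO:2", "GO:3"), sample(0:2, 1)))
  direct <- direct[lengths(direct) > 0]
  an <- goAnnotations(direct, dag)
  smp <- sample(prots, 3)
  res <- interactionGoEnrichment(net, smp, an)
  # brute force: enumerate deduplicated (protein, term) pairs
  pairs <- list()
  for (A in unique(c(net@pairs$a, net@pairs$b))) {
    terms <- character()
    for (B in interactors(net, A))
      terms <- union(terms, an@propagated[[B]])
    for (tt in terms) pairs[[length(pairs) + 1]] <- c(A, tt)
  }
  pm <- do.call(rbind, pairs)
  expect_equal(unique(res$N), nrow(pm))
  for (i in seq_len(nrow(res))) {
    tt <- res$term[i]
    expect_equal(res$K[i], sum(pm[, 2] == tt))
    expect_equal(res$n[i], sum(pm[, 1] %in% smp))
    expect_equal(res$k[i], sum(pm[, 1] %in% smp & pm[, 2] == tt))
    expect_true(res$k[i] <= res$n[i] && res$k[i] <= res$K[i])
  }
  # invariance to duplicate evidence and input order
  net2 <- interactionNetwork(c(net@pairs$b, net@pairs$a),
                             c(net@pairs$a, net@pairs$b))
  res2 <- interactionGoEnrichment(net2, smp, an)
  expect_equal(res2, res)
})

test_that("cross-referencing intersects corrected-significant terms", {
  mk <- function(terms, sig) data.frame(term = terms, holm_significant = sig)
  a <- mk(c("X", "Y"), c(TRUE, TRUE))
  b <- mk(c("Y", "Z"), c(TRUE, TRUE))
  c3 <- mk(c("Y", "W"), c(TRUE, FALSE))
  expect_equal(crossReference(a, b, c3), "Y")
  expect_length(crossReference(a, mk("Q", TRUE), c3), 0)
  set.seed(61)
  for (rep in 1:5) {
    ls <- lapply(1:3, function(.) mk(sample(LETTERS, 10),
                                     runif(10) < 0.5))
    want <- Reduce(intersect, lapply(ls, function(x)
      x$term[x$holm_significant]))
    expect_setequal(crossReference(ls[[1]], ls[[2]], ls[[3]]), want)
  }
})

test_that("GO membership enrichment is calibrated under the generator null", {
  # coupling odds 1: the examined set is independent of annotations, so
  # term counts are genuinely hypergeometric; corrected significance should
  # be rare
  hits <- 0
  for (sd in 1:40) {
    cfg <- synthConfig(nProteins = 120, nGoTerms = 40, seed = sd)
    gp <- genProteome(cfg)
    ann <- genAnnotations(cfg, gp$proteome)
    smp <- sample(gp$proteome$accession, 20)
    res <- membershipEnrichment(smp, ann$annot, gp$proteome$accession)
    if (nrow(res) && any(res$holm_significant)) hits <- hits + 1
  }
  expect_lte(hits, 4)  # FWER at 0.05: expect ~2 of 40
})
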