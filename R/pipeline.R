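#' Run the full network-enrichment analysis from a configuration
#'
#' Orchestrates: set assembly -> optional N/Q-rich domain scan -> network
#' parse -> interaction enrichment grid (whole-network and restricted
#' backgrounds) -> composite-set / hub / non-hub grid -> the GO triad
#' (membership, high-membership, interaction-based) -> cross-reference ->
#' Monte-Carlo disorder test -> category-annotated edge-list export. Every
#' table is written as TSV into the output directory together with a run
#' log (seed, counts) and the serialized configuration. Reports are
#' reproducible bit-for-bit under a fixed configuration and seed.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{fasta}{proteome FASTA path (required).}
#'     \item{mitab}{MITAB interaction file path (required).}
#'     \item{disorder}{disorder TSV path (optional).}
#'     \item{obo, gaf}{GO ontology/annotation paths (optional; enables the
#'       GO triad).}
#'     \item{nqpFile}{accession list for the NQP set; when absent the set
#'       is recomputed with [scanProteome()].}
#'     \item{pbdFile}{accession list of the PBD catalog (optional).}
#'     \item{alpha}{family-wise level, default 0.05.}
#'     \item{minPartners}{hub threshold, default 10.}
#'     \item{mcSamples}{Monte-Carlo samples, default 10000.}
#'     \item{seed}{RNG seed, default 1.}
#'     \item{outDir}{output directory (required).}
#'   }
#' @return invisibly, a list with every intermediate and result object.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(alpha = 0.05, minPartners = 10L, mcSamples = 10000L, seed = 1L),
    config)
  for (req in c("fasta", "mitab", "outDir"))
    if (is.null(cfg[[req]])) stop("config missing required field: ", req)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- c(sprintf("prionNets %s", as.character(utils::packageVersion("prionNets"))),
                sprintf("seed: %d", cfg$seed))
  note <- function(...) logLines <<- c(logLines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  set.seed(cfg$seed)

  proteome <- stage("proteome", readProteome(cfg$fasta))
  note("proteome: %d proteins", nrow(proteome))

  sets <- stage("sets", {
    s <- loadCuratedSets()
    s <- lapply(s, function(x) intersect(x, proteome$accession))
    if (!is.null(cfg$kpFile)) s$KP <- readProteinList(cfg$kpFile)
    if (!is.null(cfg$epdFile)) s$EPD <- readProteinList(cfg$epdFile)
    if (!is.null(cfg$epnFile)) s$EPN <- readProteinList(cfg$epnFile)
    s
  })

  scanRes <- NULL
  sets$NQP <- stage("nqp", {
    if (!is.null(cfg$nqpFile)) readProteinList(cfg$nqpFile)
    else {
      scanRes <- scanProteome(proteome,
                              file = file.path(cfg$outDir, "bias_scan.tsv"))
      scanRes$nqp
    }
  })
  note("set sizes: KP=%d EPD=%d EPN=%d NQP=%d", length(sets$KP),
       length(sets$EPD), length(sets$EPN), length(sets$NQP))

  network <- stage("network", readMitab(cfg$mitab))
  note("network: %d interactions (N)", numInteractions(network))

  tracks <- if (!is.null(cfg$disorder))
    stage("disorder", readDisorderTracks(cfg$disorder)) else NULL
  pbd <- if (!is.null(cfg$pbdFile))
    stage("pbd", readProteinList(cfg$pbdFile)) else character()
  composite <- stage("composite",
    deriveCompositeSets(sets$NQP, pbd, tracks))

  targets1 <- list(KP = sets$KP, EPD = sets$EPD, NQP = sets$NQP,
                   EPN = sets$EPN,
                   disordered_not_NQP = composite$disordered_not_NQP)
  samples1 <- list(KP = sets$KP, EPD = sets$EPD, EPN = sets$EPN,
                   NQP = sets$NQP)
  grid1 <- stage("enrichment-grid",
    enrichmentGrid(network, samples1, targets1, alpha = cfg$alpha,
                   file = file.path(cfg$outDir, "table1")))
  for (i in seq_len(nrow(grid1)))
    note("cell %s: N=%d K=%d n=%d k=%d", grid1$label[i], grid1$N[i],
         grid1$K[i], grid1$n[i], grid1$k[i])

  nqpBg <- stage("restricted-background", restrictNetwork(network, sets$NQP))
  gridS1 <- stage("restricted-grid",
    enrichmentGrid(network, samples1["NQP" != names(samples1)],
                   list(NQP = sets$NQP), background = nqpBg,
                   alpha = cfg$alpha,
                   file = file.path(cfg$outDir, "tableS1")))

  hubs <- stage("hubs",
    findHubs(network, sets$EPD, sets$NQP, minPartners = cfg$minPartners))
  utils::write.table(hubs, file.path(cfg$outDir, "hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("hubs: %d (>=%d NQP partners)", nrow(hubs), cfg$minPartners)
  targets2 <- c(list(NQP = sets$NQP), composite)
  grid2 <- stage("hub-partition",
    partitionAndEnrich(network, sets$EPD, hubs$accession, targets2,
                       alpha = cfg$alpha))
  utils::write.table(grid2, file.path(cfg$outDir, "table2_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  goRes <- NULL
  if (!is.null(cfg$obo) && !is.null(cfg$gaf)) {
    goRes <- stage("go-triad", {
      dag <- readGoOntology(cfg$obo)
      annot <- readGoAnnotations(cfg$gaf, dag)
      universe <- proteome$accession
      memb <- membershipEnrichment(sets$NQP, annot, universe,
                                   alpha = cfg$alpha)
      high <- highMembershipReport(memb, sets$NQP, annot, dag, universe)
      intGo <- interactionGoEnrichment(network, sets$NQP, annot,
                                       alpha = cfg$alpha)
      hubGo <- if (nrow(hubs)) {
        hi <- unique(unlist(lapply(hubs$accession, function(h)
          intersect(interactors(network, h), sets$NQP))))
        membershipEnrichment(intersect(hi, universe), annot, universe,
                             alpha = cfg$alpha)
      } else memb[0, ]
      shared <- crossReference(high, intGo, hubGo)
      utils::write.table(memb, file.path(cfg$outDir, "go_membership.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(high, file.path(cfg$outDir, "go_high_membership.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(intGo, file.path(cfg$outDir, "go_interaction.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(shared, file.path(cfg$outDir, "go_cross_reference.txt"))
      list(membership = memb, high = high, interaction = intGo,
           hub = hubGo, shared = shared)
    })
    note("go: %d terms cross-referenced", length(goRes$shared))
  }

  mc <- NULL
  if (!is.null(tracks)) {
    mc <- stage("disorder-mc", {
      res <- lapply(sets[c("KP", "EPD", "EPN")], function(s) {
        s <- intersect(s, tracks@summary$accession)
        if (!length(s)) return(NULL)
        mcDisorderTest(s, tracks, nSamples = cfg$mcSamples)
      })
      keep <- !vapply(res, is.null, logical(1))
      summ <- data.frame(
        set = names(res)[keep],
        observed = vapply(res[keep], `[[`, numeric(1), "observed"),
        target_length = vapply(res[keep], `[[`, numeric(1), "targetLength"),
        exceed_percent = 100 * vapply(res[keep], `[[`, numeric(1),
                                      "exceedFraction"))
      utils::write.table(summ, file.path(cfg$outDir, "disorder_mc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res[keep]
    })
  }

  stage("edge-export",
    exportAnnotatedEdges(network, sets,
                         file = file.path(cfg$outDir, "edges_annotated.tsv")))

  writeLines(logLines, file.path(cfg$outDir, "run_log.txt"))
  writeLines(deparse(cfg), file.path(cfg$outDir, "config.R.txt"))
  invisible(list(config = cfg, proteome = proteome, sets = sets,
                 composite = composite, network = network, tracks = tracks,
                 scan = scanRes, grid1 = grid1, gridS1 = gridS1,
                 hubs = hubs, grid2 = grid2, go = goRes, mc = mc))
}
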