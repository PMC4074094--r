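#' Configuration for the synthetic data generator
#'
#' Defaults emulate the statistical structure the analysis assumes, at desk
#' scale: a 500-protein proteome with yeast-like aggregate composition and
#' log-normal lengths (median 400 residues), 8% of proteins carrying a
#' planted N/Q-rich domain (60 residues at N/Q probability 0.4), a
#' 2000-interaction network with category preference odds, a 60-term
#' tree-shaped biological-process DAG with term/set coupling odds, and
#' per-protein disorder around a base rate of 0.2 boosted by 0.5 for
#' planted-domain proteins.
#'
#' @param nProteins number of proteins.
#' @param lengthMeanlog,lengthSdlog log-normal length distribution.
#' @param minLength floor on protein length (residues).
#' @param background named amino-acid frequencies (default yeast-like).
#' @param plantedNqpFraction fraction of proteins receiving a planted
#'   domain.
#' @param biasStrength probability that a planted-domain residue is N/Q.
#' @param domainLength planted domain length (residues).
#' @param nInteractions unique interactions to sample.
#' @param preferenceOdds square matrix of acceptance odds over category
#'   pairs (dimnames = categories); NULL means all 1 (uniform graph).
#' @param nGoTerms number of GO terms in the random tree DAG.
#' @param dagDepth approximate tree depth.
#' @param leafAnnotationProb base probability a protein is annotated to a
#'   given leaf term.
#' @param couplingOdds named list: term id -> list(set = accessions,
#'   odds = numeric); boosts those proteins' annotation odds for that term.
#' @param disorderBase mean disorder fraction for background proteins.
#' @param disorderBoost added mean disorder fraction for planted-NQP
#'   proteins.
#' @param seed RNG seed recorded in every output.
#' @return list of class \code{synthConfig}.
#' @export
synthConfig <- function(nProteins = 500L,
                        lengthMeanlog = log(400), lengthSdlog = 0.45,
                        minLength = 50L,
                        background = YEAST_AA_FREQ,
                        plantedNqpFraction = 0.08,
                        biasStrength = 0.4, domainLength = 60L,
                        nInteractions = 2000L,
                        preferenceOdds = NULL,
                        nGoTerms = 60L, dagDepth = 3L,
                        leafAnnotationProb = 0.05,
                        couplingOdds = list(),
                        disorderBase = 0.2, disorderBoost = 0.5,
                        seed = 1L) {
  stopifnot(plantedNqpFraction >= 0, plantedNqpFraction <= 1,
            biasStrength >= 0, biasStrength <= 1,
            disorderBase >= 0, disorderBase <= 1,
            abs(sum(background) - 1) < 1e-9)
  if (!is.null(preferenceOdds) && any(preferenceOdds < 0))
    stop("preference odds must be >= 0")
  structure(as.list(environment()), class = "synthConfig")
}

#' Generate a synthetic proteome with planted N/Q-rich domains
#'
#' Sequences are drawn i.i.d. from the background composition; a configured
#' fraction of proteins receives an inserted domain whose residues are N or
#' Q (equiprobable) with probability \code{biasStrength}, otherwise drawn
#' from the background. The truth table records each planted domain's
#' coordinates and realized N/Q count; downstream recovery tests read the
#' truth, never recompute it.
#'
#' @param cfg a [synthConfig()] object.
#' @param file optional FASTA output path.
#' @return list: \code{proteome} (data.frame accession/sequence/length),
#'   \code{truth} (data.frame accession/start/end/nq_count for planted
#'   domains), \code{seed}.
#' @export
genProteome <- function(cfg, file = NULL) {
  set.seed(cfg$seed)
  n <- cfg$nProteins
  lens <- pmax(cfg$minLength,
               round(stats::rlnorm(n, cfg$lengthMeanlog, cfg$lengthSdlog)))
  acc <- sprintf("SYN%04d", seq_len(n))
  aa <- names(cfg$background)
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE, prob = cfg$background),
          collapse = ""), character(1))
  nPlant <- round(cfg$plantedNqpFraction * n)
  truth <- data.frame(accession = character(), start = integer(),
                      end = integer(), nq_count = integer(),
                      stringsAsFactors = FALSE)
  if (nPlant > 0) {
    planted <- sample.int(n, nPlant)
    for (i in planted) {
      L <- lens[i]; dl <- min(cfg$domainLength, L)
      start <- sample.int(L - dl + 1L, 1L)
      dom <- vapply(seq_len(dl), function(.) {
        if (stats::runif(1) < cfg$biasStrength)
          sample(c("N", "Q"), 1L)
        else sample(aa, 1L, prob = cfg$background)
      }, character(1))
      s <- strsplit(seqs[i], "")[[1]]
      s[start:(start + dl - 1L)] <- dom
      seqs[i] <- paste(s, collapse = "")
      truth <- rbind(truth, data.frame(
        accession = acc[i], start = start, end = start + dl - 1L,
        nq_count = sum(dom %in% c("N", "Q")), stringsAsFactors = FALSE))
    }
    truth <- truth[order(truth$accession), , drop = FALSE]
    rownames(truth) <- NULL
  }
  proteome <- data.frame(accession = acc, sequence = seqs,
                         length = nchar(seqs), stringsAsFactors = FALSE)
  if (!is.null(file)) writeProteome(proteome, file)
  list(proteome = proteome, truth = truth, seed = cfg$seed)
}

#' Assign study-like category sets over synthetic accessions
#'
#' Mirrors the curated study structure at generator scale: 10 "KP" inside
#' 27 "EPD", 18 disjoint "EPN", and "NQP" = the planted-domain proteins
#' (or a random set of matching size when no truth is supplied).
#'
#' @param accessions proteome accessions.
#' @param truth planted-domain truth table from [genProteome()] (optional).
#' @param sizes named integer vector with elements KP, EPD, EPN.
#' @param seed RNG seed.
#' @return named list of accession vectors: KP, EPD, EPN, NQP, other.
#' @export
genStudySets <- function(accessions, truth = NULL,
                         sizes = c(KP = 10L, EPD = 27L, EPN = 18L),
                         seed = 1L) {
  set.seed(seed)
  nqp <- if (!is.null(truth) && nrow(truth)) truth$accession
         else sample(accessions, max(1L, round(0.08 * length(accessions))))
  pool <- sample(setdiff(accessions, nqp))
  epd <- pool[seq_len(sizes[["EPD"]])]
  kp <- epd[seq_len(sizes[["KP"]])]
  epn <- pool[sizes[["EPD"]] + seq_len(sizes[["EPN"]])]
  list(KP = kp, EPD = epd, EPN = epn, NQP = nqp,
       other = setdiff(accessions, c(epd, epn, nqp)))
}

# Category of each accession under a named list of (possibly overlapping)
# sets; first matching set wins, "other" if none.
categoryOf <- function(accessions, sets) {
  cat <- rep("other", length(accessions))
  for (nm in rev(names(sets)))
    cat[accessions %in% sets[[nm]]] <- nm
  cat
}

#' Generate an interaction network with planted category preference
#'
#' Samples unique unordered protein pairs uniformly and accepts each with
#' probability proportional to the preference odds of its category pair; an
#' all-ones odds matrix yields a uniform random graph. Optionally writes a
#' MITAB 2.5 file parseable by [readMitab()].
#'
#' @param cfg a [synthConfig()] object (uses \code{nInteractions},
#'   \code{preferenceOdds}, \code{seed}).
#' @param accessions proteome accessions.
#' @param categories character vector (parallel to accessions) of category
#'   labels matching the odds matrix dimnames, or NULL for uniform.
#' @param file optional MITAB output path.
#' @return an [InteractionNetwork-class] object.
#' @export
genNetwork <- function(cfg, accessions, categories = NULL, file = NULL) {
  set.seed(cfg$seed)
  nP <- length(accessions)
  m <- cfg$nInteractions
  if (m > nP * (nP - 1) / 2)
    stop("requested interactions exceed possible pairs")
  odds <- cfg$preferenceOdds
  if (m == 0) {
    net <- interactionNetwork()
  } else {
    key <- character(0)
    a <- integer(0); b <- integer(0)
    maxOdds <- if (is.null(odds)) 1 else max(odds)
    while (length(key) < m) {
      todo <- (m - length(key)) * 2L + 20L
      i <- sample.int(nP, todo, replace = TRUE)
      j <- sample.int(nP, todo, replace = TRUE)
      ok <- i != j
      i <- i[ok]; j <- j[ok]
      if (!is.null(odds)) {
        w <- odds[cbind(categories[i], categories[j])] / maxOdds
        keep <- stats::runif(length(i)) < w
        i <- i[keep]; j <- j[keep]
      }
      lo <- pmin(i, j); hi <- pmax(i, j)
      kk <- paste(lo, hi)
      new <- !kk %in% key & !duplicated(kk)
      key <- c(key, kk[new])
      a <- c(a, lo[new]); b <- c(b, hi[new])
    }
    a <- a[seq_len(m)]; b <- b[seq_len(m)]
    net <- interactionNetwork(accessions[a], accessions[b])
  }
  if (!is.null(file)) writeMitab(net, file)
  net
}

#' Write an interaction network as MITAB 2.5
#'
#' @param network an [InteractionNetwork-class] object.
#' @param file output path.
#' @param taxid taxon id written in columns 10-11 (default 559292).
#' @return invisibly, the path.
#' @export
writeMitab <- function(network, file, taxid = 559292L) {
  p <- network@pairs
  tax <- sprintf("taxid:%d(synthetic yeast)", taxid)
  lines <- sprintf(
    "uniprotkb:%s\tuniprotkb:%s\t-\t-\t-\t-\tpsi-mi:\"MI:0018\"(two hybrid)\t-\tpubmed:0\t%s\t%s\tpsi-mi:\"MI:0915\"(physical association)\tpsi-mi:\"MI:0469\"(IntAct)\t-\t-",
    p$a, p$b, tax, tax)
  writeLines(c("#ID(s) interactor A\tID(s) interactor B\tAlt. ID(s) A\tAlt. ID(s) B\tAlias(es) A\tAlias(es) B\tInteraction detection method(s)\tPublication 1st author(s)\tPublication Identifier(s)\tTaxid interactor A\tTaxid interactor B\tInteraction type(s)\tSource database(s)\tInteraction identifier(s)\tConfidence value(s)",
               lines), file)
  invisible(file)
}

#' Generate GO annotations, ontology and disorder tracks
#'
#' Builds a random tree-shaped biological-process DAG (each term has one
#' parent among earlier terms, bounded depth), annotates proteins to leaf
#' terms with a base probability boosted by term/set coupling odds (odds o
#' turn probability p into op/(1-p+op)), propagates up the tree, and draws
#' per-protein disorder fractions (Beta-distributed around the base rate,
#' boosted for planted-NQP proteins). Optionally writes OBO, GAF and
#' disorder TSV files parseable by the package readers.
#'
#' @param cfg a [synthConfig()] object.
#' @param proteome proteome data.frame (accession, length at minimum).
#' @param nqp accessions whose disorder is boosted (the planted set).
#' @param oboFile,gafFile,disorderFile optional output paths.
#' @return list: \code{dag} ([GoDag-class]), \code{annot}
#'   ([GoAnnotations-class]), \code{tracks} ([DisorderTracks-class]).
#' @export
genAnnotations <- function(cfg, proteome, nqp = character(),
                           oboFile = NULL, gafFile = NULL,
                           disorderFile = NULL) {
  set.seed(cfg$seed + 1L)
  nT <- cfg$nGoTerms
  ids <- sprintf("GO:%07d", seq_len(nT))
  depth <- integer(nT); depth[1] <- 0L
  parents <- vector("list", nT); parents[[1]] <- character()
  for (i in seq_len(nT)[-1]) {
    elig <- which(depth[seq_len(i - 1L)] < cfg$dagDepth)
    p <- if (length(elig) == 1L) elig else sample(elig, 1L)
    parents[[i]] <- ids[p]
    depth[i] <- depth[p] + 1L
  }
  names(parents) <- ids
  terms <- data.frame(id = ids, name = paste("synthetic process", seq_len(nT)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  dag <- goDag(terms, parents)
  leaves <- ids[!ids %in% unlist(parents, use.names = FALSE)]
  acc <- proteome$accession
  direct <- stats::setNames(vector("list", length(acc)), acc)
  boost <- function(p, o) o * p / (1 - p + o * p)
  for (leaf in leaves) {
    pr <- rep(cfg$leafAnnotationProb, length(acc))
    cp <- cfg$couplingOdds[[leaf]]
    if (!is.null(cp))
      pr[acc %in% cp$set] <- boost(cfg$leafAnnotationProb, cp$odds)
    hit <- stats::runif(length(acc)) < pr
    for (A in acc[hit]) direct[[A]] <- c(direct[[A]], leaf)
  }
  direct <- direct[lengths(direct) > 0]
  annot <- goAnnotations(direct, dag)
  lens <- proteome$length
  mu <- ifelse(acc %in% nqp,
               pmin(0.95, cfg$disorderBase + cfg$disorderBoost),
               cfg$disorderBase)
  conc <- 30
  frac <- stats::rbeta(length(acc), mu * conc, (1 - mu) * conc)
  dis <- round(frac * lens)
  tracks <- disorderTracks(acc, lens, dis)
  if (!is.null(oboFile)) {
    stanzas <- vapply(seq_len(nT), function(i) paste0(
      "[Term]\nid: ", ids[i], "\nname: ", terms$name[i],
      "\nnamespace: biological_process\n",
      paste0(vapply(parents[[i]], function(p)
        paste0("is_a: ", p, " ! parent\n"), character(1)), collapse = "")),
      character(1))
    writeLines(c("format-version: 1.2", "", stanzas), oboFile)
  }
  if (!is.null(gafFile)) {
    rows <- unlist(lapply(names(direct), function(A)
      sprintf("UniProtKB\t%s\t%s\t\t%s\tPMID:0\tIEA\t\tP\t\t\tprotein\ttaxon:559292\t20140101\tSYN\t\t",
              A, A, direct[[A]])), use.names = FALSE)
    writeLines(c("!gaf-version: 2.1", rows), gafFile)
  }
  if (!is.null(disorderFile)) {
    writeLines(c("# accession\tlength\tdisordered_count",
                 sprintf("%s\t%d\t%d", acc, lens, dis)), disorderFile)
  }
  list(dag = dag, annot = annot, tracks = tracks)
}
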