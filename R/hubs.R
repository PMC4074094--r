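#' Find partner-set hubs within a sample set
#'
#' Members of \code{sample} with at least \code{minPartners} distinct
#' interactors in \code{partnerSet}, sorted by that partner count
#' descending. The default threshold of 10 is the operational reading of
#' "more than 10" partner-set interactors that reproduces the three
#' published hubs (one of which has exactly 10).
#'
#' @param network an [InteractionNetwork-class] object.
#' @param sample character vector (e.g. the EPD set).
#' @param partnerSet character vector (e.g. the NQP set).
#' @param minPartners hub threshold (default 10).
#' @return data.frame: accession, interactor_count, partner_count, p_raw
#'   (per-hub enrichment, see [hubEnrichment()]).
#' @export
findHubs <- function(network, sample, partnerSet, minPartners = 10L) {
  rows <- lapply(sample, function(acc) {
    ints <- interactors(network, acc)
    data.frame(accession = acc, interactor_count = length(ints),
               partner_count = sum(ints %in% partnerSet),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$partner_count >= minPartners, , drop = FALSE]
  if (!nrow(tab)) {
    tab$p_raw <- numeric(0)
    return(tab)
  }
  tab$p_raw <- vapply(tab$accession, function(acc)
    hubEnrichment(network, acc, partnerSet)$p_raw, numeric(1))
  tab <- tab[order(-tab$partner_count, tab$accession), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-hub partner-set enrichment
#'
#' For one hub protein: n = its distinct interactors, k = those in the
#' partner set; upper-tail hypergeometric against the interaction-level
#' background (N = all interactions in the network, K = interactions
#' involving a partner-set member).
#'
#' @param network an [InteractionNetwork-class] object.
#' @param hub accession of a protein present in the network.
#' @param partnerSet character vector of accessions.
#' @return one-row data.frame: accession, N, K, n, k, p_raw.
#' @export
hubEnrichment <- function(network, hub, partnerSet) {
  ints <- interactors(network, hub)
  if (!length(ints)) stop("hub ", hub, " absent from network")
  N <- numInteractions(network)
  K <- setInteractions(network, partnerSet)$n
  n <- length(ints)
  k <- sum(ints %in% partnerSet)
  data.frame(accession = hub, N = N, K = K, n = n, k = k,
             p_raw = hypergeomUpper(N, K, n, min(k, K)),
             stringsAsFactors = FALSE)
}

#' Split a sample's interactions into hub and non-hub partitions and re-test
#'
#' The sample set's interactions are partitioned into those involving at
#' least one hub versus the rest; [interactorSetEnrichment()]-style counts
#' are then computed for each partition against every target set, with the
#' background unchanged. Partition sizes always sum to the full sample
#' interaction count.
#'
#' @param network an [InteractionNetwork-class] object.
#' @param sample character vector of accessions.
#' @param hubs character vector, a subset of \code{sample}.
#' @param targets named list of target sets.
#' @param background optional background network.
#' @param alpha family-wise level applied over all tests run here.
#' @return data.frame with one row per partition x target: partition,
#'   target, N, K, n, k, direction, p_raw, holm_significant.
#' @export
partitionAndEnrich <- function(network, sample, hubs, targets,
                               background = NULL, alpha = 0.05) {
  stopifnot(all(hubs %in% sample))
  bg <- if (is.null(background)) network else background
  p <- bg@pairs
  inS <- p$a %in% sample | p$b %in% sample
  inH <- p$a %in% hubs | p$b %in% hubs
  parts <- list(hub = inS & inH, nonhub = inS & !inH)
  rows <- list()
  for (pname in names(parts)) for (tnm in names(targets)) {
    tset <- targets[[tnm]]
    inT <- p$a %in% tset | p$b %in% tset
    cross <- (p$a %in% sample & p$b %in% tset) |
             (p$b %in% sample & p$a %in% tset)
    N <- nrow(p); K <- sum(inT)
    n <- sum(parts[[pname]]); k <- sum(parts[[pname]] & cross)
    if (N == 0 || K == 0 || n == 0) {
      pe <- 1; pd <- 1; dir <- "enrichment"; praw <- 1
    } else {
      pe <- max(hypergeomUpper(N, K, n, k), .Machine$double.xmin)
      pd <- max(hypergeomLower(N, K, n, k), .Machine$double.xmin)
      dir <- if (k >= n * K / N) "enrichment" else "depletion"
      praw <- if (dir == "enrichment") pe else pd
    }
    rows[[length(rows) + 1L]] <- data.frame(
      partition = pname, target = tnm, N = N, K = K, n = n, k = k,
      direction = dir, p_enrich = pe, p_deplete = pd, p_raw = praw,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$holm_significant <- holmBonferroni(out$p_raw, alpha)
  out
}
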