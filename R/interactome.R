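#' Construct an interaction network from accession pairs
#'
#' Canonicalizes (unordered pairs, isoform suffixes stripped) and
#' deduplicates. Used by [readMitab()] and by the synthetic generator.
#'
#' @param a,b character vectors of interactor accessions.
#' @param nSkipped rows dropped upstream (bookkeeping).
#' @param keepSelf retain self-interactions (default TRUE; they count once
#'   and put a protein in its own interactor list).
#' @return an [InteractionNetwork-class] object.
#' @export
interactionNetwork <- function(a = character(), b = character(),
                               nSkipped = 0L, keepSelf = TRUE) {
  a <- stripIsoform(a); b <- stripIsoform(b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi))
  if (!keepSelf) keep <- keep & lo != hi
  p <- data.frame(a = lo[keep], b = hi[keep], self = lo[keep] == hi[keep],
                  stringsAsFactors = FALSE)
  p <- p[order(p$a, p$b), , drop = FALSE]
  rownames(p) <- NULL
  new("InteractionNetwork", pairs = p, nSkipped = as.integer(nSkipped))
}

#' Read binary interactions from a PSI-MI TAB (MITAB 2.5+) file
#'
#' Extracts UniProt accessions (\code{uniprotkb:} prefix) from the interactor
#' ID columns (columns 1-2), falling back to the alternative-ID columns
#' (3-4). Rows where either side yields no UniProt accession are skipped and
#' counted. A-B and B-A rows, and duplicate evidence lines, collapse to one
#' interaction. When taxon columns (10-11) are present and \code{taxa} is
#' non-NULL, rows whose interactors are not in the allowed taxa are skipped.
#'
#' @param path MITAB file; a leading \code{#} header line is tolerated.
#' @param taxa allowed NCBI taxon ids (default S. cerevisiae:
#'   \code{c(559292, 4932)}); NULL disables the filter.
#' @param keepSelf retain self-interactions (default TRUE).
#' @return an [InteractionNetwork-class] object.
#' @export
readMitab <- function(path, taxa = c(559292L, 4932L), keepSelf = TRUE) {
  if (!file.exists(path)) stop("cannot read MITAB file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "#")) lines <- lines[-1]
  if (!length(lines)) {
    warning("no parseable MITAB rows in ", path)
    return(interactionNetwork())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pickUniprot <- function(f, i, j) {
    ids <- c(f[i], if (length(f) >= j) f[j])
    m <- regmatches(ids, regexpr("uniprotkb:[^|(\t]+", ids))
    if (length(m)) sub("^uniprotkb:", "", m[1]) else NA_character_
  }
  pickTaxon <- function(f, i) {
    if (length(f) < i || f[i] %in% c("-", "")) return(NA_integer_)
    m <- regmatches(f[i], regexpr("taxid:-?[0-9]+", f[i]))
    if (length(m)) as.integer(sub("^taxid:", "", m)) else NA_integer_
  }
  a <- vapply(fields, pickUniprot, character(1), i = 1L, j = 3L)
  b <- vapply(fields, pickUniprot, character(1), i = 2L, j = 4L)
  ok <- !is.na(a) & !is.na(b)
  if (!is.null(taxa)) {
    ta <- vapply(fields, pickTaxon, integer(1), i = 10L)
    tb <- vapply(fields, pickTaxon, integer(1), i = 11L)
    ok <- ok & (is.na(ta) | ta %in% taxa) & (is.na(tb) | tb %in% taxa)
  }
  if (!any(ok)) {
    warning("no parseable MITAB rows in ", path)
    return(interactionNetwork(nSkipped = sum(!ok)))
  }
  interactionNetwork(a[ok], b[ok], nSkipped = sum(!ok), keepSelf = keepSelf)
}

#' Number of interactions in a network
#' @param network an [InteractionNetwork-class] object.
#' @return integer count of unique interactions.
#' @export
numInteractions <- function(network) nrow(network@pairs)

#' Interactor set of a protein
#'
#' All partners of \code{accession}; contains the protein itself iff a
#' self-interaction exists. Absent proteins yield an empty set.
#'
#' @param network an [InteractionNetwork-class] object.
#' @param accession protein accession.
#' @return character vector of partner accessions.
#' @export
interactors <- function(network, accession) {
  p <- network@pairs
  part <- c(p$b[p$a == accession], p$a[p$b == accession & !p$self])
  unique(part)
}

#' Interactions involving a protein set
#'
#' Counts each unique interaction with at least one endpoint in the set
#' exactly once; this is the interaction-level sample size n (and, for a
#' target set, the population-success count K) of the enrichment tests.
#'
#' @param network an [InteractionNetwork-class] object.
#' @param set character vector of accessions.
#' @return list with \code{n} (count) and \code{interactions} (the pair
#'   data.frame subset).
#' @export
setInteractions <- function(network, set) {
  p <- network@pairs
  hit <- p$a %in% set | p$b %in% set
  list(n = sum(hit), interactions = p[hit, , drop = FALSE])
}

#' Restrict a network to interactions involving a protein set
#'
#' The restricted background used by the supplementary analysis that takes
#' one set's interactions (e.g. all NQP interactions) as the population.
#'
#' @param network an [InteractionNetwork-class] object.
#' @param set character vector of accessions.
#' @return an [InteractionNetwork-class] object containing only
#'   interactions with at least one endpoint in \code{set}.
#' @export
restrictNetwork <- function(network, set) {
  sub <- setInteractions(network, set)$interactions
  rownames(sub) <- NULL
  new("InteractionNetwork", pairs = sub, nSkipped = 0L)
}

#' Export a category-annotated edge list for network viewers
#'
#' Writes a TSV with one row per interaction and node category/colour
#' attributes, using the standard palette ([categoryPalette()]): known
#' prions black, other prionogenic proteins grey, prion negatives yellow,
#' N/Q-rich prion-like proteins dark blue, other proteins brown. Category
#' precedence per node: KP > EPD > EPN > NQP > other.
#'
#' @param network an [InteractionNetwork-class] object.
#' @param sets named list with (any of) \code{KP}, \code{EPD}, \code{EPN},
#'   \code{NQP} accession vectors.
#' @param file optional output TSV path.
#' @return the annotated edge data.frame, invisibly if \code{file} given.
#' @export
exportAnnotatedEdges <- function(network, sets, file = NULL) {
  categorize <- function(acc) {
    ifelse(acc %in% sets$KP, "KP",
      ifelse(acc %in% sets$EPD, "EPD",
        ifelse(acc %in% sets$EPN, "EPN",
          ifelse(acc %in% sets$NQP, "NQP", "other"))))
  }
  pal <- categoryPalette()
  p <- network@pairs
  out <- data.frame(a = p$a, b = p$b,
                    category_a = categorize(p$a), category_b = categorize(p$b),
                    stringsAsFactors = FALSE)
  out$color_a <- unname(pal[out$category_a])
  out$color_b <- unname(pal[out$category_b])
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
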