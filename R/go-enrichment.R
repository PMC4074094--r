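# Term -> annotated accessions (propagated), over a universe.
termMembers <- function(annot, universe) {
  prop <- annot@propagated[intersect(names(annot@propagated), universe)]
  if (!length(prop)) return(list())
  accs <- rep(names(prop), lengths(prop))
  split(accs, unlist(prop, use.names = FALSE))
}

#' GO membership enrichment of a protein set
#'
#' Per biological-process term: N = universe size, K = proteins annotated
#' with the term (after ancestor propagation), n = sample size, k =
#' annotated sample members; upper-tail hypergeometric P with
#' Holm-Bonferroni flags over all terms tested for this sample set. Terms
#' annotating fewer than \code{minAnnotated} universe proteins are skipped
#' (singleton terms are uninformative and dominate high-membership
#' ranking).
#'
#' @param sample character vector of accessions (subset of universe).
#' @param annot a [GoAnnotations-class] object.
#' @param universe character vector: the proteome accessions.
#' @param alpha family-wise level (default 0.05).
#' @param minAnnotated minimum universe annotation count (default 2).
#' @return data.frame: term, N, K, n, k, p_raw, holm_significant; ordered
#'   by p_raw.
#' @export
membershipEnrichment <- function(sample, annot, universe, alpha = 0.05,
                                 minAnnotated = 2L) {
  if (!length(sample))
    return(data.frame(term = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_raw = numeric(),
                      holm_significant = logical()))
  checkMembers(sample, universe, "sample")
  tm <- termMembers(annot, universe)
  tm <- tm[vapply(tm, length, 1L) >= minAnnotated]
  if (!length(tm)) return(membershipEnrichment(character(), annot, universe))
  N <- length(universe); n <- length(sample)
  K <- vapply(tm, length, 1L)
  k <- vapply(tm, function(m) sum(m %in% sample), 1L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(tm), N = N, K = unname(K), n = n,
                    k = unname(k), p_raw = unname(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$holm_significant <- holmBonferroni(out$p_raw, alpha)
  out[order(out$p_raw, out$term), ]
}

#' High-membership report with most-specific-term collapse
#'
#' Retains enriched terms for which the examined set covers at least
#' \code{minFraction} of the term's annotated universe proteins, ranks by
#' the number of covered proteins (descending), and collapses nested terms:
#' when an ancestor and a descendant are both retained with the identical
#' covered-protein list, the ancestor is dropped only if the more specific
#' term has a strictly lower P-value — otherwise both are kept.
#'
#' @param results output of [membershipEnrichment()] for the same sample.
#' @param sample the examined set.
#' @param annot a [GoAnnotations-class] object.
#' @param dag a [GoDag-class] object.
#' @param universe the proteome accessions.
#' @param minFraction membership threshold (default 0.5).
#' @param maxP only consider terms with raw P at or below this (default
#'   1e-4, the report convention for listing candidate enrichments).
#' @return data.frame: term, yeast_count, set_count, fraction, p_raw,
#'   holm_significant; ranked by set_count descending.
#' @export
highMembershipReport <- function(results, sample, annot, dag, universe,
                                 minFraction = 0.5, maxP = 1e-4) {
  tm <- termMembers(annot, universe)
  res <- results[results$p_raw <= maxP, , drop = FALSE]
  if (!nrow(res))
    return(data.frame(term = character(), yeast_count = integer(),
                      set_count = integer(), fraction = numeric(),
                      p_raw = numeric(), holm_significant = logical()))
  covered <- lapply(tm[res$term], function(m) sort(m[m %in% sample]))
  frac <- res$k / res$K
  keep <- frac >= minFraction
  res <- res[keep, , drop = FALSE]; covered <- covered[keep]
  drop <- rep(FALSE, nrow(res))
  if (nrow(res) > 1) {
    key <- vapply(covered, paste, character(1), collapse = ",")
    for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
      if (i == j || key[i] != key[j]) next
      # j an ancestor of i, identical protein list: keep only the more
      # specific term i if it has the lower P-value
      if (res$term[j] %in% dag@ancestors[[res$term[i]]] &&
          res$p_raw[i] < res$p_raw[j]) drop[j] <- TRUE
    }
  }
  res <- res[!drop, , drop = FALSE]
  out <- data.frame(term = res$term, yeast_count = res$K,
                    set_count = res$k, fraction = res$k / res$K,
                    p_raw = res$p_raw,
                    holm_significant = res$holm_significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$set_count, out$p_raw, out$term), ]
}

#' Interaction-based GO enrichment
#'
#' Interacting partners are collapsed to their GO terms: if a protein
#' interacts with several partners annotated to the same term, that counts
#' as a single protein-term interaction pair. Over the deduplicated pair
#' set: N = all protein-term pairs proteome-wide, K = pairs with the term,
#' n = pairs whose protein is a sample member, k = sample pairs with the
#' term; upper-tail hypergeometric with Holm-Bonferroni over all terms
#' tested.
#'
#' @param network an [InteractionNetwork-class] object.
#' @param sample character vector of accessions.
#' @param annot a [GoAnnotations-class] object (propagated).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: term, N, K, n, k, p_raw, holm_significant.
#' @export
interactionGoEnrichment <- function(network, sample, annot, alpha = 0.05) {
  p <- network@pairs
  empty <- data.frame(term = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_raw = numeric(),
                      holm_significant = logical())
  if (!nrow(p)) return(empty)
  # protein -> union of its partners' (propagated) term sets, deduplicated
  prot <- unique(c(p$a, p$b))
  pairsOf <- lapply(prot, function(A) {
    terms <- unlist(annot@propagated[interactors(network, A)],
                    use.names = FALSE)
    unique(terms)
  })
  names(pairsOf) <- prot
  nPairs <- lengths(pairsOf)
  N <- sum(nPairs)
  if (N == 0) return(empty)
  allTerms <- unlist(pairsOf, use.names = FALSE)
  Ktab <- table(allTerms)
  inSample <- prot %in% sample
  n <- sum(nPairs[inSample])
  ktab <- table(unlist(pairsOf[inSample], use.names = FALSE))
  terms <- names(Ktab)
  k <- as.integer(ktab[terms]); k[is.na(k)] <- 0L
  K <- as.integer(Ktab)
  pr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, N = N, K = K, n = n, k = k, p_raw = pr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$holm_significant <- holmBonferroni(out$p_raw, alpha)
  out[order(out$p_raw, out$term), ]
}

#' Cross-reference three enrichment result lists
#'
#' Terms that are Holm-significant in all three analyses (the triad:
#' high-membership, interaction enrichment of the set, and hub-interactor
#' enrichment).
#'
#' @param a,b,c data.frames with columns \code{term} and
#'   \code{holm_significant}.
#' @return character vector of terms significant in all three.
#' @export
crossReference <- function(a, b, c) {
  sig <- function(x) x$term[x$holm_significant]
  intersect(intersect(sig(a), sig(b)), sig(c))
}
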