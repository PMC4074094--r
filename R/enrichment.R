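#' Contingency counts for a hypergeometric test
#'
#' @param N population size.
#' @param K population successes.
#' @param n sample size.
#' @param k sample successes.
#' @return validated list of the four counts.
#' @export
contingencyCounts <- function(N, K, n, k) {
  if (K > N || n > N) stop("require K <= N and n <= N")
  if (k < 0 || k > min(n, K)) stop("require 0 <= k <= min(n, K)")
  list(N = N, K = K, n = n, k = k)
}

#' Hypergeometric upper tail P(X >= k)
#'
#' Exact tail of the hypergeometric distribution with population \code{N},
#' \code{K} successes and a sample of size \code{n}, computed in log space
#' so that magnitudes far below 1e-300 remain representable via
#' \code{log10p}.
#'
#' @inheritParams contingencyCounts
#' @param log10p if TRUE return log10 of the tail probability.
#' @return P(X >= k); 1 when k = 0.
#' @export
hypergeomUpper <- function(N, K, n, k, log10p = FALSE) {
  contingencyCounts(N, K, n, k)
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Hypergeometric lower tail P(X <= k)
#'
#' @inheritParams hypergeomUpper
#' @return P(X <= k); 1 when k = n.
#' @export
hypergeomLower <- function(N, K, n, k, log10p = FALSE) {
  contingencyCounts(N, K, n, k)
  lp <- stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Holm-Bonferroni family-wise significance flags
#'
#' Step-down procedure: sort the m p-values ascending and reject while
#' p_(i) <= alpha / (m - i + 1), stopping at the first failure. Flags are
#' returned in input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha family-wise error level (default 0.05).
#' @return logical vector: TRUE where the test is rejected (significant).
#' @export
holmBonferroni <- function(p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(p)) return(logical(0))
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Interaction-level set-vs-set enrichment test
#'
#' The counting convention of the interaction analyses: with background
#' network B, N = |B|; K = interactions in B involving at least one
#' \code{target} member; n = interactions involving at least one
#' \code{sample} member; k = interactions in which one endpoint is a sample
#' member and the other endpoint a target member (so, within a sample
#' protein's interactor list, the interactions whose partner belongs to the
#' target set). An interaction internal to both sets counts once in each of
#' K, n and k; no special-casing when the sets overlap — for sample =
#' target, k is the number of set-internal interactions, not n. The
#' direction is
#' the side of the expectation nK/N on which k falls; both one-sided tails
#' are reported and \code{p_raw} is the tail in the observed direction (no
#' two-sided doubling).
#'
#' @param network an [InteractionNetwork-class] object.
#' @param sample,target character vectors of accessions.
#' @param background optional [InteractionNetwork-class] to use as the
#'   population (e.g. [restrictNetwork()] output for a restricted-background
#'   analysis); defaults to \code{network}.
#' @param label optional test label.
#' @return one-row data.frame: label, N, K, n, k, expected, direction,
#'   p_enrich, p_deplete, p_raw, log10_p_raw.
#' @export
interactorSetEnrichment <- function(network, sample, target,
                                    background = NULL, label = NA_character_) {
  bg <- if (is.null(background)) network else background
  p <- bg@pairs
  inS <- p$a %in% sample | p$b %in% sample
  inT <- p$a %in% target | p$b %in% target
  cross <- (p$a %in% sample & p$b %in% target) |
           (p$b %in% sample & p$a %in% target)
  N <- nrow(p); K <- sum(inT); n <- sum(inS); k <- sum(cross)
  if (N == 0 || K == 0 || n == 0) {
    return(data.frame(label = label, N = N, K = K, n = n, k = k,
                      expected = 0, direction = "enrichment",
                      p_enrich = 1, p_deplete = 1, p_raw = 1,
                      log10_p_raw = 0, stringsAsFactors = FALSE))
  }
  expected <- n * K / N
  # under this counting convention the observed k can fall outside the
  # hypergeometric support (e.g. heavily overlapping sets in a restricted
  # background), where the tail underflows to an exact zero; floor at the
  # smallest positive double so downstream corrections stay defined
  pe <- max(hypergeomUpper(N, K, n, k), .Machine$double.xmin)
  pd <- max(hypergeomLower(N, K, n, k), .Machine$double.xmin)
  dir <- if (k >= expected) "enrichment" else "depletion"
  praw <- if (dir == "enrichment") pe else pd
  l10 <- if (dir == "enrichment") hypergeomUpper(N, K, n, k, log10p = TRUE)
         else hypergeomLower(N, K, n, k, log10p = TRUE)
  l10 <- max(l10, log10(.Machine$double.xmin))
  data.frame(label = label, N = N, K = K, n = n, k = k, expected = expected,
             direction = dir, p_enrich = pe, p_deplete = pd, p_raw = praw,
             log10_p_raw = l10, stringsAsFactors = FALSE)
}

#' Grid of interaction enrichments over sample and target sets
#'
#' Runs [interactorSetEnrichment()] for every sample x target combination
#' (the layout of the interaction-preference tables), applies
#' Holm-Bonferroni over the whole family of executed tests, and optionally
#' writes a wide table (cells \code{k/n (p, direction, sig)}) plus a long
#' table with full counts.
#'
#' @param network an [InteractionNetwork-class] object.
#' @param samples named list of sample sets (table rows).
#' @param targets named list of target sets (table columns).
#' @param background optional background network for all tests.
#' @param alpha family-wise level for Holm-Bonferroni (default 0.05).
#' @param extraP optional additional raw p-values belonging to the same
#'   correction family (e.g. from a companion grid), appended before the
#'   Holm step so the family matches the full analysis.
#' @param file optional base path; writes \code{<file>_wide.tsv} and
#'   \code{<file>_long.tsv}.
#' @return long-format data.frame with one row per test and a
#'   \code{holm_significant} flag.
#' @export
enrichmentGrid <- function(network, samples, targets, background = NULL,
                           alpha = 0.05, extraP = numeric(), file = NULL) {
  rows <- list()
  for (snm in names(samples)) for (tnm in names(targets)) {
    r <- interactorSetEnrichment(network, samples[[snm]], targets[[tnm]],
                                 background = background,
                                 label = paste(snm, tnm, sep = "~"))
    r$sample <- snm; r$target <- tnm
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  fam <- c(out$p_raw, extraP)
  out$holm_significant <- holmBonferroni(fam, alpha)[seq_len(nrow(out))]
  if (!is.null(file)) {
    cell <- sprintf("%d/%d (%.3g, %s%s)", out$k, out$n, out$p_raw,
                    out$direction,
                    ifelse(out$holm_significant, ", sig", ""))
    wide <- matrix(cell, nrow = length(samples), byrow = TRUE,
                   dimnames = list(names(samples), names(targets)))
    utils::write.table(data.frame(sample = rownames(wide), wide,
                                  check.names = FALSE),
                       paste0(file, "_wide.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(out, paste0(file, "_long.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
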