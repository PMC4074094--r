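#' Draw one length-matched random sample of the proteome
#'
#' Proteins are drawn uniformly without replacement until the cumulative
#' length reaches the target; the final protein contributes only the
#' fraction needed to hit the target residue count exactly, and its
#' disordered-residue contribution is prorated by that fraction (a
#' positional N-terminal prefix mode is available instead).
#'
#' @param tracks a [DisorderTracks-class] object covering the proteome.
#' @param targetLength target total residue count (> 0).
#' @param mode "prorate" (default) or "prefix" for the fractional protein's
#'   disorder contribution ("prefix" requires per-residue flags for the
#'   final protein and truncates its track at the cut).
#' @return list: \code{members} (full proteins), \code{fractionalAccession},
#'   \code{fraction} in (0,1], \code{residues} (== targetLength),
#'   \code{disordered} (possibly fractional).
#' @export
drawLengthMatchedSample <- function(tracks, targetLength,
                                    mode = c("prorate", "prefix")) {
  mode <- match.arg(mode)
  if (targetLength <= 0) stop("targetLength must be positive")
  s <- tracks@summary
  if (sum(s$length) < targetLength)
    stop("proteome shorter than target length")
  ord <- sample.int(nrow(s))
  cum <- cumsum(s$length[ord])
  cut <- which(cum >= targetLength)[1]
  idx <- ord[seq_len(cut)]
  full <- idx[-cut]
  last <- idx[cut]
  need <- targetLength - (if (cut > 1) cum[cut - 1] else 0)
  frac <- need / s$length[last]
  disLast <- if (mode == "prorate" || frac == 1) {
    frac * s$disordered[last]
  } else {
    bits <- tracks@flags[[s$accession[last]]]
    if (is.null(bits))
      stop("prefix mode needs per-residue flags for ", s$accession[last])
    sum(bits[seq_len(need)])
  }
  list(members = s$accession[full],
       fractionalAccession = s$accession[last], fraction = frac,
       residues = targetLength,
       disordered = sum(s$disordered[full]) + disLast)
}

#' Monte-Carlo length-matched disorder test
#'
#' Compares the total disordered residue count of a protein set against
#' random proteome samples of exactly the same total protein length
#' (fractional final protein, see [drawLengthMatchedSample()]). Reports the
#' fraction of samples with strictly greater total disorder than observed.
#'
#' @param set character vector of accessions (all must have tracks).
#' @param tracks a [DisorderTracks-class] object for the whole proteome.
#' @param nSamples number of Monte-Carlo samples (default 10000).
#' @param seed optional RNG seed for reproducibility.
#' @param mode fractional-protein mode, see [drawLengthMatchedSample()].
#' @return list: \code{observed} (disordered residues in the set),
#'   \code{targetLength}, \code{nSamples}, \code{exceedCount},
#'   \code{exceedFraction}, \code{samples} (vector of sampled disorder
#'   totals), \code{seed}.
#' @export
mcDisorderTest <- function(set, tracks, nSamples = 10000L, seed = NULL,
                           mode = "prorate") {
  s <- tracks@summary
  i <- match(set, s$accession)
  if (anyNA(i))
    stop("no disorder track for: ", paste(set[is.na(i)], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  observed <- sum(s$disordered[i])
  target <- sum(s$length[i])
  totals <- vapply(seq_len(nSamples), function(.)
    drawLengthMatchedSample(tracks, target, mode = mode)$disordered,
    numeric(1))
  exceed <- sum(totals > observed)
  list(observed = observed, targetLength = target,
       nSamples = as.integer(nSamples), exceedCount = exceed,
       exceedFraction = exceed / nSamples, samples = totals,
       seed = seed)
}

#' Histogram summary of a Monte-Carlo disorder test
#'
#' Bin counts of the sampled disorder totals plus the observed value, the
#' inset-table style summary of the resampling figure.
#'
#' @param result output of [mcDisorderTest()].
#' @param breaks number of histogram bins (default 30).
#' @return list with \code{breaks}, \code{counts}, \code{observed},
#'   \code{exceedPercent}.
#' @export
mcDisorderHistogram <- function(result, breaks = 30L) {
  h <- graphics::hist(result$samples, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, observed = result$observed,
       exceedPercent = 100 * result$exceedFraction)
}
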