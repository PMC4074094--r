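#' Exact binomial upper-tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p), computed in log space. This is the
#' score minimized by the lowest-probability-subsequence (LPS) search for
#' compositionally biased regions.
#'
#' @param k successes observed (0 <= k <= n).
#' @param n trials.
#' @param p success probability, in (0, 1).
#' @param log10p if TRUE return log10 of the tail.
#' @return upper-tail probability (1 when k = 0).
#' @export
binomialTail <- function(k, n, p, log10p = FALSE) {
  if (any(p <= 0) || any(p >= 1)) stop("p must be in (0, 1)")
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  lp <- stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Aggregate amino-acid composition of a proteome
#'
#' Frequencies over the 20 standard amino acids (other letters, e.g. X, are
#' ignored), the default background for bias detection.
#'
#' @param proteome proteome data.frame from [readProteome()].
#' @return named numeric vector of 20 frequencies summing to 1.
#' @export
proteomeComposition <- function(proteome) {
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::AAStringSet(proteome$sequence), AA20))
  names(counts) <- AA20
  counts / sum(counts)
}

#' Uniform amino-acid background (1/20 each)
#' @return named numeric vector.
#' @export
uniformComposition <- function() stats::setNames(rep(1 / 20, 20), AA20)

#' Threshold rules for N/Q-rich prion-like (NQP) classification
#'
#' A region must reach binomial P <= \code{mainP} for N and/or Q (alone or
#' with one subsidiary Y/S/G bias at P < \code{subsidiaryP} within the
#' region), and must not carry a contributing bias (P < \code{exclusionP},
#' within the region) from charged residues D/E/R/K or major hydrophobics
#' V/I/L/M.
#'
#' @param mainP main region threshold (default 1e-10).
#' @param subsidiaryP threshold for an admissible subsidiary bias (1e-4).
#' @param exclusionP threshold at which an excluded-residue bias rejects
#'   the protein (1e-4).
#' @param minRegionLength minimum region length in residues (default 20).
#' @return list of thresholds and residue classes.
#' @export
biasThresholds <- function(mainP = 1e-10, subsidiaryP = 1e-4,
                           exclusionP = 1e-4, minRegionLength = 20L) {
  stopifnot(mainP > 0, mainP <= 1, subsidiaryP > 0, subsidiaryP <= 1,
            exclusionP > 0, exclusionP <= 1, minRegionLength >= 1)
  list(mainP = mainP, subsidiaryP = subsidiaryP, exclusionP = exclusionP,
       subsidiaryResidues = c("Y", "S", "G"),
       excludedResidues = c("D", "E", "R", "K", "V", "I", "L", "M"),
       minRegionLength = as.integer(minRegionLength))
}

# Core LPS search on a pre-split character vector. Exact: the minimal-tail
# region of length >= minLen either starts and ends on a biased residue
# (shrinking a non-biased end residue strictly lowers the tail when the
# count is positive) or has length exactly minLen, so only those windows
# are scored. Ties broken by lower P, then greater length, then smaller
# start. Returns NULL if the sequence is shorter than minLen.
minPRegionChars <- function(chars, residueSet, pSet, minLen) {
  L <- length(chars)
  if (L < minLen) return(NULL)
  flags <- chars %in% residueSet
  cs <- c(0L, cumsum(flags))
  starts <- seq_len(L - minLen + 1L)
  ends <- starts + minLen - 1L
  pos <- which(flags)
  m <- length(pos)
  if (m >= 2L) {
    ij <- which(outer(pos, pos, function(a, b) b - a + 1L >= minLen),
                arr.ind = TRUE)
    if (nrow(ij)) {
      starts <- c(starts, pos[ij[, 1]])
      ends <- c(ends, pos[ij[, 2]])
    }
  }
  starts <- c(starts, 1L); ends <- c(ends, L)  # whole sequence candidate
  len <- ends - starts + 1L
  cnt <- cs[ends + 1L] - cs[starts]
  logp <- stats::pbinom(cnt - 1L, len, pSet, lower.tail = FALSE, log.p = TRUE)
  best <- order(logp, -len, starts)[1L]
  list(start = starts[best], end = ends[best],
       residueSet = residueSet, count = cnt[best], length = len[best],
       pvalue = exp(logp[best]), log10p = logp[best] / log(10))
}

#' Find the minimal binomial-tail region for a residue set
#'
#' The lowest-probability-subsequence search: over all contiguous regions of
#' length at least \code{thresholds$minRegionLength}, find the one whose
#' count of \code{residueSet} residues has the smallest binomial upper-tail
#' probability under the background composition. Exhaustive and
#' deterministic (ties: lower P, then greater length, then smaller start).
#'
#' @param record one-row proteome data.frame, or a list with
#'   \code{accession} and \code{sequence}.
#' @param residueSet character vector of single-letter amino acids, e.g.
#'   \code{c("N","Q")}.
#' @param bg background composition (named frequencies, as from
#'   [proteomeComposition()]).
#' @param thresholds from [biasThresholds()].
#' @return list with \code{start}, \code{end} (1-based inclusive),
#'   \code{residueSet}, \code{count}, \code{length}, \code{pvalue},
#'   \code{log10p}; or NULL (with a message) if the sequence is shorter
#'   than the minimum region length.
#' @export
findMinPRegion <- function(record, residueSet, bg,
                           thresholds = biasThresholds()) {
  stopifnot(length(residueSet) >= 1)
  seqc <- toupper(sub("\\*+$", "", record$sequence[[1]]))
  chars <- strsplit(seqc, "")[[1]]
  if (length(chars) < thresholds$minRegionLength) {
    message("sequence ", record$accession[[1]], " shorter than ",
            thresholds$minRegionLength, " residues; no region")
    return(NULL)
  }
  pSet <- sum(bg[residueSet])
  minPRegionChars(chars, residueSet, pSet, thresholds$minRegionLength)
}

# Candidate residue sets for NQP classification: N and/or Q alone, and each
# base set extended by one subsidiary residue.
nqpCandidateSets <- function(subsidiary = c("Y", "S", "G")) {
  base <- list("N", "Q", c("N", "Q"))
  out <- base
  for (b in base) for (s in subsidiary) out[[length(out) + 1L]] <- c(b, s)
  out
}

#' Classify a protein as N/Q-rich prion-like
#'
#' Runs the minimal-tail region search for each candidate residue set (N, Q
#' and N/Q, alone or extended by one subsidiary Y/S/G bias), takes the best
#' admissible region, and applies the threshold rules: the region P-value
#' must reach \code{mainP}; a subsidiary residue in the winning set must
#' itself show a within-region bias below \code{subsidiaryP}; and no
#' excluded residue (D/E/R/K/V/I/L/M) may show a within-region bias below
#' \code{exclusionP}.
#'
#' @inheritParams findMinPRegion
#' @return list with \code{accepted} (logical), \code{region} (best region,
#'   or NULL), \code{reason} ("ok", "main threshold",
#'   "excluded-residue bias" or "too short").
#' @export
classifyNqp <- function(record, bg, thresholds = biasThresholds()) {
  seqc <- toupper(sub("\\*+$", "", record$sequence[[1]]))
  chars <- strsplit(seqc, "")[[1]]
  if (length(chars) < thresholds$minRegionLength)
    return(list(accepted = FALSE, region = NULL, reason = "too short"))
  best <- NULL
  for (rs in nqpCandidateSets(thresholds$subsidiaryResidues)) {
    reg <- minPRegionChars(chars, rs, sum(bg[rs]), thresholds$minRegionLength)
    sub <- intersect(rs, thresholds$subsidiaryResidues)
    if (length(sub)) {  # subsidiary bias must hold within this region
      window <- chars[reg$start:reg$end]
      pSub <- binomialTail(sum(window %in% sub), reg$length, sum(bg[sub]))
      if (pSub >= thresholds$subsidiaryP) next
    }
    if (is.null(best) || reg$pvalue < best$pvalue) best <- reg
  }
  if (is.null(best) || best$pvalue > thresholds$mainP)
    return(list(accepted = FALSE, region = best, reason = "main threshold"))
  window <- chars[best$start:best$end]
  for (r in thresholds$excludedResidues) {
    pr <- binomialTail(sum(window == r), best$length, bg[[r]])
    if (pr < thresholds$exclusionP)
      return(list(accepted = FALSE, region = best,
                  reason = "excluded-residue bias"))
  }
  list(accepted = TRUE, region = best, reason = "ok")
}

#' Scan a proteome for N/Q-rich prion-like proteins
#'
#' Applies [classifyNqp()] to every record; deterministic. Optionally
#' writes the per-protein region table as TSV.
#'
#' @param proteome proteome data.frame from [readProteome()].
#' @param bg background composition; defaults to the proteome's aggregate
#'   composition ([proteomeComposition()]).
#' @param thresholds from [biasThresholds()].
#' @param file optional TSV path for the region report.
#' @return list with \code{nqp} (accessions classified NQP) and
#'   \code{table} (data.frame: accession, start, end, residue_set, count,
#'   pvalue, decision, reason).
#' @export
scanProteome <- function(proteome, bg = NULL, thresholds = biasThresholds(),
                         file = NULL) {
  if (is.null(bg)) bg <- proteomeComposition(proteome)
  n <- nrow(proteome)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- classifyNqp(proteome[i, ], bg, thresholds)
    reg <- res$region
    rows[[i]] <- data.frame(
      accession = proteome$accession[i],
      start = if (is.null(reg)) NA_integer_ else reg$start,
      end = if (is.null(reg)) NA_integer_ else reg$end,
      residue_set = if (is.null(reg)) NA_character_ else
        paste(reg$residueSet, collapse = ""),
      count = if (is.null(reg)) NA_integer_ else reg$count,
      pvalue = if (is.null(reg)) NA_real_ else reg$pvalue,
      decision = res$accepted, reason = res$reason,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(nqp = tab$accession[tab$decision], table = tab)
}
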