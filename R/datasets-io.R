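#' Read a proteome from FASTA
#'
#' Parses a protein FASTA file into a proteome table. The accession is taken
#' from the first whitespace-delimited token of each header; both the UniProt
#' \code{sp|ACC|NAME} dialect and bare accessions are accepted. Sequences are
#' uppercased and trailing stop characters (\code{*}) removed, so downstream
#' classification is case- and stop-insensitive.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{accession}, \code{sequence},
#'   \code{length}; one row per FASTA entry.
#' @export
readProteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- vapply(strsplit(headers, "\\s+"), function(tok) {
    if (!length(tok) || !nzchar(tok[1]))
      stop("malformed FASTA header: '", paste(tok, collapse = " "), "'")
    parts <- strsplit(tok[1], "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else tok[1]
  }, character(1))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  seqs <- unname(seqs)
  data.frame(accession = unname(acc), sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a proteome table to FASTA
#'
#' @param proteome proteome data.frame as returned by [readProteome()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeProteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- proteome$accession
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a one-accession-per-line protein set file
#'
#' Lines starting with \code{#} are comments; anything after the first
#' whitespace on a line is ignored. Isoform suffixes are stripped.
#'
#' @param path set file.
#' @return character vector of accessions (unique, order preserved).
#' @export
readProteinList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  acc <- vapply(strsplit(lines, "\\s+"), `[`, character(1), 1)
  unique(stripIsoform(acc))
}

#' Load the curated prion protein sets
#'
#' Returns the three experimentally grounded protein sets shipped with the
#' package: the 10 known prions (KP), the 27 experimental prionogenic domain
#' proteins (EPD = KP plus 17 SUP35C-assay positives), and the 18
#' experimental prion negatives (EPN). KP is a subset of EPD by
#' construction. The bioinformatically derived N/Q-rich prion-like set (NQP)
#' is not curated here: supply it as a file or recompute it with
#' [scanProteome()].
#'
#' @param dropLowDisorderKp if TRUE, drop MOD5 (P07884) and NEW1 (Q08972)
#'   from KP (and hence EPD); the two lowest-disorder known prions, whose
#'   exclusion only marginally affects enrichment results.
#' @return named list of character vectors: \code{KP}, \code{EPD}, \code{EPN}.
#' @export
loadCuratedSets <- function(dropLowDisorderKp = FALSE) {
  dir <- system.file("extdata", "curated", package = "prionNets")
  kp  <- readProteinList(file.path(dir, "kp.txt"))
  epd <- c(kp, readProteinList(file.path(dir, "epd_additional.txt")))
  epn <- readProteinList(file.path(dir, "epn.txt"))
  if (dropLowDisorderKp) {
    drop <- c("P07884", "Q08972")
    kp <- setdiff(kp, drop)
    epd <- setdiff(epd, drop)
  }
  list(KP = kp, EPD = epd, EPN = epn)
}

#' Read intrinsic disorder tracks
#'
#' Accepts the two upstream-predictor output granularities:
#' \code{accession<TAB>length<TAB>disordered_count} (per-protein summary) or
#' \code{accession<TAB>binary-string} (per-residue flags, e.g.
#' \code{P1<TAB>0011100}). The two row types may be mixed; a per-residue row
#' takes precedence over a summary row for the same accession.
#'
#' @param path tab-separated disorder file; \code{#} comment lines allowed.
#' @return a [DisorderTracks-class] object.
#' @export
readDisorderTracks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  flags <- list()
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    acc <- stripIsoform(trimws(f[1]))
    if (length(f) >= 3 && grepl("^[0-9]+$", trimws(f[2]))) {
      len <- as.integer(trimws(f[2])); dis <- as.numeric(trimws(f[3]))
      rows[[acc]] <- c(len, dis)
    } else if (length(f) >= 2 && grepl("^[01]+$", trimws(f[2]))) {
      bits <- as.integer(strsplit(trimws(f[2]), "")[[1]])
      flags[[acc]] <- bits
      rows[[acc]] <- c(length(bits), sum(bits))
    } else {
      stop("unparseable disorder line: '", ln, "'")
    }
  }
  m <- do.call(rbind, rows)
  s <- if (is.null(m)) {
    data.frame(accession = character(), length = integer(),
               disordered = numeric(), fraction = numeric())
  } else {
    data.frame(accession = names(rows), length = as.integer(m[, 1]),
               disordered = m[, 2],
               fraction = ifelse(m[, 1] > 0, m[, 2] / m[, 1], 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  new("DisorderTracks", summary = s, flags = flags)
}

#' Build a DisorderTracks object from vectors
#'
#' @param accession,length,disordered parallel vectors.
#' @return a [DisorderTracks-class] object.
#' @export
disorderTracks <- function(accession, length, disordered) {
  new("DisorderTracks",
      summary = data.frame(accession = accession, length = as.integer(length),
                           disordered = disordered,
                           fraction = ifelse(length > 0, disordered / length, 0),
                           stringsAsFactors = FALSE),
      flags = list())
}

#' Derive the composite protein sets used by the Table 1/2 analyses
#'
#' From the N/Q-rich prion-like set (NQP), the catalog of proteins with
#' protein-binding domains or predicted coiled coils (PBD), and disorder
#' tracks, builds: \code{PBD_not_NQP}, \code{NQP_not_PBD}, \code{NQP_and_PBD}
#' and \code{disordered_not_NQP} (proteins with disorder fraction strictly
#' greater than \code{threshold}, excluding NQP members). The first three
#' are pairwise disjoint by construction.
#'
#' @param nqp character vector of NQP accessions.
#' @param pbd character vector of PBD-catalog accessions.
#' @param tracks a [DisorderTracks-class] object (may cover only part of the
#'   proteome; proteins without a track are excluded from the disorder set,
#'   with a warning).
#' @param threshold strict disorder-fraction cutoff (default 0.5).
#' @return named list of four character vectors.
#' @export
deriveCompositeSets <- function(nqp, pbd, tracks = NULL, threshold = 0.5) {
  nqp <- unique(stripIsoform(nqp)); pbd <- unique(stripIsoform(pbd))
  out <- list(
    PBD_not_NQP = setdiff(pbd, nqp),
    NQP_not_PBD = setdiff(nqp, pbd),
    NQP_and_PBD = intersect(nqp, pbd))
  if (!is.null(tracks)) {
    s <- tracks@summary
    dis <- s$accession[s$fraction > threshold]
    out$disordered_not_NQP <- setdiff(dis, nqp)
  } else {
    out$disordered_not_NQP <- character()
  }
  out
}

#' Total disorder content of a protein set
#'
#' Sums disordered residues over the set members and reports the overall
#' disordered fraction (total disordered residues / total residues).
#'
#' @param set character vector of accessions.
#' @param tracks a [DisorderTracks-class] object covering every member.
#' @return list with \code{residues}, \code{disordered}, \code{fraction}.
#' @export
disorderContent <- function(set, tracks) {
  s <- tracks@summary
  i <- match(set, s$accession)
  if (anyNA(i))
    stop("no disorder track for: ", paste(set[is.na(i)], collapse = ", "))
  tot <- sum(s$length[i]); dis <- sum(s$disordered[i])
  list(residues = tot, disordered = dis,
       fraction = if (tot > 0) dis / tot else 0)
}
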