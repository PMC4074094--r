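#' @import methods
NULL

#' Undirected binary protein interaction network
#'
#' Holds a deduplicated set of undirected binary interactions between protein
#' accessions. Pairs are stored canonically (\code{a <= b} lexicographically),
#' so an A--B and a B--A evidence line describe the same interaction.
#' Self-interactions (\code{a == b}) are retained and flagged; they count as a
#' single interaction and contribute a protein to its own interactor list.
#'
#' @slot pairs data.frame with character columns \code{a}, \code{b} (canonical
#'   order) and logical column \code{self}.
#' @slot nSkipped integer; input rows dropped during parsing (non-UniProt
#'   identifiers, taxon filter).
#'
#' @seealso [readMitab()], [interactors()], [setInteractions()]
#' @export
setClass("InteractionNetwork",
  representation(pairs = "data.frame", nSkipped = "integer"),
  prototype(pairs = data.frame(a = character(), b = character(),
                               self = logical(), stringsAsFactors = FALSE),
            nSkipped = 0L))

setValidity("InteractionNetwork", function(object) {
  p <- object@pairs
  if (!all(c("a", "b", "self") %in% names(p)))
    return("pairs must have columns a, b, self")
  if (nrow(p)) {
    if (any(p$a > p$b)) return("pairs must be canonically ordered (a <= b)")
    if (anyDuplicated(paste(p$a, p$b))) return("duplicate interaction pairs")
    if (!identical(p$self, p$a == p$b)) return("self flag inconsistent")
  }
  TRUE
})

#' Gene Ontology graph (biological_process sub-ontology)
#'
#' A parsed, namespace-filtered GO graph: term table, child-to-parent edges
#' (is_a and, optionally, part_of), and the transitively complete ancestor
#' closure used for annotation propagation and for the most-specific-term
#' collapse rule.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot parents named list: term id -> character vector of direct parents.
#' @slot ancestors named list: term id -> all ancestors (excluding the term
#'   itself), transitively complete.
#'
#' @seealso [readGoOntology()]
#' @export
setClass("GoDag",
  representation(terms = "data.frame", parents = "list", ancestors = "list"))

setValidity("GoDag", function(object) {
  ids <- object@terms$id
  if (anyDuplicated(ids)) return("duplicate term ids")
  par <- unlist(object@parents, use.names = FALSE)
  if (length(par) && !all(par %in% ids))
    return("parent edge points to unknown term")
  for (id in ids)  # acyclicity: no term is its own ancestor
    if (id %in% object@ancestors[[id]]) return(paste("cycle at", id))
  TRUE
})

#' GO annotations with ancestor propagation
#'
#' Direct annotations (from a GAF file or a generator) and the ancestor-
#' propagated map used by all enrichment counting. Restricted to
#' biological_process.
#'
#' @slot direct named list: accession -> directly annotated term ids.
#' @slot propagated named list: accession -> annotated terms plus all their
#'   ancestors.
#'
#' @seealso [readGoAnnotations()], [membershipEnrichment()]
#' @export
setClass("GoAnnotations",
  representation(direct = "list", propagated = "list"))

setValidity("GoAnnotations", function(object) {
  if (!all(names(object@direct) %in% names(object@propagated)))
    return("propagated map missing accessions present in direct map")
  for (acc in names(object@direct))
    if (!all(object@direct[[acc]] %in% object@propagated[[acc]]))
      return("propagated must contain direct annotations")
  TRUE
})

#' Per-protein intrinsic disorder annotations
#'
#' Disorder is consumed as upstream predictor output, at either of two
#' granularities: per-residue binary flags, or a per-protein disordered
#' residue count. When both are supplied the per-residue track wins.
#'
#' @slot summary data.frame with columns \code{accession}, \code{length},
#'   \code{disordered} (residue count) and \code{fraction}.
#' @slot flags named list of integer 0/1 vectors for proteins with
#'   per-residue tracks (may be empty).
#'
#' @seealso [readDisorderTracks()], [disorderContent()], [mcDisorderTest()]
#' @export
setClass("DisorderTracks",
  representation(summary = "data.frame", flags = "list"))

setValidity("DisorderTracks", function(object) {
  s <- object@summary
  if (!all(c("accession", "length", "disordered", "fraction") %in% names(s)))
    return("summary must have accession, length, disordered, fraction")
  if (anyDuplicated(s$accession)) return("duplicate accessions")
  if (nrow(s)) {
    if (any(s$disordered > s$length)) return("disordered exceeds length")
    if (any(s$fraction < 0 | s$fraction > 1)) return("fraction outside [0,1]")
  }
  for (acc in names(object@flags)) {
    i <- match(acc, s$accession)
    if (is.na(i)) return(paste("flags for unknown accession", acc))
    if (length(object@flags[[acc]]) != s$length[i])
      return(paste("flag track length mismatch for", acc))
  }
  TRUE
})

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork with", nrow(object@pairs), "interactions (",
      sum(object@pairs$self), "self ) over",
      length(unique(c(object@pairs$a, object@pairs$b))), "proteins\n")
  if (object@nSkipped > 0L)
    cat("  (", object@nSkipped, "input rows skipped during parsing )\n")
})

setMethod("show", "GoDag", function(object) {
  nleaf <- sum(!object@terms$id %in% unlist(object@parents, use.names = FALSE))
  cat("GoDag:", nrow(object@terms), "biological_process terms,",
      nleaf, "leaves\n")
})

setMethod("show", "GoAnnotations", function(object) {
  cat("GoAnnotations:", length(object@direct), "proteins,",
      length(unique(unlist(object@propagated, use.names = FALSE))),
      "distinct terms after propagation\n")
})

setMethod("show", "DisorderTracks", function(object) {
  s <- object@summary
  cat("DisorderTracks:", nrow(s), "proteins (",
      length(object@flags), "with per-residue flags );",
      "overall disorder fraction",
      round(sum(s$disordered) / max(1, sum(s$length)), 3), "\n")
})
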