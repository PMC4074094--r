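#' Read a GO ontology graph from an OBO file
#'
#' Minimal OBO 1.2/1.4 reader for the fields this analysis needs: term ids,
#' names, namespaces, and ancestry edges (\code{is_a}, plus \code{part_of}
#' relationships unless disabled). Obsolete terms are dropped. The graph is
#' restricted to the \code{biological_process} namespace and the ancestor
#' closure is computed on construction; a cyclic ontology is an error.
#'
#' @param path OBO file.
#' @param namespace sub-ontology to keep (default "biological_process").
#' @param partOf treat part_of relationships as ancestry (default TRUE).
#' @return a [GoDag-class] object.
#' @export
readGoOntology <- function(path, namespace = "biological_process",
                           partOf = TRUE) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  bounds <- c(grep("^\\[", lines), length(lines) + 1L)
  ids <- character(); nms <- character(); nss <- character()
  parents <- list()
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    getf <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      sub("\\s*!.*$", "", substring(v, nchar(key) + 3L))
    }
    if (length(getf("is_obsolete")) && any(getf("is_obsolete") == "true"))
      next
    id <- getf("id"); if (!length(id)) next
    par <- getf("is_a")
    if (partOf) {
      rel <- getf("relationship")
      po <- rel[startsWith(rel, "part_of ")]
      par <- c(par, sub("^part_of\\s+", "", po))
    }
    ids <- c(ids, id[1])
    nm <- getf("name"); nms <- c(nms, if (length(nm)) nm[1] else "")
    ns <- getf("namespace"); nss <- c(nss, if (length(ns)) ns[1] else "")
    parents[[id[1]]] <- trimws(par)
  }
  keep <- nss == namespace | !nzchar(nss)  # undeclared namespace kept
  goDag(data.frame(id = ids[keep], name = nms[keep], namespace = nss[keep],
                   stringsAsFactors = FALSE),
        lapply(parents[ids[keep]], function(p) intersect(p, ids[keep])))
}

#' Build a GoDag from a term table and parent edges
#'
#' Computes the transitively complete ancestor closure; errors on cycles.
#'
#' @param terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @param parents named list: id -> character vector of direct parent ids.
#' @return a [GoDag-class] object.
#' @export
goDag <- function(terms, parents) {
  ids <- terms$id
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  anc <- vector("list", length(ids)); names(anc) <- ids
  state <- integer(length(ids)); names(state) <- ids  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return(anc[[id]])
    if (state[[id]] == 1L) stop("cyclic ontology at term ", id)
    state[[id]] <<- 1L
    a <- character()
    for (p in parents[[id]]) a <- union(a, c(p, visit(p)))
    anc[[id]] <<- a
    state[[id]] <<- 2L
    a
  }
  for (id in ids) visit(id)
  new("GoDag", terms = terms, parents = parents, ancestors = anc)
}

#' Read GO annotations from a GAF file and propagate them up the DAG
#'
#' GAF 2.x: comment lines start with \code{!}; column 2 is the object id
#' (accession), column 4 the qualifier (rows containing NOT are dropped),
#' column 5 the GO id, column 9 the aspect (kept when it matches the DAG's
#' namespace initial, "P" for biological_process). Annotations to terms
#' absent from the DAG are skipped with a warning. Every protein's term set
#' is propagated to all ancestors.
#'
#' @param path GAF file.
#' @param dag a [GoDag-class] object.
#' @return a [GoAnnotations-class] object.
#' @export
readGoAnnotations <- function(path, dag) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  aspectWanted <- switch(as.character(dag@terms$namespace[1]),
                         biological_process = "P",
                         molecular_function = "F",
                         cellular_component = "C", "P")
  acc <- character(); term <- character()
  unknown <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) next
    if (grepl("(^|\\|)NOT(\\||$)", f[4])) next
    if (length(f) >= 9 && nzchar(f[9]) && f[9] != aspectWanted) next
    if (!f[5] %in% dag@terms$id) { unknown <- c(unknown, f[5]); next }
    acc <- c(acc, stripIsoform(f[2])); term <- c(term, f[5])
  }
  if (length(unknown))
    warning("skipped annotations to unknown terms: ",
            paste(unique(unknown), collapse = ", "))
  goAnnotations(split(term, acc), dag)
}

#' Build GoAnnotations from a direct-annotation list
#'
#' @param direct named list: accession -> directly annotated term ids.
#' @param dag a [GoDag-class] object.
#' @return a [GoAnnotations-class] object with ancestor-propagated map.
#' @export
goAnnotations <- function(direct, dag) {
  direct <- lapply(direct, unique)
  prop <- lapply(direct, function(ts)
    unique(c(ts, unlist(dag@ancestors[ts], use.names = FALSE))))
  new("GoAnnotations", direct = direct, propagated = prop)
}
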