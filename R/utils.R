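#' Strip UniProt isoform suffixes
#'
#' Interaction files mix isoform ("P12345-2") and canonical identifiers;
#' all set algebra in this package is over canonical accessions.
#'
#' @param x character vector of accessions.
#' @return character vector with \code{-n} isoform suffixes removed.
#' @export
#' @examples stripIsoform(c("P12345-2", "Q00001"))
stripIsoform <- function(x) sub("-[0-9]+$", "", x)

# Amino-acid frequencies of the S. cerevisiae proteome (aggregate), used as
# the default background when no proteome is supplied to the generator.
YEAST_AA_FREQ <- local({
  f <- c(A = 0.0550, C = 0.0131, D = 0.0585, E = 0.0656, F = 0.0441,
         G = 0.0498, H = 0.0217, I = 0.0657, K = 0.0734, L = 0.0957,
         M = 0.0209, N = 0.0614, P = 0.0438, Q = 0.0394, R = 0.0445,
         S = 0.0902, T = 0.0592, V = 0.0556, W = 0.0104, Y = 0.0337)
  f / sum(f)
})

AA20 <- names(YEAST_AA_FREQ)

#' Node colours for category-annotated network export
#'
#' The palette used when exporting an annotated edge list for network
#' viewers: known prions black, other experimental prionogenic proteins
#' grey, experimental prion negatives yellow, N/Q-rich prion-like proteins
#' dark blue, everything else brown.
#'
#' @return named character vector of colours.
#' @export
categoryPalette <- function() {
  c(KP = "black", EPD = "grey", EPN = "yellow",
    NQP = "darkblue", other = "brown")
}

# Validate that set members are drawn from a known universe of accessions.
checkMembers <- function(members, universe, what = "set") {
  bad <- setdiff(members, universe)
  if (length(bad))
    stop(what, " contains accessions absent from the proteome: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  invisible(TRUE)
}
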