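#' Read out the genetic code implied by a network
#'
#' Forward-propagates all 64 codon encodings and assigns each codon the
#' amino acid nearest (Euclidean, canonical alphabetical tie-break) to the
#' network's output point in chemical space. Decoding is deterministic and
#' total: every codon maps to some amino acid.
#'
#' @param net A \code{perceptron_translator}.
#' @param aa_tab An \code{"aa_table"}.
#' @return A \code{codon_table}.
#' @export
read_code <- function(net, aa_tab) {
  Y <- forward(net, .codon_encoding_matrix())
  chem <- chem_matrix(aa_tab)
  idx <- .nearest_rows(Y, chem)
  structure(stats::setNames(rownames(chem)[idx], codons()),
            class = "codon_table")
}

.codon_encoding_matrix <- function() {
  if (is.null(.protocode_cache$enc)) {
    .protocode_cache$enc <- encode_codon(codons())
  }
  .protocode_cache$enc
}

#' Expressivity of a codon table
#'
#' The number of distinct amino acids appearing among the (sense)
#' assignments; range \[1, 20\]. Stop codons, present only in the standard
#' genetic code comparator, are not counted.
#'
#' @param tab A \code{codon_table}.
#' @return Integer in \[1, 20\].
#' @export
expressivity <- function(tab) {
  v <- unclass(tab)
  length(unique(v[v != "Stop"]))
}

#' Obverter choice of codon for a target amino acid
#'
#' The obverter procedure: to signal a meaning (amino acid), the donor
#' chooses the signal (codon) that its own comprehension system decodes
#' closest to that meaning. All 64 codons are scanned exhaustively; the one
#' whose network output minimises Euclidean distance in chemical space to
#' the target's 11-D vector is returned, ties broken by canonical codon
#' order.
#'
#' Because the scan minimises distance to the target's idealised vector --
#' not to the donor's own read-out table -- the chosen codon can disagree
#' with the donor's table at that codon. This emergent transmission error is
#' the model's source of novel amino-acid assignments.
#'
#' @param net The donor's \code{perceptron_translator}.
#' @param target Three-letter amino-acid code, or an 11-D numeric point.
#' @param aa_tab An \code{"aa_table"}.
#' @return A codon (length-3 character string).
#' @export
obverter_codon <- function(net, target, aa_tab) {
  chem <- chem_matrix(aa_tab)
  point <- if (is.character(target)) {
    if (!(target %in% rownames(chem))) stop("unknown amino acid: ", target)
    chem[target, ]
  } else {
    stopifnot(length(target) == ncol(chem), all(is.finite(target)))
    as.numeric(target)
  }
  Y <- forward(net, .codon_encoding_matrix())
  d2 <- rowSums((Y - matrix(point, nrow(Y), ncol(Y), byrow = TRUE))^2)
  codons()[which.min(d2)]
}
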