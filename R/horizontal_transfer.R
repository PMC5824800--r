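#' Horizontal transfer of code fragments
#'
#' One communal-evolution event: the donor emits a fragment of its code --
#' 10 distinct amino acids sampled by abundance, each paired with its
#' obverter codon -- and the receiver assimilates the fragment by
#' backpropagation (500 training presentations), pulling its code toward
#' the donor's. No fitness, selection or replication is involved.
#'
#' @name horizontal_transfer
NULL

# Weighted sampling without replacement as successive draws with
# renormalised weights; base sample(prob =) implements exactly this.
.weighted_draw <- function(weights, k) {
  sample.int(length(weights), k, replace = FALSE, prob = weights)
}

#' Sample a code fragment from a donor
#'
#' Draws \code{n_pairs} distinct amino acids from the 20, without
#' replacement, with per-draw probability proportional to
#' \code{transfer_weight} (cRAAA -- less costly amino acids are more
#' abundant, hence more likely to be transferred). Each is paired with the
#' donor's obverter codon. The sampling pool is all 20 amino acids whether
#' or not the donor currently encodes them; together with obverter
#' transmission errors this is what injects novel assignments into the
#' population.
#'
#' @param donor_net The donor's \code{perceptron_translator}.
#' @param aa_tab An \code{"aa_table"}.
#' @param n_pairs Fragment size (default 10).
#' @return A \code{data.frame} with columns \code{codon} and \code{aa}
#'   (\code{n_pairs} rows, amino acids pairwise distinct).
#' @export
sample_fragment <- function(donor_net, aa_tab, n_pairs = 10) {
  w <- aa_tab$transfer_weight
  if (sum(w > 0) < n_pairs) {
    stop("need at least ", n_pairs, " amino acids with positive ",
         "transfer weight")
  }
  idx <- .weighted_draw(w, n_pairs)
  aas <- aa_tab$aa[idx]
  # one shared forward pass over the 64 codons; per-target scan identical
  # in arithmetic to obverter_codon (tested for agreement)
  Y <- forward(donor_net, .codon_encoding_matrix())
  chem <- chem_matrix(aa_tab)
  cods <- vapply(aas, function(a) {
    point <- chem[a, ]
    d2 <- rowSums((Y - matrix(point, nrow(Y), ncol(Y), byrow = TRUE))^2)
    codons()[which.min(d2)]
  }, character(1))
  structure(list(codon = unname(cods), aa = aas),
            class = "data.frame", row.names = seq_len(n_pairs))
}

#' Assimilate a fragment into a receiver
#'
#' Converts the fragment's pairs to (codon encoding, target chemical-space
#' vector) training samples and trains the receiver for \code{epochs}
#' passes (default 500, the number of training presentations per transfer),
#' presenting the pairs in a freshly shuffled order each pass.
#'
#' @param receiver_net The receiver's \code{perceptron_translator}.
#' @param fragment A fragment from \code{\link{sample_fragment}}.
#' @param aa_tab An \code{"aa_table"}.
#' @param epochs Training passes (0 leaves the receiver unchanged).
#' @return The updated receiver network.
#' @export
apply_transfer <- function(receiver_net, fragment, aa_tab, epochs = 500) {
  if (!all(c("codon", "aa") %in% names(fragment)) || nrow(fragment) == 0) {
    stop("fragment must be a nonempty data.frame with columns codon, aa")
  }
  X <- encode_codon(fragment$codon)
  if (is.null(dim(X))) X <- matrix(X, 1)
  D <- chem_matrix(aa_tab)[fragment$aa, , drop = FALSE]
  train_on_pairs(receiver_net, X, D, epochs = epochs)
}
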