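#' The standard genetic code
#'
#' The canonical 64-codon table: 61 sense codons covering all 20 amino
#' acids, plus the three stop codons UAA, UAG and UGA. Stops carry no
#' amino-acid identity and no chemical-space point; they exist only in this
#' comparator and are invisible to the simulator (the model itself encodes
#' no stop or start signals).
#'
#' @return A \code{codon_table} (with \code{"Stop"} entries) for
#'   \code{sgc_table()}; the 61 sense codons for \code{sgc_sense_codons()}.
#' @examples
#' expressivity(sgc_table())  # 20
#' @export
sgc_table <- function() {
  if (is.null(.protocode_cache$sgc)) {
    a <- c(
      UUU = "Phe", UUC = "Phe", UUA = "Leu", UUG = "Leu",
      UCU = "Ser", UCC = "Ser", UCA = "Ser", UCG = "Ser",
      UAU = "Tyr", UAC = "Tyr", UAA = "Stop", UAG = "Stop",
      UGU = "Cys", UGC = "Cys", UGA = "Stop", UGG = "Trp",
      CUU = "Leu", CUC = "Leu", CUA = "Leu", CUG = "Leu",
      CCU = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
      CAU = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
      CGU = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
      AUU = "Ile", AUC = "Ile", AUA = "Ile", AUG = "Met",
      ACU = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
      AAU = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
      AGU = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
      GUU = "Val", GUC = "Val", GUA = "Val", GUG = "Val",
      GCU = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
      GAU = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
      GGU = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly")
    .protocode_cache$sgc <- codon_table(a, allow_stop = TRUE)
  }
  .protocode_cache$sgc
}

#' @rdname sgc_table
#' @export
sgc_sense_codons <- function() {
  tab <- sgc_table()
  codons()[unclass(tab) != "Stop"]
}
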