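#' Codon space
#'
#' The 64 codons over the alphabet U, C, A, G, their numeric input encoding
#' for the translation network, single-nucleotide neighbourhoods, and codon
#' tables (total maps codon -> amino acid).
#'
#' @name codon_space
NULL

CODON_BASES <- c("U", "C", "A", "G")

# Pyrimidines (U, C) and purines (A, G) are placed unevenly on [0, 1] so the
# two chemical classes are separated: within-class gap 0.3, between-class 0.4.
BASE_ENCODING <- c(U = 0, C = 0.3, A = 0.7, G = 1)

.protocode_cache <- new.env(parent = emptyenv())

#' All 64 codons in canonical order
#'
#' Lexicographic over the base order U, C, A, G (the convention of printed
#' codon tables), first position most significant.
#'
#' @return Character vector of length 64.
#' @export
codons <- function() {
  if (is.null(.protocode_cache$codons)) {
    g <- expand.grid(b3 = CODON_BASES, b2 = CODON_BASES, b1 = CODON_BASES,
                     stringsAsFactors = FALSE)
    .protocode_cache$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .protocode_cache$codons
}

#' Encode codons as network inputs
#'
#' Maps each base to its input value (U = 0, C = 0.3, A = 0.7, G = 1),
#' preserving base order; position 1/2/3 feeds input node 1/2/3.
#'
#' @param codon Character vector of codons (e.g. \code{"UCA"}).
#' @return For a single codon, a numeric 3-vector; for several, an n x 3
#'   matrix with one row per codon.
#' @examples
#' encode_codon("UCA")  # 0.0 0.3 0.7
#' @export
encode_codon <- function(codon) {
  .check_codons(codon)
  # BASE_ENCODING[matrix] flattens column-major, so refill column-major
  m <- matrix(BASE_ENCODING[.split_bases(codon)], ncol = 3)
  rownames(m) <- codon
  if (length(codon) == 1L) {
    v <- m[1, ]
    names(v) <- NULL
    return(v)
  }
  m
}

.split_bases <- function(codon) {
  t(vapply(strsplit(codon, "", fixed = TRUE), identity, character(3)))
}

.check_codons <- function(codon) {
  if (!is.character(codon) || any(nchar(codon) != 3)) {
    stop("codons must be 3-character strings over U/C/A/G")
  }
  bad <- grepl("[^UCAG]", codon)
  if (any(bad)) {
    stop("invalid base symbol in codon(s): ",
         paste(codon[bad], collapse = ", "))
  }
  invisible(codon)
}

#' Single-nucleotide neighbours of a codon
#'
#' The 9 codons differing from the input at exactly one position
#' (3 positions x 3 alternative bases); the input itself is excluded.
#'
#' @param codon A single codon.
#' @return Character vector of length 9.
#' @examples
#' codon_neighbors("AAA")
#' @export
codon_neighbors <- function(codon) {
  .check_codons(codon)
  stopifnot(length(codon) == 1L)
  out <- character(0)
  for (pos in 1:3) {
    for (b in CODON_BASES) {
      if (b != substr(codon, pos, pos)) {
        x <- codon
        substr(x, pos, pos) <- b
        out <- c(out, x)
      }
    }
  }
  out
}

# 64 x 9 integer matrix: row c holds the positions (in codons()) of the
# single-nucleotide neighbours of codons()[c]. Memoised.
.neighbor_index <- function() {
  if (is.null(.protocode_cache$nbr_idx)) {
    cods <- codons()
    idx <- t(vapply(cods, function(c3) match(codon_neighbors(c3), cods),
                    integer(9)))
    rownames(idx) <- cods
    .protocode_cache$nbr_idx <- idx
  }
  .protocode_cache$nbr_idx
}

#' Construct a codon table
#'
#' A codon table is a total map from the 64 codons to amino-acid three-letter
#' codes. Values are validated against the canonical 20 (plus \code{"Stop"}
#' when \code{allow_stop = TRUE}, used only for the standard genetic code --
#' the simulator itself never produces stops).
#'
#' @param assignment Named character vector: names are the 64 codons, values
#'   three-letter amino-acid codes. Order is normalised to \code{codons()}.
#' @param allow_stop Permit the value \code{"Stop"}.
#' @return Named character vector of length 64 with class
#'   \code{"codon_table"}.
#' @export
codon_table <- function(assignment, allow_stop = FALSE) {
  if (length(assignment) != 64 || is.null(names(assignment))) {
    stop("assignment must be a named character vector of length 64")
  }
  if (!setequal(names(assignment), codons())) {
    stop("assignment names must be exactly the 64 codons")
  }
  assignment <- assignment[codons()]
  valid <- rownames(chem_matrix(.default_aa_table()))
  if (allow_stop) valid <- c(valid, "Stop")
  bad <- which(!(assignment %in% valid))
  if (length(bad) > 0) {
    stop("unknown amino-acid identifier '", assignment[bad[1]],
         "' at codon ", names(assignment)[bad[1]])
  }
  structure(assignment, class = "codon_table")
}

.default_aa_table <- function() {
  if (is.null(.protocode_cache$aa_tab)) {
    .protocode_cache$aa_tab <- amino_acid_table()
  }
  .protocode_cache$aa_tab
}

#' @export
print.codon_table <- function(x, ...) {
  cat("codon table:", expressivity(x), "amino acids encoded\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Distance between two codon tables
#'
#' The number of codons whose assigned amino acid differs between the two
#' tables (a Hamming distance on assignments, range \[0, 64\]).
#'
#' @param a,b Codon tables.
#' @return Integer in \[0, 64\].
#' @export
table_distance <- function(a, b) {
  sum(unclass(a)[codons()] != unclass(b)[codons()])
}

#' Read/write codon tables
#'
#' Tab-delimited form: two columns, \code{codon} and \code{aa}, one row per
#' codon, header included. The JSON form wraps the same assignment together
#' with an arbitrary metadata list. Both round-trip losslessly.
#'
#' @param tab A codon table.
#' @param file Path.
#' @param allow_stop Passed through to \code{\link{codon_table}} validation.
#' @param metadata Optional named list stored alongside the assignment
#'   (JSON form only).
#' @return \code{read_codon_table} returns a \code{codon_table};
#'   \code{read_codon_table_json} returns a list with elements
#'   \code{table} and \code{metadata}.
#' @export
write_codon_table <- function(tab, file) {
  df <- data.frame(codon = codons(), aa = unclass(tab)[codons()])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_codon_table
#' @export
read_codon_table <- function(file, allow_stop = FALSE) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("codon", "aa") %in% names(df))) {
    stop("codon-table file ", file, " must have columns 'codon' and 'aa'")
  }
  codon_table(stats::setNames(df$aa, df$codon), allow_stop = allow_stop)
}

#' @rdname write_codon_table
#' @export
write_codon_table_json <- function(tab, file, metadata = list()) {
  obj <- list(assignment = as.list(stats::setNames(unclass(tab)[codons()],
                                                   codons())),
              metadata = metadata)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_codon_table
#' @export
read_codon_table_json <- function(file, allow_stop = FALSE) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  list(table = codon_table(unlist(obj$assignment), allow_stop = allow_stop),
       metadata = obj$metadata)
}
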