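#' Amino-acid chemical space
#'
#' The 20 encoded amino acids are represented as points in an 11-dimensional
#' chemical space: four continuous physicochemical properties, min-max
#' normalised to \[0, 1\] over the 20 amino acids -- van der Waals volume
#' (size), side-chain pKa (charge), logP (hydrophobicity) and molecular
#' weight -- plus five binary side-chain composition flags (C, N, O, S,
#' benzene ring) and two binary backbone-type flags (primary alpha-amine vs
#' cyclic secondary amine, i.e. proline). Every amino acid is uniquely
#' specified in this space. Auxiliary scalars carried alongside: Woese's
#' polar requirement (used by \code{\link{delta_code}}), raw molecular
#' weight, a simple/complex/sulfur class label, the aminoacyl-tRNA
#' synthetase class, and a positive transfer weight (cellular relative
#' amino-acid abundance, cRAAA) that biases which amino acids get donated
#' during horizontal transfer.
#'
#' @name chemical_space
NULL

AA_TABLE_COLUMNS <- c("aa", "letter", "vdw_volume", "pka", "logp", "mol_weight",
                      "sc_c", "sc_n", "sc_o", "sc_s", "sc_benzene",
                      "bb_ia", "bb_iva",
                      "polar_requirement", "aa_class", "aars_class",
                      "transfer_weight")

AA_FLAG_COLUMNS <- c("sc_c", "sc_n", "sc_o", "sc_s", "sc_benzene",
                     "bb_ia", "bb_iva")

AA_CONTINUOUS_COLUMNS <- c("vdw_volume", "pka", "logp", "mol_weight")

CHEM_DIMENSIONS <- c("size", "charge", "hydrophobicity", "mol_weight",
                     "sc_c", "sc_n", "sc_o", "sc_s", "sc_benzene",
                     "bb_ia", "bb_iva")

#' Load the amino-acid descriptor table
#'
#' Reads the built-in table of 20 amino-acid descriptors (or a user-supplied
#' file in the same tab-delimited layout), validates it, and attaches the
#' normalised 20 x 11 chemical-space matrix as the \code{"chem"} attribute
#' (retrieved with \code{\link{chem_matrix}}). Rows are ordered
#' alphabetically by three-letter code; this ordering is the canonical
#' tie-break order used by \code{\link{nearest_amino_acid}}.
#'
#' Continuous properties are min-max normalised over the 20 amino acids, so
#' the extreme raw values map to exactly 0 and 1. Binary flags must be
#' exactly 0 or 1.
#'
#' @param file Optional path to a tab-delimited table with a header row and
#'   the columns \code{aa}, \code{letter}, \code{vdw_volume}, \code{pka},
#'   \code{logp}, \code{mol_weight}, \code{sc_c}, \code{sc_n}, \code{sc_o},
#'   \code{sc_s}, \code{sc_benzene}, \code{bb_ia}, \code{bb_iva},
#'   \code{polar_requirement}, \code{aa_class}, \code{aars_class},
#'   \code{transfer_weight}. \code{NULL} (default) loads the built-in table.
#' @return A \code{data.frame} of class \code{"aa_table"} with exactly 20
#'   rows, one per amino acid.
#' @examples
#' aa <- amino_acid_table()
#' nrow(aa)            # 20
#' range(chem_matrix(aa))  # 0 1
#' @export
amino_acid_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "amino_acids.tsv",
                        package = "protocode", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  missing_cols <- setdiff(AA_TABLE_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop("amino-acid table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, AA_TABLE_COLUMNS]
  if (nrow(tab) != 20) {
    stop("amino-acid table must have exactly 20 rows, got ", nrow(tab))
  }
  dup <- tab$aa[duplicated(tab$aa)]
  if (length(dup) > 0) {
    stop("duplicate amino-acid name(s): ", paste(unique(dup), collapse = ", "))
  }
  for (col in c(AA_CONTINUOUS_COLUMNS, AA_FLAG_COLUMNS,
                "polar_requirement", "transfer_weight")) {
    bad <- which(!is.finite(tab[[col]]))
    if (length(bad) > 0) {
      stop("non-finite or missing '", col, "' in row for ", tab$aa[bad[1]])
    }
  }
  for (col in AA_FLAG_COLUMNS) {
    bad <- which(!(tab[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop("flag column '", col, "' must be 0 or 1; offending row: ",
           tab$aa[bad[1]], " (value ", tab[[col]][bad[1]], ")")
    }
  }
  bad_w <- which(tab$transfer_weight <= 0)
  if (length(bad_w) > 0) {
    stop("transfer_weight must be positive; offending row: ", tab$aa[bad_w[1]])
  }
  bad_class <- which(!(tab$aa_class %in% c("simple", "complex", "sulfur")))
  if (length(bad_class) > 0) {
    stop("aa_class must be simple/complex/sulfur; offending row: ",
         tab$aa[bad_class[1]])
  }
  bad_aars <- which(!(tab$aars_class %in% c("I", "II")))
  if (length(bad_aars) > 0) {
    stop("aars_class must be I or II; offending row: ", tab$aa[bad_aars[1]])
  }
  tab <- tab[order(tab$aa), , drop = FALSE]
  rownames(tab) <- tab$aa

  chem <- .build_chem_matrix(tab)
  if (anyDuplicated(chem) > 0) {
    d <- which(duplicated(chem))[1]
    stop("chemical-space vectors are not pairwise distinct; duplicate row: ",
         rownames(chem)[d])
  }
  attr(tab, "chem") <- chem
  class(tab) <- c("aa_table", "data.frame")
  tab
}

.build_chem_matrix <- function(tab) {
  minmax <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) stop("cannot min-max normalise a constant property")
    (x - r[1]) / (r[2] - r[1])
  }
  m <- cbind(size = minmax(tab$vdw_volume),
             charge = minmax(tab$pka),
             hydrophobicity = minmax(tab$logp),
             mol_weight = minmax(tab$mol_weight),
             as.matrix(tab[, AA_FLAG_COLUMNS]))
  rownames(m) <- tab$aa
  storage.mode(m) <- "double"
  m
}

#' Normalised chemical-space matrix
#'
#' @param aa_tab An \code{"aa_table"} from \code{\link{amino_acid_table}}.
#' @return A 20 x 11 numeric matrix, rows named by three-letter amino-acid
#'   code (alphabetical), columns the 11 chemical-space dimensions. All
#'   entries lie in \[0, 1\].
#' @export
chem_matrix <- function(aa_tab) {
  chem <- attr(aa_tab, "chem")
  if (is.null(chem)) stop("not an aa_table: missing chemical-space matrix")
  chem
}

#' Nearest amino acid in chemical space
#'
#' Finds the amino acid whose 11-D chemical-space vector minimises Euclidean
#' distance to \code{point}. Ties are broken deterministically in favour of
#' the amino acid earlier in the canonical alphabetical three-letter order.
#'
#' @param point Numeric vector of length 11, all components finite.
#' @param aa_tab An \code{"aa_table"}.
#' @param metric Distance metric; only \code{"euclidean"} is provided.
#' @return The three-letter code of the nearest amino acid.
#' @examples
#' aa <- amino_acid_table()
#' nearest_amino_acid(chem_matrix(aa)["Gly", ], aa)  # "Gly"
#' @export
nearest_amino_acid <- function(point, aa_tab, metric = "euclidean") {
  metric <- match.arg(metric, "euclidean")
  m <- chem_matrix(aa_tab)
  if (nrow(m) == 0) stop("empty amino-acid table")
  if (length(point) != ncol(m)) {
    stop("point must have ", ncol(m), " components")
  }
  if (!all(is.finite(point))) stop("point components must be finite")
  d2 <- colSums((t(m) - point)^2)
  rownames(m)[which.min(d2)]
}

# Row indices of the nearest amino acid for each row of Y (n x 11).
# which-min per row with ties to the lowest index, i.e. alphabetical order.
.nearest_rows <- function(Y, chem) {
  # squared distance trick: argmin_a |y - m_a|^2 = argmax_a (2 y.m_a - |m_a|^2)
  # kept as explicit distances to match nearest_amino_acid bit-for-bit
  n <- nrow(Y)
  idx <- integer(n)
  tm <- t(chem)
  for (r in seq_len(n)) {
    idx[r] <- which.min(colSums((tm - Y[r, ])^2))
  }
  idx
}
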