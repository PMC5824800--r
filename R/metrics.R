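#' Code optimality: polar-requirement error robustness
#'
#' \eqn{\Delta_{code}}: for each codon in \code{codon_subset}, take all
#' single-nucleotide neighbours also in the subset, average the squared
#' difference in Woese polar requirement between the codon's amino acid and
#' each neighbour's, then average those per-codon means over the subset.
#' Lower values mean single-nucleotide changes land on chemically more
#' similar amino acids, i.e. a more error-robust code.
#'
#' For simulator tables the subset is all 64 codons. For the standard
#' genetic code it is the 61 sense codons: stop codons carry no
#' polar-requirement value and are excluded both as source codons and as
#' neighbour targets (a sense codon adjacent to a stop simply has fewer
#' neighbours in its average). With the canonical polar-requirement scale
#' this reading reproduces the reference value 5.24 for the standard code;
#' see the package vignette for the calibration.
#'
#' @param tab A \code{codon_table}.
#' @param aa_tab An \code{"aa_table"} (supplies polar requirements).
#' @param codon_subset Codons to include (default: all 64). For tables
#'   containing \code{"Stop"}, pass the sense codons.
#' @param scale \code{"squared"} (default, the calibrated reading) or
#'   \code{"abs"} for the absolute-difference alternative.
#' @return Non-negative real.
#' @examples
#' aa <- amino_acid_table()
#' delta_code(sgc_table(), aa, codon_subset = sgc_sense_codons())  # 5.24
#' @export
delta_code <- function(tab, aa_tab, codon_subset = NULL,
                       scale = c("squared", "abs")) {
  scale <- match.arg(scale)
  cods <- codons()
  if (is.null(codon_subset)) codon_subset <- cods
  if (length(codon_subset) == 0) stop("empty codon subset")
  .check_codons(codon_subset)
  v <- unclass(tab)[cods]
  in_subset <- cods %in% codon_subset
  if (any(v[in_subset] == "Stop")) {
    stop("codon subset contains stop codons, which have no polar requirement")
  }
  pr_scale <- stats::setNames(aa_tab$polar_requirement, aa_tab$aa)
  pr <- pr_scale[v]               # NA at stops; never touched below
  nbr <- .neighbor_index()
  per_codon <- rep(NA_real_, 64)
  for (ci in which(in_subset)) {
    nb <- nbr[ci, ]
    nb <- nb[in_subset[nb]]
    if (length(nb) == 0) next
    d <- pr[ci] - pr[nb]
    per_codon[ci] <- if (scale == "squared") mean(d^2) else mean(abs(d))
  }
  vals <- per_codon[in_subset]
  if (anyNA(vals)) {
    warning("dropping codon(s) with no neighbours inside the subset")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

#' Universality of a population of codes
#'
#' Mean and standard deviation of \code{\link{table_distance}} over all
#' unordered pairs of tables: how far the population is from sharing one
#' universal code (0 = identical codes everywhere).
#'
#' @param codes List of at least 2 \code{codon_table}s.
#' @return Named numeric vector \code{c(mean =, sd =)}. The sd is the
#'   sample standard deviation over pairs (0 for a single pair).
#' @export
universality <- function(codes) {
  n <- length(codes)
  if (n < 2) stop("universality needs at least 2 codon tables")
  m <- vapply(codes, function(tt) unclass(tt)[codons()], character(64))
  d <- numeric(n * (n - 1) / 2)
  k <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1
      d[k] <- sum(m[, i] != m[, j])
    }
  }
  c(mean = mean(d), sd = if (k > 1) stats::sd(d) else 0)
}

#' Random codon tables with fixed expressivity
#'
#' Monte-Carlo null for optimality comparisons: assigns the 64 codons
#' uniformly at random, conditioned on the table using exactly
#' \code{n_aa} distinct amino acids (each of the \code{n_aa} chosen amino
#' acids gets one guaranteed codon; the rest are uniform).
#'
#' @param aa_tab An \code{"aa_table"}.
#' @param n_aa Required expressivity (default 20).
#' @return A \code{codon_table}.
#' @export
random_code <- function(aa_tab, n_aa = 20) {
  stopifnot(n_aa >= 1, n_aa <= 20)
  aas <- sample(aa_tab$aa, n_aa)
  assign <- sample(aas, 64, replace = TRUE)
  # guarantee presence of each chosen amino acid
  slots <- sample.int(64, n_aa)
  assign[slots] <- aas
  codon_table(stats::setNames(assign, codons()))
}
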