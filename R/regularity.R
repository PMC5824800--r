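#' Regularities of evolved codes
#'
#' Post-hoc analyses of the most optimal evolved codes: how codon
#' assignments distribute over amino-acid complexity classes, and how
#' per-amino-acid assignment counts correlate with transfer probability
#' (abundance) and with molecular weight.
#'
#' @name regularity
NULL

#' Select each run's most optimal code
#'
#' From each run's final population, the code with minimal
#' \eqn{\Delta_{code}}; ties broken by higher expressivity, then by first
#' protocell index.
#'
#' @param populations List of runs; each element a list of
#'   \code{codon_table}s (one run's final population).
#' @param aa_tab An \code{"aa_table"}.
#' @return List of \code{codon_table}s, one per run.
#' @export
select_optimal_codes <- function(populations, aa_tab) {
  lapply(populations, function(codes) {
    d <- vapply(codes, delta_code, numeric(1), aa_tab = aa_tab)
    e <- vapply(codes, expressivity, integer(1))
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[e[best] == max(e[best])]
    codes[[best[1]]]
  })
}

# per-amino-acid codon counts (named 20-vector, zeros included) for one code
.aa_counts <- function(tab, aa_tab) {
  v <- factor(unclass(tab), levels = aa_tab$aa)
  stats::setNames(as.integer(table(v)), aa_tab$aa)
}

#' Codon assignments per amino-acid class
#'
#' Raw variant: the total number of codons assigned to each class
#' (simple / complex / sulfur), averaged over codes; totals across classes
#' sum to 64 per code. Corrected variant: class totals divided by the
#' number of amino acids in the class (per-capita counts), which removes
#' the effect of the classes' unequal sizes among the 20 encoded amino
#' acids.
#'
#' @param codes List of \code{codon_table}s.
#' @param aa_tab An \code{"aa_table"}.
#' @param corrected Per-capita counts instead of totals.
#' @return Named numeric vector over the classes present in
#'   \code{aa_tab$aa_class}.
#' @export
assignments_per_class <- function(codes, aa_tab, corrected = FALSE) {
  counts <- vapply(codes, .aa_counts, numeric(20), aa_tab = aa_tab)
  mean_counts <- rowMeans(counts)
  cls <- factor(aa_tab$aa_class, levels = c("simple", "complex", "sulfur"))
  totals <- tapply(mean_counts, cls, sum)
  if (!corrected) return(c(totals))
  c(totals / table(cls))
}

#' Assignment-count correlations
#'
#' Correlation of the 20 amino acids' mean codon counts (across the
#' supplied codes) with their transfer weight (abundance) and with raw
#' molecular weight. Rank correlation by default since the functional form
#' of the relationships is unknown; zero variance in the counts yields
#' \code{NA} (undefined correlation), not an error.
#'
#' @param codes List of at least 2 \code{codon_table}s.
#' @param aa_tab An \code{"aa_table"}.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return List with elements \code{transfer_weight},
#'   \code{molecular_weight} (correlation coefficients or \code{NA}) and
#'   \code{mean_counts} (the underlying 20-vector).
#' @export
assignment_correlations <- function(codes, aa_tab,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(codes) < 2) stop("need at least 2 codes")
  counts <- vapply(codes, .aa_counts, numeric(20), aa_tab = aa_tab)
  mean_counts <- rowMeans(counts)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  list(transfer_weight = safe_cor(mean_counts, aa_tab$transfer_weight),
       molecular_weight = safe_cor(mean_counts, aa_tab$mol_weight),
       mean_counts = mean_counts)
}
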