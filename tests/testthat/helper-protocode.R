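# shared fixtures, all built in code

AA <- amino_acid_table()
CHEM <- chem_matrix(AA)

fresh_net <- function(seed, ...) {
  set.seed(seed)
  init_network(...)
}

# full central-difference gradient of eps = 1/2 |d - y(x)|^2 over all 101
# parameters, next to the analytic gradient implied by one training update
numgrad_vs_analytic <- function(net, after, x, d, h = 1e-6) {
  eps_of <- function(n) { y <- forward(n, x); 0.5 * sum((d - y)^2) }
  flds <- c("w_ih", "b_h", "w_ho", "b_o")
  g_num <- c(); g_ana <- c()
  for (fld in flds) {
    for (idx in seq_along(net[[fld]])) {
      np <- net
      np[[fld]][idx] <- net[[fld]][idx] + h
      ep <- eps_of(np)
      np[[fld]][idx] <- net[[fld]][idx] - h
      em <- eps_of(np)
      g_num <- c(g_num, (ep - em) / (2 * h))
      g_ana <- c(g_ana,
                 -(after[[fld]][idx] - net[[fld]][idx]) / net$learning_rate)
    }
  }
  list(num = g_num, ana = g_ana)
}

# a random total codon table (not conditioned on expressivity)
rand_table <- function(seed) {
  set.seed(seed)
  codon_table(stats::setNames(sample(AA$aa, 64, replace = TRUE), codons()))
}

# write a modified copy of the built-in amino-acid table and return its path
write_aa_fixture <- function(mutate) {
  tab <- utils::read.delim(system.file("extdata", "amino_acids.tsv",
                                       package = "protocode"))
  tab <- mutate(tab)
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
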