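#' Run configuration
#'
#' Bundles and validates the parameters of a communal-evolution run.
#' Defaults are the reference operating point of the model: a community of
#' N = 16 protocells, 100,000 transfers per run, 10 codon/amino-acid pairs
#' per transfer, 500 training presentations per transfer, learning rate
#' 0.1, metrics recorded every 500 transfers, and 50 independent runs for
#' replicate averaging. Desk-scale experiments override \code{transfers}
#' and \code{runs} downward.
#'
#' @param population Community size N (>= 2).
#' @param transfers Total horizontal transfers per run.
#' @param pairs_per_transfer Fragment size (distinct amino acids per
#'   transfer).
#' @param epochs Training presentations per transfer.
#' @param learning_rate Backpropagation rate eta.
#' @param interval Metric-recording cadence in transfers.
#' @param seed Master seed; every source of randomness in a run (and the
#'   per-run seeds of \code{\link{run_replicates}}) derives from it.
#' @param runs Number of independent replicate runs.
#' @param init Initial-weight distribution, \code{"uniform"} or
#'   \code{"gaussian"}.
#' @param checkpoint_every Optionally write network checkpoints every this
#'   many transfers (requires \code{checkpoint_dir}).
#' @param checkpoint_dir Directory for checkpoints.
#' @return A validated list of class \code{"run_config"}.
#' @export
run_config <- function(population = 16, transfers = 100000,
                       pairs_per_transfer = 10, epochs = 500,
                       learning_rate = 0.1, interval = 500, seed = 1,
                       runs = 50, init = c("uniform", "gaussian"),
                       checkpoint_every = NULL, checkpoint_dir = NULL) {
  init <- match.arg(init)
  stopifnot(population >= 2, population == as.integer(population),
            transfers >= 1, pairs_per_transfer >= 1,
            pairs_per_transfer <= 20, epochs >= 0,
            learning_rate >= 0, interval >= 1, runs >= 1,
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!is.null(checkpoint_every)) {
    stopifnot(checkpoint_every >= 1, !is.null(checkpoint_dir))
  }
  structure(list(population = as.integer(population),
                 transfers = as.integer(transfers),
                 pairs_per_transfer = as.integer(pairs_per_transfer),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 interval = as.integer(interval),
                 seed = as.integer(seed),
                 runs = as.integer(runs),
                 init = init,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: N =", x$population, "|", x$transfers, "transfers |",
      x$pairs_per_transfer, "pairs |", x$epochs, "epochs | eta =",
      x$learning_rate, "| interval", x$interval, "| seed", x$seed,
      "|", x$runs, "runs\n")
  invisible(x)
}

# Fast all-64-codon delta for the per-transfer hot path; equals
# delta_code(tab, aa_tab) (tested).
.delta_all64 <- function(assignment, pr_scale, nbr) {
  pr <- pr_scale[assignment]
  mean(rowMeans((pr - matrix(pr[nbr], 64, 9))^2))
}

.box_stats <- function(x, prefix) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  stats::setNames(c(mean(x), q[1], q[2], q[3], min(x), max(x)),
                  paste0(prefix, c("_mean", "_q1", "_median", "_q3",
                                   "_min", "_max")))
}

#' Run one communal-evolution simulation
#'
#' Initialises N translation networks, then iterates horizontal transfers:
#' draw an ordered (donor, receiver) pair uniformly at random with
#' donor != receiver, sample a fragment from the donor
#' (\code{\link{sample_fragment}}), assimilate it into the receiver
#' (\code{\link{apply_transfer}}). The receiver's expressivity and
#' \eqn{\Delta_{code}} are recorded after every transfer; every
#' \code{interval} transfers the population universality and snapshot
#' statistics are recorded. Networks are never created or destroyed after
#' initialisation -- there is no vertical descent. The whole trajectory is
#' a deterministic function of \code{config$seed}.
#'
#' @param config A \code{\link{run_config}}.
#' @param aa_tab An \code{"aa_table"} (default: built-in).
#' @param record_transfers Keep the per-transfer log (default TRUE).
#' @param networks Optional list of \code{config$population} pre-built
#'   \code{perceptron_translator}s to start from instead of fresh random
#'   initialisation (used e.g. to study frozen or cloned populations).
#' @return A list of class \code{"code_run"} with elements
#'   \code{networks} (final N networks), \code{codes} (their read-out
#'   tables), \code{metrics} (one row per recording point), \code{transfers}
#'   (per-transfer log: donor, receiver, mismatches with the donor's own
#'   table among the transmitted pairs, receiver expressivity and
#'   \eqn{\Delta_{code}} after training), and \code{config}.
#' @export
run_simulation <- function(config, aa_tab = amino_acid_table(),
                           record_transfers = TRUE, networks = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  N <- config$population
  nT <- config$transfers
  nets <- if (is.null(networks)) {
    lapply(seq_len(N), function(i) {
      init_network(learning_rate = config$learning_rate, init = config$init)
    })
  } else {
    stopifnot(length(networks) == N)
    networks
  }
  codes <- lapply(nets, read_code, aa_tab = aa_tab)
  code_mat <- vapply(codes, unclass, character(64))

  pr_scale <- stats::setNames(aa_tab$polar_requirement, aa_tab$aa)
  nbr <- .neighbor_index()

  rec_at <- unique(c(seq(config$interval, nT, by = config$interval), nT))
  n_rec <- length(rec_at)
  metrics <- vector("list", n_rec)
  log_donor <- integer(nT); log_receiver <- integer(nT)
  log_mismatch <- integer(nT); log_expr <- integer(nT)
  log_delta <- numeric(nT)

  win_start <- 1L
  rec_i <- 1L
  for (t in seq_len(nT)) {
    pair <- sample.int(N, 2)           # ordered, uniform over N(N-1)
    donor <- pair[1]; receiver <- pair[2]
    frag <- sample_fragment(nets[[donor]], aa_tab,
                            n_pairs = config$pairs_per_transfer)
    mism <- sum(code_mat[frag$codon, donor] != frag$aa)
    nets[[receiver]] <- apply_transfer(nets[[receiver]], frag, aa_tab,
                                       epochs = config$epochs)
    new_code <- read_code(nets[[receiver]], aa_tab)
    codes[[receiver]] <- new_code
    code_mat[, receiver] <- unclass(new_code)

    log_donor[t] <- donor; log_receiver[t] <- receiver
    log_mismatch[t] <- mism
    log_expr[t] <- expressivity(new_code)
    log_delta[t] <- .delta_all64(code_mat[, receiver], pr_scale, nbr)

    if (rec_i <= n_rec && t == rec_at[rec_i]) {
      win <- win_start:t
      univ <- universality(codes)
      pop_expr <- vapply(codes, expressivity, integer(1))
      pop_delta <- apply(code_mat, 2, .delta_all64, pr_scale = pr_scale,
                         nbr = nbr)
      metrics[[rec_i]] <- c(transfer = t,
                            .box_stats(log_expr[win], "expr"),
                            .box_stats(log_delta[win], "delta"),
                            univ_mean = unname(univ["mean"]),
                            univ_sd = unname(univ["sd"]),
                            pop_expr_mean = mean(pop_expr),
                            pop_delta_mean = mean(pop_delta))
      win_start <- t + 1L
      rec_i <- rec_i + 1L
    }
    if (!is.null(config$checkpoint_every) &&
        t %% config$checkpoint_every == 0) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE,
                 recursive = TRUE)
      for (i in seq_len(N)) {
        write_network(nets[[i]], file.path(config$checkpoint_dir,
                                           sprintf("t%07d_cell%02d.json",
                                                   t, i)))
      }
    }
  }
  out <- list(networks = nets, codes = codes,
              metrics = as.data.frame(do.call(rbind, metrics)),
              transfers = if (record_transfers) {
                data.frame(transfer = seq_len(nT), donor = log_donor,
                           receiver = log_receiver, mismatch = log_mismatch,
                           expressivity = log_expr, delta_code = log_delta)
              } else NULL,
              config = config)
  class(out) <- "code_run"
  out
}

#' @export
print.code_run <- function(x, ...) {
  u <- universality(x$codes)
  cat("code_run:", x$config$transfers, "transfers, N =",
      x$config$population, "\n",
      "final mean expressivity",
      round(mean(vapply(x$codes, expressivity, integer(1))), 2),
      "| final universality", round(u["mean"], 2), "\n")
  invisible(x)
}

#' Replicate runs and pointwise-averaged metrics
#'
#' Runs \code{config$runs} independent simulations with distinct per-run
#' seeds derived deterministically from the master seed, averages the
#' metric series pointwise, and retains each run's final codes plus its
#' most optimal code (minimum \eqn{\Delta_{code}}) for regularity analysis.
#'
#' @param config A \code{\link{run_config}}.
#' @param aa_tab An \code{"aa_table"}.
#' @param record_transfers Keep per-transfer logs inside each run
#'   (default FALSE to bound memory).
#' @return A list of class \code{"code_replicates"}: \code{metrics}
#'   (pointwise mean over runs), \code{runs} (per-run \code{code_run}
#'   objects), \code{optimal_codes} (one table per run),
#'   \code{run_seeds}, \code{config}.
#' @export
run_replicates <- function(config, aa_tab = amino_acid_table(),
                           record_transfers = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, config$runs)
  runs <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    cfg_r <- config
    cfg_r$seed <- run_seeds[r]
    runs[[r]] <- run_simulation(cfg_r, aa_tab,
                                record_transfers = record_transfers)
  }
  mets <- lapply(runs, `[[`, "metrics")
  agg <- Reduce(`+`, mets) / length(mets)
  optimal <- select_optimal_codes(lapply(runs, `[[`, "codes"), aa_tab)
  structure(list(metrics = agg, runs = runs, optimal_codes = optimal,
                 run_seeds = run_seeds, config = config),
            class = "code_replicates")
}
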