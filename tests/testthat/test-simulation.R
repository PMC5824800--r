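test_that("run_config validates and carries defaults", {
  cfg <- run_config()
  expect_equal(cfg$population, 16L)
  expect_equal(cfg$transfers, 100000L)
  expect_equal(cfg$pairs_per_transfer, 10L)
  expect_equal(cfg$epochs, 500L)
  expect_equal(cfg$learning_rate, 0.1)
  expect_equal(cfg$interval, 500L)
  expect_equal(cfg$runs, 50L)
  expect_error(run_config(population = 1), "population")
  expect_error(run_config(transfers = 0))
  expect_error(run_config(checkpoint_every = 10), "checkpoint_dir")
})

test_that("identical config and seed give identical runs", {
  cfg <- run_config(population = 6, transfers = 120, interval = 40,
                    seed = 77, runs = 1)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$codes, r2$codes)
  expect_identical(r1$transfers, r2$transfers)
})

test_that("a frozen cloned population has constant pairwise distance", {
  base <- fresh_net(5)
  base$learning_rate <- 0
  cfg <- run_config(population = 2, transfers = 100, interval = 25,
                    learning_rate = 0, seed = 5, runs = 1)
  run <- run_simulation(cfg, networks = list(base, base))
  expect_true(all(run$metrics$univ_mean == 0))
  expect_true(all(run$metrics$expr_min == run$metrics$expr_max))
})

test_that("metric series respects ranges and the recording grid", {
  cfg <- run_config(population = 8, transfers = 130, interval = 50,
                    seed = 3, runs = 1)
  run <- run_simulation(cfg)
  expect_equal(run$metrics$transfer, c(50, 100, 130))  # truncated final window
  expect_true(all(run$metrics$univ_mean >= 0 & run$metrics$univ_mean <= 64))
  expect_true(all(run$metrics$expr_min >= 1 & run$metrics$expr_max <= 20))
  expect_true(all(run$transfers$mismatch >= 0 & run$transfers$mismatch <= 10))
  expect_true(all(run$transfers$donor != run$transfers$receiver))
  expect_equal(nrow(run$transfers), 130L)
})

test_that("replicates: singleton aggregation is the run itself, seeds differ", {
  cfg <- run_config(population = 4, transfers = 60, interval = 30,
                    seed = 11, runs = 1)
  reps <- run_replicates(cfg)
  expect_equal(reps$metrics, reps$runs[[1]]$metrics)

  cfg3 <- run_config(population = 4, transfers = 40, interval = 20,
                     seed = 11, runs = 3)
  reps3 <- run_replicates(cfg3)
  expect_equal(anyDuplicated(reps3$run_seeds), 0L)
  # reproducible seed derivation
  reps3b <- run_replicates(cfg3)
  expect_identical(reps3$run_seeds, reps3b$run_seeds)
  expect_identical(reps3$metrics, reps3b$metrics)
  expect_equal(length(reps3$optimal_codes), 3L)
  # aggregated metrics are pointwise means
  expect_equal(reps3$metrics$univ_mean,
               rowMeans(vapply(reps3$runs,
                               function(r) r$metrics$univ_mean,
                               numeric(2))))
})

test_that("checkpointing writes restorable network state", {
  dir <- withr::local_tempdir()
  cfg <- run_config(population = 3, transfers = 20, interval = 10, seed = 2,
                    runs = 1, checkpoint_every = 10, checkpoint_dir = dir)
  run <- run_simulation(cfg)
  files <- list.files(dir)
  expect_length(files, 6L)  # 2 checkpoints x 3 cells
  last <- file.path(dir, "t0000020_cell01.json")
  expect_true(file.exists(last))
  expect_equal(read_network(last)[1:4], run$networks[[1]][1:4],
               tolerance = 0)
})
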