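test_that("fragments carry 10 pairwise-distinct amino acids", {
  set.seed(21)
  net <- init_network()
  for (i in 1:50) {
    frag <- sample_fragment(net, AA)
    expect_equal(nrow(frag), 10L)
    expect_equal(anyDuplicated(frag$aa), 0L)
    expect_true(all(frag$codon %in% codons()))
  }
})

test_that("weighted sampling without replacement behaves as specified", {
  # equal weights: every amino acid included with frequency ~ 10/20
  set.seed(22)
  hits <- numeric(20)
  for (i in 1:2000) {
    idx <- protocode:::.weighted_draw(rep(1, 20), 10)
    hits[idx] <- hits[idx] + 1
  }
  expect_true(all(abs(hits / 2000 - 0.5) < 0.05))

  # one dominating weight appears in essentially every draw
  set.seed(23)
  w <- c(1e6, rep(1, 19))
  in_draws <- mean(replicate(500, 1 %in% protocode:::.weighted_draw(w, 10)))
  expect_gt(in_draws, 0.999)
})

test_that("inclusion frequencies match exact successive-draw enumeration", {
  # miniature: 5 weights, 2 draws; enumerate all ordered pairs
  w <- c(5, 3, 1, 0.5, 0.5)
  p1 <- w / sum(w)
  incl <- numeric(5)
  for (i in 1:5) for (j in setdiff(1:5, i)) {
    pij <- p1[i] * w[j] / (sum(w) - w[i])
    incl[i] <- incl[i] + pij
    incl[j] <- incl[j] + pij
  }
  set.seed(24)
  emp <- numeric(5)
  for (r in 1:100000) {
    idx <- protocode:::.weighted_draw(w, 2)
    emp[idx] <- emp[idx] + 1
  }
  emp <- emp / 100000
  expect_true(all(abs(emp - incl) < 0.006))
})

test_that("sample_fragment needs 10 positively weighted amino acids", {
  aa2 <- AA
  aa2$transfer_weight[1:12] <- 0   # only 8 positive left
  net <- fresh_net(30)
  expect_error(sample_fragment(net, aa2), "positive")
})

test_that("apply_transfer with epochs = 0 is the identity", {
  net <- fresh_net(31)
  frag <- data.frame(codon = c("UUU", "GGG"), aa = c("Phe", "Gly"))
  expect_identical(apply_transfer(net, frag, AA, epochs = 0), net)
  expect_error(apply_transfer(net, frag[0, ], AA), "nonempty")
})

test_that("assimilation pulls the receiver toward donor and fragment", {
  # On freshly initialised (near-degenerate) protocells the novelty injected
  # by a transfer dominates, so donor-receiver distance is tested in the
  # evolving regime: draw donors/receivers from a population that has been
  # through a few hundred transfers.
  cfg <- run_config(population = 8, transfers = 600, interval = 300,
                    seed = 77, runs = 1)
  pop <- run_simulation(cfg, record_transfers = FALSE)$networks
  set.seed(33)
  agree_before <- numeric(40); agree_after <- numeric(40)
  dist_before <- numeric(40); dist_after <- numeric(40)
  for (i in 1:40) {
    ids <- sample(8, 2)
    donor <- pop[[ids[1]]]; receiver <- pop[[ids[2]]]
    dtab <- read_code(donor, AA)
    rtab <- read_code(receiver, AA)
    frag <- sample_fragment(donor, AA)
    agree_before[i] <- sum(unclass(rtab)[frag$codon] == frag$aa)
    dist_before[i] <- table_distance(dtab, rtab)
    receiver2 <- apply_transfer(receiver, frag, AA)
    rtab2 <- read_code(receiver2, AA)
    agree_after[i] <- sum(unclass(rtab2)[frag$codon] == frag$aa)
    dist_after[i] <- table_distance(dtab, rtab2)
  }
  expect_gt(mean(agree_after), mean(agree_before))
  expect_lte(mean(dist_after), mean(dist_before))
})

test_that("self-transfer does not degrade code transmission", {
  set.seed(34)
  ok <- logical(20)
  for (i in 1:20) {
    donor <- init_network()
    dtab <- read_code(donor, AA)
    frag <- sample_fragment(donor, AA)
    dis_before <- sum(unclass(dtab)[frag$codon] != frag$aa)
    clone2 <- apply_transfer(donor, frag, AA)
    ctab <- read_code(clone2, AA)
    dis_after <- sum(unclass(ctab)[frag$codon] != frag$aa)
    ok[i] <- (table_distance(dtab, ctab) == 0) || (dis_after <= dis_before)
  }
  expect_gt(mean(ok), 0.8)
})

test_that("transfers inject amino acids absent from the donor's table", {
  set.seed(35)
  gained <- logical(80)
  for (i in 1:80) {
    donor <- init_network(); receiver <- init_network()
    dset <- unique(unclass(read_code(donor, AA)))
    frag <- sample_fragment(donor, AA)
    receiver2 <- apply_transfer(receiver, frag, AA)
    rset2 <- unique(unclass(read_code(receiver2, AA)))
    gained[i] <- length(setdiff(rset2, dset)) > 0
  }
  expect_gt(sum(gained), 0)
})
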