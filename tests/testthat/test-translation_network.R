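test_that("initial weights have the stated moments (Monte Carlo)", {
  set.seed(501)
  w <- unlist(replicate(1000, {
    n <- init_network()
    c(n$w_ih, n$b_h, n$w_ho, n$b_o)
  }, simplify = FALSE))
  expect_gte(length(w), 1e5)
  se_mean <- 0.1 / sqrt(length(w))
  expect_lt(abs(mean(w)), 3 * se_mean)
  # se of sd for a uniform, approx sd/sqrt(2n) scaled by kurtosis; 3x the
  # gaussian-approx se is a generous band at n ~ 1e5
  expect_lt(abs(sd(w) - 0.1), 3 * 0.1 / sqrt(2 * length(w)) * 2)
  # uniform support: no draw beyond 0.1 * sqrt(3)
  expect_lte(max(abs(w)), 0.1 * sqrt(3))

  set.seed(502)
  wg <- unlist(replicate(500, {
    n <- init_network(init = "gaussian")
    c(n$w_ih, n$b_h, n$w_ho, n$b_o)
  }, simplify = FALSE))
  expect_lt(abs(sd(wg) - 0.1), 0.005)
  expect_gt(max(abs(wg)), 0.1 * sqrt(3))  # gaussian tails exceed uniform support
})

test_that("same seed gives bitwise-identical networks", {
  expect_identical(fresh_net(9), fresh_net(9))
})

test_that("forward pass matches the logistic closed form and an oracle", {
  net <- fresh_net(1)
  net$w_ih[] <- 0; net$b_h[] <- 0; net$w_ho[] <- 0; net$b_o[] <- 0
  expect_equal(forward(net, c(0.2, 0.5, 0.9)), rep(0.5, 11))

  # independent hand-rolled matrix implementation
  set.seed(77)
  for (i in 1:100) {
    n <- init_network(sd = runif(1, 0.05, 1))
    x <- runif(3)
    h <- plogis(drop(x %*% n$w_ih) + n$b_h)
    y <- plogis(drop(h %*% n$w_ho) + n$b_o)
    expect_equal(forward(n, x), y, tolerance = 1e-12)
    expect_true(all(forward(n, x) > 0 & forward(n, x) < 1))
  }
  expect_error(forward(net, c(1, NA, 0)), "finite")
})

test_that("backpropagation equals central-difference gradients to 1e-6", {
  # standard gradient check: relative error of the full gradient vectors
  # (componentwise relative error is dominated by float roundoff on the
  # near-zero input-layer components)
  set.seed(88)
  for (case in 1:10) {
    net <- init_network(sd = runif(1, 0.1, 0.8))
    x <- runif(3); d <- runif(11)
    after <- train_on_pairs(net, x, d, epochs = 1)
    g <- numgrad_vs_analytic(net, after, x, d)
    expect_lt(sqrt(sum((g$num - g$ana)^2)) / sqrt(sum(g$num^2)), 1e-6)
  }
})

test_that("training contract: eta = 0 and epochs = 0 leave the net unchanged", {
  net <- fresh_net(3)
  x <- matrix(runif(30), 10, 3); d <- matrix(runif(110), 10, 11)
  net0 <- net; net0$learning_rate <- 0
  expect_equal(train_on_pairs(net0, x, d, epochs = 5)[1:4], net0[1:4])
  expect_identical(train_on_pairs(net, x, d, epochs = 0), net)
  expect_error(train_on_pairs(net, x, matrix(0, 10, 5), epochs = 1),
               "dimension mismatch")
})

test_that("gradient descent on a single pair reduces the error", {
  set.seed(12)
  net <- init_network()
  x <- runif(3); d <- runif(11)
  eps0 <- 0.5 * sum((d - forward(net, x))^2)
  trained <- train_on_pairs(net, x, d, epochs = 200)
  eps1 <- 0.5 * sum((d - forward(trained, x))^2)
  expect_lt(eps1, eps0)
})

test_that("capacity: 20 distinct codons trainable toward all 20 amino acids", {
  # an arbitrary 64->20 labelling is not representable (see vignette); the
  # claim tested is that the architecture can express and recover the full
  # amino-acid repertoire from distinct signals
  set.seed(7)
  cods <- sample(codons(), 20)
  frag <- data.frame(codon = cods, aa = AA$aa)
  net <- apply_transfer(init_network(), frag, AA, epochs = 50000)
  got <- read_code(net, AA)
  expect_gte(sum(unclass(got)[cods] == AA$aa), 14)
  expect_gte(expressivity(got), 15)
})

test_that("network JSON checkpoints round-trip exactly", {
  net <- fresh_net(42)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back, net, tolerance = 0)
})
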