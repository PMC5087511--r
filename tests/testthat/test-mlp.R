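test_that("sigmoid satisfies its closed-form identities", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  set.seed(1)
  x <- rnorm(50, sd = 5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 50))
  # stable at extreme arguments
  expect_equal(sigmoid(700), 1)
  expect_equal(sigmoid(-700), 0)
  expect_true(all(is.finite(sigmoid(c(-700, 700)))))
})

test_that("forward propagation matches hand evaluation and checks shapes", {
  zero <- tiny_net(0, 0, 0, 0)
  expect_equal(unname(forward_mlp(zero, 0.7)$output[1, 1]), 0.5)

  net <- tiny_net(1, 0, 1, 0)
  expect_equal(unname(forward_mlp(net, 0)$output[1, 1]), sigmoid(sigmoid(0)),
               tolerance = 1e-12)  # ~0.6225

  expect_error(forward_mlp(net, c(0, 1)), class = "skelwatch_shape")
})

test_that("the objective equals the brute-force sum of squared residuals", {
  # one pattern, one output, d = 1, o = 0.5 -> E = 0.125
  zero <- tiny_net(0, 0, 0, 0)
  expect_equal(mlp_mse(zero, matrix(0.3), matrix(1)), 0.125)

  for (seed in 1:3) {
    net <- random_net(4, 3, 2, seed)
    pats <- random_patterns(7, 4, 2, seed + 10)
    expect_equal(mlp_mse(net, pats$x, pats$d),
                 brute_force_error(net, pats$x, pats$d), tolerance = 1e-12)
  }
  expect_error(mlp_mse(zero, matrix(numeric(0), 0, 1), matrix(numeric(0), 0, 1)),
               class = "skelwatch_bad_inputs")
})

test_that("analytic gradients match central finite differences", {
  for (arch in list(c(4, 3, 2, 7), c(15, 12, 5, 8))) {
    net <- random_net(arch[1], arch[2], arch[3], arch[4])
    pats <- random_patterns(6, arch[1], arch[3], arch[4] + 20)
    ana <- skelwatch:::mlp_gradients(net, pats$x, pats$d)
    num <- finite_diff_gradients(net, pats$x, pats$d)
    for (part in names(ana))
      expect_lt(max(abs(ana[[part]] - num[[part]])), 1e-6)
  }
  # tanh variant too
  net <- random_net(4, 3, 2, 3, transfer = "tanh")
  pats <- random_patterns(5, 4, 2, 33)
  ana <- skelwatch:::mlp_gradients(net, pats$x, pats$d)
  num <- finite_diff_gradients(net, pats$x, pats$d)
  for (part in names(ana))
    expect_lt(max(abs(ana[[part]] - num[[part]])), 1e-6)
})

test_that("a zero learning rate leaves the weights at their initialization", {
  pats <- random_patterns(10, 3, 2, 5)
  f <- mlp(pats$x, pats$d, n_hidden = 4, learning_rate = 0, max_epochs = 50, seed = 9)
  init <- skelwatch:::mlp_init(3, 4, 2, "sigmoid", 9, 0.5)
  expect_identical(f$W1, init$W1)
  expect_identical(f$b1, init$b1)
  expect_identical(f$W2, init$W2)
  expect_identical(f$b2, init$b2)
})

test_that("one small full-batch step strictly decreases the objective", {
  pats <- random_patterns(12, 5, 3, 21)
  init <- skelwatch:::mlp_init(5, 4, 3, "sigmoid", 4, 0.5)
  init$levels <- colnames(pats$d)
  before <- mlp_mse(init, pats$x, pats$d)
  f <- mlp(pats$x, pats$d, n_hidden = 4, learning_rate = 1e-3, max_epochs = 1,
           seed = 4, batch_scale = "sum")
  expect_equal(f$trace[1], before)     # trace records E before the update
  expect_lt(mlp_mse(f, pats$x, pats$d), before)
})

test_that("training is reproducible bit-for-bit given a seed", {
  pats <- random_patterns(20, 4, 2, 2)
  f1 <- mlp(pats$x, pats$d, n_hidden = 3, max_epochs = 200, seed = 11)
  f2 <- mlp(pats$x, pats$d, n_hidden = 3, max_epochs = 200, seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  f3 <- mlp(pats$x, pats$d, n_hidden = 3, max_epochs = 200, seed = 12)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("two separable Gaussian blobs are learned to 100% training accuracy", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, 0.3, 0.05), 20, 2),
             matrix(rnorm(40, 0.7, 0.05), 20, 2))
  x <- pmin(pmax(x, 0), 1)
  y <- rep(c("a", "b"), each = 20)
  f <- mlp(x, y, n_hidden = 4, max_error = 0.05, max_epochs = 10000, seed = 1)
  expect_true(f$converged)
  expect_lte(f$final_error, 0.05)
  expect_equal(mean(predict(f, x, threshold = 0, margin = 0) == y), 1)
  expect_true(all(diff(f$trace) <= 1e-9))  # monotone descent on this problem
})

test_that("hidden sizing heuristic rounds half away from zero", {
  expect_equal(size_hidden(15, 5), 13L)
  expect_equal(size_hidden(18, 2), 13L)
  expect_equal(size_hidden(3, 3), 4L)
  expect_equal(size_hidden(30, 2), 21L)
})

test_that("label decoding applies threshold, margin and first-index ties", {
  labs <- c("a", "b", "c")
  expect_equal(predict_label(c(0.9, 0.1, 0.1), labs), "a")
  expect_equal(predict_label(c(0.4, 0.4, 0.4), labs), "none")     # below threshold
  expect_equal(predict_label(c(0.8, 0.8), c("a", "b")), "none")   # tie vs margin
  expect_equal(predict_label(c(0.8, 0.8), c("a", "b"), margin = 0), "a")
  expect_equal(predict_label(rbind(c(0.9, 0.2), c(0.3, 0.2)), c("a", "b")),
               c("a", "none"))
})

test_that("the tanh variant keeps outputs in (0, 1) and still learns", {
  pats <- random_patterns(30, 4, 2, 14)
  f <- mlp(pats$x, pats$d, n_hidden = 4, transfer = "tanh", max_epochs = 500, seed = 3)
  o <- forward_mlp(f, pats$x)
  expect_true(all(o$hidden > -1 & o$hidden < 1))
  expect_true(all(o$output > 0 & o$output < 1))
  expect_lt(f$final_error, f$trace[1])
})

test_that("training rejects inputs outside [0, 1] and diverging runs raise", {
  pats <- random_patterns(5, 3, 2, 1)
  bad <- pats$x; bad[1, 1] <- 1.4
  expect_error(mlp(bad, pats$d, n_hidden = 2), class = "skelwatch_bad_inputs")
})

test_that("model JSON serialization reproduces outputs bit-exactly", {
  pats <- random_patterns(25, 6, 3, 17)
  f <- mlp(pats$x, pats$d, n_hidden = 5, max_epochs = 300, seed = 6)
  p <- withr::local_tempfile(fileext = ".json")
  write_mlp(f, p)
  g <- read_mlp(p)
  expect_identical(forward_mlp(g, pats$x)$output, forward_mlp(f, pats$x)$output)
  expect_identical(g$levels, f$levels)
  expect_identical(g$config$n_hidden, f$config$n_hidden)
})
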