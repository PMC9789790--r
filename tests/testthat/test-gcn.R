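test_that("forward pass matches hand arithmetic on an isolated node", {
  # one pseudo node, no edges: A_norm = [[1]], so each layer is x W
  X <- matrix(c(1, 2), 1, 2)
  A <- matrix(0, 1, 1)
  lab <- proportion_matrix(matrix(c(0.5, 0.5), 1), "p1", c("A", "B"))
  g <- manual_graph(X, A, lab, n_pseudo = 1)
  model <- init_gcn(c(2, 2, 2, 2), seed = 1)
  model$W0 <- matrix(c(1, 0, -1, 1), 2, 2)
  model$W1 <- matrix(c(0.5, 0.5, -2, 1), 2, 2)
  model$W2 <- matrix(c(1, 0, 0, 1), 2, 2)
  # by hand: h1 = relu([1*1+2*0, 1*-1+2*1]) = [1, 1]
  #          h2 = relu([0.5+0.5, -2+1]) = [1, 0]
  #          z3 = [1, 0]; softmax = exp([1,0]) / sum
  expected <- exp(c(1, 0)) / sum(exp(c(1, 0)))
  got <- gcn_forward(model, g)
  expect_equal(unname(unclass(got)[1, ]), expected, tolerance = 1e-12)
})

test_that("every forward output row is a composition summing to one", {
  set.seed(6)
  X <- matrix(rnorm(12 * 5), 12, 5)
  A <- matrix(0, 12, 12)
  A[cbind(1:6, 7:12)] <- 1
  A <- A + t(A)
  lab <- proportion_matrix(matrix(1 / 3, 8, 3), sprintf("p%d", 1:8),
                           c("A", "B", "C"))
  g <- manual_graph(X, A, lab, n_pseudo = 8)
  for (s in 1:3) {
    model <- init_gcn(c(5, 4, 3, 3), seed = s)
    out <- gcn_forward(model, g)
    expect_equal(unname(rowSums(unclass(out))), rep(1, 12),
                 tolerance = 1e-6)
    expect_true(all(unclass(out) > 0 & unclass(out) < 1))
  }
  # all-zero final layer: softmax of zeros is uniform over T
  model <- init_gcn(c(5, 4, 3, 3), seed = 1)
  model$W2 <- matrix(0, 3, 3)
  out <- gcn_forward(model, g)
  expect_equal(unname(unclass(out)[1, ]), rep(1 / 3, 3))
})

test_that("training drives the loss near zero on a constant one-hot target", {
  set.seed(4)
  n_p <- 20
  X <- matrix(rnorm(n_p * 4), n_p, 4)
  A <- matrix(0, n_p, n_p)
  lab <- proportion_matrix(cbind(1, matrix(0, n_p, 1)),
                           sprintf("p%d", seq_len(n_p)), c("A", "B"))
  g <- manual_graph(X, A, lab, n_pseudo = n_p)
  model <- train_gcn(g, lr = 0.05, max_epochs = 200, patience = 200,
                     hidden_dims = c(8, 4), seed = 2)
  expect_lt(dplyr::last(model$log$train_loss), 0.05)
})

test_that("training is seeded-deterministic", {
  set.seed(10)
  X <- matrix(rnorm(30 * 6), 30, 6)
  A <- matrix(0, 30, 30)
  A[cbind(1:20, c(21:30, 21:30))] <- 1
  A <- pmin(A + t(A), 1)
  lab_v <- matrix(rexp(20 * 3), 20, 3)
  lab <- proportion_matrix(lab_v / rowSums(lab_v),
                           sprintf("p%d", 1:20), c("A", "B", "C"))
  g <- manual_graph(X, A, lab, n_pseudo = 20, train = 1:16)
  g$masks$val <- 17:20
  m1 <- train_gcn(g, max_epochs = 30, seed = 7)
  m2 <- train_gcn(g, max_epochs = 30, seed = 7)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$W0, m2$W0)
})

test_that("early stopping restores the best validation epoch", {
  set.seed(10)
  # labels on the validation nodes are anti-correlated with the training
  # signal, so validation loss deteriorates while training loss falls
  X <- rbind(matrix(rnorm(16 * 3, mean = 2), 16, 3),
             matrix(rnorm(4 * 3, mean = 2), 4, 3))
  A <- matrix(0, 20, 20)
  lab <- proportion_matrix(rbind(cbind(1, matrix(0, 16, 1)),
                                 cbind(0, matrix(1, 4, 1))),
                           sprintf("p%d", 1:20), c("A", "B"))
  g <- manual_graph(X, A, lab, n_pseudo = 20, train = 1:16)
  g$masks$val <- 17:20
  model <- train_gcn(g, lr = 0.1, max_epochs = 200, patience = 10, seed = 1)
  n_ep <- nrow(model$log)
  expect_lt(n_ep, 200)
  best <- model$best_epoch
  expect_equal(model$log$val_loss[best], min(model$log$val_loss))
  # stops exactly `patience` epochs after the best one
  expect_equal(n_ep, best + 10)
})

test_that("labels propagate across disconnected components to real nodes", {
  set.seed(3)
  # two components: pseudo nodes 1..10 (type A) + real 21, 11..20 (B) + 22
  X <- rbind(matrix(rnorm(10 * 4, mean = 3), 10, 4),
             matrix(rnorm(10 * 4, mean = -3), 10, 4),
             matrix(rnorm(1 * 4, mean = 3), 1, 4),
             matrix(rnorm(1 * 4, mean = -3), 1, 4))
  A <- matrix(0, 22, 22)
  A[cbind(1:10, 21)] <- 1
  A[cbind(11:20, 22)] <- 1
  A <- pmin(A + t(A), 1)
  lab <- proportion_matrix(rbind(cbind(1, matrix(0, 10, 1)),
                                 cbind(0, matrix(1, 10, 1))),
                           sprintf("p%d", 1:20), c("A", "B"))
  g <- manual_graph(X, A, lab, n_pseudo = 20)
  model <- train_gcn(g, lr = 0.05, max_epochs = 200, patience = 200,
                     seed = 5)
  pred <- predict_real_proportions(model, g)
  expect_gte(unclass(pred)[1, "A"], 0.9)
  expect_gte(unclass(pred)[2, "B"], 0.9)
})

test_that("an untrained model warns and real predictions keep structure", {
  set.seed(1)
  X <- matrix(rnorm(6 * 3), 6, 3)
  lab <- proportion_matrix(matrix(0.25, 4, 4), sprintf("p%d", 1:4),
                           c("A", "B", "C", "D"))
  g <- manual_graph(X, matrix(0, 6, 6), lab, n_pseudo = 4)
  model <- init_gcn(c(3, 4, 4, 4), seed = 2)
  expect_warning(pred <- predict_real_proportions(model, g), "untrained")
  expect_equal(nrow(pred), 2L)
  expect_equal(ncol(pred), 4L)
  expect_equal(unname(rowSums(unclass(pred))), rep(1, 2), tolerance = 1e-9)
})

test_that("the low-proportion filter zeroes, renormalizes and backstops", {
  pm <- proportion_matrix(matrix(c(0.90, 0.06, 0.04), 1), "s1",
                          c("A", "B", "C"))
  out <- filter_low_proportions(pm, 0.05)
  expect_equal(unname(unclass(out)[1, ]), c(0.9375, 0.0625, 0))

  even <- proportion_matrix(matrix(0.5, 1, 2), "s1", c("A", "B"))
  expect_equal(unclass(filter_low_proportions(even, 0.05))[, ],
               unclass(even)[, ])

  # every entry below threshold: fall back to one-hot on the max
  flat <- proportion_matrix(matrix(1 / 25, 1, 25), "s1",
                            sprintf("t%d", 1:25))
  out2 <- filter_low_proportions(flat, 0.05)
  expect_equal(unname(unclass(out2)[1, ]), c(1, rep(0, 24)))

  expect_error(filter_low_proportions(pm, 1), "threshold")
})
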