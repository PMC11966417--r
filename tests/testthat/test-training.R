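test_that("backprop gradients match central finite differences", {
  spec <- connectivity_spec(5, 0.6, seed = 11)
  net <- build_network(spec, input_dim = 4, n_classes = 3)
  # scale the tiny init up so the loss surface is far from flat
  net$w_in <- net$w_in * 300
  net$w_hh <- net$w_hh * 300
  net$w_out <- net$w_out * 300
  set.seed(2)
  x <- array(runif(6 * 3 * 4), c(6, 3, 4))  # T = 3
  y <- sample(0:2, 6, replace = TRUE)
  g <- network_gradients(net, x, y)
  h <- 1e-6
  for (nm in c("w_in", "w_hh", "w_out")) {
    for (k in seq_along(net[[nm]])) {
      plus <- net
      plus[[nm]][k] <- plus[[nm]][k] + h
      minus <- net
      minus[[nm]][k] <- minus[[nm]][k] - h
      fd <- (network_gradients(plus, x, y)$loss -
               network_gradients(minus, x, y)$loss) / (2 * h)
      expect_equal(g$grads[[nm]][k], fd,
                   tolerance = 1e-4,
                   label = paste0(nm, "[", k, "] backprop gradient"))
    }
  }
})

test_that("masked positions stay exactly zero across training", {
  task <- tiny_task()
  net <- tiny_network(n_hidden = 32, p = 0.4, seed = 5)
  cfg <- training_config(max_epochs = 4, batch_size = 20, seed = 5)
  fit <- train_network(net, task$train, task$test, cfg)
  expect_true(all(fit$params$w_hh[net$mask == 0] == 0))
  # and unmasked weights did move
  expect_false(all(fit$params$w_hh[net$mask == 1] == net$w_hh[net$mask == 1]))
})

test_that("Dale training zeroes sign-flipping weights instead of reversing them", {
  task <- tiny_task()
  net <- tiny_network(n_hidden = 32, p = 0.6, seed = 6, dale = TRUE,
                      inhibitory_fraction = 0.25)
  cfg <- training_config(max_epochs = 4, batch_size = 20, seed = 6)
  fit <- train_network(net, task$train, task$test, cfg)
  s <- fit$params$signs
  expect_true(all(fit$params$w_hh * s >= 0))
  expect_true(all(fit$params$w_out * s >= 0))
  # clipping actually happened at least once on this task
  expect_gt(sum(fit$trace$zeroed_by_dale), 0)
  # a zeroed weight remains trainable: training from a hand-zeroed state
  # still moves some previously-zero unmasked entries
  expect_error(
    train_network(net, task$train, task$test, cfg, signs = rep(1, 10)),
    "length"
  )
})

test_that("training reduces the loss on a learnable task", {
  task <- tiny_task(n_train = 200)
  net <- tiny_network(n_hidden = 48, p = 0.5, seed = 7)
  cfg <- training_config(max_epochs = 20, batch_size = 20, seed = 7)
  init_loss <- network_gradients(net, task$train$sequences,
                                 task$train$labels)$loss
  fit <- train_network(net, task$train, task$test, cfg)
  final_loss <- network_gradients(fit$params, task$train$sequences,
                                  task$train$labels)$loss
  expect_lt(final_loss, init_loss)
  expect_gt(max(fit$trace$test_accuracy), 0.5)
  expect_gt(fit$trace$test_accuracy[nrow(fit$trace)], 0.4)
})

test_that("training is deterministic given the seed", {
  task <- tiny_task()
  cfg <- training_config(max_epochs = 2, batch_size = 25, seed = 9)
  net <- tiny_network(seed = 9)
  a <- train_network(net, task$train, task$test, cfg)
  b <- train_network(net, task$train, task$test, cfg)
  expect_identical(a$params$w_hh, b$params$w_hh)
  expect_identical(a$trace, b$trace)
  expect_identical(
    single_epoch_accuracy(net, task$train, task$test, cfg),
    single_epoch_accuracy(net, task$train, task$test, cfg)
  )
})

test_that("an untrained network scores at chance on a balanced test set", {
  task <- tiny_task(n_test = 200, n_classes = 4)
  net <- tiny_network(seed = 31)
  acc <- evaluate_accuracy(net, task$test)
  expect_lt(abs(acc - 0.25), 0.15)
})

test_that("sparse-to-dense mode lets zero-initialized weights become nonzero", {
  task <- tiny_task()
  net <- tiny_network(n_hidden = 32, p = 0.1, seed = 10)
  n_init <- sum(net$w_hh != 0)
  cfg <- training_config(max_epochs = 3, batch_size = 20,
                         mode = "sparse_to_dense", seed = 10)
  fit <- train_network(net, task$train, task$test, cfg)
  expect_gte(sum(fit$params$w_hh != 0), n_init)
  expect_gt(sum(fit$params$w_hh[net$mask == 0] != 0), 0)
})

test_that("early stopping halts after the configured patience", {
  task <- tiny_task(n_train = 40, n_test = 40)
  net <- tiny_network(seed = 12)
  # tiny weights and tiny lr: accuracy will not improve
  cfg <- training_config(max_epochs = 30, batch_size = 20,
                         learning_rate = 1e-9,
                         early_stop_patience = 2, seed = 12)
  fit <- train_network(net, task$train, task$test, cfg)
  expect_lte(nrow(fit$trace), 4)
})

test_that("sign-change statistics match a brute-force tally", {
  expect_equal(
    sign_change_stats(matrix(c(1, -1), 1), matrix(c(-1, -2), 1)),
    list(pos_to_neg = 1L, neg_to_pos = 0L,
         pos_magnitude_increase = 0L, neg_magnitude_increase = 1L)
  )
  m <- matrix(rnorm(100), 10)
  expect_equal(sign_change_stats(m, m),
               list(pos_to_neg = 0L, neg_to_pos = 0L,
                    pos_magnitude_increase = 0L, neg_magnitude_increase = 0L))
  set.seed(3)
  a <- matrix(rnorm(400), 20)
  b <- matrix(rnorm(400), 20)
  got <- sign_change_stats(a, b)
  brute <- c(0L, 0L, 0L, 0L)
  for (k in seq_along(a)) {
    if (a[k] > 0 && b[k] < 0) brute[1] <- brute[1] + 1L
    if (a[k] < 0 && b[k] > 0) brute[2] <- brute[2] + 1L
    if (a[k] > 0 && b[k] > a[k]) brute[3] <- brute[3] + 1L
    if (a[k] < 0 && b[k] < a[k]) brute[4] <- brute[4] + 1L
  }
  expect_equal(unlist(got, use.names = FALSE), brute)
  expect_error(sign_change_stats(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("gradient magnitude recording averages over unmasked entries", {
  expect_equal(record_gradient_magnitude(matrix(0, 3, 3)), 0)
  g <- matrix(c(-2, 4), 1, 2)
  expect_equal(record_gradient_magnitude(g, matrix(1, 1, 2)), 3)
  expect_true(is.na(record_gradient_magnitude(g, matrix(0, 1, 2))))
  # masked entries do not dilute the average
  g2 <- matrix(c(-2, 4, 100, 100), 2, 2)
  m2 <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(record_gradient_magnitude(g2, m2), 3)
})
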