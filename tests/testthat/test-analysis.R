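test_that("nonzero fractions equal a brute-force tally", {
  expect_equal(nonzero_fraction(matrix(0, 4, 10))$mean, 0)
  half <- cbind(matrix(0.5, 3, 5), matrix(0, 3, 5))
  expect_equal(nonzero_fraction(half)$per_sample, rep(0.5, 3))
  set.seed(4)
  r <- matrix(pmax(rnorm(200), 0), 10, 20)
  nf <- nonzero_fraction(r)
  brute <- sapply(1:10, function(i) sum(r[i, ] > 0) / 20)
  expect_equal(nf$per_sample, brute)
  expect_equal(nf$mean, mean(brute))
  expect_error(nonzero_fraction(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("activation magnitude summaries recompute moments correctly", {
  empty <- activation_magnitude_summary(matrix(0, 3, 3))
  expect_equal(nrow(empty$histogram), 0)
  expect_equal(empty$n_nonzero, 0L)
  one <- activation_magnitude_summary(matrix(c(2, 0, 0, 0), 2, 2))
  expect_equal(one$mean, 2)
  set.seed(5)
  r <- matrix(pmax(rnorm(300), 0), 15, 20)
  s <- activation_magnitude_summary(r)
  vals <- r[r != 0]
  expect_equal(s$mean, mean(vals))
  expect_equal(s$sd, sd(vals))
  expect_equal(sum(s$histogram$count), length(vals))
})

test_that("k-NN MI agrees with the exhaustive histogram oracle on discrete data", {
  set.seed(11)
  n <- 3000
  x <- sample(0:2, n, replace = TRUE)
  y <- ifelse(runif(n) < 0.85, x, sample(0:2, n, replace = TRUE))
  oracle <- histogram_mi(x, y)
  set.seed(12)
  est <- knn_mutual_information(x, y, k = 3)
  # estimator tolerance for strongly dependent, low-cardinality discrete
  # pairs at this n: 0.1 nat
  expect_lt(abs(est - oracle), 0.1)

  # a second, weaker dependence level
  y2 <- ifelse(runif(n) < 0.5, x, sample(0:2, n, replace = TRUE))
  expect_lt(abs(knn_mutual_information(x, y2) - histogram_mi(x, y2)), 0.1)
})

test_that("MI is near zero for independent nodes and large for near-copies", {
  set.seed(13)
  x <- rnorm(4000)
  y <- rnorm(4000)
  expect_lt(abs(knn_mutual_information(x, y)), 0.05)
  copy_mi <- knn_mutual_information(x, x + rnorm(4000, sd = 1e-3))
  expect_gt(copy_mi, 2)
  # zero-variance guard
  expect_equal(knn_mutual_information(rep(1, 100), rnorm(100)), 0)
})

test_that("pairwise MI sampling is seeded, distinct and clipped at zero", {
  set.seed(14)
  rec <- matrix(rnorm(80 * 12), 80, 12)
  a <- pairwise_mutual_information(rec, n_pairs = 20, seed = 3)
  b <- pairwise_mutual_information(rec, n_pairs = 20, seed = 3)
  expect_identical(a$mi, b$mi)
  expect_true(all(a$mi >= 0))
  key <- paste(a$pairs[, 1], a$pairs[, 2])
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(a$pairs[, 1] < a$pairs[, 2]))
  # requesting more pairs than exist returns them all
  all_pairs <- pairwise_mutual_information(rec[, 1:4], n_pairs = 100, seed = 1)
  expect_equal(nrow(all_pairs$pairs), 6)
})

test_that("activation correlations recover exact duplicate and inverted nodes", {
  set.seed(15)
  base <- rnorm(60)
  rec <- cbind(base, base, -2 * base, rnorm(60), rep(1, 60))
  colnames(rec) <- NULL
  res <- activation_correlations(rec, n_pairs = 100, seed = 2)
  expect_equal(res$n_constant, 1L)
  expect_true(all(res$r >= -1 & res$r <= 1))
  expect_true(any(abs(res$r - 1) < 1e-12))   # duplicated columns
  expect_true(any(abs(res$r + 1) < 1e-12))   # anti-proportional columns
  expect_error(activation_correlations(matrix(1, 5, 3)), "varying")
})

test_that("dropout keeps the fraction-0 identity and fraction-1 degeneracy", {
  task <- tiny_task(n_test = 80)
  net <- tiny_network(seed = 16)
  base <- evaluate_accuracy(net, task$test)
  res <- dropout_robustness(net, task$test, c(0, 1), seed = 4)
  expect_identical(res$accuracy[res$fraction == 0], base)
  # all nodes dropped: logits all zero, tie rule forces class 0
  expect_equal(res$accuracy[res$fraction == 1],
               mean(task$test$labels == 0))
})

test_that("dropout accuracy matches exhaustive enumeration on a 3-node voter", {
  # hand-built network state: 3 hidden nodes vote for class 0 or 1 through
  # the readout; we enumerate all subsets of dropped nodes exactly.
  record <- matrix(c(1, 0.5, 0.2), 1, 3)  # one sample's activations
  w_out <- matrix(c(1, 0, 0, 0, 1, 1), 3, 2)  # node 1 -> class 0; 2,3 -> class 1
  net <- tiny_network(n_hidden = 3, p = 1, input_dim = 2, n_classes = 2,
                      seed = 17)
  net$w_out <- w_out
  label <- 1L
  # enumeration oracle: drop exactly 1 of 3 nodes (fraction 1/3), uniform
  # over the 3 subsets; prediction per subset by argmax with tie -> 0
  accs <- sapply(1:3, function(drop) {
    h <- record
    h[drop] <- 0
    logits <- h %*% w_out
    as.integer(which.max(logits) - 1L == label)
  })
  oracle <- mean(accs)  # = 1/3: only dropping node 1 lets class 1 win
  ds <- sequence_dataset(array(runif(2), c(1, 1, 2)), label, n_classes = 2)
  got <- dropout_robustness(net, ds, fractions = 1 / 3, n_repeats = 600,
                            seed = 5, record = record)
  expect_lt(abs(got$accuracy - oracle), 0.1)
})

test_that("training delay follows its definition including the never case", {
  d <- training_delay(c(0.10, 0.11, 0.35, 0.60), n_classes = 10, margin = 0.02)
  expect_equal(d$first_above_chance, 3L)
  expect_equal(d$delay_epochs, 2L)
  expect_true(d$crossed)

  immediate <- training_delay(c(0.90, 0.95), n_classes = 10)
  expect_equal(immediate$first_above_chance, 1L)
  expect_equal(immediate$delay_epochs, 0L)

  never <- training_delay(rep(0.10, 6), n_classes = 10)
  expect_false(never$crossed)
  expect_equal(never$delay_epochs, Inf)

  # invariant to appending epochs after the first crossing
  d2 <- training_delay(c(0.10, 0.11, 0.35, 0.60, 0.10, 0.99), n_classes = 10)
  expect_equal(d2$first_above_chance, d$first_above_chance)

  # sustained crossing requires two consecutive epochs above threshold
  spike <- training_delay(c(0.10, 0.30, 0.10, 0.40, 0.50), n_classes = 10,
                          sustained = TRUE)
  expect_equal(spike$first_above_chance, 4L)

  expect_error(training_delay(numeric(0), 10), "empty")
  expect_error(training_delay(c(0.5), 10, margin = -1), "margin")
})
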